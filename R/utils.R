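`%||%` <- function(a, b) if (is.null(a)) b else a

# standard comment header written at the top of every output file:
# version, seed (when one applies) and a hash of the echoed configuration
output_header <- function(config = list(), seed = NULL) {
  config_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  hash <- sum(utf8ToInt(as.character(config_json)) *
                (seq_len(nchar(config_json)) %% 97 + 1)) %% 1e9
  c(sprintf("# burstkin %s", as.character(utils::packageVersion("burstkin"))),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("# config_hash: %09d", hash),
    sprintf("# config: %s", config_json))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p) - log1p(-p)
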