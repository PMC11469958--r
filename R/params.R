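#' Telegraph-model kinetic parameters
#'
#' Bundles the four rate constants of the two-state telegraph model of
#' transcription: the promoter switches on at rate `k_on` and off at rate
#' `k_off` (both per hour), synthesises RNA at `k_syn` molecules per hour
#' while on, and labelled molecules degrade at rate `k_d` per hour.
#'
#' @param k_on On-switching rate (per hour).
#' @param k_off Off-switching rate (per hour).
#' @param k_syn Synthesis rate while on (molecules per hour).
#' @param k_d Degradation rate (per hour).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(k_on = 1, k_off = 5, k_syn = 20, k_d = 0.065)
#' @export
kinetic_params <- function(k_on, k_off, k_syn, k_d) {
  p <- list(k_on = as.numeric(k_on), k_off = as.numeric(k_off),
            k_syn = as.numeric(k_syn), k_d = as.numeric(k_d))
  rates <- unlist(p)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("kinetic parameters must be finite and non-negative")
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "telegraph kinetics: k_on=%.4g k_off=%.4g k_syn=%.4g k_d=%.4g (per hour)\n",
    x$k_on, x$k_off, x$k_syn, x$k_d))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  kinetic_params(x[["k_on"]], x[["k_off"]], x[["k_syn"]], x[["k_d"]])
}

#' Promoter occupancy of a telegraph gene
#'
#' Stationary fraction of time spent in the on state,
#' `k_on / (k_on + k_off)`.
#'
#' @param params A [kinetic_params()] object.
#' @return Occupancy in \[0, 1\].
#' @export
occupancy <- function(params) {
  params <- as_kinetic_params(params)
  if (params$k_on + params$k_off <= 0) {
    stop("occupancy requires k_on + k_off > 0")
  }
  params$k_on / (params$k_on + params$k_off)
}

#' Derived bursting quantities
#'
#' Computes the standard derived quantities of the telegraph model:
#' * occupancy (fraction of time on) `k_on / (k_on + k_off)`,
#' * burst size (RNAs per on state) `k_syn / k_off`,
#' * burst frequency (on states per hour) `1 / (1/k_on + 1/k_off)`,
#' * expression rate (RNAs per hour) `k_syn * k_on / (k_on + k_off)`.
#'
#' @param params A [kinetic_params()] object with `k_on > 0` and `k_off > 0`.
#' @return A list of class `derived_kinetics` with fields `occupancy`,
#'   `burst_size`, `burst_frequency` and `expression_rate`.
#' @examples
#' derived_kinetics(kinetic_params(1, 1, 10, 0.065))
#' @export
derived_kinetics <- function(params) {
  params <- as_kinetic_params(params)
  if (params$k_on <= 0 || params$k_off <= 0) {
    stop("derived kinetics require k_on > 0 and k_off > 0")
  }
  occ <- params$k_on / (params$k_on + params$k_off)
  structure(list(
    occupancy = occ,
    burst_size = params$k_syn / params$k_off,
    burst_frequency = 1 / (1 / params$k_on + 1 / params$k_off),
    expression_rate = params$k_syn * occ
  ), class = "derived_kinetics")
}

#' @export
print.derived_kinetics <- function(x, ...) {
  cat(sprintf(paste0(
    "occupancy %.4g | burst size %.4g RNAs | burst frequency %.4g /h | ",
    "expression rate %.4g RNAs/h\n"),
    x$occupancy, x$burst_size, x$burst_frequency, x$expression_rate))
  invisible(x)
}
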