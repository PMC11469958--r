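#' Read tagged alignments into a per-position table
#'
#' Loads a coordinate-sorted SAM/BAM file carrying cell, UMI and gene tags
#' and expands every aligned read into one row per aligned reference
#' position, with the reference base reconstructed from the MD tag. This is
#' the entry point of the molecule-calling stage; downstream steps
#' ([consensus_molecules()], [molecule_conversion_stats()]) operate on the
#' returned table.
#'
#' Only reads whose UMI group maps to a single gene are useful downstream;
#' multi-locus UMI groups are discarded there with a counter. CIGAR
#' operations M/=/X are consumed base by base, I and S advance the query,
#' D and N the reference.
#'
#' @param path SAM or BAM path (SAM is converted on the fly).
#' @param cell_tag,umi_tag,gene_tag Two-letter tag names holding the cell
#'   barcode, error-corrected UMI and assigned gene.
#' @return Data.frame with columns `cell`, `umi`, `gene`, `read`, `strand`,
#'   `chrom`, `pos` (1-based reference), `ref`, `obs`, `qual`.
#' @export
read_tagged_sam <- function(path, cell_tag = "CB", umi_tag = "UB",
                            gene_tag = "GE") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("MD", cell_tag, umi_tag, gene_tag))
  bam <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(bam$qname)
  if (n == 0) {
    return(data.frame(cell = character(0), umi = character(0),
                      gene = character(0), read = character(0),
                      strand = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      obs = character(0), qual = numeric(0)))
  }
  seqs <- as.character(bam$seq)
  quals <- methods::as(bam$qual, "IntegerList")
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    md <- bam$tag$MD[r]
    if (is.na(bam$pos[r]) || is.na(md)) next
    aln <- align_read_positions(bam$cigar[r], bam$pos[r], seqs[r], md)
    if (is.null(aln)) next
    q <- quals[[r]]
    rows[[r]] <- data.frame(
      cell = bam$tag[[cell_tag]][r] %||% NA_character_,
      umi = bam$tag[[umi_tag]][r] %||% NA_character_,
      gene = bam$tag[[gene_tag]][r] %||% NA_character_,
      read = bam$qname[r],
      strand = if (bitwAnd(bam$flag[r], 16L) > 0L) "-" else "+",
      chrom = as.character(bam$rname[r]),
      pos = aln$rpos, ref = aln$ref, obs = aln$obs,
      qual = q[aln$qpos], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# walk CIGAR + MD to produce aligned (query, reference) position pairs with
# reference bases; returns NULL for unusable records
align_read_positions <- function(cigar, pos, seq, md) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0) return(NULL)
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  kinds <- sub("\\d+", "", ops)
  qpos <- integer(0)
  rpos <- integer(0)
  q <- 0L
  rp <- pos - 1L
  for (i in seq_along(ops)) {
    L <- lens[i]
    k <- kinds[i]
    if (k %in% c("M", "=", "X")) {
      qpos <- c(qpos, q + seq_len(L))
      rpos <- c(rpos, rp + seq_len(L))
      q <- q + L
      rp <- rp + L
    } else if (k %in% c("I", "S")) {
      q <- q + L
    } else if (k %in% c("D", "N")) {
      rp <- rp + L
    }  # H, P consume nothing here
  }
  obs <- substring(seq, qpos, qpos)
  ref <- obs
  # MD walk: numbers = matches, letters = mismatched reference base,
  # ^XYZ = deleted reference (not aligned to the query, skip)
  tokens <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]",
                                    md))[[1]]
  ai <- 1L  # index into the aligned (M/=/X) positions
  for (tok in tokens) {
    if (grepl("^\\d+$", tok)) {
      ai <- ai + as.integer(tok)
    } else if (startsWith(tok, "^")) {
      # deletion: reference bases absent from the query; nothing aligned
    } else {
      if (ai > length(ref)) return(NULL)
      ref[ai] <- toupper(tok)
      ai <- ai + 1L
    }
  }
  list(qpos = qpos, rpos = rpos, ref = ref, obs = toupper(obs))
}

#' Consensus molecule sequences from UMI-grouped reads
#'
#' Groups aligned read positions by (cell, UMI, gene) and merges each group
#' into one consensus molecule with [merge_read_group()]. UMI groups whose
#' reads span more than one gene are discarded and counted in
#' `attr(, "n_multilocus")`.
#'
#' @param read_positions Output of [read_tagged_sam()].
#' @return Data.frame with `cell`, `umi`, `gene`, `strand`, `pos`, `ref`,
#'   `base`, `qual` (one row per covered position per molecule).
#' @export
consensus_molecules <- function(read_positions) {
  rp <- read_positions[!is.na(read_positions$cell) &
                         !is.na(read_positions$umi) &
                         !is.na(read_positions$gene), , drop = FALSE]
  key_cu <- paste(rp$cell, rp$umi, sep = "\r")
  genes_per_umi <- tapply(rp$gene, key_cu, function(g) length(unique(g)))
  multi <- names(genes_per_umi)[genes_per_umi > 1]
  rp <- rp[!(key_cu %in% multi), , drop = FALSE]
  out <- lapply(split(rp, paste(rp$cell, rp$umi, rp$gene, sep = "\r")),
                function(g) {
    cons <- merge_read_group(data.frame(read = g$read, pos = g$pos,
                                        base = g$obs, qual = g$qual))
    ref_at <- g$ref[match(cons$pos, g$pos)]
    data.frame(cell = g$cell[1], umi = g$umi[1], gene = g$gene[1],
               strand = g$strand[1], pos = cons$pos, ref = ref_at,
               base = cons$base, qual = cons$qual,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_multilocus") <- length(multi)
  res
}

#' Per-molecule conversion and allele statistics
#'
#' Reduces consensus molecules to the counts that drive new-RNA calling:
#' convertible sites are covered reference T positions for plus-strand
#' genes (reference A for minus-strand), conversions are T>C (A>G)
#' consensus mismatches at those sites; masked positions and SNP positions
#' contribute to neither count. The complementary C>T and G>A mismatch
#' counts (error-process proxies) and the exclusive maternal/paternal SNP
#' evidence are tallied alongside.
#'
#' @param cons Output of [consensus_molecules()].
#' @param masked_positions Integer vector of positions to exclude.
#' @param snps Optional `snp_table` ([read_snp_table()]).
#' @return Data.frame with one row per molecule: `cell`, `gene`, `umi`,
#'   `n_convertible`, `n_converted`, `n_c_sites`, `n_c_to_t`, `n_g_sites`,
#'   `n_g_to_a`, `n_maternal`, `n_paternal`, `allele`.
#' @export
molecule_conversion_stats <- function(cons, masked_positions = integer(0),
                                      snps = NULL) {
  is_snp <- if (!is.null(snps) && nrow(snps) > 0) {
    cons$pos %in% snps$pos
  } else rep(FALSE, nrow(cons))
  snp_m <- snp_p <- rep(FALSE, nrow(cons))
  if (any(is_snp)) {
    idx <- match(cons$pos, snps$pos)
    snp_m <- is_snp & cons$base == snps$maternal[idx]
    snp_p <- is_snp & cons$base == snps$paternal[idx]
  }
  usable <- !(cons$pos %in% masked_positions) & !is_snp &
    cons$base != "N"
  conv_site <- usable & ((cons$strand == "+" & cons$ref == "T") |
                           (cons$strand == "-" & cons$ref == "A"))
  converted <- conv_site & ((cons$strand == "+" & cons$base == "C") |
                              (cons$strand == "-" & cons$base == "G"))
  c_site <- usable & cons$ref == "C"
  c_to_t <- c_site & cons$base == "T"
  g_site <- usable & cons$ref == "G"
  g_to_a <- g_site & cons$base == "A"
  key <- paste(cons$cell, cons$gene, cons$umi, sep = "\r")
  agg <- function(x) as.integer(tapply(x, key, sum))
  # tapply orders by sorted key; build the frame in that order
  ukey <- sort(unique(key))
  fi <- match(ukey, key)
  mol <- data.frame(cell = cons$cell[fi], gene = cons$gene[fi],
                    umi = cons$umi[fi],
                    n_convertible = agg(conv_site),
                    n_converted = agg(converted),
                    n_c_sites = agg(c_site), n_c_to_t = agg(c_to_t),
                    n_g_sites = agg(g_site), n_g_to_a = agg(g_to_a),
                    n_maternal = agg(snp_m), n_paternal = agg(snp_p),
                    stringsAsFactors = FALSE)
  mol$allele <- genotype_molecule(mol$n_maternal, mol$n_paternal)
  rownames(mol) <- NULL
  mol
}

#' Per-position mismatch statistics for artifact masking
#'
#' Tallies, per gene and reference position, how many consensus molecules
#' cover the position and how many show the conversion-sense mismatch
#' (T>C on plus-strand genes, A>G on minus-strand), the input to
#' [mask_artifact_positions()].
#'
#' @param cons Output of [consensus_molecules()] for one gene.
#' @return Data.frame with `pos`, `n_molecules`, `n_mismatch`.
#' @export
position_mismatch_stats <- function(cons) {
  covered <- cons$base != "N"
  sense_site <- covered & ((cons$strand == "+" & cons$ref == "T") |
                             (cons$strand == "-" & cons$ref == "A"))
  mism <- sense_site & ((cons$strand == "+" & cons$base == "C") |
                          (cons$strand == "-" & cons$base == "G"))
  pos <- sort(unique(cons$pos[sense_site]))
  data.frame(pos = pos,
             n_molecules = as.integer(
               tapply(sense_site, cons$pos, sum)[as.character(pos)]),
             n_mismatch = as.integer(
               tapply(mism, cons$pos, sum)[as.character(pos)]))
}
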