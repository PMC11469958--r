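# shared fixtures, built lazily once per test run

.fixtures <- new.env(parent = emptyenv())

# mid-resolution lookup table over the published axis ranges (full k_on
# span; coarser k_syn/k_off axes, whose resolution matters little because
# initialisation is weakly identified along that direction)
shared_lookup <- function() {
  if (is.null(.fixtures$lookup)) {
    grid <- lookup_grid_spec(n_kon = 49, n_ksyn = 10, n_koff = 12)
    .fixtures$lookup <- build_lookup_table(grid, seed = 7)
  }
  .fixtures$lookup
}

# counts sampled from the transient PMF
sample_counts <- function(params, n_cells, label_time = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- burstkin:::pmf_vector(params, label_time, tol = 1e-11)
  sample.int(length(p), n_cells, replace = TRUE, prob = p) - 1L
}

mid_grid_params <- function() kinetic_params(0.8944, 77.46, 22.36, 0.065)

# tiny lookup table for initialisation-logic tests (fast to build)
tiny_lookup <- function() {
  if (is.null(.fixtures$tiny)) {
    grid <- lookup_grid_spec(n_kon = 7, kon_range = c(0.05, 5),
                             n_ksyn = 5, ksyn_range = c(2, 60),
                             n_koff = 6, koff_range = c(2, 200))
    .fixtures$tiny <- build_lookup_table(grid, seed = 3)
  }
  .fixtures$tiny
}

# a small SAM file exercising tags, CIGAR and MD parsing; returns the path
write_test_sam <- function(path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    # molecule 1 (cellA/umi1, geneX, + strand): two overlapping reads;
    # read r1 has T>C at pos 105 (MD shows ref T), both cover 101-110/106-115
    paste("r1", 0, "chr1", 101, 60, "10M", "*", 0, 0,
          "ACGTCTGCAT", "IIIIIIIIII", "MD:Z:4T5",
          "CB:Z:cellA", "UB:Z:umi1", "GE:Z:geneX", sep = "\t"),
    paste("r2", 0, "chr1", 106, 60, "10M", "*", 0, 0,
          "TGCATAGGCA", "IIIIIIIIII", "MD:Z:10",
          "CB:Z:cellA", "UB:Z:umi1", "GE:Z:geneX", sep = "\t"),
    # molecule 2 (cellA/umi2, geneX): clean read, covers a SNP at pos 210
    paste("r3", 0, "chr1", 201, 60, "5M2D5M", "*", 0, 0,
          "ACGTAGGCAT", "IIIIIIIIII", "MD:Z:5^CA2A2",
          "CB:Z:cellA", "UB:Z:umi2", "GE:Z:geneX", sep = "\t"),
    # multi-locus UMI group (discarded): same cell/umi, two genes
    paste("r4", 0, "chr1", 301, 60, "6M", "*", 0, 0,
          "ACGTAC", "IIIIII", "MD:Z:6",
          "CB:Z:cellB", "UB:Z:umi3", "GE:Z:geneX", sep = "\t"),
    paste("r5", 0, "chr1", 501, 60, "6M", "*", 0, 0,
          "ACGTAC", "IIIIII", "MD:Z:6",
          "CB:Z:cellB", "UB:Z:umi3", "GE:Z:geneY", sep = "\t"))
  writeLines(lines, path)
  path
}
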