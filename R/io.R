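#' Read and write gene-by-cell count matrices
#'
#' Lossless round-trip IO for integer count matrices in two dialects: TSV
#' (genes in rows with a header row of cell names and a leading `gene`
#' column; comment header lines start with `#`) and MatrixMarket (`.mtx`
#' triplet file plus `<prefix>_rows.txt` / `<prefix>_cols.txt` name files).
#'
#' @param mat Integer matrix with dimnames.
#' @param path Output path (for MTX, the `.mtx` path; name files are placed
#'   alongside).
#' @param format `"tsv"` or `"mtx"`; inferred from the extension when
#'   missing.
#' @param seed Optional seed echoed into the TSV header.
#' @return `write_count_matrix()` the path invisibly;
#'   `read_count_matrix()` the integer matrix.
#' @export
write_count_matrix <- function(mat, path, format = NULL, seed = NULL) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0) || any(mat != floor(mat))) {
    stop("counts must be non-negative integers")
  }
  format <- format %||% (if (grepl("\\.mtx$", path)) "mtx" else "tsv")
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(output_header(list(kind = "count_matrix",
                                  dim = dim(mat)), seed = seed), con)
    genes <- rownames(mat) %||% sprintf("gene%d", seq_len(nrow(mat)))
    cells <- colnames(mat) %||% sprintf("cell%d", seq_len(ncol(mat)))
    writeLines(paste(c("gene", cells), collapse = "\t"), con)
    if (nrow(mat) > 0) {
      body <- apply(mat, 1, paste, collapse = "\t")
      writeLines(paste(genes, body, sep = if (ncol(mat)) "\t" else ""), con)
    }
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(mat,
                                                           sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    base <- sub("\\.mtx$", "", path)
    writeLines(rownames(mat) %||% paste0("gene", seq_len(nrow(mat))),
               paste0(base, "_rows.txt"))
    writeLines(colnames(mat) %||% paste0("cell", seq_len(ncol(mat))),
               paste0(base, "_cols.txt"))
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.mtx$", path)) "mtx" else "tsv")
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             colClasses = NA)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(mat) <- "integer"
    rownames(mat) <- tab[[1]]
    mat
  } else {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "integer"
    base <- sub("\\.mtx$", "", path)
    rows <- paste0(base, "_rows.txt")
    cols <- paste0(base, "_cols.txt")
    if (file.exists(rows)) rownames(m) <- readLines(rows)
    if (file.exists(cols)) colnames(m) <- readLines(cols)
    m
  }
}

#' Write / read allelic count matrices
#'
#' An [allelic_counts()] object is stored as two count matrices (suffixes
#' `_maternal` and `_paternal`) plus a gene coordinate TSV (suffix
#' `_genes`).
#'
#' @param ac An [allelic_counts()] object.
#' @param prefix Path prefix for the three files.
#' @param seed Optional seed echoed into headers.
#' @return `write_allelic_counts()` the prefix invisibly;
#'   `read_allelic_counts()` the reconstructed object.
#' @export
write_allelic_counts <- function(ac, prefix, seed = NULL) {
  stopifnot(inherits(ac, "allelic_counts"))
  write_count_matrix(ac$maternal, paste0(prefix, "_maternal.tsv"),
                     seed = seed)
  write_count_matrix(ac$paternal, paste0(prefix, "_paternal.tsv"),
                     seed = seed)
  con <- file(paste0(prefix, "_genes.tsv"), "w")
  on.exit(close(con))
  writeLines(output_header(list(kind = "gene_coords"), seed = seed), con)
  utils::write.table(ac$coords, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_allelic_counts
#' @export
read_allelic_counts <- function(prefix) {
  m <- read_count_matrix(paste0(prefix, "_maternal.tsv"))
  p <- read_count_matrix(paste0(prefix, "_paternal.tsv"))
  coords <- utils::read.table(paste0(prefix, "_genes.tsv"), header = TRUE,
                              sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE)
  allelic_counts(m, p, coords)
}

#' Read gene coordinates from a BED file
#'
#' BED is 0-based half-open; the returned `start` keeps the 0-based
#' convention used internally. Columns beyond the sixth are ignored.
#'
#' @param path BED file path.
#' @return Data.frame with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED file needs at least 4 columns (name)")
  data.frame(gene = tab[[4]], chrom = tab[[1]], start = tab[[2]],
             end = tab[[3]],
             strand = if (ncol(tab) >= 6) tab[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Read a strain-discriminating SNP table from a VCF subset
#'
#' Expects biallelic SNV records where REF carries the maternal-strain base
#' and the first ALT allele the paternal-strain base (the usual encoding of
#' a validated F1-cross variant subset against the maternal reference).
#' Positions are 1-based as in VCF.
#'
#' @param path VCF path (plain text).
#' @return Data.frame of class `snp_table`: `chrom`, `pos`, `maternal`,
#'   `paternal`.
#' @export
read_snp_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(structure(data.frame(chrom = character(0), pos = integer(0),
                                maternal = character(0),
                                paternal = character(0)),
                     class = c("snp_table", "data.frame")))
  }
  f <- strsplit(lines, "\t")
  tab <- data.frame(chrom = vapply(f, `[`, "", 1),
                    pos = as.integer(vapply(f, `[`, "", 2)),
                    maternal = toupper(vapply(f, `[`, "", 4)),
                    paternal = toupper(sub(",.*", "",
                                           vapply(f, `[`, "", 5))),
                    stringsAsFactors = FALSE)
  keep <- nchar(tab$maternal) == 1 & nchar(tab$paternal) == 1 &
    tab$maternal != tab$paternal
  structure(tab[keep, , drop = FALSE],
            class = c("snp_table", "data.frame"))
}
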