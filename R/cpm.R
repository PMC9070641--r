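#' Counts-per-million low-expression filter
#'
#' Mirrors the standard RNA-seq prefilter: a gene is kept when its CPM
#' (count x 1e6 / library size) reaches `min_cpm` in at least `min_samples`
#' samples; the default (`min_cpm = 1`, `min_samples = 1`) drops genes that
#' never reach one count per million in any library. The boundary is
#' inclusive: CPM exactly equal to `min_cpm` keeps the gene.
#'
#' @param counts Matrix of non-negative integer counts with gene rownames
#'   and sample colnames, or a [count_matrix()].
#' @param min_cpm Minimum CPM, default 1.
#' @param min_samples Minimum number of samples in which the CPM threshold
#'   must be met, default 1.
#' @return A list with sorted character vectors `kept` and `dropped`
#'   forming a partition of the input gene ids, plus the numeric `cpm`
#'   matrix used.
#' @examples
#' cnt <- matrix(c(0, 5, 0, 8), 2, 2,
#'   dimnames = list(c("G1", "G2"), c("S1", "S2")))
#' cpm_filter(cnt)$kept
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 1L) {
  counts <- validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stopf(
      "sample '%s' has zero library size",
      colnames(counts)[which(lib <= 0)[1L]]
    )
  }
  if (min_samples < 1L || min_samples > ncol(counts)) {
    stopf("min_samples must be between 1 and the number of samples")
  }
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  ok <- rowSums(cpm >= min_cpm) >= min_samples
  list(
    kept = sort(rownames(counts)[ok]),
    dropped = sort(rownames(counts)[!ok]),
    cpm = cpm
  )
}

#' Validated count matrix
#'
#' @param counts Numeric matrix of non-negative integral counts with gene
#'   rownames and sample colnames.
#' @return The matrix, validated.
#' @export
count_matrix <- function(counts) validate_counts(counts)

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry gene rownames and sample colnames")
  }
  assert_character_ids(rownames(counts), "gene ids")
  assert_character_ids(colnames(counts), "sample ids")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stopf("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stopf("counts must be integral")
  }
  counts
}

#' Read a raw-count matrix from TSV
#'
#' Same layout as [read_expression_table()] (genes in rows, first column
#' gene id) but validated as non-negative integral counts.
#'
#' @param path File path.
#' @return A validated count matrix.
#' @export
read_count_table <- function(path) {
  validate_counts(read_numeric_table(path, what = "count"))
}
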