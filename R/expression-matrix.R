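#' Construct a validated expression matrix
#'
#' The substrate of all correlation computations: a genes-by-samples numeric
#' matrix of normalized expression values (e.g. log-CPM) plus per-sample
#' metadata giving the time point and biological replicate of each library.
#' The package neither applies nor requires a particular normalization; it
#' assumes the values it is handed are already on a scale where Pearson
#' correlation is meaningful.
#'
#' @param values Numeric matrix, one row per gene, with unique rownames
#'   (gene ids) and colnames (sample ids); all entries must be finite.
#' @param sample_meta Data frame with columns `sample_id`, `time_point`,
#'   `replicate` and optionally `condition`, one row per sample.
#'
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` (the matrix) and `sample_meta` (data frame aligned to the
#'   matrix columns).
#' @examples
#' vals <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' meta <- data.frame(sample_id = paste0("S", 1:4),
#'   time_point = c("T1", "T1", "T2", "T2"), replicate = c(1, 2, 1, 2))
#' em <- expression_matrix(vals, meta)
#' dim(em$values)
#' @export
expression_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("values must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("values must carry gene ids as rownames and sample ids as colnames")
  }
  assert_character_ids(gene_ids, "gene ids")
  assert_character_ids(sample_ids, "sample ids")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf(
      "non-finite expression value at gene '%s', sample '%s'",
      gene_ids[bad[1L]], sample_ids[bad[2L]]
    )
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  needed <- c("sample_id", "time_point", "replicate")
  missing_cols <- setdiff(needed, names(sample_meta))
  if (length(missing_cols) > 0L) {
    stopf(
      "sample metadata lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (!("condition" %in% names(sample_meta))) {
    sample_meta$condition <- "unspecified"
  }
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  assert_character_ids(sample_meta$sample_id, "metadata sample ids")
  absent <- setdiff(sample_ids, sample_meta$sample_id)
  if (length(absent) > 0L) {
    stopf(
      "samples missing from metadata: %s",
      paste(utils::head(absent, 5L), collapse = ", ")
    )
  }
  sample_meta <- sample_meta[
    match(sample_ids, sample_meta$sample_id),
    c("sample_id", "time_point", "replicate", "condition"),
    drop = FALSE
  ]
  if (anyNA(sample_meta$time_point) || anyNA(sample_meta$replicate)) {
    stopf("every sample needs non-missing time_point and replicate")
  }
  rownames(sample_meta) <- NULL
  structure(
    list(values = values, sample_meta = sample_meta),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples (%d time points, %d replicates)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$sample_meta$time_point)),
    length(unique(x$sample_meta$replicate))
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV
#'
#' Expression tables are tab-separated UTF-8 text: a header row of sample
#' ids, first column gene ids, one row per gene. Lines starting with `#`
#' are ignored. The metadata table maps `sample_id` to `time_point`,
#' `replicate` and optionally `condition`.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Path to the sample-metadata TSV. Required: correlations
#'   over samples are only interpretable when the design is known.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, meta_path) {
  if (missing(meta_path) || is.null(meta_path)) {
    stopf("meta_path is required: every sample needs time/replicate metadata")
  }
  values <- read_numeric_table(path, what = "expression")
  meta <- utils::read.delim(
    meta_path,
    sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
    check.names = FALSE
  )
  expression_matrix(values, meta)
}

#' Write an expression matrix (and optionally metadata) to TSV
#'
#' Values are written at full double precision so that a write/read
#' round-trip reproduces them to at least 12 decimal places.
#'
#' @param em An [expression_matrix()].
#' @param path Output path for the expression TSV.
#' @param meta_path Optional output path for the sample-metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(em, path, meta_path = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  write_numeric_table(em$values, path, id_col = "gene_id")
  if (!is.null(meta_path)) {
    utils::write.table(
      em$sample_meta, meta_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

# Shared reader for genes-in-rows numeric TSV tables (expression or counts).
read_numeric_table <- function(path, what = "numeric") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(
    path,
    sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character"
  )
  if (ncol(tab) < 2L) stopf("%s table needs an id column plus data: %s",
                            what, path)
  ids <- tab[[1L]]
  assert_character_ids(ids, sprintf("gene ids in %s", basename(path)))
  sample_ids <- colnames(tab)[-1L]
  assert_character_ids(sample_ids, sprintf("sample ids in %s", basename(path)))
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- is.na(num) & !(cells %in% c("NA", "NaN"))
  if (any(bad)) {
    where <- which(bad, arr.ind = TRUE)[1L, ]
    stopf(
      "non-numeric value '%s' at row %d (gene '%s'), column '%s' of %s",
      cells[where[1L], where[2L]], where[1L], ids[where[1L]],
      sample_ids[where[2L]], basename(path)
    )
  }
  dimnames(num) <- list(ids, sample_ids)
  num
}

write_numeric_table <- function(mat, path, id_col = "gene_id") {
  txt <- matrix(fmt_full(mat), nrow = nrow(mat), dimnames = dimnames(mat))
  out <- data.frame(
    id = rownames(mat),
    txt,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- c(id_col, colnames(mat))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
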