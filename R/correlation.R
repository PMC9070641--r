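#' Pearson correlation with exact t-test significance
#'
#' Sample Pearson correlation between two expression profiles, with a
#' two-sided p-value from the exact transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. All
#' libraries (time points x replicates) are treated as observations.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return A list with elements `cc` and `p_value`.
#' @examples
#' pearson_cc(c(1, 2, 3, 4), c(2, 4, 6, 8))$cc
#' @export
pearson_cc <- function(x, y) {
  check_profile(x, "x")
  check_profile(y, "y")
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 observations, got %d", n)
  cc <- stats::cor(x, y)
  list(cc = cc, p_value = cor_pvalue(cc, n))
}

check_profile <- function(v, name) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stopf("vector '%s' must be finite numeric", name)
  }
  if (stats::var(v) == 0) {
    stopf("vector '%s' has zero variance", name)
  }
  invisible(v)
}

# Two-sided p-value of the Pearson correlation t-test; vectorized.
cor_pvalue <- function(cc, n) {
  df <- n - 2L
  p <- rep(NA_real_, length(cc))
  sat <- !is.na(cc) & abs(cc) >= 1
  p[sat] <- 0
  ok <- !is.na(cc) & !sat
  tstat <- cc[ok] * sqrt(df / (1 - cc[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p
}

#' First-order partial correlation from pairwise correlations
#'
#' The triple-gene formula at the core of the algorithm: the correlation
#' between genes x and y after removing the linear effect of a conditioning
#' gene z,
#' \deqn{r_{xy|z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{1 - r_{xz}^2}\sqrt{1 - r_{yz}^2}}.}
#' When either denominator term `1 - r^2` is at or below
#' `epsilon_degenerate` — z is (numerically) perfectly correlated with x or
#' y, so the residual has no variance — the value is undefined and `NA` is
#' returned.
#'
#' @param r_xy,r_xz,r_yz Correlations in `[-1, 1]`.
#' @param epsilon_degenerate Degeneracy guard on `1 - r^2`; see
#'   [threshold_config()].
#' @return The partial correlation, or `NA_real_` when degenerate.
#' @examples
#' partial_cc(0.9, 0, 0)       # reduces to r_xy
#' partial_cc(0.48, 0.6, 0.8)  # numerator exactly zero
#' partial_cc(0.5, 1, 0.5)     # degenerate: NA
#' @export
partial_cc <- function(r_xy, r_xz, r_yz, epsilon_degenerate = 1e-8) {
  for (r in list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz)) {
    if (!is.numeric(r) || anyNA(r) || any(abs(r) > 1 + 1e-12)) {
      stopf("correlations must lie in [-1, 1]")
    }
  }
  d_xz <- 1 - pmin(abs(r_xz), 1)^2
  d_yz <- 1 - pmin(abs(r_yz), 1)^2
  out <- (r_xy - r_xz * r_yz) / (sqrt(d_xz) * sqrt(d_yz))
  out[d_xz <= epsilon_degenerate | d_yz <= epsilon_degenerate] <- NA_real_
  out
}

#' First-order partial correlation from expression profiles
#'
#' Computes the three pairwise Pearson correlations and applies
#' [partial_cc()]. Equivalent (within numerical tolerance) to correlating
#' the residuals of least-squares regressions of x on z and y on z.
#'
#' @param x,y Profiles of the gene pair.
#' @param z Profile of the conditioning regulator.
#' @inheritParams partial_cc
#' @return The partial correlation, or `NA_real_` when degenerate.
#' @export
partial_cc_from_data <- function(x, y, z, epsilon_degenerate = 1e-8) {
  r_xy <- pearson_cc(x, y)$cc
  r_xz <- pearson_cc(x, z)$cc
  r_yz <- pearson_cc(y, z)$cc
  partial_cc(r_xy, r_xz, r_yz, epsilon_degenerate)
}

#' Enumerate co-expressed gene pairs
#'
#' Screens all unordered pairs among `genes` for co-expression: Pearson
#' `cc >= cc_min` (or `|cc| >= cc_min` with `use_absolute_cc`) and
#' two-sided `p < cc_pval_max`. Pairs are returned in canonical order
#' (`gene_a < gene_b` lexicographically, rows sorted), deduplicated.
#' Genes whose profile has zero variance across samples cannot be
#' correlated and are excluded with a warning.
#'
#' @param em An [expression_matrix()].
#' @param genes Character vector of gene ids to screen (default: all).
#' @param config A [threshold_config()] (or list of its arguments).
#' @return Data frame with columns `gene_a`, `gene_b`, `cc`, `p_value`.
#' @export
find_coexpressed_pairs <- function(em, genes = NULL, config = threshold_config()) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  config <- as_threshold_config(config)
  genes <- sort(unique(genes %||% rownames(em$values)))
  absent <- setdiff(genes, rownames(em$values))
  if (length(absent) > 0L) {
    stopf(
      "gene(s) absent from expression matrix: %s",
      paste(utils::head(absent, 5L), collapse = ", ")
    )
  }
  empty <- data.frame(
    gene_a = character(), gene_b = character(),
    cc = numeric(), p_value = numeric(), stringsAsFactors = FALSE
  )
  if (length(genes) < 2L) return(empty)
  sub <- em$values[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warnf(
      "excluding %d zero-variance gene(s) from pair screening (e.g. '%s')",
      sum(sds == 0), genes[which(sds == 0)[1L]]
    )
    genes <- genes[sds > 0]
    if (length(genes) < 2L) return(empty)
    sub <- sub[genes, , drop = FALSE]
  }
  n <- ncol(sub)
  if (n < 3L) stopf("need at least 3 samples to screen pairs, got %d", n)
  cmat <- stats::cor(t(sub))
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  cc <- cmat[idx]
  pval <- cor_pvalue(cc, n)
  keep <- if (config$use_absolute_cc) abs(cc) >= config$cc_min else
    cc >= config$cc_min
  keep <- keep & pval < config$cc_pval_max
  out <- data.frame(
    gene_a = genes[idx[keep, 1L]],
    gene_b = genes[idx[keep, 2L]],
    cc = cc[keep],
    p_value = pval[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test which regulators break a co-expressed pair
#'
#' The "co-expression breaking" test: for a co-expressed pair (A, B) and a
#' candidate TF C, compute the first-order partial correlation of A and B
#' conditioning on C. If it is defined and falls below `pcc_max` (in
#' magnitude by default), C is taken to destroy the pair's co-expression
#' and hence to regulate both members. An undefined partial correlation
#' (degenerate denominator) never counts as breaking.
#'
#' @param pair One-row data frame (or list) with `gene_a`, `gene_b` and
#'   optionally `cc`; typically a row of [find_coexpressed_pairs()] output.
#' @param candidates Character vector of candidate regulator ids; must not
#'   contain either pair member.
#' @param em An [expression_matrix()] containing all genes involved.
#' @param config A [threshold_config()].
#' @return Data frame with one row per candidate: `regulator`, `gene_a`,
#'   `gene_b`, `pcc` (`NA` when undefined), `breaks`.
#' @export
find_breaking_regulators <- function(pair, candidates, em,
                                     config = threshold_config()) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  config <- as_threshold_config(config)
  a <- as.character(pair$gene_a)
  b <- as.character(pair$gene_b)
  candidates <- sort(unique(as.character(candidates)))
  if (any(candidates %in% c(a, b))) {
    stopf(
      "candidate '%s' is a member of the pair under test",
      intersect(candidates, c(a, b))[1L]
    )
  }
  if (length(candidates) == 0L) {
    return(data.frame(
      regulator = character(), gene_a = character(), gene_b = character(),
      pcc = numeric(), breaks = logical(), stringsAsFactors = FALSE
    ))
  }
  need <- c(a, b, candidates)
  absent <- setdiff(need, rownames(em$values))
  if (length(absent) > 0L) {
    stopf("gene(s) absent from expression matrix: %s",
          paste(utils::head(absent, 5L), collapse = ", "))
  }
  r_xy <- if (!is.null(pair$cc)) as.numeric(pair$cc) else
    pearson_cc(em$values[a, ], em$values[b, ])$cc
  zc <- suppressWarnings(
    stats::cor(t(em$values[candidates, , drop = FALSE]),
               t(em$values[c(a, b), , drop = FALSE]))
  )
  ok <- stats::complete.cases(zc)  # zero-variance candidates yield NA
  pcc <- rep(NA_real_, length(candidates))
  if (any(ok)) {
    pcc[ok] <- partial_cc(
      r_xy, zc[ok, 1L], zc[ok, 2L], config$epsilon_degenerate
    )
  }
  breaks <- !is.na(pcc) &
    (if (config$use_absolute_pcc) abs(pcc) else pcc) < config$pcc_max
  data.frame(
    regulator = candidates, gene_a = a, gene_b = b,
    pcc = as.numeric(pcc), breaks = breaks, stringsAsFactors = FALSE
  )
}

#' Serialize pair / breaking tables to TSV
#'
#' @param x Data frame from [find_coexpressed_pairs()] or
#'   [find_breaking_regulators()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs_table <- function(x, path) {
  out <- x
  for (col in intersect(names(out), c("cc", "p_value", "pcc"))) {
    out[[col]] <- fmt_full(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
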