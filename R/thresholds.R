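#' Threshold configuration for the partial-correlation GRN algorithm
#'
#' Bundles the numeric cutoffs that drive the two screening stages: the
#' Pearson co-expression screen applied to structural-gene pairs, and the
#' partial-correlation "co-expression breaking" test applied to candidate
#' regulators. Defaults follow the published procedure: a pair is
#' co-expressed when CC >= 0.8 with two-sided P < 0.001, and a TF breaks
#' the pair when the first-order partial correlation conditioning on it
#' falls below 0.3 in magnitude.
#'
#' @param cc_min Minimum Pearson correlation for a co-expressed pair, in
#'   (0, 1]. Compared against the signed correlation unless
#'   `use_absolute_cc` is `TRUE`.
#' @param cc_pval_max Two-sided p-value ceiling for the co-expression
#'   screen, in (0, 1).
#' @param pcc_max Partial-correlation ceiling below which a pair counts as
#'   "broken" by the conditioning regulator, in [0, 1). Must be smaller
#'   than `cc_min`.
#' @param use_absolute_cc If `TRUE`, screen on |CC| so strongly
#'   anti-correlated pairs (repression) also count as co-expressed.
#' @param use_absolute_pcc If `TRUE` (default), the breaking test uses
#'   |PCC| < `pcc_max`: destruction of co-expression is about magnitude,
#'   and a strongly negative conditional correlation is not destruction.
#' @param epsilon_degenerate Denominator guard for the partial-correlation
#'   formula: when `1 - r^2` of either regulator-gene correlation falls at
#'   or below this value the partial correlation is reported as undefined
#'   (`NA`) rather than divided out.
#'
#' @return A list of class `"pcgrn_config"`.
#' @examples
#' cfg <- threshold_config()
#' cfg$cc_min
#' @export
threshold_config <- function(cc_min = 0.8,
                             cc_pval_max = 0.001,
                             pcc_max = 0.3,
                             use_absolute_cc = FALSE,
                             use_absolute_pcc = TRUE,
                             epsilon_degenerate = 1e-8) {
  if (!is.numeric(cc_min) || length(cc_min) != 1L ||
      cc_min <= 0 || cc_min > 1) {
    stopf("cc_min must be a single value in (0, 1], got %s", cc_min)
  }
  if (!is.numeric(cc_pval_max) || length(cc_pval_max) != 1L ||
      cc_pval_max <= 0 || cc_pval_max >= 1) {
    stopf("cc_pval_max must be a single value in (0, 1)")
  }
  if (!is.numeric(pcc_max) || length(pcc_max) != 1L ||
      pcc_max < 0 || pcc_max >= 1) {
    stopf("pcc_max must be a single value in [0, 1)")
  }
  if (pcc_max >= cc_min) {
    stopf("pcc_max (%s) must be below cc_min (%s)", pcc_max, cc_min)
  }
  if (!is.numeric(epsilon_degenerate) || epsilon_degenerate <= 0) {
    stopf("epsilon_degenerate must be a small positive real")
  }
  structure(
    list(
      cc_min = cc_min,
      cc_pval_max = cc_pval_max,
      pcc_max = pcc_max,
      use_absolute_cc = isTRUE(use_absolute_cc),
      use_absolute_pcc = isTRUE(use_absolute_pcc),
      epsilon_degenerate = epsilon_degenerate
    ),
    class = "pcgrn_config"
  )
}

as_threshold_config <- function(config) {
  if (inherits(config, "pcgrn_config")) return(config)
  if (is.null(config)) return(threshold_config())
  if (is.list(config)) return(do.call(threshold_config, config))
  stopf("config must be NULL, a list, or a threshold_config()")
}
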