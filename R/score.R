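#' Score recovery of a planted network
#'
#' Compares an inferred hierarchy against the ground truth it was simulated
#' from. Layers are aligned from the bottom (the bottom layer is the given
#' input, layer "b1" the first inferred layer above it, and so on), since
#' an inferred network may have fewer layers than the truth. For each
#' layer, membership precision and recall are reported; for each
#' adjacent-layer interface, edge precision and recall over
#' (regulator, target) keys. An empty prediction has recall 0 and
#' undefined (`NA`) precision.
#'
#' Overall `membership_accuracy` is the fraction of truth genes placed in
#' their true layer (counted from the bottom); unplaced or misplaced genes
#' count as wrong.
#'
#' @param inferred A `"HierarchicalGRN"`.
#' @param truth A `"PlantedNetwork"` (or a `"HierarchicalGRN"` used as
#'   truth).
#' @return A list of class `"RecoveryReport"`: `layer_metrics` and
#'   `edge_metrics` data frames, `membership_accuracy`,
#'   `exact_layers`, `exact_edges`.
#' @export
score_recovery <- function(inferred, truth) {
  inf_layers <- rev(inferred$layers)   # index 1 = bottom
  tru_layers <- rev(truth$layers)
  inf_edges <- edge_keys_by_interface(inferred$edges, inferred$layers)
  tru_edges <- edge_keys_by_interface(truth$edges, truth$layers)

  n_lay <- max(length(inf_layers), length(tru_layers))
  layer_metrics <- do.call(rbind, lapply(seq_len(n_lay), function(b) {
    pred <- if (b <= length(inf_layers)) inf_layers[[b]] else character()
    act <- if (b <= length(tru_layers)) tru_layers[[b]] else character()
    tp <- length(intersect(pred, act))
    data.frame(
      layer_from_bottom = b - 1L,
      precision = if (length(pred) == 0L) NA_real_ else tp / length(pred),
      recall = if (length(act) == 0L) NA_real_ else tp / length(act),
      n_true = length(act), n_predicted = length(pred)
    )
  }))

  n_int <- max(length(inf_edges), length(tru_edges))
  edge_metrics <- if (n_int == 0L) {
    data.frame(
      interface_from_bottom = integer(), precision = numeric(),
      recall = numeric(), n_true = integer(), n_predicted = integer()
    )
  } else {
    do.call(rbind, lapply(seq_len(n_int), function(b) {
      pred <- if (b <= length(inf_edges)) inf_edges[[b]] else character()
      act <- if (b <= length(tru_edges)) tru_edges[[b]] else character()
      tp <- length(intersect(pred, act))
      data.frame(
        interface_from_bottom = b,
        precision = if (length(pred) == 0L) NA_real_ else tp / length(pred),
        recall = if (length(act) == 0L) NA_real_ else tp / length(act),
        n_true = length(act), n_predicted = length(pred)
      )
    }))
  }

  # layer index (from bottom) of every truth gene in the inferred network
  placement <- unlist(lapply(seq_along(inf_layers), function(b) {
    stats::setNames(rep(b, length(inf_layers[[b]])), inf_layers[[b]])
  }))
  correct <- 0L
  total <- 0L
  for (b in seq_along(tru_layers)) {
    for (g in tru_layers[[b]]) {
      total <- total + 1L
      if (!is.na(placement[g]) && identical(unname(placement[g]), b)) {
        correct <- correct + 1L
      }
    }
  }

  structure(
    list(
      layer_metrics = layer_metrics,
      edge_metrics = edge_metrics,
      membership_accuracy = if (total > 0L) correct / total else NA_real_,
      exact_layers = identical(
        lapply(inf_layers, sort),
        lapply(tru_layers, sort)
      ),
      exact_edges = identical(
        lapply(inf_edges, sort),
        lapply(tru_edges, sort)
      )
    ),
    class = "RecoveryReport"
  )
}

# Split an edge table into per-interface "regulator->target" key vectors,
# indexed from the bottom: element 1 = edges into the bottom layer. The
# regulator's layer is derived from membership, so planted-network edge
# tables (regulator, target, weight) work as well as built GRN tables.
edge_keys_by_interface <- function(edges, layers) {
  n_layers <- length(layers)
  if (is.null(edges) || nrow(edges) == 0L || n_layers < 2L) return(list())
  layer_of <- unlist(lapply(seq_along(layers), function(k) {
    stats::setNames(rep(k, length(layers[[k]])), layers[[k]])
  }))
  from <- unname(layer_of[edges$regulator])
  lapply(seq_len(n_layers - 1L), function(b) {
    k <- n_layers - b  # layer_from of the interface b levels above bottom
    sel <- !is.na(from) & from == k
    sort(paste(edges$regulator[sel], edges$target[sel], sep = "->"))
  })
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat("Recovery report\n")
  cat(sprintf("  membership accuracy: %s\n", fmt_num(x$membership_accuracy)))
  cat(sprintf("  exact layers: %s, exact edges: %s\n",
              x$exact_layers, x$exact_edges))
  lm <- x$layer_metrics
  for (i in seq_len(nrow(lm))) {
    cat(sprintf(
      "  layer +%d: precision %s, recall %s (%d true, %d predicted)\n",
      lm$layer_from_bottom[i], fmt_num(lm$precision[i]),
      fmt_num(lm$recall[i]), lm$n_true[i], lm$n_predicted[i]
    ))
  }
  em <- x$edge_metrics
  for (i in seq_len(nrow(em))) {
    cat(sprintf(
      "  interface +%d: precision %s, recall %s (%d true, %d predicted)\n",
      em$interface_from_bottom[i], fmt_num(em$precision[i]),
      fmt_num(em$recall[i]), em$n_true[i], em$n_predicted[i]
    ))
  }
  invisible(x)
}
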