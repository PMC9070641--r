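#' Summarize a hierarchical GRN
#'
#' Composition counts mirroring how such networks are reported: per-layer
#' gene counts, edge counts per adjacent-layer interface, regulator
#' out-degrees, the bottom-layer genes each top-layer regulator reaches
#' through one intermediate regulator (two-hop reachability), and — when a
#' process map is supplied — per biological process, how many member genes
#' of the bottom layer receive at least one incoming edge.
#'
#' @param grn A `"HierarchicalGRN"` from [build_hierarchical_grn()].
#' @param processes Optional [process_map()]; members are interpreted
#'   against bottom-layer genes.
#' @return A list of class `"GrnSummary"` with elements
#'   `per_layer_counts`, `edge_count_total`, `edge_counts_between_layers`,
#'   `out_degree_by_regulator`, `regulated_targets_by_top_regulator`,
#'   `per_process_counts`.
#' @export
summarize_grn <- function(grn, processes = NULL) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  layers <- grn$layers
  n <- length(layers)
  e <- grn$edges
  per_layer <- vapply(layers, length, 0L)
  interface_counts <- if (n >= 2L) {
    vapply(seq_len(n - 1L), function(k) sum(e$layer_from == k), 0L)
  } else {
    integer()
  }

  out_degree <- integer(0)
  if (n >= 2L) {
    regs <- sort(unlist(layers[seq_len(n - 1L)]))
    out_degree <- vapply(regs, function(g) sum(e$regulator == g), 0L)
  }

  # Two-hop reach of each top regulator: top -> intermediate -> bottom.
  reach <- list()
  if (n >= 3L) {
    for (g in sort(layers[[1L]])) {
      mid <- e$target[e$regulator == g & e$layer_from == 1L]
      down <- e$target[e$regulator %in% mid & e$layer_from == 2L]
      reach[[g]] <- sort(unique(down))
    }
  }

  per_process <- list()
  if (!is.null(processes)) {
    stopifnot(inherits(processes, "ProcessMap"))
    bottom <- layers[[n]]
    regulated <- unique(e$target[e$layer_to == n])
    for (nm in names(processes)) {
      members <- intersect(processes[[nm]], bottom)
      per_process[[nm]] <- c(
        regulated_count = length(intersect(members, regulated)),
        total_count = length(members)
      )
    }
  }

  structure(
    list(
      per_layer_counts = as.integer(per_layer),
      edge_count_total = nrow(e),
      edge_counts_between_layers = interface_counts,
      out_degree_by_regulator = out_degree,
      regulated_targets_by_top_regulator = reach,
      per_process_counts = per_process
    ),
    class = "GrnSummary"
  )
}

#' @export
print.GrnSummary <- function(x, ...) {
  cat(sprintf(
    "GRN summary: layers [%s], %d edges [%s per interface]\n",
    paste(x$per_layer_counts, collapse = "/"),
    x$edge_count_total,
    paste(x$edge_counts_between_layers, collapse = "/")
  ))
  if (length(x$regulated_targets_by_top_regulator) > 0L) {
    for (g in names(x$regulated_targets_by_top_regulator)) {
      cat(sprintf(
        "  top regulator %s reaches %d bottom gene(s)\n",
        g, length(x$regulated_targets_by_top_regulator[[g]])
      ))
    }
  }
  if (length(x$per_process_counts) > 0L) {
    for (nm in names(x$per_process_counts)) {
      v <- x$per_process_counts[[nm]]
      cat(sprintf("  process '%s': %d of %d genes regulated\n",
                  nm, v[["regulated_count"]], v[["total_count"]]))
    }
  }
  invisible(x)
}
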