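#' Infer one regulator layer above a bottom gene set
#'
#' One pass of the bottom-up construction: enumerate co-expressed pairs
#' among the `bottom` genes, then test every candidate regulator against
#' every pair with the co-expression-breaking test. A candidate that breaks
#' at least `min_pairs_broken` pairs is assigned to the new layer, with a
#' directed edge to each member of every pair it breaks.
#'
#' @param bottom Character vector of current bottom-layer gene ids.
#' @param candidates Character vector of candidate regulator ids, disjoint
#'   from `bottom`.
#' @param em An [expression_matrix()].
#' @param config A [threshold_config()].
#' @param min_pairs_broken Minimum number of broken pairs required to
#'   declare a candidate a regulator (default 1: breaking a single pair
#'   suffices, the algorithm's literal rule; raise for stringency).
#' @return A list with `assigned` (sorted gene ids), `edges` (data frame
#'   `regulator`, `target`, `n_supporting_pairs`, `min_abs_pcc`), and
#'   `pairs` (the co-expressed pairs screened).
#' @export
infer_layer <- function(bottom, candidates, em, config = threshold_config(),
                        min_pairs_broken = 1L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  config <- as_threshold_config(config)
  bottom <- sort(unique(as.character(bottom)))
  candidates <- sort(unique(as.character(candidates)))
  overlap <- intersect(bottom, candidates)
  if (length(overlap) > 0L) {
    stopf("bottom and candidate sets overlap: %s", overlap[1L])
  }
  empty_edges <- data.frame(
    regulator = character(), target = character(),
    n_supporting_pairs = integer(), min_abs_pcc = numeric(),
    stringsAsFactors = FALSE
  )
  empty_pairs <- data.frame(
    gene_a = character(), gene_b = character(),
    cc = numeric(), p_value = numeric(), stringsAsFactors = FALSE
  )
  if (length(bottom) < 2L) {
    warnf("fewer than 2 bottom genes: no pairs exist, nothing to infer")
    return(list(assigned = character(), edges = empty_edges,
                pairs = empty_pairs))
  }
  pairs <- find_coexpressed_pairs(em, bottom, config)
  if (nrow(pairs) == 0L || length(candidates) == 0L) {
    return(list(assigned = character(), edges = empty_edges, pairs = pairs))
  }

  # One correlation pass over (candidates x bottom), then the closed-form
  # partial correlation for every (pair, candidate) combination.
  zc <- suppressWarnings(stats::cor(
    t(em$values[candidates, , drop = FALSE]),
    t(em$values[bottom, , drop = FALSE])
  ))
  broken_by <- vector("list", length(candidates))
  names(broken_by) <- candidates
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    r_xz <- zc[, a]
    r_yz <- zc[, b]
    ok <- !is.na(r_xz) & !is.na(r_yz)
    pcc <- rep(NA_real_, length(candidates))
    pcc[ok] <- partial_cc(
      pairs$cc[i], r_xz[ok], r_yz[ok], config$epsilon_degenerate
    )
    val <- if (config$use_absolute_pcc) abs(pcc) else pcc
    hits <- which(!is.na(val) & val < config$pcc_max)
    for (j in hits) {
      broken_by[[j]][[length(broken_by[[j]]) + 1L]] <-
        list(a = a, b = b, pcc = pcc[j])
    }
  }

  n_broken <- lengths(broken_by)
  assigned <- candidates[n_broken >= min_pairs_broken]
  if (length(assigned) == 0L) {
    return(list(assigned = character(), edges = empty_edges, pairs = pairs))
  }
  rows <- list()
  for (z in assigned) {
    ev <- broken_by[[z]]
    targets <- c(
      vapply(ev, `[[`, "", "a"),
      vapply(ev, `[[`, "", "b")
    )
    pccs <- rep(vapply(ev, `[[`, 0, "pcc"), 2L)
    agg_n <- tapply(pccs, targets, length)
    agg_min <- tapply(abs(pccs), targets, min)
    tg <- sort(unique(targets))
    rows[[z]] <- data.frame(
      regulator = z, target = tg,
      n_supporting_pairs = as.integer(agg_n[tg]),
      min_abs_pcc = as.numeric(agg_min[tg]),
      stringsAsFactors = FALSE
    )
  }
  edges <- do.call(rbind, rows)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(assigned = assigned, edges = edges, pairs = pairs)
}

#' Build a multi-layer hierarchical GRN bottom-up
#'
#' Starting from a bottom layer of structural genes, repeatedly applies
#' [infer_layer()]: first to find the TFs that directly regulate the
#' structural genes (layer 2 in a 3-layer network), then — using those TFs
#' as the new bottom — the TFs above them, and so on. Assigned regulators
#' are removed from the candidate pool after each pass, so layers are
#' disjoint. Construction stops after `n_layers - 1` inferences or as soon
#' as a pass assigns no regulator (graceful degradation on sparse data).
#'
#' @param em An [expression_matrix()].
#' @param catalog A [gene_catalog()]; its regulator genes present in the
#'   matrix form the candidate pool.
#' @param bottom_genes Character vector of structural gene ids forming the
#'   bottom layer; all must have structural role in `catalog`.
#' @param n_layers Maximum number of layers including the bottom
#'   (default 3).
#' @param config A [threshold_config()].
#' @param min_pairs_broken See [infer_layer()].
#' @return An object of class `"HierarchicalGRN"`: list with `layers`
#'   (list of gene-id vectors, element 1 = top layer), `edges` (data frame
#'   `regulator`, `target`, `layer_from`, `layer_to`,
#'   `n_supporting_pairs`, `min_abs_pcc`), and `unplaced_regulators`.
#' @export
build_hierarchical_grn <- function(em, catalog, bottom_genes = NULL,
                                   n_layers = 3L,
                                   config = threshold_config(),
                                   min_pairs_broken = 1L) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(catalog, "GeneCatalog"))
  config <- as_threshold_config(config)
  if (n_layers < 2L) stopf("n_layers must be at least 2")
  bottom_genes <- sort(unique(as.character(
    bottom_genes %||% intersect(structural_genes(catalog), rownames(em$values))
  )))
  roles <- catalog$role[match(bottom_genes, catalog$gene_id)]
  if (anyNA(roles)) {
    stopf("bottom gene '%s' is not in the catalog",
          bottom_genes[which(is.na(roles))[1L]])
  }
  if (any(roles == "regulator")) {
    stopf("bottom gene '%s' has regulator role",
          bottom_genes[which(roles == "regulator")[1L]])
  }
  absent <- setdiff(bottom_genes, rownames(em$values))
  if (length(absent) > 0L) {
    stopf("bottom gene(s) absent from expression matrix: %s",
          paste(utils::head(absent, 5L), collapse = ", "))
  }

  pool <- intersect(regulator_genes(catalog), rownames(em$values))
  layers_up <- list(bottom_genes)  # element 1 = bottom, grows upward
  edge_tabs <- list()
  current <- bottom_genes
  for (k in seq_len(n_layers - 1L)) {
    if (length(pool) == 0L) break
    res <- infer_layer(current, pool, em, config, min_pairs_broken)
    if (length(res$assigned) == 0L) break
    edge_tabs[[k]] <- res$edges
    layers_up[[k + 1L]] <- res$assigned
    pool <- setdiff(pool, res$assigned)
    current <- res$assigned
  }

  layers <- rev(layers_up)  # element 1 = top
  n <- length(layers)
  edges <- data.frame(
    regulator = character(), target = character(),
    layer_from = integer(), layer_to = integer(),
    n_supporting_pairs = integer(), min_abs_pcc = numeric(),
    stringsAsFactors = FALSE
  )
  if (length(edge_tabs) > 0L) {
    tabs <- lapply(seq_along(edge_tabs), function(k) {
      tab <- edge_tabs[[k]]
      # pass k connects layer (n - k) down to layer (n - k + 1)
      tab$layer_from <- n - k
      tab$layer_to <- n - k + 1L
      tab
    })
    edges <- do.call(rbind, tabs)
    edges <- edges[
      order(edges$layer_from, edges$regulator, edges$target), ,
      drop = FALSE
    ]
    edges <- edges[
      , c("regulator", "target", "layer_from", "layer_to",
          "n_supporting_pairs", "min_abs_pcc"),
      drop = FALSE
    ]
    rownames(edges) <- NULL
  }
  grn <- structure(
    list(layers = layers, edges = edges, unplaced_regulators = sort(pool)),
    class = "HierarchicalGRN"
  )
  validate_grn(grn)
  grn
}

#' Validate the structural invariants of a hierarchical GRN
#'
#' Asserts: layers are pairwise disjoint; every edge points downward
#' between adjacent layers; edge (regulator, target) keys are unique;
#' every non-bottom-layer gene has at least one outgoing edge.
#'
#' @param grn A `"HierarchicalGRN"`.
#' @return Invisibly, `grn`; errors on violation.
#' @export
validate_grn <- function(grn) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  layers <- grn$layers
  all_genes <- unlist(layers)
  if (anyDuplicated(all_genes)) {
    stopf("layers are not disjoint: gene '%s' appears twice",
          all_genes[duplicated(all_genes)][1L])
  }
  e <- grn$edges
  if (nrow(e) > 0L) {
    if (any(e$layer_to != e$layer_from + 1L)) {
      stopf("edge connecting non-adjacent layers found")
    }
    key <- paste(e$regulator, e$target, sep = "\r")
    if (anyDuplicated(key)) stopf("duplicate edge keys found")
    for (i in seq_len(nrow(e))) {
      if (!(e$regulator[i] %in% layers[[e$layer_from[i]]]) ||
          !(e$target[i] %in% layers[[e$layer_to[i]]])) {
        stopf("edge %s -> %s inconsistent with layer membership",
              e$regulator[i], e$target[i])
      }
    }
  }
  if (length(layers) > 1L) {
    for (k in seq_len(length(layers) - 1L)) {
      no_out <- setdiff(layers[[k]], e$regulator[e$layer_from == k])
      if (length(no_out) > 0L) {
        stopf("non-bottom gene '%s' (layer %d) has no outgoing edge",
              no_out[1L], k)
      }
    }
  }
  invisible(grn)
}

#' @export
print.HierarchicalGRN <- function(x, ...) {
  sizes <- vapply(x$layers, length, 0L)
  cat(sprintf(
    "HierarchicalGRN: %d layer(s) [%s genes], %d edges, %d unplaced regulators\n",
    length(sizes), paste(sizes, collapse = "/"), nrow(x$edges),
    length(x$unplaced_regulators)
  ))
  invisible(x)
}
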