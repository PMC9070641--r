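#' Export / import a hierarchical GRN
#'
#' Three standard serializations:
#' * edge-list TSV with columns `regulator`, `target`, `layer_from`,
#'   `layer_to`, `n_supporting_pairs`, `min_abs_pcc` plus a companion
#'   node table (`gene_id`, `layer`) so genes without edges survive the
#'   round trip;
#' * SIF (`regulator<TAB>regulates<TAB>target`), edge topology only;
#' * GraphML via igraph, with a `layer` vertex attribute and the edge
#'   attributes above — the only single-file lossless format here.
#'
#' @param grn A `"HierarchicalGRN"`.
#' @param path Output file path.
#' @param nodes_path Optional companion node-table path for the TSV writer
#'   (defaults to `<path>` with a `.nodes.tsv` suffix).
#' @return Invisibly, `path`.
#' @name grn_io
NULL

#' @rdname grn_io
#' @export
write_grn_edges <- function(grn, path, nodes_path = default_nodes_path(path)) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  out <- grn$edges
  out$min_abs_pcc <- fmt_full(out$min_abs_pcc)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- grn_node_table(grn)
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_nodes_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", ".nodes.tsv", path)
}

grn_node_table <- function(grn) {
  layer_of <- unlist(lapply(seq_along(grn$layers), function(k) {
    stats::setNames(rep(k, length(grn$layers[[k]])), grn$layers[[k]])
  }))
  ids <- sort(names(layer_of))
  nodes <- data.frame(
    gene_id = ids, layer = unname(layer_of[ids]), stringsAsFactors = FALSE
  )
  if (length(grn$unplaced_regulators) > 0L) {
    nodes <- rbind(nodes, data.frame(
      gene_id = sort(grn$unplaced_regulators), layer = NA_integer_,
      stringsAsFactors = FALSE
    ))
  }
  nodes
}

#' @rdname grn_io
#' @export
read_grn_edges <- function(path, nodes_path = default_nodes_path(path)) {
  edges <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "#")
  needed <- c("regulator", "target", "layer_from", "layer_to")
  if (!all(needed %in% names(edges))) {
    stopf("edge table %s lacks column(s): %s", path,
          paste(setdiff(needed, names(edges)), collapse = ", "))
  }
  if (!file.exists(nodes_path)) {
    stopf("node table not found alongside edge list: %s", nodes_path)
  }
  nodes <- utils::read.delim(nodes_path, sep = "\t", stringsAsFactors = FALSE)
  grn_from_tables(edges, nodes)
}

grn_from_tables <- function(edges, nodes) {
  placed <- nodes[!is.na(nodes$layer), , drop = FALSE]
  n <- if (nrow(placed) > 0L) max(placed$layer) else 0L
  layers <- lapply(seq_len(n), function(k) {
    sort(placed$gene_id[placed$layer == k])
  })
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$layer_from, edges$regulator, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    if (is.null(edges$n_supporting_pairs)) edges$n_supporting_pairs <- NA_integer_
    if (is.null(edges$min_abs_pcc)) edges$min_abs_pcc <- NA_real_
  }
  grn <- structure(
    list(
      layers = layers,
      edges = edges,
      unplaced_regulators = sort(nodes$gene_id[is.na(nodes$layer)])
    ),
    class = "HierarchicalGRN"
  )
  validate_grn(grn)
  grn
}

#' @rdname grn_io
#' @export
write_grn_sif <- function(grn, path) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  e <- grn$edges
  lines <- if (nrow(e) > 0L) {
    paste(e$regulator, "regulates", e$target, sep = "\t")
  } else {
    character()
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a SIF file into an edge data frame
#'
#' SIF carries topology only; the result has columns `regulator`,
#' `target`.
#'
#' @param path SIF file path.
#' @return Data frame of directed edges.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(regulator = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) stopf("malformed SIF line %d in %s", bad[1L], path)
  out <- data.frame(
    regulator = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname grn_io
#' @export
write_grn_graphml <- function(grn, path) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  nodes <- grn_node_table(grn)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, nrow(nodes),
                            name = nodes$gene_id,
                            layer = ifelse(is.na(nodes$layer), -1L,
                                           nodes$layer))
  e <- grn$edges
  if (nrow(e) > 0L) {
    g <- igraph::add_edges(
      g, as.vector(rbind(e$regulator, e$target)),
      n_supporting_pairs = e$n_supporting_pairs,
      min_abs_pcc = e$min_abs_pcc
    )
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname grn_io
#' @export
read_grn_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  layer <- as.integer(round(igraph::V(g)$layer))
  nodes <- data.frame(
    gene_id = igraph::V(g)$name,
    layer = ifelse(layer < 0L, NA_integer_, layer),
    stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  layer_of <- stats::setNames(nodes$layer, nodes$gene_id)
  edges <- data.frame(
    regulator = el[, 1L], target = el[, 2L],
    layer_from = unname(layer_of[el[, 1L]]),
    layer_to = unname(layer_of[el[, 2L]]),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) > 0L) {
    edges$n_supporting_pairs <-
      as.integer(igraph::E(g)$n_supporting_pairs %||%
                   rep(NA_integer_, nrow(edges)))
    edges$min_abs_pcc <- as.numeric(igraph::E(g)$min_abs_pcc %||%
                                      rep(NA_real_, nrow(edges)))
  } else {
    edges$n_supporting_pairs <- integer()
    edges$min_abs_pcc <- numeric()
  }
  grn_from_tables(edges, nodes)
}
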