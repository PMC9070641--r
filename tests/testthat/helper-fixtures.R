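# Shared fixtures and independent oracles, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expression matrix from a plain values matrix; metadata synthesized as a
# time course with one replicate per sample unless a design is given.
em_from_values <- function(values, n_reps = 1L) {
  ns <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ns))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  }
  meta <- data.frame(
    sample_id = colnames(values),
    time_point = sprintf("T%02d", rep(seq_len(ceiling(ns / n_reps)),
                                      each = n_reps)[seq_len(ns)]),
    replicate = sprintf("R%d", rep(seq_len(n_reps),
                                   times = ceiling(ns / n_reps))[seq_len(ns)]),
    stringsAsFactors = FALSE
  )
  expression_matrix(values, meta)
}

rand_em <- function(n_genes, n_samples, seed = 1L) {
  vals <- withr::with_seed(seed, matrix(rnorm(n_genes * n_samples),
                                        n_genes, n_samples))
  em_from_values(vals)
}

# Independent partial-correlation oracle: correlate the residuals of
# least-squares regressions of x on z and y on z.
residual_pcc <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  if (stats::sd(rx) < 1e-10 || stats::sd(ry) < 1e-10) return(NA_real_)
  stats::cor(rx, ry)
}

# Simulation bundle helper for builder/recovery tests.
sim_bundle <- function(seed, noise_sd = 0.1, layer_sizes = c(2, 4, 12),
                       fan_out = 3L) {
  net <- generate_planted_network(
    layer_sizes = layer_sizes, fan_out = fan_out, noise_sd = noise_sd,
    seed = seed
  )
  list(net = net, em = simulate_expression(net),
       catalog = make_gene_catalog(net))
}

# A small hand-built hierarchy for summary/scoring/io tests: layers
# (1, 2, 4) with a complete adjacent-layer bipartite edge set.
bipartite_grn <- function() {
  layers <- list("T1", c("M1", "M2"), c("B1", "B2", "B3", "B4"))
  e1 <- expand.grid(regulator = "T1", target = c("M1", "M2"),
                    stringsAsFactors = FALSE)
  e1$layer_from <- 1L
  e1$layer_to <- 2L
  e2 <- expand.grid(regulator = c("M1", "M2"),
                    target = c("B1", "B2", "B3", "B4"),
                    stringsAsFactors = FALSE)
  e2$layer_from <- 2L
  e2$layer_to <- 3L
  edges <- rbind(e1, e2)
  edges$n_supporting_pairs <- 1L
  edges$min_abs_pcc <- 0.1
  edges <- edges[order(edges$layer_from, edges$regulator, edges$target), ]
  rownames(edges) <- NULL
  structure(
    list(layers = layers, edges = edges, unplaced_regulators = character()),
    class = "HierarchicalGRN"
  )
}
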