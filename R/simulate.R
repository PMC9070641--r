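#' Generate a planted hierarchical regulatory network
#'
#' Ground truth for benchmarking: a layered directed acyclic network in
#' which each regulator in layer k picks `fan_out` random targets in layer
#' k+1, followed by a repair pass that attaches one random parent to any
#' orphaned gene so that every non-top gene has at least one parent. Edge
#' weights are drawn uniformly from `weight_range`; draws inside the
#' zero-neighborhood (|w| < 0.05) are rejected and redrawn so that no
#' planted edge is effectively absent. The default range (0.5, 1.5) keeps
#' regulation activating, matching the signed co-expression screen of the
#' default [threshold_config()].
#'
#' @param layer_sizes Integer vector of layer sizes, top first (e.g.
#'   `c(2, 4, 12)` for 2 top TFs, 4 intermediate TFs, 12 structural genes).
#' @param fan_out Targets sampled per regulator (capped at the next
#'   layer's size).
#' @param weight_range Length-2 numeric interval for edge weights.
#' @param noise_sd Relative replicate-level noise level passed on to
#'   [simulate_expression()]: noise sd as a fraction of each gene's signal
#'   sd.
#' @param n_timepoints,n_replicates Time-course shape of the simulated
#'   design. Defaults: 8 time points, 3 biological replicates — a
#'   three-replicate time series (as in typical stress time-course
#'   designs) with enough libraries (n = 24) that the co-expression
#'   p-value threshold has realistic power.
#' @param seed Integer seed; networks are reproducible given identical
#'   arguments.
#' @return A list of class `"PlantedNetwork"`: `layers` (top first),
#'   `edges` (data frame `regulator`, `target`, `weight`), plus the
#'   simulation parameters above.
#' @examples
#' net <- generate_planted_network(c(2, 4, 12), seed = 1)
#' nrow(net$edges)
#' @export
generate_planted_network <- function(layer_sizes = c(2L, 4L, 12L),
                                     fan_out = 3L,
                                     weight_range = c(0.5, 1.5),
                                     noise_sd = 0.1,
                                     n_timepoints = 8L,
                                     n_replicates = 3L,
                                     seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stopf("layer_sizes needs >= 2 layers, each with >= 1 gene")
  }
  if (fan_out < 1L) stopf("fan_out must be >= 1")
  if (length(weight_range) != 2L || weight_range[1L] >= weight_range[2L]) {
    stopf("weight_range must be an increasing length-2 interval")
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (n_timepoints < 3L) stopf("n_timepoints must be >= 3")
  if (n_replicates < 1L) stopf("n_replicates must be >= 1")
  for (k in seq_len(length(layer_sizes) - 1L)) {
    if (fan_out * layer_sizes[k] < layer_sizes[k + 1L]) {
      stopf(
        "layer %d cannot cover layer %d: fan_out %d x %d regulators < %d targets",
        k, k + 1L, fan_out, layer_sizes[k], layer_sizes[k + 1L]
      )
    }
  }

  layers <- lapply(seq_along(layer_sizes), function(k) {
    sprintf("L%d_G%02d", k, seq_len(layer_sizes[k]))
  })

  edges <- with_seed(seed, {
    rows <- list()
    for (k in seq_len(length(layer_sizes) - 1L)) {
      parents <- layers[[k]]
      children <- layers[[k + 1L]]
      m <- min(fan_out, length(children))
      tab <- list()
      for (p in parents) {
        tg <- sort(sample(children, m))
        tab[[p]] <- data.frame(
          regulator = p, target = tg, stringsAsFactors = FALSE
        )
      }
      tab <- do.call(rbind, tab)
      orphans <- setdiff(children, tab$target)
      for (ch in orphans) {
        tab <- rbind(tab, data.frame(
          regulator = sample(parents, 1L), target = ch,
          stringsAsFactors = FALSE
        ))
      }
      rows[[k]] <- tab
    }
    e <- do.call(rbind, rows)
    e$weight <- draw_weights(nrow(e), weight_range)
    e <- e[order(e$regulator, e$target), , drop = FALSE]
    rownames(e) <- NULL
    e
  })

  structure(
    list(
      layers = layers, edges = edges,
      noise_sd = noise_sd, n_timepoints = as.integer(n_timepoints),
      n_replicates = as.integer(n_replicates),
      fan_out = as.integer(fan_out), weight_range = weight_range,
      seed = as.integer(seed)
    ),
    class = "PlantedNetwork"
  )
}

# Uniform weights avoiding a zero-neighborhood so no edge is vacuous.
draw_weights <- function(n, range, zero_gap = 0.05) {
  w <- stats::runif(n, range[1L], range[2L])
  for (tries in 1:100) {
    bad <- abs(w) < zero_gap
    if (!any(bad)) break
    w[bad] <- stats::runif(sum(bad), range[1L], range[2L])
  }
  w[abs(w) < zero_gap] <- zero_gap  # pathological range fallback
  w
}

#' @export
print.PlantedNetwork <- function(x, ...) {
  cat(sprintf(
    "PlantedNetwork: layers [%s], %d edges, noise_sd %s, %d timepoints x %d replicates, seed %d\n",
    paste(vapply(x$layers, length, 0L), collapse = "/"),
    nrow(x$edges), fmt_num(x$noise_sd), x$n_timepoints, x$n_replicates,
    x$seed
  ))
  invisible(x)
}

#' Simulate time-series expression from a planted network
#'
#' Top-layer regulators receive linearly independent smooth time profiles
#' (randomized low-order polynomial trend plus sinusoid, standardized to
#' zero mean and unit sd across time points; near-collinear draws are
#' rejected). Every other gene's observed profile is the weighted sum of
#' its parents' observed profiles plus its own replicate-level Gaussian
#' noise with sd `noise_sd x signal sd`, where signal sd is the sd of the
#' gene's noise-free propagated profile. Propagating the parents' observed
#' (noisy) expression — rather than their noise-free signal — reflects
#' that targets respond to the regulator's realized transcript abundance,
#' and it is what makes the layer hierarchy statistically separable:
#' conditioning on the true parent removes the noise the children inherit
#' from it, while conditioning on a grandparent does not.
#'
#' Replicates share the time profile and differ only through noise. With
#' `noise_sd = 0` every child equals its weighted parent sum exactly.
#'
#' @param net A [generate_planted_network()] result.
#' @param basis Optional matrix of top-layer profiles (rows = top genes,
#'   columns = time points), overriding the randomized default.
#' @return An [expression_matrix()] with `n_timepoints * n_replicates`
#'   samples and metadata columns `time_point`, `replicate`, `condition`.
#' @export
simulate_expression <- function(net, basis = NULL) {
  stopifnot(inherits(net, "PlantedNetwork"))
  tt <- net$n_timepoints
  rr <- net$n_replicates
  layers <- net$layers
  top <- layers[[1L]]
  all_genes <- unlist(layers)
  if (!is.null(basis)) {
    if (!is.matrix(basis) || nrow(basis) != length(top) || ncol(basis) != tt) {
      stopf("basis must be a %d x %d matrix (top genes x time points)",
            length(top), tt)
    }
  }
  if (tt < length(top)) {
    warnf(
      "%d time points cannot support %d linearly independent top profiles",
      tt, length(top)
    )
  }

  sample_ids <- as.vector(vapply(seq_len(tt), function(t) {
    sprintf("T%02d_R%d", t, seq_len(rr))
  }, character(rr)))
  meta <- data.frame(
    sample_id = sample_ids,
    time_point = sprintf("T%02d", rep(seq_len(tt), each = rr)),
    replicate = sprintf("R%d", rep(seq_len(rr), times = tt)),
    condition = "simulated",
    stringsAsFactors = FALSE
  )

  # Derive the simulation stream from the topology seed so that a network
  # and its expression matrix come from one reproducible seed.
  values <- with_seed(net$seed + 499979L, {
    prof <- basis %||% draw_top_profiles(length(top), tt)
    rownames(prof) <- top

    # Noise-free signal recursion (genes x time points), used for scaling.
    signal <- matrix(0, length(all_genes), tt,
                     dimnames = list(all_genes, NULL))
    signal[top, ] <- prof
    for (k in seq_len(length(layers) - 1L)) {
      for (ch in layers[[k + 1L]]) {
        sel <- net$edges$target == ch
        w <- net$edges$weight[sel]
        par <- net$edges$regulator[sel]
        signal[ch, ] <- as.numeric(w %*% signal[par, , drop = FALSE])
      }
    }
    signal_sd <- apply(signal, 1L, stats::sd)

    # Observed recursion over samples: children inherit parental noise.
    obs <- matrix(0, length(all_genes), tt * rr,
                  dimnames = list(all_genes, sample_ids))
    tp_of_sample <- rep(seq_len(tt), each = rr)
    for (g in top) {
      obs[g, ] <- signal[g, tp_of_sample] +
        stats::rnorm(tt * rr, sd = net$noise_sd * 1)
    }
    for (k in seq_len(length(layers) - 1L)) {
      for (ch in layers[[k + 1L]]) {
        sel <- net$edges$target == ch
        w <- net$edges$weight[sel]
        par <- net$edges$regulator[sel]
        scale_sd <- max(signal_sd[ch], 1e-12)
        obs[ch, ] <- as.numeric(w %*% obs[par, , drop = FALSE]) +
          stats::rnorm(tt * rr, sd = net$noise_sd * scale_sd)
      }
    }
    obs
  })

  expression_matrix(values, meta)
}

# Randomized standardized smooth profiles: linear + quadratic trend plus a
# sinusoid; redraw any profile nearly collinear with an earlier one.
draw_top_profiles <- function(n_profiles, tt, max_abs_cor = 0.95) {
  tn <- seq(0, 1, length.out = tt)
  prof <- matrix(0, n_profiles, tt)
  for (i in seq_len(n_profiles)) {
    for (try in 1:50) {
      a <- stats::runif(3L, -1, 1)
      freq <- sample(c(1, 1.5, 2), 1L)
      phase <- stats::runif(1L)
      p <- a[1L] * tn + a[2L] * tn^2 +
        a[3L] * sin(2 * pi * (freq * tn + phase))
      if (stats::sd(p) < 1e-6) next
      p <- (p - mean(p)) / stats::sd(p)
      if (i == 1L) break
      cors <- abs(stats::cor(t(prof[seq_len(i - 1L), , drop = FALSE]), p))
      if (max(cors) <= max_abs_cor) break
    }
    prof[i, ] <- p
  }
  prof
}

#' Derive the gene catalog of a planted network
#'
#' Bottom-layer genes are labeled structural; every other layer is labeled
#' regulator.
#'
#' @param net A [generate_planted_network()] result.
#' @return A [gene_catalog()].
#' @export
make_gene_catalog <- function(net) {
  stopifnot(inherits(net, "PlantedNetwork"))
  n <- length(net$layers)
  ids <- unlist(net$layers)
  roles <- rep("regulator", length(ids))
  if (n >= 2L) {
    roles[ids %in% net$layers[[n]]] <- "structural"
  } else {
    roles[] <- "structural"  # single-layer network: nothing regulates
  }
  gene_catalog(ids, roles)
}

#' Write / read the planted truth edge list
#'
#' TSV columns: `regulator`, `target`, `weight`, `layer_from`, `layer_to`.
#'
#' @param net A `"PlantedNetwork"`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_truth_edges <- function(net, path) {
  layer_of <- unlist(lapply(seq_along(net$layers), function(k) {
    stats::setNames(rep(k, length(net$layers[[k]])), net$layers[[k]])
  }))
  out <- data.frame(
    regulator = net$edges$regulator,
    target = net$edges$target,
    weight = fmt_full(net$edges$weight),
    layer_from = unname(layer_of[net$edges$regulator]),
    layer_to = unname(layer_of[net$edges$target]),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
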