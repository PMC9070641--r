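test_that("planted networks are reproducible and seeds matter", {
  n1 <- generate_planted_network(c(2, 4, 12), seed = 5)
  n2 <- generate_planted_network(c(2, 4, 12), seed = 5)
  expect_identical(n1, n2)
  n3 <- generate_planted_network(c(2, 4, 12), seed = 6)
  expect_false(identical(n1$edges, n3$edges))

  e1 <- simulate_expression(n1)
  e2 <- simulate_expression(n2)
  expect_identical(e1, e2)
  expect_false(identical(e1$values, simulate_expression(n3)$values))
})

test_that("every non-top gene has a parent after the repair pass", {
  for (seed in 1:5) {
    net <- generate_planted_network(c(2, 4, 12), fan_out = 3, seed = seed)
    non_top <- unlist(net$layers[-1])
    expect_true(all(non_top %in% net$edges$target))
    expect_true(all(abs(net$edges$weight) >= 0.05))
  }
  # forced chain topology
  chain <- generate_planted_network(c(1, 1, 1), fan_out = 1, seed = 1)
  expect_identical(nrow(chain$edges), 2L)
  expect_identical(chain$edges$regulator, c("L1_G01", "L2_G01"))
  # a too-narrow layer cannot cover the next one
  expect_error(generate_planted_network(c(1, 5, 2), fan_out = 3, seed = 1),
               "cover")
  expect_error(generate_planted_network(c(0, 4, 8), seed = 1), "layer_sizes")
})

test_that("noise-free children are exact weighted parent sums", {
  net <- generate_planted_network(c(2, 4, 12), noise_sd = 0, seed = 3)
  em <- simulate_expression(net)
  for (ch in unlist(net$layers[-1])) {
    sel <- net$edges$target == ch
    pred <- as.numeric(
      net$edges$weight[sel] %*%
        em$values[net$edges$regulator[sel], , drop = FALSE]
    )
    expect_lt(max(abs(em$values[ch, ] - pred)), 1e-12)
  }
  # a single-parent child is an exact affine image of its parent
  fan_in <- table(net$edges$target)
  single <- names(fan_in)[fan_in == 1][1]
  parent <- net$edges$regulator[net$edges$target == single]
  expect_equal(pearson_cc(em$values[single, ], em$values[parent, ])$cc, 1)
})

test_that("replicate-level noise has the advertised magnitude", {
  net <- generate_planted_network(c(2, 4, 12), noise_sd = 0.1, seed = 7,
                                  n_timepoints = 8, n_replicates = 3)
  em <- simulate_expression(net)
  # own-noise of a child = child minus weighted sum of observed parents;
  # pool across children for a stable empirical sd
  ratios <- vapply(unlist(net$layers[-1]), function(ch) {
    sel <- net$edges$target == ch
    resid <- em$values[ch, ] - as.numeric(
      net$edges$weight[sel] %*%
        em$values[net$edges$regulator[sel], , drop = FALSE]
    )
    sd(resid)
  }, 0)
  # compare pooled noise sd against the target 0.1 x signal sd
  net0 <- net
  net0$noise_sd <- 0
  signal <- simulate_expression(net0)$values
  targets <- 0.1 * apply(signal[unlist(net$layers[-1]), ], 1, sd)
  expect_lt(abs(mean(ratios / targets) - 1), 0.15)
})

test_that("the derived catalog labels the bottom layer structural", {
  net <- generate_planted_network(c(2, 4, 12), seed = 9)
  cat <- make_gene_catalog(net)
  expect_identical(sum(cat$role == "regulator"), 6L)
  expect_identical(sum(cat$role == "structural"), 12L)
  expect_identical(structural_genes(cat), sort(net$layers[[3]]))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_catalog(cat, path)
  expect_identical(as.data.frame(read_gene_catalog(path)),
                   as.data.frame(cat))
})

test_that("recovery degrades as noise rises well beyond the signal", {
  recall_at <- function(noise) {
    mean(vapply(1:5, function(s) {
      b <- sim_bundle(seed = 100 + s, noise_sd = noise)
      # at extreme noise a pass can assign a single TF, making the next
      # bottom degenerate; that warning is the expected behavior here
      grn <- suppressWarnings(build_hierarchical_grn(b$em, b$catalog))
      rep <- score_recovery(grn, b$net)
      r <- rep$edge_metrics$recall[1]
      if (is.na(r)) 0 else r
    }, 0))
  }
  expect_gt(recall_at(0.1), recall_at(1.5))
})
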