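test_that("pair screening finds exactly the co-expressed pairs", {
  vals <- withr::with_seed(1, {
    base <- rnorm(12)
    rbind(
      G1 = base,
      G2 = 2 * base + 1,      # exact affine image of G1
      G3 = rnorm(12),
      G4 = rnorm(12)
    )
  })
  colnames(vals) <- sprintf("S%02d", 1:12)
  em <- em_from_values(vals)
  pairs <- find_coexpressed_pairs(em)
  expect_identical(pairs$gene_a, "G1")
  expect_identical(pairs$gene_b, "G2")
  expect_equal(pairs$cc, 1)

  expect_identical(nrow(find_coexpressed_pairs(em, character())), 0L)
  expect_error(find_coexpressed_pairs(em, c("G1", "Gmissing")), "Gmissing")
})

test_that("pair screening equals the brute-force double loop", {
  em <- rand_em(30, 15, seed = 99)
  # add some genuinely correlated blocks so the screen finds something
  em$values[1:5, ] <- em$values[1, ] +
    withr::with_seed(100, matrix(rnorm(5 * 15, sd = 0.2), 5, 15))
  cfg <- threshold_config()
  got <- find_coexpressed_pairs(em, config = cfg)

  genes <- sort(rownames(em$values))
  expected <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      ct <- stats::cor.test(em$values[genes[i], ], em$values[genes[j], ])
      if (ct$estimate >= cfg$cc_min && ct$p.value < cfg$cc_pval_max) {
        expected[[length(expected) + 1L]] <-
          data.frame(gene_a = genes[i], gene_b = genes[j],
                     cc = unname(ct$estimate), p_value = ct$p.value,
                     stringsAsFactors = FALSE)
      }
    }
  }
  expected <- do.call(rbind, expected)
  rownames(expected) <- NULL
  expect_gt(nrow(got), 0L)
  expect_identical(got[, c("gene_a", "gene_b")],
                   expected[, c("gene_a", "gene_b")])
  expect_equal(got$cc, expected$cc, tolerance = 1e-12)
  expect_equal(got$p_value, expected$p_value, tolerance = 1e-12)
})

test_that("pair counts are antitone in cc_min and monotone in cc_pval_max", {
  em <- rand_em(25, 15, seed = 55)
  em$values[1:8, ] <- em$values[1, ] +
    withr::with_seed(56, matrix(rnorm(8 * 15, sd = 0.5), 8, 15))
  key <- function(p) paste(p$gene_a, p$gene_b)
  prev <- NULL
  for (ccm in c(0.6, 0.7, 0.8, 0.9)) {
    cur <- find_coexpressed_pairs(em, config = threshold_config(cc_min = ccm))
    if (!is.null(prev)) expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
  prev <- NULL
  for (pv in c(0.01, 0.001, 1e-4, 1e-5)) {
    cur <- find_coexpressed_pairs(
      em, config = threshold_config(cc_min = 0.6, cc_pval_max = pv)
    )
    if (!is.null(prev)) expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("a planted common regulator breaks its targets' co-expression", {
  vals <- withr::with_seed(77, {
    n <- 60L  # large enough that noise-noise correlation is reliably small
    z <- rnorm(n)
    rbind(
      Z = z,
      X = z + rnorm(n, sd = 0.05),
      Y = z + rnorm(n, sd = 0.05),
      W = rnorm(n)  # independent bystander
    )
  })
  em <- em_from_values(vals)
  pair <- find_coexpressed_pairs(em, c("X", "Y"))
  expect_identical(nrow(pair), 1L)

  res <- find_breaking_regulators(pair[1, ], c("Z", "W"), em)
  expect_identical(res$regulator, c("W", "Z"))
  z_row <- res[res$regulator == "Z", ]
  w_row <- res[res$regulator == "W", ]
  expect_true(z_row$breaks)
  expect_false(w_row$breaks)
  # the pcc agrees with the residual oracle and is near zero for Z
  oracle <- residual_pcc(em$values["X", ], em$values["Y", ], em$values["Z", ])
  expect_equal(z_row$pcc, oracle, tolerance = 1e-10)
  expect_lt(abs(z_row$pcc), 0.3)
  # an unrelated candidate leaves the pair's correlation essentially intact
  expect_gt(abs(w_row$pcc), 0.7)

  expect_identical(nrow(find_breaking_regulators(pair[1, ], character(), em)),
                   0L)
  expect_error(find_breaking_regulators(pair[1, ], c("X", "Z"), em),
               "member of the pair")
})

test_that("degenerate conditioning yields undefined pcc and no break", {
  vals <- withr::with_seed(88, {
    n <- 12L
    z <- rnorm(n)
    rbind(Z = z, X = 2 * z, Y = 3 * z + 1)  # exact collinear family
  })
  em <- em_from_values(vals)
  pair <- data.frame(gene_a = "X", gene_b = "Y", cc = 1, p_value = 0,
                     stringsAsFactors = FALSE)
  res <- find_breaking_regulators(pair, "Z", em)
  expect_true(is.na(res$pcc))
  expect_false(res$breaks)
})
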