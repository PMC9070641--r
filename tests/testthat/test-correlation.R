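test_that("pearson_cc is exact on linear dependence and errors on bad input", {
  expect_equal(pearson_cc(c(1, 2, 3, 4), c(2, 4, 6, 8)),
               list(cc = 1, p_value = 0))
  expect_equal(pearson_cc(c(1, 2, 3, 4), c(4, 3, 2, 1)),
               list(cc = -1, p_value = 0))
  expect_error(pearson_cc(c(1, 1, 1), c(1, 2, 3)), "'x'.*zero variance")
  expect_error(pearson_cc(c(1, 2, 3), c(5, 5, 5)), "'y'.*zero variance")
  expect_error(pearson_cc(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_cc(1:4, 1:5), "equal length")
})

test_that("pearson_cc matches covariance-formula and t-CDF oracles", {
  n <- 15L
  worst_cc <- 0
  worst_p <- 0
  withr::with_seed(101, {
    for (i in 1:300) {
      x <- rnorm(n)
      y <- rnorm(n) + runif(1, -2, 2) * x
      got <- pearson_cc(x, y)
      cc_oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      ct <- stats::cor.test(x, y)
      worst_cc <- max(worst_cc, abs(got$cc - cc_oracle))
      worst_p <- max(worst_p, abs(got$p_value - ct$p.value))
    }
  })
  expect_lt(worst_cc, 1e-12)
  expect_lt(worst_p, 1e-12)
})

test_that("partial_cc satisfies the formula's identities", {
  for (r in c(-1, -0.5, 0, 0.5, 0.9, 1)) {
    expect_identical(partial_cc(r, 0, 0), r)
  }
  # numerator r_xy - r_xz * r_yz exactly zero
  expect_identical(partial_cc(0.48, 0.6, 0.8), 0)
  expect_identical(partial_cc(0.06, 0.2, 0.3), 0)
  # degenerate denominators yield the undefined marker
  expect_identical(partial_cc(0.5, 1, 0.5), NA_real_)
  expect_identical(partial_cc(0.5, 0.5, -1), NA_real_)
  expect_identical(partial_cc(0.9, sqrt(1 - 1e-10), 0), NA_real_)
  # out-of-range correlations are rejected
  expect_error(partial_cc(1.2, 0, 0), "\\[-1, 1\\]")
  # pair-role symmetry: swapping x and y swaps r_xz and r_yz
  withr::with_seed(5, {
    for (i in 1:50) {
      r <- runif(3, -0.9, 0.9)
      expect_equal(partial_cc(r[1], r[2], r[3]),
                   partial_cc(r[1], r[3], r[2]))
    }
  })
})

test_that("partial_cc_from_data matches the regress-and-correlate oracle", {
  n <- 20L
  worst <- 0
  withr::with_seed(202, {
    for (i in 1:300) {
      z <- rnorm(n)
      x <- 0.8 * z + rnorm(n)
      y <- 0.8 * z + rnorm(n)
      got <- partial_cc_from_data(x, y, z)
      expect_false(is.na(got))
      worst <- max(worst, abs(got - residual_pcc(x, y, z)))
    }
  })
  expect_lt(worst, 1e-10)
})

test_that("partial_cc_from_data flags degenerate conditioning and recovers limits", {
  z <- c(1.2, -0.3, 0.5, 2.0, -1.1)
  expect_identical(partial_cc_from_data(z, z, z), NA_real_)
  expect_identical(partial_cc_from_data(2 * z + 1, z, z), NA_real_)
  # z independent of a correlated pair: conditioning changes little
  withr::with_seed(303, {
    n <- 2000L
    z <- rnorm(n)
    base <- rnorm(n)
    x <- base + 0.3 * rnorm(n)
    y <- base + 0.3 * rnorm(n)
    expect_equal(partial_cc_from_data(x, y, z),
                 pearson_cc(x, y)$cc, tolerance = 0.05)
  })
})

test_that("cc and pcc are invariant under positive affine rescaling", {
  withr::with_seed(404, {
    n <- 18L
    z <- rnorm(n)
    x <- z + rnorm(n)
    y <- z + rnorm(n)
    cc0 <- pearson_cc(x, y)$cc
    pcc0 <- partial_cc_from_data(x, y, z)
    for (i in 1:20) {
      a <- runif(3, 0.1, 10)
      b <- runif(3, -5, 5)
      expect_equal(pearson_cc(a[1] * x + b[1], a[2] * y + b[2])$cc, cc0,
                   tolerance = 1e-12)
      expect_equal(
        partial_cc_from_data(a[1] * x + b[1], a[2] * y + b[2],
                             a[3] * z + b[3]),
        pcc0, tolerance = 1e-12
      )
    }
  })
})
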