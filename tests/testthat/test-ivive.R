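# IVIVE comparison statistics: POD derivation, exact binomial tests,
# ratio statistics and prediction-ratio grids.

test_that("the tangent-based point of departure sits at ~12% response", {
  # independent derivation: logistic f(x) = 1/(1+exp(-x)); tangent at the
  # inflection (0, 1/2) has slope 1/4 and meets the lower asymptote at x = -2
  x_int <- stats::uniroot(function(x) 0.5 + x / 4, c(-5, 0))$root
  expect_equal(x_int, -2, tolerance = 1e-9)
  expect_equal(pod_response_fraction(), stats::plogis(-2), tolerance = 1e-15)
  expect_equal(round(100 * pod_response_fraction()), 12)
  # logistic symmetry: the upper intersection mirrors it
  expect_equal(1 - pod_response_fraction(), stats::plogis(2), tolerance = 1e-15)
})

test_that("the exact binomial test matches integer tail enumeration", {
  # oracle: two-sided tail sum at null 1/2 by symmetry, exact integers over 2^36
  exact_p <- function(k, n) {
    k_hi <- max(k, n - k)
    min(1, 2 * sum(choose(n, k_hi:n)) / 2^n)
  }
  n <- 36
  for (k in 0:n) {
    pecs <- c(rep(0.5, k), rep(2, n - k))
    b <- binomial_underprediction(pecs, rep(1, n))
    expect_equal(b$k, k)
    expect_equal(b$p_two_sided, exact_p(k, n), tolerance = 1e-12)
  }
  expect_equal(binomial_underprediction(rep(c(0.5, 2), c(18, 18)),
                                        rep(1, 36))$p_two_sided, 1)
})

test_that("ties count as not-below and are reported", {
  b <- binomial_underprediction(c(1, 1, 0.5, 2), c(1, 1, 1, 1))
  expect_equal(b$k, 1)
  expect_equal(b$n_ties, 2)
  expect_error(binomial_underprediction(numeric(0), numeric(0)), "n = 0")
  expect_error(binomial_underprediction(c(1, 2), 1), "equal length")
})

test_that("ratio statistics detect shifted and identical samples", {
  set.seed(91)
  loecs <- 10^stats::runif(36, -1, 1)
  same <- list(a = loecs * 2, b = loecs * 2)
  cr <- ratio_statistics(same, loecs)
  expect_equal(cr$t_tests$statistic, 0)
  expect_equal(cr$t_tests$p_value, 1)
  # two samples shifted by 3 log10 units with sd 0.5 are overwhelmingly distinct
  sh <- list(lo = loecs * 10^stats::rnorm(36, -3, 0.5),
             hi = loecs * 10^stats::rnorm(36, 0, 0.5))
  cr2 <- ratio_statistics(sh, loecs)
  expect_lt(cr2$t_tests$p_value, 1e-10)
  # each KDE integrates to one over its support
  for (kde in cr2$kde) {
    area <- sum(diff(kde$x) * (head(kde$y, -1) + tail(kde$y, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }
  expect_error(ratio_statistics(list(a = 1), 1), "at least 2")
})

test_that("exposure reconstruction is linear in the assay concentration", {
  tab <- generate_chemical_table(synthetic_table_spec(n_chemicals = 8, seed = 4))
  r1 <- reconstruct_exposures("6C", tab)
  tab2 <- tab; tab2$ac10 <- 2 * tab2$ac10
  r2 <- reconstruct_exposures("6C", tab2)
  expect_rel_equal(r2$pec_uM, 2 * r1$pec_uM, 1e-12)
  bad <- tab; bad$ac10[1] <- 0
  expect_error(reconstruct_exposures("6C", bad), "positive")
})

test_that("reconstructed exposures round-trip through the forward model", {
  tab <- generate_chemical_table(synthetic_table_spec(n_chemicals = 6, seed = 14))
  for (obs in c("whole_body", "tissue:gonads")) {
    rec <- reconstruct_exposures("7C", tab, observable = obs)
    for (i in seq_len(nrow(tab))) {
      chem <- chemical_descriptor(tab$name[i], tab$log_kow[i], k_met = tab$k_met[i])
      ss <- steady_state("7C", chem, rec$pec_uM[i])
      back <- if (identical(obs, "whole_body")) ss$whole_body else ss$c_ss[["gonads"]]
      expect_rel_equal(back, tab$ac10[i], 1e-9)
    }
  }
})

test_that("a model compared against itself gives an all-zero ratio grid", {
  g <- prediction_ratio_grid("6C", "6C",
                             log10_kmet_grid = seq(-6, -2, length.out = 4),
                             log10_kow_grid = seq(0, 6, length.out = 4))
  expect_equal(max(abs(g$log10_ratio)), 0)
})

test_that("the ratio grid is independent of the observed concentration", {
  km <- seq(-6, -2, length.out = 5); ko <- seq(0, 7, length.out = 5)
  g1 <- prediction_ratio_grid("6C", "1C", km, ko, c_body = 1)
  g100 <- prediction_ratio_grid("6C", "1C", km, ko, c_body = 100)
  expect_lt(max(abs(g1$log10_ratio - g100$log10_ratio)), 1e-9)
  expect_error(prediction_ratio_grid("6C", "1C", km, ko, c_body = -1), "c_body")
})

test_that("clearance has little leverage at low lipophilicity", {
  # at K_ow = 1 partitioning is water-like and clearance barely moves the
  # prediction ratio, while at very high K_ow the same clearance axis swings
  # the ratio by orders of magnitude (chemical must partition into tissue
  # before metabolism can destroy it)
  km <- seq(-7, -1, length.out = 13)
  for (pair in list(c("6C", "1C"), c("7C", "1C"))) {
    g <- prediction_ratio_grid(pair[1], pair[2], km, c(0, 8))
    span_low <- diff(range(g$log10_ratio[, 1]))
    span_high <- diff(range(g$log10_ratio[, 2]))
    expect_lt(span_low, span_high / 4)
  }
  # in the slow-clearance regime the low-K_ow ratio is flat to within 5%
  km_slow <- seq(-7, -5, length.out = 9)
  g <- prediction_ratio_grid("6C", "1C", km_slow, c(0, 0.5))
  for (j in 1:2)
    expect_lt(diff(range(g$log10_ratio[, j])), log10(1.05))
})
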