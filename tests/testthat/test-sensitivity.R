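test_that("beta moment-matching reproduces the worked example", {
  f <- fit_beta_from_range(0.5, 0.304, 0.696)
  expect_equal(f$shape1, 12, tolerance = 1e-10)
  expect_equal(f$shape2, 12, tolerance = 1e-10)
  expect_identical(fit_beta_from_range(0.3, 0.3, 0.3),
                   list(family = "fixed", value = 0.3))
  expect_warning(fit_beta_from_range(0.9, 0.1, 0.5), "outside its range")
})

test_that("fitted families recover their base values", {
  set.seed(11)
  for (i in 1:100) {
    m <- stats::runif(1, 0.05, 0.95)
    half <- stats::runif(1, 0.005, min(m, 1 - m) * 0.9)
    f <- fit_beta_from_range(m, m - half, m + half)
    expect_equal(strokecea:::spec_mean(f), m, tolerance = 1e-6)
  }
  for (i in 1:50) {
    m <- stats::runif(1, 1, 30000)
    f <- fit_gamma_from_range(m, m * 0.5, m * 1.5)
    expect_equal(strokecea:::spec_mean(f), m, tolerance = 1e-6)
    fl <- fit_lognormal_from_ci(m, m * 0.7, m * 1.4)
    expect_equal(exp(fl$meanlog), m, tolerance = 1e-6)  # median
  }
})

test_that("Dirichlet day-90 draws have the multinomial moments", {
  p <- default_parameters()
  set.seed(5)
  d <- sample_dirichlet_day90(p$arms$edaravone, n = 10000)
  expect_equal(rowSums(d), rep(1, 10000))
  expect_true(all(abs(colMeans(d) - p$arms$edaravone$day90 /
                        sum(p$arms$edaravone$day90)) < 0.01))
  # marginal sd of mrs01: sqrt(p(1-p)/(n+1))
  expect_equal(sd(d[, "mrs01"]), sqrt(0.59 * 0.41 / 601), tolerance = 0.05)
  # concentration limit
  big <- p$arms$edaravone; big$arm_size <- 1e8
  db <- sample_dirichlet_day90(big, n = 50)
  expect_true(all(abs(t(db) - big$day90 / sum(big$day90)) < 1e-3))
})

test_that("tornado entries are sorted, spread-consistent and complete", {
  p <- default_parameters(utility_preset = "table1")
  tor <- owsa(p, horizon = 30)
  expect_setequal(tor$parameter_id, p$ranges$parameter_id)
  expect_true(all(diff(tor$spread) <= 0))
  expect_equal(tor$spread, abs(tor$high_inmb - tor$low_inmb))
  # degenerate range collapses to zero spread
  pd <- p
  i <- match("cost_injection", pd$ranges$parameter_id)
  pd$ranges$low[i] <- pd$ranges$high[i] <- pd$ranges$base[i]
  tor2 <- owsa(pd, horizon = 5)
  expect_equal(tor2$spread[tor2$parameter_id == "cost_injection"], 0)
})

test_that("PSA is reproducible, self-consistent and degenerates to base case", {
  p <- degenerate_ranges(default_parameters())
  p$arms$edaravone$arm_size <- 1e10
  p$arms$edaravone_dexborneol$arm_size <- 1e10
  base <- cea(p, horizons = c(1, 30))$results
  res <- run_psa(p, n_iterations = 1, seed = 3, horizons = c(1, 30))
  expect_equal(res$samples$delta_qaly, base$delta_qaly, tolerance = 1e-3)
  expect_equal(res$samples$delta_cost, base$delta_cost, tolerance = 1e-2)

  q <- default_parameters()
  a <- run_psa(q, n_iterations = 25, seed = 99, horizons = c(1, 30))
  b <- run_psa(q, n_iterations = 25, seed = 99, horizons = c(1, 30))
  expect_identical(a$samples, b$samples)
  expect_identical(a$ceac, b$ceac)

  # every drawn day-90 distribution and probability parameter is valid,
  # and INMB is the linear form of the recorded increments
  expect_equal(a$samples$inmb,
               a$samples$delta_qaly * q$econ$wtp_per_qaly - a$samples$delta_cost)
})

test_that("CEAC equals the count rule and rises with WTP for QALY gains", {
  p <- default_parameters(utility_preset = "table1")
  res <- run_psa(p, n_iterations = 60, seed = 21, horizons = 30,
                 wtp_grid = seq(0, 300000, by = 50000))
  s <- res$samples
  for (w in unique(res$ceac$wtp)) {
    expect_equal(res$ceac$prob_cost_effective[res$ceac$wtp == w],
                 mean(s$delta_qaly * w - s$delta_cost > 0))
  }
  # the scalar probability matches the CEAC read off at the threshold WTP
  res2 <- run_psa(p, n_iterations = 40, seed = 8, horizons = 30,
                  wtp_grid = c(0, p$econ$wtp_per_qaly, 300000))
  expect_equal(unname(res2$prob_cost_effective),
               res2$ceac$prob_cost_effective[res2$ceac$wtp == p$econ$wtp_per_qaly])
  # restricted to draws with positive QALY gain the curve is monotone
  pos <- s[s$delta_qaly > 0, ]
  grid <- seq(0, 300000, by = 50000)
  curve <- vapply(grid, function(w) mean(pos$delta_qaly * w - pos$delta_cost > 0),
                  numeric(1))
  expect_true(all(diff(curve) >= 0))
})

test_that("sensitivity writers produce the documented CSVs", {
  p <- default_parameters()
  d <- withr::local_tempdir()
  res <- run_psa(p, n_iterations = 5, seed = 1, horizons = 30)
  write_sensitivity(res, d)
  expect_true(file.exists(file.path(d, "psa_samples.csv")))
  expect_true(file.exists(file.path(d, "ceac.csv")))
  tor <- owsa(p, horizon = 1)
  write_sensitivity(tor, d)
  expect_identical(utils::read.csv(file.path(d, "tornado.csv"))$parameter_id,
                   tor$parameter_id)
})
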