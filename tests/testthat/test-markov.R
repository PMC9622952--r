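test_that("recurrence probability follows the growing-rate closed form", {
  expect_equal(recurrence_prob(0.12, 1.019, 1), 1 - exp(-0.12))
  expect_equal(recurrence_prob(0.12, 1.019, 1), 0.11307956, tolerance = 1e-7)
  expect_equal(recurrence_prob(0.12, 1.019, 2), 1 - exp(-0.12 * 1.019))
  expect_equal(recurrence_prob(0.12, 1.019, 2), 0.11509944, tolerance = 1e-7)
  expect_equal(recurrence_prob(0.12, 1, 17), recurrence_prob(0.12, 1, 1))
  expect_equal(recurrence_prob(0.12, 1.019, 3, mode = "literal"),
               0.12 * 1.019^2)
  expect_error(recurrence_prob(0.5, 1.25, 12), "pathological")
})

test_that("transition matrix rows are conservative and structurally right", {
  p <- default_parameters()
  lt <- gompertz_life_table()
  m <- build_transition_matrix(p, lt, 1, 63)
  expect_equal(rowSums(m), setNames(rep(1, 7), rownames(m)))
  expect_true(all(m >= 0 & m <= 1))
  # dead is absorbing
  expect_equal(unname(m["dead", ]), c(0, 0, 0, 0, 0, 0, 1))
  # tunnels empty completely each cycle
  expect_equal(unname(m[c("tunnel01", "tunnel23", "tunnel45"),
                        c("tunnel01", "tunnel23", "tunnel45")]),
               matrix(0, 3, 3))

  # no recurrence, no mortality: identity on the alive states
  p0 <- no_event_parameters()
  m0 <- build_transition_matrix(p0, null_mortality_table(), 1, 63)
  expect_equal(m0[1:3, 1:3], diag(3), ignore_attr = TRUE, tolerance = 1e-12)

  # tunnel exit with negligible background mortality: 0.21 dead, 0.79 back
  mt <- build_transition_matrix(p, null_mortality_table(), 1, 63)
  expect_equal(mt["tunnel01", "dead"], 0.21, tolerance = 1e-12)
  expect_equal(mt["tunnel01", "post01"], 0.79, tolerance = 1e-12)

  # a worsening destination matrix redirects tunnel survivors
  pw <- p
  pw$recurrence_destination <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 1), 3, 3,
                                      byrow = TRUE)
  mw <- build_transition_matrix(pw, null_mortality_table(), 1, 63)
  expect_equal(mw["tunnel01", "post23"], 0.79, tolerance = 1e-12)
  expect_equal(mw["tunnel01", "post01"], 0)
})

test_that("row sums hold across perturbed parameter space and ages", {
  lt <- gompertz_life_table()
  for (p in perturbed_sets(15)) {
    for (cyc in c(1, 10, 30)) {
      m <- build_transition_matrix(p, lt, cyc, 62 + cyc)
      expect_equal(rowSums(m), setNames(rep(1, 7), rownames(m)))
    }
  }
})

test_that("cohort trace conserves mass, absorbs into death, hits limits", {
  p <- default_parameters()
  lt <- gompertz_life_table()
  tr <- run_cohort(build_acute_outcome(p, "edaravone"), p, lt, 30)
  occ <- as.matrix(tr[, strokecea:::EXPANDED_STATES])
  expect_equal(unname(rowSums(occ)), rep(1, 31))
  expect_true(all(diff(tr$dead) >= 0))
  expect_error(run_cohort(build_acute_outcome(p, "edaravone"), p, lt, 40),
               "life table")

  # zero mortality / recurrence / discount with unit utilities:
  # 0.25 acute quarter + one QALY per full annual cycle
  p0 <- no_event_parameters()
  p0$switches$first_cycle_mode <- "full_year"
  tr0 <- run_cohort(build_acute_outcome(p0, "edaravone"), p0,
                    null_mortality_table(), 7)
  expect_equal(sum(tr0$qaly_disc), 0.25 + 7, tolerance = 1e-9)
  # default first-cycle mode charges 0.75 y for cycle 1
  p1 <- no_event_parameters()
  tr1 <- run_cohort(build_acute_outcome(p1, "edaravone"), p1,
                    null_mortality_table(), 7)
  expect_equal(sum(tr1$qaly_disc), 7, tolerance = 1e-9)
})

test_that("discounting is geometric in the cycle index", {
  # constant flow of 100/cycle for cycles 1..2 at 5%
  p <- no_event_parameters()
  p$econ$discount_rate <- 0.05
  p$switches$first_cycle_mode <- "full_year"
  p$costs$posthosp_annual[] <- 100
  p$arms$edaravone$day90 <- c(mrs01 = 1, mrs23 = 0, mrs45 = 0, dead = 0)
  ac <- build_acute_outcome(p, "edaravone")
  tr <- run_cohort(ac, p, null_mortality_table(), 2)
  expect_equal(tr$cost_disc[2:3], c(100 / 1.05, 100 / 1.05^2))
  # start-of-cycle timing shifts the exponent down by one
  p$switches$discount_timing <- "start_of_cycle"
  tr2 <- run_cohort(ac, p, null_mortality_table(), 2)
  expect_equal(tr2$cost_disc[2:3], c(100, 100 / 1.05))
})

test_that("total QALYs fall as discounting, mortality or recurrence grow", {
  lt <- gompertz_life_table()
  total_q <- function(p) {
    sum(run_cohort(build_acute_outcome(p, "edaravone"), p, lt, 30)$qaly_disc)
  }
  base <- default_parameters()
  qs <- sapply(c(0, 0.03, 0.05, 0.08), function(r) {
    p <- base; p$econ$discount_rate <- r; total_q(p)
  })
  expect_true(all(diff(qs) < 0))
  qs <- sapply(c(1, 1.5, 2.5), function(h) {
    p <- base; p$transitions$nonstroke_death_hr[["mrs45"]] <- h; total_q(p)
  })
  expect_true(all(diff(qs) < 0))
  qs <- sapply(c(0.05, 0.12, 0.3), function(r) {
    p <- base; p$transitions$annual_recurrence_rate <- r; total_q(p)
  })
  expect_true(all(diff(qs) < 0))
})

test_that("trace CSV writer emits a deterministic rectangular file", {
  p <- default_parameters()
  tr <- run_cohort(build_acute_outcome(p, "edaravone"), p,
                   gompertz_life_table(), 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), names(as.data.frame(tr)))
  expect_equal(back$qaly_disc, tr$qaly_disc)
})
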