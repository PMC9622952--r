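test_that("defaults reproduce the tabulated base case", {
  p <- default_parameters()
  expect_equal(p$arms$edaravone_dexborneol$day90,
               c(mrs01 = 0.672, mrs23 = 0.237, mrs45 = 0.078, dead = 0.014))
  expect_equal(p$arms$edaravone$day90,
               c(mrs01 = 0.590, mrs23 = 0.281, mrs45 = 0.112, dead = 0.017))
  expect_identical(p$transitions$annual_recurrence_rate, 0.12)
  expect_identical(p$transitions$recurrence_growth_rr, 1.019)
  expect_identical(p$transitions$recurrent_death_prob, 0.21)
  expect_equal(p$transitions$nonstroke_death_hr,
               c(mrs01 = 1.00, mrs23 = 1.19, mrs45 = 2.04))
  expect_identical(p$costs$recurrence_cost, 28987.05)
  expect_identical(p$costs$injection_cost, 7.25)
  expect_identical(p$arms$edaravone_dexborneol$drug_course_cost, 4099.20)
  expect_identical(p$econ$wtp_per_qaly, 121464)
  expect_identical(p$econ$discount_rate, 0.05)
  expect_equal(p$utilities$state_utility,
               c(mrs01 = 0.80, mrs23 = 0.58, mrs45 = 0.28, dead = 0))
  expect_identical(p$utilities$recurrence_utility, 0.34)
})

test_that("the two utility presets carry the intended weights", {
  expect_equal(default_parameters("text")$utilities$state_utility,
               c(mrs01 = 0.84, mrs23 = 0.78, mrs45 = 0.36, dead = 0))
  p <- set_utility_preset(default_parameters(), "text")
  expect_identical(p$utilities$preset, "text")
  # range bases follow the active preset so sensitivity analyses stay centred
  expect_equal(p$ranges$base[p$ranges$parameter_id == "utility_mrs45"], 0.36)
})

test_that("validation rejects broken inputs and names the rule", {
  p <- default_parameters()
  bad <- p; bad$arms$edaravone$day90 <- c(mrs01 = 0.5, mrs23 = 0.3,
                                          mrs45 = 0.08, dead = 0.02)
  expect_error(validate_parameters(bad), "sums to")
  bad <- p; bad$costs$recurrence_cost <- NaN
  expect_error(validate_parameters(bad), "costs")
  bad <- p; bad$utilities$state_utility[["mrs23"]] <- 0.9
  expect_error(validate_parameters(bad), "non-increasing")
  bad <- p; bad$econ$discount_rate <- 0.09
  expect_error(validate_parameters(bad), "discount_rate")
  bad <- p; bad$ranges$parameter_id[2] <- "no_such_field"
  expect_error(validate_parameters(bad), "no_such_field")
  # edge of the admissible discount range is valid
  ok <- p; ok$econ$discount_rate <- 0
  expect_silent(validate_parameters(ok))
})

test_that("configuration round-trip is lossless and the bundled file matches", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  expect_equal(unclass(load_parameters(f)), unclass(p), tolerance = 0)

  p$efficacy_or$odds_ratio <- 1.81; p$efficacy_or$ci_high <- 1.81
  write_parameters(p, f)
  expect_identical(load_parameters(f)$efficacy_or$odds_ratio, 1.81)

  bad <- p; bad$costs$recurrence_cost <- NaN
  expect_error(write_parameters(bad, f), "costs")

  bundled <- system.file("extdata", "default_parameters.yaml",
                         package = "strokecea")
  expect_equal(unclass(load_parameters(bundled)),
               unclass(default_parameters()), tolerance = 0)
})

test_that("parameter getter/setter resolve every ranged identifier", {
  p <- default_parameters()
  for (id in setdiff(p$ranges$parameter_id, "or_mrs01")) {
    i <- match(id, p$ranges$parameter_id)
    expect_identical(get_parameter(p, id), p$ranges$base[i])
    p2 <- set_parameter(p, id, 0.123)
    expect_identical(get_parameter(p2, id), 0.123)
  }
  expect_error(get_parameter(p, "bogus"), "unknown parameter")
})
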