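#' Specification for synthetic test fixtures
#'
#' Bundles the seed, Gompertz life-table calibration, and perturbation
#' settings used to generate every synthetic input the test-suite needs.
#'
#' @param seed Integer RNG seed.
#' @param a,b,age_min,age_max Gompertz life-table calibration (see
#'   [gompertz_life_table()]).
#' @param perturbation_scale Relative standard deviation of the
#'   multiplicative perturbations applied to parameter values.
#' @param n_parameter_sets Number of perturbed parameter sets to generate.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed = 20631L, a = 2.0e-5, b = 0.085,
                         age_min = 63L, age_max = 93L,
                         perturbation_scale = 0.1, n_parameter_sets = 20L) {
  stopifnot(perturbation_scale >= 0, n_parameter_sets >= 1)
  structure(list(seed = seed, a = a, b = b, age_min = age_min,
                 age_max = age_max, perturbation_scale = perturbation_scale,
                 n_parameter_sets = n_parameter_sets),
            class = "fixture_spec")
}

#' Generate the life-table fixture
#'
#' Deterministic delegation to [gompertz_life_table()]; optionally writes
#' the two-column text fixture so that tests can assert byte-identical
#' regeneration.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional output path for the text fixture.
#' @return A \code{life_table}.
#' @export
make_life_table_fixture <- function(spec = fixture_spec(), path = NULL) {
  lt <- gompertz_life_table(spec$a, spec$b, spec$age_min, spec$age_max)
  if (!is.null(path)) write_life_table(lt, path)
  lt
}

perturb_positive <- function(x, scale) {
  # mean-preserving multiplicative lognormal noise
  x * exp(stats::rnorm(length(x), -scale^2 / 2, scale))
}

perturb_prob <- function(p, scale) {
  stats::plogis(stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) +
                stats::rnorm(length(p), 0, scale))
}

#' Generate perturbed parameter sets for property testing
#'
#' Draws independent multiplicative lognormal perturbations (mean-preserving)
#' of every positive-valued input and logit-scale perturbations of every
#' probability, renormalizes the day-90 distributions, enforces the utility
#' ordering, and revalidates.  Sets violating any invariant are resampled
#' (bounded retries).
#'
#' @param spec A [fixture_spec()].
#' @return A list of \code{spec$n_parameter_sets} valid
#'   \code{cea_parameters} objects.
#' @export
make_perturbed_parameters <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  s <- spec$perturbation_scale
  base <- default_parameters()
  one <- function() {
    if (s == 0) return(base)
    p <- base
    for (arm in names(p$arms)) {
      d <- perturb_prob(p$arms[[arm]]$day90, s)
      p$arms[[arm]]$day90 <- d / sum(d)
    }
    tr <- p$transitions
    tr$annual_recurrence_rate <- perturb_positive(tr$annual_recurrence_rate, s)
    tr$recurrence_growth_rr <- 1 + perturb_positive(tr$recurrence_growth_rr - 1, s)
    tr$recurrent_death_prob <- perturb_prob(tr$recurrent_death_prob, s)
    hr <- 1 + perturb_positive(tr$nonstroke_death_hr - 1 + 1e-9, s)
    tr$nonstroke_death_hr[] <- hr
    p$transitions <- tr
    co <- p$costs
    co$injection_cost <- perturb_positive(co$injection_cost, s)
    co$hosp_onetime[] <- perturb_positive(co$hosp_onetime, s)
    co$posthosp_annual[] <- perturb_positive(co$posthosp_annual, s)
    co$recurrence_cost <- perturb_positive(co$recurrence_cost, s)
    p$costs <- co
    for (arm in names(p$arms))
      p$arms[[arm]]$drug_course_cost <-
        perturb_positive(p$arms[[arm]]$drug_course_cost, s)
    u <- perturb_prob(p$utilities$state_utility[ALIVE_BANDS], s)
    p$utilities$state_utility[ALIVE_BANDS] <- sort(u, decreasing = TRUE)
    p$utilities$recurrence_utility <- perturb_prob(p$utilities$recurrence_utility, s)
    p
  }
  out <- vector("list", spec$n_parameter_sets)
  for (i in seq_len(spec$n_parameter_sets)) {
    for (try in 1:50) {
      p <- one()
      ok <- !inherits(try(validate_parameters(p), silent = TRUE), "try-error")
      if (ok) break
    }
    if (!ok) stop("could not generate a valid perturbed parameter set",
                  call. = FALSE)
    out[[i]] <- p
  }
  out
}

#' Individual-level microsimulation oracle for the cohort engine
#'
#' Simulates \code{n_individuals} patients through exactly the per-cycle
#' transition probabilities the deterministic cohort engine uses, by direct
#' multinomial sampling.  Its per-cycle occupancy proportions converge to
#' the cohort trace, which makes it an independent cross-check (it is a test
#' oracle, not a modelling feature).
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of simulated patients.
#' @param seed Integer RNG seed.
#' @return A data frame of occupancy proportions: cycle plus one column per
#'   expanded state.
#' @export
microsim_oracle <- function(acute, params, table, horizon_years,
                            n_individuals = 1e5, seed = 1L) {
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  n <- as.integer(n_individuals)
  # entry states: day-90 bands mapped onto post states / dead
  entry_p <- c(acute$day90[ALIVE_BANDS], acute$day90[["dead"]])
  state <- sample.int(7L, n, replace = TRUE,
                      prob = c(entry_p[1:3], 0, 0, 0, entry_p[4]))
  occ <- matrix(0, horizon_years + 1L, 7L,
                dimnames = list(NULL, EXPANDED_STATES))
  occ[1L, ] <- tabulate(state, 7L) / n
  ages <- params$econ$entry_age + seq_len(horizon_years) - 1L
  for (t in seq_len(horizon_years)) {
    m <- build_transition_matrix(params, table, t, ages[t])
    newstate <- state
    for (k in which(tabulate(state, 7L) > 0)) {
      idx <- which(state == k)
      cum <- cumsum(m[k, ])
      newstate[idx] <- findInterval(stats::runif(length(idx)), cum,
                                    left.open = TRUE) + 1L
    }
    state <- newstate
    occ[t + 1L, ] <- tabulate(state, 7L) / n
  }
  data.frame(cycle = 0:horizon_years, occ)
}
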