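# Expanded Markov state space: three post-stroke disability bands, three
# one-cycle recurrent-stroke tunnel states (indexed by the pre-recurrence
# band), and the absorbing dead state.
EXPANDED_STATES <- c("post01", "post23", "post45",
                     "tunnel01", "tunnel23", "tunnel45", "dead")
POST_STATES <- 1:3
TUNNEL_STATES <- 4:6
DEAD_STATE <- 7L

#' Per-cycle recurrent-stroke probability
#'
#' The annual recurrence rate grows multiplicatively with each life year:
#' \eqn{r_t = r_1 \cdot g^{t-1}} for cycle \eqn{t}.  Under the default
#' exponential rate-to-probability conversion the cycle probability is
#' \eqn{1 - e^{-r_t}}; the \code{"literal"} mode uses the rate directly as a
#' probability.
#'
#' @param base_rate First-cycle recurrence rate per patient-year (>= 0).
#' @param growth_rr Multiplicative growth per life year (> 0).
#' @param cycle_index Cycle number, >= 1.
#' @param mode \code{"exponential"} (default) or \code{"literal"}.
#' @return Probability of a recurrent stroke during the cycle.
#' @export
#' @examples
#' recurrence_prob(0.12, 1.019, 1)
recurrence_prob <- function(base_rate, growth_rr, cycle_index,
                            mode = c("exponential", "literal")) {
  mode <- match.arg(mode)
  stopifnot(base_rate >= 0, growth_rr > 0, cycle_index >= 1)
  rate <- base_rate * growth_rr^(cycle_index - 1)
  if (any(rate >= 5))
    stop("recurrence rate >= 5 per year is pathological", call. = FALSE)
  if (mode == "literal") pmin(rate, 1) else 1 - exp(-rate)
}

#' Cycle-specific transition matrix over the expanded state space
#'
#' Competing risks are combined multiplicatively, recurrence first and then
#' death.  From a post-stroke band: recurrence moves patients into that
#' band's tunnel state; the non-recurring mass dies with the
#' disability-adjusted background probability and otherwise stays.  From a
#' tunnel state: patients die with the recurrent-stroke death probability
#' plus background mortality on survivors; the surviving mass is distributed
#' over the post-stroke bands by the recurrence destination matrix (default:
#' back to the pre-recurrence band).  Dead is absorbing.
#'
#' @param params A \code{cea_parameters} object.
#' @param table A \code{life_table} covering \code{age}.
#' @param cycle_index Cycle number, >= 1 (drives recurrence growth).
#' @param age Cohort age during the cycle.
#' @return A 7x7 row-stochastic matrix with dimnames \code{EXPANDED_STATES}.
#' @export
build_transition_matrix <- function(params, table, cycle_index, age) {
  q <- background_q(table, age)
  tr <- params$transitions
  sw <- params$switches
  p_rec <- recurrence_prob(tr$annual_recurrence_rate, tr$recurrence_growth_rr,
                           cycle_index, mode = sw$rate_to_prob)
  q_adj <- adjust_q(q, tr$nonstroke_death_hr, mode = sw$mortality_hr_mode)
  d_rec <- tr$recurrent_death_prob
  dest <- params$recurrence_destination

  m <- matrix(0, 7L, 7L, dimnames = list(EXPANDED_STATES, EXPANDED_STATES))
  for (i in 1:3) {
    m[i, TUNNEL_STATES[i]] <- p_rec
    m[i, DEAD_STATE] <- (1 - p_rec) * q_adj[i]
    m[i, i] <- (1 - p_rec) * (1 - q_adj[i])
    p_die <- d_rec + (1 - d_rec) * q_adj[i]
    m[TUNNEL_STATES[i], DEAD_STATE] <- p_die
    m[TUNNEL_STATES[i], POST_STATES] <- (1 - p_die) * dest[i, ]
  }
  m[DEAD_STATE, DEAD_STATE] <- 1
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9))
    stop("internal error: transition-matrix row sums deviate from 1",
         call. = FALSE)
  m
}

#' Run the Markov cohort model for one arm
#'
#' Propagates the day-90 cohort through annual cycles, accumulating
#' discounted costs and QALYs.  Cycle 0 is the acute quarter: occupancy is
#' the day-90 distribution mapped onto the post-stroke states, cost is the
#' acute cost, and QALYs are 0.25 years at day-90 utilities, undiscounted
#' and without half-cycle correction.  Cycles 1..H apply the cycle-specific
#' transition matrix at age \code{entry_age + cycle - 1}.  Per-cycle QALYs
#' value post-stroke occupancy at the state utilities and tunnel occupancy
#' at the recurrence utility; per-cycle costs charge annual
#' post-hospitalization maintenance on post-stroke occupancy and the
#' per-event recurrence cost on tunnel occupancy.  State-derived flows use
#' the average of start- and end-of-cycle occupancy (half-cycle correction)
#' and are discounted by \eqn{(1+r)^{-t}} (with
#' \code{switches$discount_timing = "start_of_cycle"}, by
#' \eqn{(1+r)^{-(t-1)}}, leaving the first model year undiscounted as many
#' spreadsheet implementations do).  Under the default
#' \code{first_cycle_mode = "fractional_075"} cycle 1 contributes 0.75
#' years of time-scaled flows, completing the first model year after the
#' acute quarter; \code{"full_year"} values every cycle at one year.
#'
#' @param acute An \code{acute_outcome} from [build_acute_outcome()].
#' @param params A \code{cea_parameters} object.
#' @param table A \code{life_table} covering the whole horizon.
#' @param horizon_years Number of annual cycles (>= 1).
#' @return A \code{cohort_trace}: data frame with cycle, age, occupancy of
#'   the seven expanded states, and discounted cost and QALY increments.
#' @export
#' @examples
#' p <- default_parameters()
#' lt <- gompertz_life_table()
#' tr <- run_cohort(build_acute_outcome(p, "edaravone"), p, lt, 5)
#' sum(tr$cost_disc); sum(tr$qaly_disc)
run_cohort <- function(acute, params, table, horizon_years) {
  stopifnot(inherits(acute, "acute_outcome"), horizon_years >= 1)
  ec <- params$econ
  ages <- ec$entry_age + seq_len(horizon_years) - 1L
  if (any(!(ages %in% table$age)))
    stop("horizon exceeds the life table's age range", call. = FALSE)

  u <- params$utilities$state_utility
  u_state <- c(u[ALIVE_BANDS],
               rep(params$utilities$recurrence_utility, 3), 0)
  c_state <- c(params$costs$posthosp_annual[["mrs01"]],
               rep(params$costs$posthosp_annual[["mrs25"]], 2), rep(0, 4))
  c_event <- c(rep(0, 3), rep(params$costs$recurrence_cost, 3), 0)
  r <- ec$discount_rate
  hcc <- isTRUE(ec$half_cycle_correction)
  # end_of_cycle divides cycle-t flows by (1+r)^t; start_of_cycle leaves the
  # first model year undiscounted, dividing by (1+r)^(t-1)
  t_offset <- if (identical(params$switches$discount_timing, "start_of_cycle"))
    1 else 0

  occ <- matrix(0, horizon_years + 1L, 7L,
                dimnames = list(NULL, EXPANDED_STATES))
  occ[1L, POST_STATES] <- acute$day90[ALIVE_BANDS]
  occ[1L, DEAD_STATE] <- acute$day90[["dead"]]
  cost <- qaly <- numeric(horizon_years + 1L)
  cost[1L] <- acute$acute_cost
  qaly[1L] <- 0.25 * sum(acute$day90 * u[MRS_BANDS])

  for (t in seq_len(horizon_years)) {
    m <- build_transition_matrix(params, table, t, ages[t])
    occ[t + 1L, ] <- occ[t, ] %*% m
    len <- if (t == 1L && params$switches$first_cycle_mode == "fractional_075")
      0.75 else ec$cycle_length_years
    w <- if (hcc) (occ[t, ] + occ[t + 1L, ]) / 2 else occ[t + 1L, ]
    disc <- (1 + r)^(-(t - t_offset))
    qaly[t + 1L] <- len * sum(w * u_state) * disc
    cost[t + 1L] <- (len * sum(w * c_state) + sum(w * c_event)) * disc
  }
  structure(data.frame(cycle = 0:horizon_years,
                       age = c(NA_integer_, ages), occ,
                       cost_disc = cost, qaly_disc = qaly),
            class = c("cohort_trace", "data.frame"),
            arm = acute$arm)
}

#' Run one arm end to end (decision tree + Markov cohort)
#'
#' @inheritParams build_acute_outcome
#' @param table A \code{life_table}; defaults to the Gompertz table from
#'   \code{params$life_table}.
#' @param horizon_years Number of annual cycles; defaults to
#'   \code{params$econ$horizon_years}.
#' @return A \code{cohort_trace}.
#' @export
run_arm <- function(params, arm, table = NULL, horizon_years = NULL,
                    or_override = NULL) {
  if (is.null(table)) table <- life_table_from_params(params)
  if (is.null(horizon_years)) horizon_years <- params$econ$horizon_years
  run_cohort(build_acute_outcome(params, arm, or_override), params, table,
             horizon_years)
}

life_table_from_params <- function(params) {
  lt <- params$life_table
  gompertz_life_table(lt$a, lt$b, lt$age_min, lt$age_max)
}

#' Write a cohort trace to CSV
#' @param trace A \code{cohort_trace}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
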