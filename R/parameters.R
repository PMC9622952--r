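#' @keywords internal
"_PACKAGE"

# Health-state bands used throughout: modified Rankin Scale 0-1 (no
# disability), 2-3 (minor/moderate), 4-5 (severe), 6 (dead).
MRS_BANDS <- c("mrs01", "mrs23", "mrs45", "dead")
ALIVE_BANDS <- c("mrs01", "mrs23", "mrs45")

#' Utility-weight presets for the alive mRS bands
#'
#' Two utility sets are shipped because the source evidence is ambiguous:
#' \code{"table1"} is the tabulated base case (0.80 / 0.58 / 0.28) and
#' \code{"text"} is the set implied by the narrative utility range and by
#' back-calculation of the published one-year QALY levels
#' (0.84 / 0.78 / 0.36).  The dead state always has utility 0.
#'
#' @format A named list of named numeric vectors over the alive bands.
#' @export
utility_presets <- list(
  table1 = c(mrs01 = 0.80, mrs23 = 0.58, mrs45 = 0.28),
  text   = c(mrs01 = 0.84, mrs23 = 0.78, mrs45 = 0.36)
)

# parameter_id -> location inside the parameter object.  "or_mrs01" is
# special-cased by the sensitivity code (it acts through the odds-ratio
# override of the intervention arm, not through a stored field).
PARAM_PATHS <- list(
  recurrence_rate       = c("transitions", "annual_recurrence_rate"),
  recurrence_growth     = c("transitions", "recurrence_growth_rr"),
  recurrent_death       = c("transitions", "recurrent_death_prob"),
  hr_mrs01              = c("transitions", "nonstroke_death_hr", "mrs01"),
  hr_mrs23              = c("transitions", "nonstroke_death_hr", "mrs23"),
  hr_mrs45              = c("transitions", "nonstroke_death_hr", "mrs45"),
  cost_drug_dexborneol  = c("arms", "edaravone_dexborneol", "drug_course_cost"),
  cost_drug_edaravone   = c("arms", "edaravone", "drug_course_cost"),
  cost_injection        = c("costs", "injection_cost"),
  cost_hosp_mrs01       = c("costs", "hosp_onetime", "mrs01"),
  cost_hosp_mrs25       = c("costs", "hosp_onetime", "mrs25"),
  cost_hosp_dead        = c("costs", "hosp_onetime", "dead"),
  cost_posthosp_mrs01   = c("costs", "posthosp_annual", "mrs01"),
  cost_posthosp_mrs25   = c("costs", "posthosp_annual", "mrs25"),
  cost_recurrence       = c("costs", "recurrence_cost"),
  utility_mrs01         = c("utilities", "state_utility", "mrs01"),
  utility_mrs23         = c("utilities", "state_utility", "mrs23"),
  utility_mrs45         = c("utilities", "state_utility", "mrs45"),
  utility_recurrence    = c("utilities", "recurrence_utility"),
  discount_rate         = c("econ", "discount_rate")
)

#' Default model parameters
#'
#' Constructs the complete base-case parameter set in memory: per-arm day-90
#' mRS distributions and drug course costs, the efficacy odds ratio with its
#' confidence interval, recurrence and mortality inputs, costs (2021 CNY),
#' utilities, economic settings (5\% discounting, 30-year horizon, entry age
#' 63, willingness-to-pay 121,464 CNY/QALY) and the one-way/probabilistic
#' sensitivity ranges with their distribution families.
#'
#' @param utility_preset Which utility set to use for the alive states;
#'   see [utility_presets].
#' @return An object of class \code{cea_parameters}.
#' @seealso [load_parameters()], [write_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$transitions$annual_recurrence_rate
default_parameters <- function(utility_preset = c("table1", "text")) {
  utility_preset <- match.arg(utility_preset)
  u <- utility_presets[[utility_preset]]

  ranges <- data.frame(
    parameter_id = c(
      "or_mrs01",
      "recurrence_rate", "recurrence_growth", "recurrent_death",
      "hr_mrs01", "hr_mrs23", "hr_mrs45",
      "cost_drug_dexborneol", "cost_drug_edaravone", "cost_injection",
      "cost_hosp_mrs01", "cost_hosp_mrs25", "cost_hosp_dead",
      "cost_posthosp_mrs01", "cost_posthosp_mrs25", "cost_recurrence",
      "utility_mrs01", "utility_mrs23", "utility_mrs45",
      "utility_recurrence", "discount_rate"
    ),
    base = c(
      1.42,
      0.12, 1.019, 0.21,
      1.00, 1.19, 2.04,
      4099.20, 1103.48, 7.25,
      12593.51, 16650.77, 14269.82,
      8954.0, 13623.4, 28987.05,
      u[["mrs01"]], u[["mrs23"]], u[["mrs45"]],
      0.34, 0.05
    ),
    low = c(
      1.12,
      0.1123, 1.014, 0.1887,
      1.0, 1.1, 1.4,
      3279.36, 546, 5,
      7273.72, 9150.98, 6705.26,
      2681.05, 3426.66, 26088.35,
      0.80, 0.56, 0.05,
      0.27, 0
    ),
    high = c(
      1.81,
      0.1241, 1.024, 0.2316,
      1.2, 1.3, 3,
      4099.2, 5420.80, 12,
      15856.24, 21834.39, 18861.18,
      11420.88, 17131.99, 31885.76,
      0.95, 0.78, 0.36,
      0.42, 0.08
    ),
    family = c(
      "lognormal",
      "beta", "lognormal", "beta",
      "lognormal", "lognormal", "lognormal",
      "gamma", "gamma", "gamma",
      "gamma", "gamma", "gamma",
      "gamma", "gamma", "gamma",
      "beta", "beta", "beta",
      "beta", "fixed"
    ),
    stringsAsFactors = FALSE
  )

  params <- structure(list(
    arms = list(
      edaravone = list(
        name = "edaravone",
        day90 = c(mrs01 = 0.590, mrs23 = 0.281, mrs45 = 0.112, dead = 0.017),
        arm_size = 600,
        drug_course_cost = 1103.48
      ),
      edaravone_dexborneol = list(
        name = "edaravone_dexborneol",
        day90 = c(mrs01 = 0.672, mrs23 = 0.237, mrs45 = 0.078, dead = 0.014),
        arm_size = 600,
        drug_course_cost = 4099.20
      )
    ),
    control = "edaravone",
    intervention = "edaravone_dexborneol",
    efficacy_or = list(odds_ratio = 1.42, ci_low = 1.12, ci_high = 1.81),
    transitions = list(
      annual_recurrence_rate = 0.12,
      recurrence_growth_rr = 1.019,
      recurrent_death_prob = 0.21,
      nonstroke_death_hr = c(mrs01 = 1.00, mrs23 = 1.19, mrs45 = 2.04)
    ),
    costs = list(
      injection_cost = 7.25,
      n_administrations = 28,
      hosp_onetime = c(mrs01 = 12593.51, mrs25 = 16650.77, dead = 14269.82),
      posthosp_annual = c(mrs01 = 8954.0, mrs25 = 13623.4),
      recurrence_cost = 28987.05
    ),
    utilities = list(
      preset = utility_preset,
      state_utility = c(u, dead = 0),
      recurrence_utility = 0.34
    ),
    econ = list(
      discount_rate = 0.05,
      wtp_per_qaly = 121464,
      horizon_years = 30L,
      cycle_length_years = 1,
      entry_age = 63L,
      half_cycle_correction = TRUE
    ),
    life_table = list(a = 2.0e-5, b = 0.085, age_min = 63L, age_max = 93L),
    switches = list(
      mortality_hr_mode = "hazard_power",
      rate_to_prob = "exponential",
      first_cycle_mode = "fractional_075",
      discount_timing = "end_of_cycle",
      psa_efficacy_mode = "dirichlet"
    ),
    # row-stochastic destination of recurrent-stroke survivors: rows are the
    # pre-recurrence band, columns the post-recurrence band ("equal
    # disability" by default; worsening matrices are allowed)
    recurrence_destination = diag(3),
    ranges = ranges
  ), class = "cea_parameters")
  dimnames(params$recurrence_destination) <- list(ALIVE_BANDS, ALIVE_BANDS)
  validate_parameters(params)
  params
}

#' Validate a parameter object
#'
#' Checks every structural invariant: day-90 distributions sum to one, arm
#' sizes, probability and utility bounds, monotone utility ordering over
#' disability severity, non-negative costs, odds-ratio/CI ordering, economic
#' settings within their admissible ranges, a row-stochastic recurrence
#' destination matrix, and that every sensitivity range resolves to a real
#' field.
#'
#' @param params A \code{cea_parameters} object (or plain list with the same
#'   structure).
#' @return \code{params}, invisibly, if valid; otherwise an error naming the
#'   violated rule.
#' @export
validate_parameters <- function(params) {
  fail <- function(...) stop("parameter validation: ", sprintf(...), call. = FALSE)
  need <- function(x, where) {
    if (is.null(x)) fail("missing field '%s'", where)
    x
  }
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))

  arms <- need(params$arms, "arms")
  if (length(arms) < 2L) fail("both arms must be present")
  for (arm in arms) {
    d <- need(arm$day90, paste0("arms$", arm$name, "$day90"))
    if (!identical(names(d), MRS_BANDS))
      fail("day90 distribution of '%s' must be named %s", arm$name,
           paste(MRS_BANDS, collapse = ", "))
    if (!num_ok(d) || any(d < 0) || any(d > 1))
      fail("day90 probabilities of '%s' must lie in [0,1]", arm$name)
    # published distributions are rounded to 0.1 percentage points and may
    # miss 1 by up to 0.2%; the decision tree renormalizes before use
    if (abs(sum(d) - 1) > 2e-3)
      fail("day90 distribution of '%s' sums to %.6f, not 1", arm$name, sum(d))
    if (!num_ok(arm$arm_size) || arm$arm_size < 1)
      fail("arm_size of '%s' must be >= 1", arm$name)
    if (!num_ok(arm$drug_course_cost) || arm$drug_course_cost < 0)
      fail("drug_course_cost of '%s' must be a finite non-negative number", arm$name)
  }
  for (nm in c("control", "intervention"))
    if (!need(params[[nm]], nm) %in% names(arms))
      fail("'%s' arm '%s' not found among arms", nm, params[[nm]])

  or <- need(params$efficacy_or, "efficacy_or")
  if (!(or$ci_low > 0 && or$ci_low <= or$odds_ratio && or$odds_ratio <= or$ci_high))
    fail("efficacy odds ratio must satisfy 0 < ci_low <= odds_ratio <= ci_high")

  tr <- need(params$transitions, "transitions")
  if (!num_ok(tr$annual_recurrence_rate) || tr$annual_recurrence_rate < 0)
    fail("annual_recurrence_rate must be >= 0")
  if (!num_ok(tr$recurrence_growth_rr) || tr$recurrence_growth_rr <= 0)
    fail("recurrence_growth_rr must be > 0")
  if (!num_ok(tr$recurrent_death_prob) ||
      tr$recurrent_death_prob < 0 || tr$recurrent_death_prob > 1)
    fail("recurrent_death_prob must lie in [0,1]")
  hr <- need(tr$nonstroke_death_hr, "transitions$nonstroke_death_hr")
  if (!identical(names(hr), ALIVE_BANDS) || !num_ok(hr) || any(hr <= 0))
    fail("nonstroke_death_hr must be positive and named %s",
         paste(ALIVE_BANDS, collapse = ", "))

  co <- need(params$costs, "costs")
  cost_fields <- c(co$injection_cost, co$hosp_onetime, co$posthosp_annual,
                   co$recurrence_cost)
  if (!num_ok(cost_fields) || any(cost_fields < 0))
    fail("all costs must be finite and >= 0")
  if (!identical(names(co$hosp_onetime), c("mrs01", "mrs25", "dead")))
    fail("hosp_onetime must be named mrs01, mrs25, dead")
  if (!identical(names(co$posthosp_annual), c("mrs01", "mrs25")))
    fail("posthosp_annual must be named mrs01, mrs25")
  if (!num_ok(co$n_administrations) || co$n_administrations < 0)
    fail("n_administrations must be >= 0")

  ut <- need(params$utilities, "utilities")
  su <- need(ut$state_utility, "utilities$state_utility")
  if (!identical(names(su), MRS_BANDS))
    fail("state_utility must be named %s", paste(MRS_BANDS, collapse = ", "))
  if (!num_ok(su) || any(su < 0) || any(su > 1))
    fail("utilities must lie in [0,1]")
  if (su[["dead"]] != 0) fail("utility of the dead state must be 0")
  if (!(su[["mrs01"]] >= su[["mrs23"]] && su[["mrs23"]] >= su[["mrs45"]]))
    fail("utilities must be non-increasing in disability severity")
  if (!num_ok(ut$recurrence_utility) ||
      ut$recurrence_utility < 0 || ut$recurrence_utility > 1)
    fail("recurrence_utility must lie in [0,1]")

  ec <- need(params$econ, "econ")
  if (!num_ok(ec$discount_rate) || ec$discount_rate < 0 || ec$discount_rate > 0.08)
    fail("discount_rate must lie in [0, 0.08]")
  if (!num_ok(ec$horizon_years) || ec$horizon_years < 1)
    fail("horizon_years must be >= 1")
  if (!num_ok(ec$wtp_per_qaly) || ec$wtp_per_qaly < 0)
    fail("wtp_per_qaly must be >= 0")
  lt <- need(params$life_table, "life_table")
  if (ec$entry_age + ec$horizon_years > lt$age_max + 1)
    fail("entry_age + horizon_years exceeds the life-table age range")

  dest <- need(params$recurrence_destination, "recurrence_destination")
  if (!is.matrix(dest) || any(dim(dest) != 3L) || any(dest < 0) ||
      any(abs(rowSums(dest) - 1) > 1e-9))
    fail("recurrence_destination must be a 3x3 row-stochastic matrix")

  rg <- need(params$ranges, "ranges")
  unknown <- setdiff(rg$parameter_id, c("or_mrs01", names(PARAM_PATHS)))
  if (length(unknown))
    fail("range parameter_id does not resolve to a field: %s",
         paste(unknown, collapse = ", "))
  if (!all(rg$family %in% c("dirichlet", "beta", "gamma", "lognormal", "fixed")))
    fail("unknown distribution family in ranges")

  invisible(params)
}

#' Read one parameter value by its sensitivity-range identifier
#' @param params A \code{cea_parameters} object.
#' @param id A \code{parameter_id} from \code{params$ranges} (not
#'   \code{"or_mrs01"}, which has no stored field).
#' @return The scalar value.
#' @export
get_parameter <- function(params, id) {
  path <- PARAM_PATHS[[id]]
  if (is.null(path)) stop("unknown parameter id: ", id, call. = FALSE)
  x <- params
  for (k in path) x <- x[[k]]
  x
}

#' Set one parameter value by its sensitivity-range identifier
#' @inheritParams get_parameter
#' @param value Replacement scalar.
#' @return The modified \code{cea_parameters} object (not revalidated; one-way
#'   sensitivity analysis legitimately visits range edges such as a zero
#'   discount rate).
#' @export
set_parameter <- function(params, id, value) {
  path <- PARAM_PATHS[[id]]
  if (is.null(path)) stop("unknown parameter id: ", id, call. = FALSE)
  params[[path]] <- value
  params
}

## ---- configuration file I/O (YAML) ----------------------------------------

CONFIG_VERSION <- 1L

as_config_list <- function(params) {
  vec2list <- function(v) as.list(v)
  list(
    config_version = CONFIG_VERSION,
    arms = lapply(params$arms, function(a)
      list(name = a$name, day90 = vec2list(a$day90),
           arm_size = a$arm_size, drug_course_cost = a$drug_course_cost)),
    control = params$control,
    intervention = params$intervention,
    efficacy_or = params$efficacy_or,
    transitions = list(
      annual_recurrence_rate = params$transitions$annual_recurrence_rate,
      recurrence_growth_rr = params$transitions$recurrence_growth_rr,
      recurrent_death_prob = params$transitions$recurrent_death_prob,
      nonstroke_death_hr = vec2list(params$transitions$nonstroke_death_hr)
    ),
    costs = list(
      injection_cost = params$costs$injection_cost,
      n_administrations = params$costs$n_administrations,
      hosp_onetime = vec2list(params$costs$hosp_onetime),
      posthosp_annual = vec2list(params$costs$posthosp_annual),
      recurrence_cost = params$costs$recurrence_cost
    ),
    utilities = list(
      preset = params$utilities$preset,
      state_utility = vec2list(params$utilities$state_utility),
      recurrence_utility = params$utilities$recurrence_utility
    ),
    econ = params$econ,
    life_table = params$life_table,
    switches = params$switches,
    recurrence_destination = lapply(seq_len(nrow(params$recurrence_destination)),
                                    function(i) as.list(params$recurrence_destination[i, ])),
    ranges = lapply(seq_len(nrow(params$ranges)), function(i)
      as.list(params$ranges[i, , drop = FALSE]))
  )
}

from_config_list <- function(cfg) {
  list2vec <- function(l) unlist(l)
  rg <- do.call(rbind, lapply(cfg$ranges, function(r)
    data.frame(parameter_id = r$parameter_id, base = r$base, low = r$low,
               high = r$high, family = r$family, stringsAsFactors = FALSE)))
  dest <- do.call(rbind, lapply(cfg$recurrence_destination, list2vec))
  dimnames(dest) <- list(ALIVE_BANDS, ALIVE_BANDS)
  params <- structure(list(
    arms = lapply(cfg$arms, function(a)
      list(name = a$name, day90 = list2vec(a$day90),
           arm_size = a$arm_size, drug_course_cost = a$drug_course_cost)),
    control = cfg$control,
    intervention = cfg$intervention,
    efficacy_or = cfg$efficacy_or,
    transitions = list(
      annual_recurrence_rate = cfg$transitions$annual_recurrence_rate,
      recurrence_growth_rr = cfg$transitions$recurrence_growth_rr,
      recurrent_death_prob = cfg$transitions$recurrent_death_prob,
      nonstroke_death_hr = list2vec(cfg$transitions$nonstroke_death_hr)
    ),
    costs = list(
      injection_cost = cfg$costs$injection_cost,
      n_administrations = cfg$costs$n_administrations,
      hosp_onetime = list2vec(cfg$costs$hosp_onetime),
      posthosp_annual = list2vec(cfg$costs$posthosp_annual),
      recurrence_cost = cfg$costs$recurrence_cost
    ),
    utilities = list(
      preset = cfg$utilities$preset,
      state_utility = list2vec(cfg$utilities$state_utility),
      recurrence_utility = cfg$utilities$recurrence_utility
    ),
    econ = cfg$econ,
    life_table = cfg$life_table,
    switches = cfg$switches,
    recurrence_destination = dest,
    ranges = rg
  ), class = "cea_parameters")
  params
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML configuration (the format written by [write_parameters()];
#' currencies in CNY, rates per year, utilities dimensionless) and validates
#' every invariant before returning.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated \code{cea_parameters} object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$config_version))
    stop("schema error: missing field 'config_version'", call. = FALSE)
  params <- from_config_list(cfg)
  validate_parameters(params)
  params
}

#' Write model parameters to a configuration file
#'
#' Serializes a validated parameter object to YAML with 15 significant
#' digits so that \code{load_parameters(write_parameters(p))} reproduces
#' every numeric field exactly.
#'
#' @param params A valid \code{cea_parameters} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  header <- paste0(
    "# Cost-effectiveness model parameters (schema v", CONFIG_VERSION, ")\n",
    "# Units: costs in 2021 CNY; rates per patient-year; utilities in [0,1];\n",
    "# discount rate per year; ages and horizons in years.\n")
  body <- yaml::as.yaml(as_config_list(params), precision = 15L)
  writeLines(paste0(header, body), path)
  invisible(path)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Cost-effectiveness model parameters\n")
  cat("  arms:", paste(names(x$arms), collapse = " vs "), "\n")
  for (a in x$arms)
    cat(sprintf("    %-22s day-90 mRS: %s\n", a$name,
                paste(sprintf("%.3f", a$day90), collapse = " / ")))
  cat(sprintf("  utility preset: %s (%s)\n", x$utilities$preset,
              paste(sprintf("%.2f", x$utilities$state_utility[ALIVE_BANDS]),
                    collapse = " / ")))
  cat(sprintf("  horizon %d y, entry age %d, discount %.1f%%, WTP %s CNY/QALY\n",
              x$econ$horizon_years, x$econ$entry_age,
              100 * x$econ$discount_rate,
              format(x$econ$wtp_per_qaly, big.mark = ",")))
  cat(sprintf("  %d sensitivity ranges\n", nrow(x$ranges)))
  invisible(x)
}
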