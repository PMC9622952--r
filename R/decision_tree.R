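#' Convert a baseline probability through an odds ratio
#'
#' Returns the probability in the comparator group implied by a baseline
#' probability \code{p1} and an odds ratio:
#' \deqn{p_2 = \frac{OR \, p_1}{1 + (OR - 1) p_1}}
#' the inverse of \eqn{OR = [p_2/(1-p_2)] / [p_1/(1-p_1)]}.
#'
#' @param p1 Baseline probability, strictly inside (0, 1).
#' @param odds_ratio Odds ratio, > 0.
#' @return The transformed probability, strictly inside (0, 1).
#' @export
#' @examples
#' or_to_probability(0.5897, 1.42)
or_to_probability <- function(p1, odds_ratio) {
  if (any(p1 <= 0 | p1 >= 1))
    stop("p1 must lie strictly inside (0,1)", call. = FALSE)
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0", call. = FALSE)
  (odds_ratio * p1) / (1 + (odds_ratio - 1) * p1)
}

# one-time hospitalization cost class per mRS band
hosp_class <- c(mrs01 = "mrs01", mrs23 = "mrs25", mrs45 = "mrs25", dead = "dead")

#' Acute-phase (day-90) outcome of one treatment arm
#'
#' The short-term decision-tree stage: the day-90 mRS distribution of the arm
#' and its expected acute cost (full 14-day drug course, intravenous
#' injections, and the day-90-class one-time hospitalization cost; day-90
#' deaths incur the mRS 6 hospitalization cost and the full treatment cost).
#'
#' With \code{or_override} the arm is treated as the intervention and its
#' mRS 0--1 probability is derived from the control arm's by
#' [or_to_probability()]; the remaining mass is spread over mRS 2--3, 4--5
#' and dead in proportion to the arm's base-case shares of those states.
#' This is how efficacy uncertainty enters the sensitivity analyses.
#'
#' @param params A \code{cea_parameters} object.
#' @param arm Arm name in \code{params$arms}.
#' @param or_override Optional odds ratio replacing the arm's tabulated
#'   day-90 distribution (see Details).
#' @return An \code{acute_outcome} object: list with \code{arm},
#'   \code{day90} (named probability vector) and \code{acute_cost} (CNY).
#' @export
#' @examples
#' build_acute_outcome(default_parameters(), "edaravone")
build_acute_outcome <- function(params, arm, or_override = NULL) {
  a <- params$arms[[arm]]
  if (is.null(a)) stop("unknown arm: ", arm, call. = FALSE)
  d <- a$day90 / sum(a$day90)  # absorb printed-rounding residue
  if (!is.null(or_override)) {
    ctrl <- params$arms[[params$control]]
    p2 <- or_to_probability(ctrl$day90[["mrs01"]], or_override)
    rest <- d[c("mrs23", "mrs45", "dead")]
    d <- c(mrs01 = p2, (1 - p2) * rest / sum(rest))
    names(d) <- MRS_BANDS
  }
  acute_cost <- a$drug_course_cost +
    params$costs$injection_cost * params$costs$n_administrations +
    sum(d * params$costs$hosp_onetime[hosp_class[names(d)]])
  structure(list(arm = arm, day90 = d, acute_cost = unname(acute_cost)),
            class = "acute_outcome")
}

#' @export
print.acute_outcome <- function(x, ...) {
  cat(sprintf("Acute (day-90) outcome, arm '%s'\n", x$arm))
  cat("  mRS 0-1 / 2-3 / 4-5 / dead:",
      paste(sprintf("%.4f", x$day90), collapse = " / "), "\n")
  cat(sprintf("  expected acute cost: %.2f CNY\n", x$acute_cost))
  invisible(x)
}
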