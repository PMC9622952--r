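#' Gompertz background life table
#'
#' Builds a synthetic age-indexed table of annual all-cause death
#' probabilities from a Gompertz hazard \eqn{h(x) = a e^{bx}}: the annual
#' probability at integer age \eqn{x} is \eqn{q_x = 1 - \exp(-a e^{bx})}.
#' The bundled calibration (\code{a = 2e-5}, \code{b = 0.085}) stands in for
#' a national all-cause life table over the cohort's age range; the constants
#' live in the parameter configuration, not here.
#'
#' @param a Baseline hazard at age 0; must be > 0.
#' @param b Log-hazard slope per year of age; must be >= 0 (\code{b = 0}
#'   gives a constant annual probability).
#' @param age_min,age_max Integer age range (inclusive, contiguous).
#' @return A \code{life_table} object: data frame with columns \code{age}
#'   and \code{annual_death_prob}.
#' @export
#' @examples
#' lt <- gompertz_life_table(2e-5, 0.085, 63, 93)
#' lt$annual_death_prob[lt$age == 63]
gompertz_life_table <- function(a = 2.0e-5, b = 0.085, age_min = 63L,
                                age_max = 93L) {
  stopifnot(a > 0, b >= 0, age_min < age_max)
  ages <- seq.int(age_min, age_max)
  q <- 1 - exp(-a * exp(b * ages))
  if (any(q >= 1))
    stop("Gompertz parameters give death probability >= 1 below age_max",
         call. = FALSE)
  new_life_table(ages, q)
}

new_life_table <- function(ages, q) {
  structure(data.frame(age = as.integer(ages), annual_death_prob = q),
            class = c("life_table", "data.frame"))
}

#' Read a life table from a two-column text file
#'
#' Accepts whitespace- or comma-separated text with a header line and two
#' columns: integer age and annual death probability.  Ages must be
#' contiguous and probabilities strictly inside (0, 1).
#'
#' @param path Input file path.
#' @return A \code{life_table} object.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(d) < 2L) stop("life table needs two columns: age, probability",
                         call. = FALSE)
  ages <- as.integer(d[[1L]]); q <- as.numeric(d[[2L]])
  if (any(diff(ages) != 1L)) stop("life-table ages must be contiguous", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("life-table probabilities must lie strictly in (0,1)", call. = FALSE)
  new_life_table(ages, q)
}

#' Write a life table to a two-column text file
#' @param table A \code{life_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_life_table <- function(table, path) {
  lines <- c("age\tannual_death_prob",
             sprintf("%d\t%.15g", table$age, table$annual_death_prob))
  writeLines(lines, path)
  invisible(path)
}

background_q <- function(table, age) {
  i <- match(age, table$age)
  if (is.na(i)) stop("age ", age, " outside the life table", call. = FALSE)
  table$annual_death_prob[i]
}

#' Disability-adjusted annual death probability
#'
#' Applies an mRS-band hazard ratio to the background annual death
#' probability.  The default \code{"hazard_power"} mode works on the hazard
#' scale, \eqn{1 - (1-q)^{hr}}, which equals \eqn{q \cdot hr} to first order
#' and always returns a valid probability; \code{"multiply_capped"} is the
#' literal multiplication, capped at 1.
#'
#' @param table A \code{life_table}.
#' @param age Integer age present in the table.
#' @param hr Hazard ratio (> 0) for the band.
#' @param mode \code{"hazard_power"} (default) or \code{"multiply_capped"}.
#' @return Annual death probability in [0, 1).
#' @export
#' @examples
#' lt <- gompertz_life_table()
#' adjusted_death_prob(lt, 63, 2.04)
adjusted_death_prob <- function(table, age, hr,
                                mode = c("hazard_power", "multiply_capped")) {
  mode <- match.arg(mode)
  stopifnot(hr > 0)
  q <- background_q(table, age)
  adjust_q(q, hr, mode)
}

adjust_q <- function(q, hr, mode = "hazard_power") {
  if (mode == "multiply_capped") pmin(q * hr, 1) else 1 - (1 - q)^hr
}
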