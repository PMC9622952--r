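## ---- distribution fitting from base / range -------------------------------

range_sd <- function(low, high) (high - low) / 3.92  # range read as central 95% CI

#' Fit a beta distribution from a base value and plausible range
#'
#' Moment-matching: the base value is the mean and the (low, high) range is
#' read as a central 95\% interval, so \code{sd = (high - low)/3.92}.  A
#' zero-width range yields a point mass.  If the base falls outside the
#' range the same moments are used anyway with a warning.
#'
#' @param base Mean, in [0, 1].
#' @param low,high Range endpoints in [0, 1].
#' @return A distribution spec: list with \code{family} and parameters
#'   (\code{shape1}, \code{shape2} for beta; \code{value} for fixed).
#' @export
#' @examples
#' fit_beta_from_range(0.5, 0.304, 0.696)  # alpha = beta = 12
fit_beta_from_range <- function(base, low, high) {
  stopifnot(low <= high, base >= 0, base <= 1, low >= 0, high <= 1)
  if (base < low || base > high)
    warning("base value outside its range; moment-matching on base anyway")
  s <- range_sd(low, high)
  if (s == 0 || base == 0 || base == 1)
    return(list(family = "fixed", value = base))
  nu <- base * (1 - base) / s^2 - 1
  if (nu <= 0) stop("range too wide for a beta with this mean", call. = FALSE)
  list(family = "beta", shape1 = base * nu, shape2 = (1 - base) * nu)
}

#' Fit a gamma distribution from a base value and plausible range
#' @inheritParams fit_beta_from_range
#' @param base Mean, > 0 (a zero base or zero-width range yields a point
#'   mass).
#' @return A distribution spec with \code{shape} and \code{rate}.
#' @export
fit_gamma_from_range <- function(base, low, high) {
  stopifnot(low <= high, base >= 0, low >= 0)
  if (base < low || base > high)
    warning("base value outside its range; moment-matching on base anyway")
  s <- range_sd(low, high)
  if (s == 0 || base == 0) return(list(family = "fixed", value = base))
  list(family = "gamma", shape = (base / s)^2, rate = base / s^2)
}

#' Fit a lognormal distribution from a base value and 95\% interval
#'
#' The base is the median (\code{meanlog = log(base)}) and the range is a
#' 95\% interval on the ratio scale:
#' \code{sdlog = (log(high) - log(low))/3.92}.
#'
#' @param base Median, > 0.
#' @param low,high Interval endpoints, > 0.
#' @return A distribution spec with \code{meanlog} and \code{sdlog}.
#' @export
fit_lognormal_from_ci <- function(base, low, high) {
  stopifnot(base > 0, low > 0, low <= high)
  if (base < low || base > high)
    warning("base value outside its range; matching on base anyway")
  if (low == high) return(list(family = "fixed", value = base))
  list(family = "lognormal", meanlog = log(base),
       sdlog = (log(high) - log(low)) / 3.92)
}

fit_range_row <- function(base, low, high, family) {
  switch(family,
    beta = fit_beta_from_range(base, low, high),
    gamma = fit_gamma_from_range(base, low, high),
    lognormal = fit_lognormal_from_ci(base, low, high),
    fixed = list(family = "fixed", value = base),
    stop("unknown distribution family: ", family, call. = FALSE))
}

draw_spec <- function(spec, n = 1L) {
  switch(spec$family,
    fixed = rep(spec$value, n),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog))
}

spec_mean <- function(spec) {
  switch(spec$family,
    fixed = spec$value,
    beta = spec$shape1 / (spec$shape1 + spec$shape2),
    gamma = spec$shape / spec$rate,
    lognormal = exp(spec$meanlog + spec$sdlog^2 / 2))
}

#' Draw a day-90 mRS distribution from its Dirichlet posterior
#'
#' The four-category day-90 outcome is multinomial, so its uncertainty is
#' Dirichlet with concentration equal to the implied trial counts
#' (proportions times arm size).  Zero counts receive a 0.5 continuity
#' correction.
#'
#' @param efficacy One arm's entry of \code{params$arms}: a list with
#'   \code{day90} (named probability vector) and \code{arm_size}.
#' @param n Number of draws.
#' @return For \code{n = 1} a named probability vector; otherwise an
#'   \code{n} x 4 matrix with one draw per row.  Rows sum to 1.
#' @export
#' @examples
#' set.seed(1)
#' sample_dirichlet_day90(default_parameters()$arms$edaravone)
sample_dirichlet_day90 <- function(efficacy, n = 1L) {
  stopifnot(efficacy$arm_size >= 1)
  alpha <- efficacy$day90 * efficacy$arm_size
  alpha[alpha == 0] <- 0.5
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  d <- g / rowSums(g)
  colnames(d) <- names(alpha)
  if (n == 1L) d[1L, ] else d
}

## ---- one-way sensitivity analysis -----------------------------------------

inmb_at <- function(fit, horizon) {
  r <- fit$results
  r$inmb[match(horizon, r$horizon)]
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the model with each ranged parameter set to its low and then
#' high value, everything else at base.  The efficacy odds ratio acts
#' through [build_acute_outcome()]'s override of the intervention arm's
#' day-90 distribution.  Entries are returned sorted by the absolute INMB
#' spread, ready for a tornado diagram.
#'
#' @param params A \code{cea_parameters} object.
#' @param table A \code{life_table} (defaults to the bundled fixture).
#' @param horizon Horizon in years at which INMB is evaluated (default 30).
#' @param wtp Willingness-to-pay; defaults to \code{params$econ$wtp_per_qaly}.
#' @return An \code{owsa} data frame: \code{parameter_id}, \code{low},
#'   \code{high}, \code{low_inmb}, \code{high_inmb}, \code{spread}, plus a
#'   \code{base_inmb} attribute.
#' @export
owsa <- function(params, table = NULL, horizon = 30L, wtp = NULL) {
  validate_parameters(params)
  if (is.null(table)) table <- life_table_from_params(params)
  if (!is.null(wtp)) params$econ$wtp_per_qaly <- wtp
  rg <- params$ranges
  base_fit <- cea(params, table, horizons = horizon)

  eval_at <- function(id, value) {
    if (id == "or_mrs01")
      return(inmb_at(cea(params, table, horizons = horizon,
                         or_override = value), horizon))
    p <- set_parameter(params, id, value)
    inmb_at(cea(p, table, horizons = horizon), horizon)
  }
  lo <- hi <- numeric(nrow(rg))
  for (i in seq_len(nrow(rg))) {
    lo[i] <- eval_at(rg$parameter_id[i], rg$low[i])
    hi[i] <- eval_at(rg$parameter_id[i], rg$high[i])
  }
  out <- data.frame(parameter_id = rg$parameter_id, low = rg$low,
                    high = rg$high, low_inmb = lo, high_inmb = hi,
                    spread = abs(hi - lo), stringsAsFactors = FALSE)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("owsa", "data.frame"),
            base_inmb = inmb_at(base_fit, horizon), horizon = horizon)
}

#' Tornado diagram of a one-way sensitivity analysis
#' @param x An \code{owsa} object.
#' @param n_top Number of parameters to display (default all).
#' @param ... Passed to [graphics::barplot()].
#' @return \code{x}, invisibly.
#' @export
plot.owsa <- function(x, n_top = nrow(x), ...) {
  d <- x[seq_len(min(n_top, nrow(x))), ]
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_inmb")
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  ylim <- c(0, nrow(d) + 1)
  graphics::plot(NA, xlim = range(c(d$low_inmb, d$high_inmb, base)),
                 ylim = ylim, yaxt = "n", xlab = "INMB (CNY)", ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter_id, las = 1,
                 cex.axis = 0.7)
  for (i in seq_len(nrow(d)))
    graphics::segments(d$low_inmb[i], i, d$high_inmb[i], i, lwd = 8,
                       col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

## ---- probabilistic sensitivity analysis -----------------------------------

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of every uncertain input: both arms' day-90
#' distributions from Dirichlet posteriors (or, with
#' \code{switches$psa_efficacy_mode = "or"}, the control arm's Dirichlet
#' draw pushed through a lognormal odds-ratio draw for the intervention
#' arm), and every ranged parameter from its fitted beta / gamma / lognormal
#' family (\code{fixed} entries, notably the discount rate, stay at base).
#' Utility draws violating the severity ordering are rejected and redrawn.
#' Each iteration reruns the full two-arm model; increments and INMB are
#' recorded per horizon.
#'
#' @param params A \code{cea_parameters} object.
#' @param table A \code{life_table} (defaults to the bundled fixture).
#' @param n_iterations Number of Monte-Carlo iterations (default 5000).
#' @param seed Integer RNG seed; results are reproducible bit-for-bit.
#' @param horizons Horizons in years (default 1, 5, 30).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve
#'   (default 0 to 300,000 CNY in steps of 5,000).
#' @return A \code{psa} object: \code{samples} (long data frame: iteration,
#'   horizon, delta_cost, delta_qaly, inmb), \code{prob_cost_effective} (per
#'   horizon, at \code{params$econ$wtp_per_qaly}), \code{ceac} (per horizon
#'   and grid WTP), \code{n_iterations}, \code{seed}, \code{n_redraws}.
#' @export
run_psa <- function(params, table = NULL, n_iterations = 5000L, seed = 1L,
                    horizons = c(1L, 5L, 30L),
                    wtp_grid = seq(0, 300000, by = 5000)) {
  validate_parameters(params)
  stopifnot(n_iterations >= 1)
  if (is.null(table)) table <- life_table_from_params(params)
  horizons <- sort(unique(as.integer(horizons)))
  wtp <- params$econ$wtp_per_qaly
  rg <- params$ranges
  specs <- stats::setNames(
    lapply(seq_len(nrow(rg)), function(i)
      fit_range_row(rg$base[i], rg$low[i], rg$high[i], rg$family[i])),
    rg$parameter_id)
  drawn_ids <- setdiff(rg$parameter_id, "or_mrs01")
  util_ids <- c("utility_mrs01", "utility_mrs23", "utility_mrs45")
  or_mode <- identical(params$switches$psa_efficacy_mode, "or")

  set.seed(seed)
  n_redraws <- 0L
  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    p <- params
    p$arms[[p$control]]$day90 <- sample_dirichlet_day90(p$arms[[p$control]])
    if (or_mode) {
      or_draw <- draw_spec(specs[["or_mrs01"]])
      ao <- build_acute_outcome(p, p$intervention, or_override = or_draw)
      p$arms[[p$intervention]]$day90 <- ao$day90
    } else {
      p$arms[[p$intervention]]$day90 <-
        sample_dirichlet_day90(p$arms[[p$intervention]])
    }
    for (id in drawn_ids)
      p <- set_parameter(p, id, draw_spec(specs[[id]]))
    # enforce the utility severity ordering by rejection
    tries <- 0L
    while (with(as.list(p$utilities$state_utility),
                mrs01 < mrs23 || mrs23 < mrs45) && tries < 100L) {
      for (id in util_ids)
        p <- set_parameter(p, id, draw_spec(specs[[id]]))
      n_redraws <- n_redraws + 1L; tries <- tries + 1L
    }
    if (tries == 100L)
      p$utilities$state_utility[ALIVE_BANDS] <-
        sort(p$utilities$state_utility[ALIVE_BANDS], decreasing = TRUE)
    fit <- cea(p, table, horizons = horizons)
    r <- fit$results
    rows[[it]] <- data.frame(iteration = it, horizon = r$horizon,
                             delta_cost = r$delta_cost,
                             delta_qaly = r$delta_qaly,
                             inmb = r$delta_qaly * wtp - r$delta_cost)
  }
  samples <- do.call(rbind, rows)

  prob_ce <- vapply(horizons, function(h) {
    s <- samples[samples$horizon == h, ]
    mean(s$inmb > 0)
  }, numeric(1))
  names(prob_ce) <- paste0("h", horizons)

  ceac <- do.call(rbind, lapply(horizons, function(h) {
    s <- samples[samples$horizon == h, ]
    data.frame(horizon = h, wtp = wtp_grid,
               prob_cost_effective = vapply(wtp_grid, function(w)
                 mean(s$delta_qaly * w - s$delta_cost > 0), numeric(1)))
  }))

  structure(list(samples = samples, prob_cost_effective = prob_ce,
                 ceac = ceac, n_iterations = n_iterations, seed = seed,
                 n_redraws = n_redraws, wtp = wtp, horizons = horizons),
            class = "psa")
}

#' @export
print.psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iterations, x$seed))
  for (i in seq_along(x$horizons))
    cat(sprintf("  P(cost-effective at WTP %s), %2d y: %.1f%%\n",
                format(x$wtp, big.mark = ","), x$horizons[i],
                100 * x$prob_cost_effective[i]))
  if (x$n_redraws > 0)
    cat(sprintf("  (%d utility redraws to respect severity ordering)\n",
                x$n_redraws))
  invisible(x)
}

#' Cost-effectiveness plane and acceptability curve
#' @param x A \code{psa} object.
#' @param horizon Horizon to display on the plane (default the largest).
#' @param ... Passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.psa <- function(x, horizon = max(x$horizons), ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$samples[x$samples$horizon == horizon, ]
  graphics::plot(s$delta_qaly, s$delta_cost, pch = 16, cex = 0.3,
                 col = "#00000040", xlab = "incremental QALYs",
                 ylab = "incremental cost (CNY)",
                 main = sprintf("CE plane, %d y", horizon), ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::abline(0, x$wtp, lty = 2, col = "red")
  first <- TRUE
  for (h in x$horizons) {
    cc <- x$ceac[x$ceac$horizon == h, ]
    if (first) {
      graphics::plot(cc$wtp, cc$prob_cost_effective, type = "l", ylim = c(0, 1),
                     xlab = "WTP (CNY/QALY)", ylab = "P(cost-effective)",
                     main = "CEAC")
      first <- FALSE
    } else graphics::lines(cc$wtp, cc$prob_cost_effective,
                           col = match(h, x$horizons))
  }
  graphics::legend("bottomright", paste0(x$horizons, " y"),
                   col = seq_along(x$horizons), lty = 1, bty = "n")
  invisible(x)
}

#' Write sensitivity-analysis outputs to CSV
#'
#' Writes \code{psa_samples.csv} and \code{ceac.csv} for a \code{psa}
#' object, or \code{tornado.csv} for an \code{owsa} object.
#'
#' @param x A \code{psa} or \code{owsa} object.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_sensitivity <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "psa")) {
    utils::write.csv(x$samples, file.path(dir, "psa_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(x$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  } else if (inherits(x, "owsa")) {
    utils::write.csv(as.data.frame(x), file.path(dir, "tornado.csv"),
                     row.names = FALSE)
  } else stop("x must be a 'psa' or 'owsa' object", call. = FALSE)
  invisible(dir)
}
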