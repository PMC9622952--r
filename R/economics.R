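#' Incremental cost-effectiveness ratio with dominance flags
#'
#' @param delta_cost Incremental cost (intervention minus control), CNY.
#' @param delta_qaly Incremental effectiveness, QALYs.
#' @return A list with \code{icer} (CNY per QALY, or \code{NA} when not a
#'   ratio) and \code{status}: \code{"ratio"}, \code{"dominant"} (cheaper and
#'   more effective), \code{"dominated"} (dearer and less effective), or
#'   \code{"undefined"} (zero QALY difference).
#' @export
#' @examples
#' compute_icer(100, 1)
#' compute_icer(-500, 0.2)$status
compute_icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) return(list(icer = NA_real_, status = "undefined"))
  if (delta_qaly > 0 && delta_cost < 0)
    return(list(icer = NA_real_, status = "dominant"))
  if (delta_qaly < 0 && delta_cost > 0)
    return(list(icer = NA_real_, status = "dominated"))
  list(icer = delta_cost / delta_qaly, status = "ratio")
}

#' Net monetary benefit
#'
#' \eqn{NMB = QALY \times WTP - cost}.  For a positive QALY increment the
#' incremental NMB is positive exactly when the ICER lies below the
#' willingness-to-pay threshold.
#'
#' @param total_qaly Total QALYs.
#' @param total_cost Total cost, CNY.
#' @param wtp Willingness-to-pay threshold, CNY per QALY (>= 0).
#' @return NMB in CNY.
#' @export
compute_nmb <- function(total_qaly, total_cost, wtp) {
  stopifnot(wtp >= 0)
  total_qaly * wtp - total_cost
}

cumulate_trace <- function(trace, horizon) {
  keep <- trace$cycle <= horizon
  c(cost = sum(trace$cost_disc[keep]), qaly = sum(trace$qaly_disc[keep]))
}

#' Fit the two-arm cost-effectiveness model
#'
#' The package's central model runner: builds both arms' acute outcomes,
#' propagates each through the Markov cohort engine once over the longest
#' requested horizon, and summarizes discounted totals, increments, ICER and
#' net monetary benefit at every requested horizon (shorter horizons are
#' prefix sums of the same trace, so they are mutually consistent by
#' construction).
#'
#' @param params A \code{cea_parameters} object (see [default_parameters()]).
#' @param table A \code{life_table}; defaults to the Gompertz fixture
#'   parameterized in \code{params$life_table}.
#' @param horizons Integer vector of horizons in years (default 1, 5, 30).
#' @param or_override Optional odds ratio applied to the intervention arm's
#'   day-90 distribution (used by the sensitivity analyses).
#' @return An object of class \code{cea}: list with \code{results} (one row
#'   per horizon: per-arm cost/QALY, increments, ICER and status, per-arm NMB
#'   and INMB), \code{traces} (per-arm \code{cohort_trace}), \code{params},
#'   \code{horizons}, \code{wtp}.
#' @export
#' @examples
#' fit <- cea(default_parameters(utility_preset = "text"))
#' fit
cea <- function(params, table = NULL, horizons = c(1L, 5L, 30L),
                or_override = NULL) {
  validate_parameters(params)
  stopifnot(length(horizons) >= 1, all(horizons >= 1))
  horizons <- sort(unique(as.integer(horizons)))
  if (is.null(table)) table <- life_table_from_params(params)
  hmax <- max(horizons)
  wtp <- params$econ$wtp_per_qaly

  ctrl <- run_arm(params, params$control, table, hmax)
  intv <- run_arm(params, params$intervention, table, hmax,
                  or_override = or_override)

  rows <- lapply(horizons, function(h) {
    a <- cumulate_trace(ctrl, h); b <- cumulate_trace(intv, h)
    dc <- b[["cost"]] - a[["cost"]]; dq <- b[["qaly"]] - a[["qaly"]]
    ic <- compute_icer(dc, dq)
    data.frame(
      horizon = h,
      cost_control = a[["cost"]], cost_intervention = b[["cost"]],
      qaly_control = a[["qaly"]], qaly_intervention = b[["qaly"]],
      delta_cost = dc, delta_qaly = dq,
      icer = ic$icer, icer_status = ic$status,
      nmb_control = compute_nmb(a[["qaly"]], a[["cost"]], wtp),
      nmb_intervention = compute_nmb(b[["qaly"]], b[["cost"]], wtp),
      inmb = dq * wtp - dc,
      stringsAsFactors = FALSE)
  })
  structure(list(results = do.call(rbind, rows),
                 traces = stats::setNames(list(ctrl, intv),
                                          c(params$control, params$intervention)),
                 params = params, horizons = horizons, wtp = wtp),
            class = "cea")
}

#' @export
print.cea <- function(x, digits = 2, ...) {
  cat(sprintf("Two-arm cost-effectiveness model: %s vs %s\n",
              x$params$intervention, x$params$control))
  cat(sprintf("  utility preset '%s', WTP %s CNY/QALY\n",
              x$params$utilities$preset, format(x$wtp, big.mark = ",")))
  r <- x$results
  for (i in seq_len(nrow(r))) {
    cat(sprintf("\n  Horizon %d y\n", r$horizon[i]))
    cat(sprintf("    cost  %12.2f vs %12.2f  (delta %10.2f)\n",
                r$cost_intervention[i], r$cost_control[i], r$delta_cost[i]))
    cat(sprintf("    QALY  %12.4f vs %12.4f  (delta %10.4f)\n",
                r$qaly_intervention[i], r$qaly_control[i], r$delta_qaly[i]))
    cat(sprintf("    ICER  %s\n",
                if (r$icer_status[i] == "ratio")
                  sprintf("%.2f CNY/QALY", r$icer[i]) else r$icer_status[i]))
    cat(sprintf("    INMB  %12.2f CNY\n", r$inmb[i]))
  }
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  out <- object$results
  class(out) <- c("summary.cea", "data.frame")
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Plot cumulative discounted cost and QALYs per arm against horizon
#' @param x A \code{cea} object.
#' @param ... Passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.cea <- function(x, ...) {
  tr <- x$traces
  cyc <- tr[[1L]]$cycle
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(cyc, sapply(tr, function(t) cumsum(t$cost_disc)),
                    type = "l", lty = 1, col = c(1, 2), xlab = "years",
                    ylab = "cumulative discounted cost (CNY)", ...)
  graphics::legend("bottomright", names(tr), lty = 1, col = c(1, 2), bty = "n")
  graphics::matplot(cyc, sapply(tr, function(t) cumsum(t$qaly_disc)),
                    type = "l", lty = 1, col = c(1, 2), xlab = "years",
                    ylab = "cumulative discounted QALYs", ...)
  invisible(x)
}

#' Write base-case results to CSV and JSON
#'
#' Writes \code{results.csv} (the per-horizon table in the arrangement of a
#' published cost-effectiveness results table) and \code{results.json} to a
#' directory.
#'
#' @param x A \code{cea} object.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cea_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$results, file.path(dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(x$results, file.path(dir, "results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
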