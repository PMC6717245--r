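#' Fit a two-term power model to daily calling rates
#'
#' Nonlinear least squares for \eqn{f(x) = a x^b + c} with x the day index
#' (x = 1 is the first day of the season, 1 December) and f in
#' calls/whale/day. The extrapolated curve stays roughly constant toward
#' x = 1, which is what makes it usable for back-estimating early-season
#' whale numbers: a family decaying to zero would blow the inverted
#' abundance up toward infinity.
#'
#' Starting values are data-driven: \eqn{c_0} is the minimum observed rate
#' and \eqn{(a_0, b_0)} come from a log-log regression of the excess rate
#' over \eqn{c_0} on the day index. The Levenberg-Marquardt fit is
#' deterministic given the data.
#'
#' @param days positive numeric day indices (>= 4 points).
#' @param rates observed daily calling rates, same length.
#' @return a \code{power_model}: coefficients \code{a, b, c}, coefficient
#'   covariance, \code{sse}, residual degrees of freedom \code{dof}, and the
#'   fitted data.
#' @export
fit_power_model <- function(days, rates) {
  days <- as.numeric(days); rates <- as.numeric(rates)
  if (length(days) != length(rates) || length(days) < 4L)
    stop_cfg("need >= 4 (day, rate) points")
  if (any(days <= 0)) stop_cfg("day indices must be positive")
  c0 <- min(rates)
  excess <- pmax(rates - c0, 0) + 1e-6
  ll <- stats::lm(log(excess) ~ log(days))
  # a spans many orders of magnitude, so the curve is fitted in log(a) and
  # transformed back; the optimum is identical but far better conditioned
  start <- list(la = stats::coef(ll)[[1]], b = stats::coef(ll)[[2]], c = c0)
  lm_fit <- function(s) minpack.lm::nlsLM(
    rates ~ exp(la) * days^b + c, start = s,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  fit <- tryCatch(lm_fit(start), error = function(e1) {
    # a (near-)constant series makes x^b collinear with the intercept at
    # b ~ 0; retry from a sloped start where the Jacobian has full rank
    tryCatch(lm_fit(list(la = -10, b = 1, c = start$c)),
             error = function(e2)
               stop_cfg("power-model fit failed: %s", conditionMessage(e1)))
  })
  co <- stats::coef(fit)
  co <- c(a = exp(co[["la"]]), b = co[["b"]], c = co[["c"]])
  res <- stats::residuals(fit)
  dof <- length(days) - 3L
  if (dof <= 0L) stop_cfg("not enough points for residual degrees of freedom")
  V <- tryCatch(stats::vcov(fit), error = function(e)
    stop_cfg("rank-deficient fit: coefficient covariance unavailable"))
  # delta-method transform of the covariance from (log a, b, c) to (a, b, c)
  J <- diag(c(co[["a"]], 1, 1))
  V <- J %*% V %*% t(J)
  dimnames(V) <- list(c("a", "b", "c"), c("a", "b", "c"))
  structure(list(a = co[["a"]], b = co[["b"]], c = co[["c"]],
                 covariance = V, sse = sum(res^2), dof = dof,
                 days = days, rates = rates, fit = fit),
            class = "power_model")
}

#' Evaluate a two-term power model
#'
#' @param model a \code{power_model} (or list with a, b, c).
#' @param x day index/indices (> 0).
#' @return f(x) = a x^b + c.
#' @export
predict_power <- function(model, x) {
  if (any(x <= 0)) stop_cfg("day index must be > 0")
  model$a * x^model$b + model$c
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("Two-term power model f(x) = a*x^b + c\n  a = %.4g, b = %.4g, c = %.4g\n  SSE = %.4g on %d residual dof\n",
              x$a, x$b, x$c, x$sse, x$dof))
  invisible(x)
}

#' Pointwise (non-simultaneous) prediction interval for the calling rate
#'
#' First-order (delta-method) interval for a new daily rate observation at
#' day x:
#' \deqn{f(x) \pm t_{dof,(1+level)/2}\sqrt{\hat\sigma^2 + g(x)^T V g(x)}}
#' with \eqn{g(x) = (x^b,\; a x^b \log x,\; 1)} the coefficient gradient, V
#' the coefficient covariance, and \eqn{\hat\sigma^2 = SSE/dof}. The lower
#' bound is floored at 0 (a calling rate cannot be negative).
#'
#' @param model a fitted \code{\link{fit_power_model}}.
#' @param x day index/indices (> 0).
#' @param level coverage level, default 0.95.
#' @return data.frame with \code{x, fit, low, high}.
#' @export
prediction_interval <- function(model, x, level = 0.95) {
  if (any(x <= 0)) stop_cfg("day index must be > 0")
  s2 <- model$sse / model$dof
  tq <- stats::qt((1 + level) / 2, df = model$dof)
  f <- predict_power(model, x)
  half <- vapply(x, function(xi) {
    g <- c(xi^model$b, model$a * xi^model$b * log(xi), 1)
    tq * sqrt(s2 + drop(t(g) %*% model$covariance %*% g))
  }, numeric(1))
  data.frame(x = x, fit = f, low = pmax(f - half, 0), high = f + half)
}

#' Invert the cue-rate identity to estimate whale numbers
#'
#' \deqn{\hat N_W(t) = \frac{\hat N_C(t)}{\hat r(t)\,\hat P_{SA}\,\bar t_{SA}}}
#' The bound estimates substitute the prediction-interval rate bounds: the
#' upper rate bound yields the minimum whale count and the lower rate bound
#' the maximum. Because an inverted near-zero rate diverges, rates below
#' \code{rate_floor} produce an estimate capped at the floor-based value and
#' carry a warning rather than an unbounded number.
#'
#' @param n_c_corrected corrected cue count.
#' @param rate point cue rate (cues/whale/day for the acoustic analysis).
#' @param p_sa proportion of whales in the search area, (0, 1].
#' @param t_sa a \code{\link{transit_time}} or minutes.
#' @param rate_bounds optional numeric length-2 (low, high) prediction
#'   bounds on the rate, used for the whale-count bounds.
#' @param rate_floor smallest usable rate, cues/whale/day; default 1e-6.
#' @param day optional day label.
#' @param unit time unit in which \code{rate} is expressed.
#' @return a \code{whale_estimate}: \code{n_whales, lower, upper},
#'   \code{capped} flag.
#' @export
whales_from_cues <- function(n_c_corrected, rate, p_sa, t_sa,
                             rate_bounds = NULL, rate_floor = 1e-6,
                             day = NA, unit = c("day", "hour")) {
  unit <- match.arg(unit)
  n_c <- if (inherits(n_c_corrected, "corrected_count"))
    n_c_corrected$corrected else n_c_corrected
  check_number(p_sa, "p_sa", 0, 1, strict_lower = TRUE)
  t_unit <- transit_in_unit(t_sa, unit)
  if (t_unit <= 0) stop_cfg("transit time must be > 0")
  capped <- FALSE
  if (rate <= rate_floor) {
    warning(sprintf(
      "cue rate %.3g is at or below the floor %.3g; whale estimate capped",
      rate, rate_floor), call. = FALSE)
    rate <- rate_floor
    capped <- TRUE
  }
  inv <- function(r) {
    if (is.null(r) || is.na(r)) return(NA_real_)
    n_c / (max(r, rate_floor) * p_sa * t_unit)
  }
  structure(list(day = day, n_whales = inv(rate),
                 lower = inv(rate_bounds[2]),  # high rate -> few whales
                 upper = inv(rate_bounds[1]),  # low rate -> many whales
                 capped = capped || (!is.null(rate_bounds) &&
                                       any(rate_bounds <= rate_floor,
                                           na.rm = TRUE))),
            class = "whale_estimate")
}

#' @export
print.whale_estimate <- function(x, ...) {
  cat(sprintf("Estimated whales%s: %.0f",
              if (is.na(x$day)) "" else sprintf(" (day %s)", format(x$day)),
              x$n_whales))
  if (!is.na(x$lower) || !is.na(x$upper))
    cat(sprintf(" [min %.0f, max %.0f]", x$lower, x$upper))
  if (x$capped) cat("  (rate at floor: upper bound unreliable)")
  cat("\n")
  invisible(x)
}

#' Back-estimate whale numbers for acoustic-only days
#'
#' For each day in an early-season period with acoustic data but no visual
#' effort, divides the day's corrected call count by the calling rate
#' extrapolated from the fitted power model (and by the within-array
#' proportion and the array transit time), then totals the per-day
#' estimates. The period's minimum total uses each day's upper
#' prediction-interval rate; the maximum uses the lower bound, which widens
#' rapidly when extrapolating and is reported with its capped flag.
#'
#' @param daily_corrected_calls data.frame with \code{day} (index with the
#'   same origin as the fitted model) and \code{corrected}.
#' @param model a fitted \code{\link{fit_power_model}}.
#' @param p_sa within-array proportion, (0, 1].
#' @param t_sa array \code{\link{transit_time}} or minutes.
#' @param level prediction-interval level for the bounds.
#' @param rate_floor smallest usable rate (cues/whale/day).
#' @return list with \code{per_day} (data.frame day, rate, n_whales, lower,
#'   upper), \code{total}, \code{total_min}, \code{total_max},
#'   \code{any_capped}.
#' @export
december_backestimate <- function(daily_corrected_calls, model, p_sa, t_sa,
                                  level = 0.95, rate_floor = 1e-6) {
  d <- daily_corrected_calls
  pi_ <- prediction_interval(model, d$day, level = level)
  rows <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    est <- tryCatch(
      suppressWarnings(
        whales_from_cues(d$corrected[i], pi_$fit[i], p_sa, t_sa,
                         rate_bounds = c(pi_$low[i], pi_$high[i]),
                         rate_floor = rate_floor, day = d$day[i])),
      error = function(e) NULL)
    if (is.null(est)) {
      warning(sprintf("day %s excluded from the period total", d$day[i]),
              call. = FALSE)
      next
    }
    rows[[i]] <- data.frame(day = d$day[i], rate = pi_$fit[i],
                            n_whales = est$n_whales, lower = est$lower,
                            upper = est$upper, capped = est$capped)
  }
  per_day <- do.call(rbind, rows)
  list(per_day = per_day,
       total = sum(per_day$n_whales),
       total_min = sum(per_day$lower),
       total_max = sum(per_day$upper),
       any_capped = any(per_day$capped))
}
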