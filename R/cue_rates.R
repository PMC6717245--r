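#' Offshore distribution of migrating whales from visual sightings
#'
#' One (range, whales) pair per qualifying southbound pod: the pod's offshore
#' distance is the mean range over all of its sightings and its weight is the
#' last recorded group size. Pods sighted at or above the Beaufort or
#' visibility cutoffs are excluded, as are pods whose last recorded direction
#' is not southbound.
#'
#' @param sightings data.frame with columns \code{pod_id, range_m,
#'   group_size, direction, beaufort, visibility} (one row per sighting; a
#'   pod may be sighted several times). Rows are taken in time order; supply
#'   a \code{time_s} column to enforce it.
#' @param max_beaufort exclusive Beaufort cutoff (default 5: conditions must
#'   be strictly less than 5).
#' @param max_visibility exclusive visibility-code cutoff (default 5).
#' @return an \code{\link{offshore_distribution}}.
#' @export
build_offshore_distribution <- function(sightings, max_beaufort = 5,
                                        max_visibility = 5) {
  if (!is.null(sightings$time_s))
    sightings <- sightings[order(sightings$time_s), , drop = FALSE]
  ok <- sightings$beaufort < max_beaufort &
        sightings$visibility < max_visibility
  s <- sightings[ok, , drop = FALSE]
  if (nrow(s) == 0L) stop_cfg("no sightings pass the condition cutoffs")
  pods <- split(s, s$pod_id)
  last_dir <- vapply(pods, function(p) p$direction[nrow(p)], character(1))
  pods <- pods[last_dir == "south"]
  if (length(pods) == 0L) stop_cfg("no qualifying southbound pods")
  offshore_distribution(
    ranges_m = vapply(pods, function(p) mean(p$range_m), numeric(1)),
    weights = vapply(pods, function(p) p$group_size[nrow(p)], numeric(1)))
}

#' Offshore distribution container
#'
#' @param ranges_m per-pod mean offshore ranges, metres.
#' @param weights whale counts at each range (>= 0, positive total).
#' @return an object of class \code{offshore_distribution}.
#' @export
offshore_distribution <- function(ranges_m, weights) {
  if (length(ranges_m) != length(weights))
    stop_cfg("ranges and weights must have equal length")
  if (any(weights < 0) || sum(weights) <= 0)
    stop_cfg("weights must be >= 0 with a positive total")
  structure(list(ranges_m = as.numeric(ranges_m),
                 weights = as.numeric(weights)),
            class = "offshore_distribution")
}

#' Proportion of whales in an offshore interval
#'
#' Group-size-weighted fraction of whales with offshore distance in
#' \code{(r_min, r_max]} (half-open, matching the "greater than 0.5 km and
#' less than or equal to 2.1 km" band convention).
#'
#' @param dist an \code{\link{offshore_distribution}}.
#' @param r_min,r_max interval bounds in metres, \code{r_min < r_max}.
#' @return proportion in [0, 1].
#' @export
proportion_in_interval <- function(dist, r_min, r_max) {
  stopifnot(inherits(dist, "offshore_distribution"))
  if (r_min >= r_max) stop_cfg("need r_min < r_max")
  inside <- dist$ranges_m > r_min & dist$ranges_m <= r_max
  sum(dist$weights[inside]) / sum(dist$weights)
}

#' Proportion of non-southbound whales from a day's sightings
#'
#' Whale-weighted complement of the southbound share: \eqn{\hat c_N = 1 -}
#' (southbound whales)/(all whales), with each pod contributing its last
#' recorded group size and direction. Calls from northbound or milling
#' whales are false alarms for a southbound-only abundance model, so
#' \eqn{\hat c_N} is the correction applied to raw call counts.
#'
#' @param sightings a day's sightings (columns \code{pod_id, group_size,
#'   direction}; optional \code{time_s} for ordering).
#' @param day optional day label attached to the result.
#' @return list with \code{day}, \code{c_N}, and \code{southbound_share}.
#' @export
southbound_proportion <- function(sightings, day = NA) {
  if (nrow(sightings) == 0L)
    return(list(day = day, c_N = NA_real_, southbound_share = NA_real_))
  if (!is.null(sightings$time_s))
    sightings <- sightings[order(sightings$time_s), , drop = FALSE]
  pods <- if (!is.null(sightings$pod_id)) split(sightings, sightings$pod_id)
          else split(sightings, seq_len(nrow(sightings)))
  gs <- vapply(pods, function(p) p$group_size[nrow(p)], numeric(1))
  dir <- vapply(pods, function(p) p$direction[nrow(p)], character(1))
  share <- sum(gs[dir == "south"]) / sum(gs)
  list(day = day, c_N = 1 - share, southbound_share = share)
}

#' Cue rate from a corrected cue count
#'
#' The central identity of cue counting:
#' \deqn{\hat r(t) = \frac{\hat N_C(t)}{\hat N_W(t)\,\hat P_{SA}\,\bar t_{SA}}}
#' cues per whale per unit time, where \eqn{\hat N_C} is the estimated
#' number of cues produced in the search area, \eqn{\hat N_W} the number of
#' whales present, \eqn{\hat P_{SA}} the proportion of them inside the
#' search area, and \eqn{\bar t_{SA}} the mean time a whale spends there
#' (converted to the rate's time unit). Uncertainty bounds substitute the
#' abundance credibility bounds: the upper abundance bound gives the lower
#' rate bound and vice versa.
#'
#' @param n_c_corrected corrected cue count (\eqn{\hat N_C}), or a
#'   \code{corrected_count}.
#' @param abundance list/row with \code{median_whales} and optional
#'   \code{ci_low, ci_high} (95\% credibility bounds), or a single number.
#' @param p_sa proportion of whales in the search area, in (0, 1].
#' @param t_sa a \code{\link{transit_time}} (or minutes).
#' @param unit time unit of the returned rate: \code{"day"} or
#'   \code{"hour"}.
#' @param day optional day label.
#' @param rate_floor smallest denominator-safe rate; a computed rate below
#'   it is flagged (\code{degenerate = TRUE}) because inverting a
#'   near-zero cue rate sends abundance estimates toward infinity.
#' @return a \code{cue_rate_estimate}: \code{rate, lower, upper} (cues per
#'   whale per \code{unit}), the inputs used, and a degeneracy flag.
#' @export
cue_rate <- function(n_c_corrected, abundance, p_sa, t_sa,
                     unit = c("day", "hour"), day = NA, rate_floor = 1e-9) {
  unit <- match.arg(unit)
  n_c <- if (inherits(n_c_corrected, "corrected_count"))
    n_c_corrected$corrected else n_c_corrected
  if (is.numeric(abundance) && length(abundance) == 1L)
    abundance <- list(median_whales = abundance)
  nw <- abundance$median_whales
  check_number(nw, "median_whales", 0, strict_lower = TRUE)
  check_number(p_sa, "p_sa", 0, 1, strict_lower = TRUE)
  t_unit <- transit_in_unit(t_sa, unit)
  if (t_unit <= 0) stop_cfg("transit time must be > 0")
  r <- n_c / (nw * p_sa * t_unit)
  bound <- function(n) if (is.null(n) || is.na(n) || n <= 0) NA_real_
                       else n_c / (n * p_sa * t_unit)
  structure(list(day = day, rate = r,
                 lower = bound(abundance$ci_high %||% NA),
                 upper = bound(abundance$ci_low %||% NA),
                 unit = paste0("cues/whale/", unit),
                 p_sa = p_sa, t_sa_minutes = transit_in_unit(t_sa, "minute"),
                 n_c = n_c, n_w = nw,
                 degenerate = r < rate_floor),
            class = "cue_rate_estimate")
}

#' @export
print.cue_rate_estimate <- function(x, ...) {
  cat(sprintf("Cue rate%s: %.2f %s",
              if (is.na(x$day)) "" else sprintf(" (day %s)", format(x$day)),
              x$rate, x$unit))
  if (!is.na(x$lower) || !is.na(x$upper))
    cat(sprintf(" [%.2f, %.2f]", x$lower, x$upper))
  cat("\n")
  invisible(x)
}

#' Per-day cue rates over a season
#'
#' Vectorized wrapper around \code{\link{cue_rate}} joining daily corrected
#' counts with daily abundance by day.
#'
#' @param counts data.frame with \code{day} and \code{corrected}.
#' @param abundance data.frame with \code{day, median_whales} and optional
#'   \code{ci_low, ci_high}.
#' @param p_sa,t_sa,unit as in \code{\link{cue_rate}}.
#' @return data.frame with day, rate, lower, upper.
#' @export
daily_cue_rates <- function(counts, abundance, p_sa, t_sa,
                            unit = c("day", "hour")) {
  unit <- match.arg(unit)
  m <- merge(counts, abundance, by = "day")
  out <- lapply(seq_len(nrow(m)), function(i) {
    est <- cue_rate(m$corrected[i],
                    list(median_whales = m$median_whales[i],
                         ci_low = m$ci_low[i] %||% NA,
                         ci_high = m$ci_high[i] %||% NA),
                    p_sa, t_sa, unit = unit, day = m$day[i])
    data.frame(day = m$day[i], rate = est$rate, lower = est$lower,
               upper = est$upper)
  })
  do.call(rbind, out)
}
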