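#' Monte Carlo field for the probability of acoustic localization
#'
#' Holds everything needed to evaluate, per minute and per grid cell, the
#' probability that a call produced at that cell is localized by the
#' hydrophone array: source-level realizations drawn from the call source
#' level distribution, per-cell per-hydrophone transmission loss, and
#' per-hydrophone per-minute noise levels in the call band (20--100 Hz).
#'
#' @param grid data.frame of source locations with columns \code{x_m, y_m}
#'   (shore-relative metres); one row per cell inside the array.
#' @param sl_samples numeric vector of source-level realizations, dB re
#'   1 uPa at 1 m (100 draws in the standard analysis).
#' @param tl matrix of transmission loss, dB: \code{nrow(grid)} rows by
#'   n-hydrophone columns.
#' @param nl matrix of noise level, dB re 1 uPa (20--100 Hz): n-hydrophone
#'   rows by n-minute columns (use \code{NA} for minutes without data).
#' @param snr_threshold_db detection threshold on the minimum across-array
#'   SNR; default 0.5 dB.
#' @return an object of class \code{localization_field}.
#' @export
localization_field <- function(grid, sl_samples, tl, nl,
                               snr_threshold_db = 0.5) {
  tl <- as.matrix(tl); nl <- as.matrix(nl)
  if (nrow(tl) != nrow(grid))
    stop_cfg("tl must have one row per grid cell")
  if (ncol(tl) != nrow(nl))
    stop_cfg("tl columns and nl rows must both equal the hydrophone count")
  if (!is.finite(snr_threshold_db)) stop_cfg("threshold must be finite")
  structure(list(grid = grid, sl_samples = as.numeric(sl_samples),
                 tl = tl, nl = nl, snr_threshold_db = snr_threshold_db,
                 n_hydro = ncol(tl)),
            class = "localization_field")
}

#' Default transmission-loss model
#'
#' Geometric spherical spreading, \eqn{TL = 20\log_{10}(r)} dB at range r
#' metres; a pluggable simplification standing where a site-specific
#' propagation model would otherwise be used.
#'
#' @param range_m range(s) in metres (> 0).
#' @return transmission loss in dB.
#' @export
tl_spherical_spreading <- function(range_m) {
  if (any(range_m <= 0)) stop_cfg("range must be > 0 for spreading loss")
  20 * log10(range_m)
}

#' Probability of localization for one minute
#'
#' For each grid cell, the SNR at hydrophone i is
#' \eqn{SNR_i = SL - TL_i - NL_i}; the cell's score per source-level
#' realization is the minimum SNR across the hydrophones (a call must be
#' received on the whole array to be localized), and the cell probability is
#' the fraction of realizations whose minimum SNR exceeds the threshold. The
#' returned minute-level probability is the unweighted mean over cells.
#'
#' @param field a \code{\link{localization_field}}.
#' @param minute minute index into the noise-level columns.
#' @return area-mean probability of localization in [0, 1], or \code{NA}
#'   (a no-effort signal) when the minute's noise level is missing.
#' @export
probability_of_localization <- function(field, minute) {
  stopifnot(inherits(field, "localization_field"))
  if (minute < 1L || minute > ncol(field$nl)) return(NA_real_)
  nl_t <- field$nl[, minute]
  if (anyNA(nl_t)) return(NA_real_)
  # effective per-cell threshold: min_i(SL - TL_i - NL_i) > thr
  #   <=> SL > thr + max_i(TL_i + NL_i)
  worst <- apply(sweep(field$tl, 2, nl_t, `+`), 1, max)
  cell_p <- vapply(worst, function(w) {
    mean(field$sl_samples > field$snr_threshold_db + w)
  }, numeric(1))
  mean(cell_p)
}

#' Per-minute probabilities of localization
#'
#' @param field a \code{\link{localization_field}}.
#' @param minutes minute indices (default: all noise-level columns).
#' @return numeric vector of area-mean probabilities (NA = no data).
#' @export
probability_of_localization_series <- function(field,
                                               minutes = seq_len(ncol(field$nl))) {
  vapply(minutes, function(m) probability_of_localization(field, m),
         numeric(1))
}

#' Apply the minimum-localizability effort rule
#'
#' Minutes whose probability of localization falls below 0.5 (or is missing)
#' are declared off-effort: their detections are dropped and they count
#' toward the no-effort proportion P_NE.
#'
#' @param p_l_minutes per-minute probabilities of localization (NA = no
#'   data).
#' @param detections data.frame of detections with a \code{time_s} column
#'   (seconds from the start of the period) or a \code{minute} column.
#' @param p_l_min effort cutoff on the probability of localization,
#'   default 0.5.
#' @return list with \code{detections} (retained rows), \code{effort} (an
#'   \code{\link{effort_log}}) and \code{p_l_effort_mean}, the mean
#'   probability of localization over on-effort minutes.
#' @export
apply_effort_rule <- function(p_l_minutes, detections, p_l_min = 0.5) {
  ok <- !is.na(p_l_minutes) & p_l_minutes >= p_l_min
  eff <- effort_log(ok)
  minute <- if (!is.null(detections$minute)) detections$minute
            else floor(detections$time_s / 60) + 1L
  keep <- !is.na(minute) & minute >= 1L & minute <= length(ok) & ok[minute]
  list(detections = detections[keep, , drop = FALSE],
       effort = eff,
       p_l_effort_mean = if (any(ok)) mean(p_l_minutes[ok]) else NA_real_)
}

corrected_count <- function(day, raw, corrected, components) {
  structure(list(day = day, raw = raw, corrected = corrected,
                 components = components), class = "corrected_count")
}

#' @export
print.corrected_count <- function(x, ...) {
  cat(sprintf("Corrected cue count (day %s): raw %g -> %.2f\n",
              format(x$day), x$raw, x$corrected))
  invisible(x)
}

#' Correct a raw localized call count to calls produced
#'
#' Estimated number of calls produced in the search area:
#' \deqn{\hat N_C = n_c \frac{1 - \hat c_N}{\hat P_L (1 - P_{NE})}}
#' where \eqn{\hat c_N} removes calls attributable to northbound or milling
#' whales (the visual abundance counts southbound whales only), \eqn{\hat
#' P_L} is the probability of localization, and \eqn{P_{NE}} the proportion
#' of time with no effort.
#'
#' @param n_c raw number of calls detected and localized.
#' @param c_N proportion of northbound + milling whales, in [0, 1].
#' @param p_l probability of localization, in (0, 1].
#' @param p_ne proportion of time with no effort, in [0, 1).
#' @param day optional day label.
#' @return a \code{corrected_count}.
#' @export
correct_call_count <- function(n_c, c_N, p_l, p_ne, day = NA) {
  check_number(n_c, "n_c", 0)
  check_number(c_N, "c_N", 0, 1)
  check_number(p_l, "p_l", 0, 1, strict_lower = TRUE)
  check_number(p_ne, "p_ne", 0, 1, strict_upper = TRUE)
  corrected_count(day, n_c, n_c * (1 - c_N) / (p_l * (1 - p_ne)),
                  list(c_N = c_N, p_l = p_l, p_ne = p_ne))
}

#' Daily corrected call count by per-minute correction
#'
#' The per-minute form of the call-count correction: each on-effort minute's
#' localized calls are divided by that minute's probability of localization,
#' the minute-level corrections are summed, and the day-level factors
#' (northbound/milling proportion, no-effort proportion) are applied to the
#' sum. Minutes failing the effort rule are dropped and counted in
#' \eqn{P_{NE}}. With a constant per-minute probability this reduces to
#' \code{\link{correct_call_count}}.
#'
#' @param detections data.frame of localized calls with \code{minute} (or
#'   \code{time_s} seconds from the period start).
#' @param p_l_minutes per-minute probabilities of localization.
#' @param c_N northbound + milling proportion, in [0, 1].
#' @param p_l_min effort cutoff, default 0.5.
#' @param day optional day label.
#' @return a \code{corrected_count}.
#' @export
correct_call_count_by_minute <- function(detections, p_l_minutes, c_N = 0,
                                         p_l_min = 0.5, day = NA) {
  check_number(c_N, "c_N", 0, 1)
  filt <- apply_effort_rule(p_l_minutes, detections, p_l_min = p_l_min)
  p_ne <- filt$effort$p_ne
  if (p_ne >= 1) stop_cfg("no on-effort minutes: correction undefined")
  det <- filt$detections
  minute <- if (!is.null(det$minute)) det$minute
            else floor(det$time_s / 60) + 1L
  per_min <- if (nrow(det)) sum(1 / p_l_minutes[minute]) else 0
  corrected_count(day, nrow(det),
                  per_min * (1 - c_N) / (1 - p_ne),
                  list(c_N = c_N, p_ne = p_ne, p_l_min = p_l_min))
}

#' Correct a raw blow count to blows produced
#'
#' \deqn{\hat N_C = n_b \frac{1 - \hat c}{\hat P_D (1 - P_{NE})}}
#' with \eqn{\hat c} the false-detection proportion (zero for manual logging
#' well before the northbound migration), \eqn{\hat P_D} the probability of
#' detection (1 inside the camera's effective range window), and
#' \eqn{P_{NE}} the proportion of the day without video. Blows outside the
#' usable range window must already be excluded from \code{n_b}.
#'
#' @param n_b raw number of blows detected.
#' @param c false-detection proportion, in [0, 1].
#' @param p_d probability of detection, in (0, 1].
#' @param p_ne proportion of time with no video, in [0, 1).
#' @param day optional day label.
#' @return a \code{corrected_count}.
#' @export
correct_blow_count <- function(n_b, c = 0, p_d = 1, p_ne = 0, day = NA) {
  check_number(n_b, "n_b", 0)
  check_number(c, "c", 0, 1)
  check_number(p_d, "p_d", 0, 1, strict_lower = TRUE)
  check_number(p_ne, "p_ne", 0, 1, strict_upper = TRUE)
  corrected_count(day, n_b, n_b * (1 - c) / (p_d * (1 - p_ne)),
                  list(c = c, p_d = p_d, p_ne = p_ne))
}

#' Effective detection range of the camera from cumulative-range curves
#'
#' Compares the cumulative count of camera blow detections against the
#' cumulative count of visual sightings (a proxy for the true offshore whale
#' density) as functions of range. Where the camera detects everything, the
#' detections-per-sighting cumulative ratio is flat; beyond the camera's
#' effective range it falls. The effective maximum range is estimated as the
#' change point maximizing the fit improvement of a continuous two-segment
#' piecewise-linear model of the ratio over a single line.
#'
#' @param camera_detections data.frame with \code{range_m}.
#' @param sightings data.frame with \code{range_m} (same days).
#' @param near_cutoff_m near-shore exclusion radius where the wedge field of
#'   view is too narrow to be useful; default 500 m.
#' @param min_points minimum number of points required in each collection.
#' @return an \code{effective_range_result}: the cumulative curves, the
#'   estimated \code{effective_max_range_m}, \code{near_cutoff_m}, and a
#'   \code{degenerate} flag (TRUE when no slope drop is identifiable, in
#'   which case the maximum observed range is returned).
#' @export
effective_detection_range <- function(camera_detections, sightings,
                                      near_cutoff_m = 500, min_points = 10L) {
  rd <- sort(camera_detections$range_m)
  rs <- sort(sightings$range_m)
  if (length(rd) < min_points || length(rs) < min_points)
    stop_cfg("insufficient data: need >= %d detections and sightings",
             min_points)
  if (length(unique(rd)) < 3L)
    return(structure(list(cumulative_detections = data.frame(range_m = rd,
                            count = seq_along(rd)),
                          cumulative_sightings = data.frame(range_m = rs,
                            count = seq_along(rs)),
                          effective_max_range_m = max(rd),
                          near_cutoff_m = near_cutoff_m, degenerate = TRUE),
                     class = "effective_range_result"))

  # evaluate both cumulative curves on a common grid of sighting ranges;
  # the ratio is unstable until enough sightings have accumulated, so the
  # innermost points (fewer than 10 or 5% of sightings) are not used for
  # the change-point
  grid <- rs[rs >= min(rd)]
  cum_d <- findInterval(grid, rd)        # detections with range <= grid
  cum_s <- findInterval(grid, rs)
  stable <- cum_s >= max(10, 0.05 * length(rs))
  grid <- grid[stable]; cum_d <- cum_d[stable]; cum_s <- cum_s[stable]
  if (length(grid) < 10L)
    stop_cfg("insufficient data: too few stable cumulative points")
  ratio <- cum_d / pmax(cum_s, 1L)

  # continuous two-segment least squares over candidate breakpoints
  sse_line <- function(x, y) {
    f <- stats::lm.fit(cbind(1, x), y)
    sum(f$residuals^2)
  }
  base_sse <- sse_line(grid, ratio)
  n <- length(grid)
  cand <- unique(grid[seq(3L, n - 3L)])
  if (length(cand) > 200L)
    cand <- stats::quantile(cand, probs = seq(0, 1, length.out = 200L),
                            names = FALSE, type = 1)
  seg_sse <- vapply(cand, function(b) {
    x1 <- pmin(grid, b); x2 <- pmax(grid - b, 0)
    f <- stats::lm.fit(cbind(1, x1, x2), ratio)
    sum(f$residuals^2)
  }, numeric(1))
  best <- which.min(seg_sse)
  degenerate <- base_sse < 1e-10 ||
    (base_sse - seg_sse[best]) / base_sse < 0.2
  eff <- if (degenerate) max(rd) else cand[best]
  structure(list(
    cumulative_detections = data.frame(range_m = rd, count = seq_along(rd)),
    cumulative_sightings = data.frame(range_m = rs, count = seq_along(rs)),
    effective_max_range_m = eff,
    near_cutoff_m = near_cutoff_m,
    degenerate = degenerate), class = "effective_range_result")
}

#' @export
print.effective_range_result <- function(x, ...) {
  cat(sprintf("Effective camera detection range: %.0f m (near cutoff %.0f m)%s\n",
              x$effective_max_range_m, x$near_cutoff_m,
              if (x$degenerate) " [degenerate: no slope drop found]" else ""))
  invisible(x)
}

#' Day/night comparison of hourly blow detections
#'
#' Returns the share of detections inside the daytime watch window together
#' with a two-sided Wilcoxon rank-sum test comparing blows per hour between
#' day and night hours. Under equal day/night detectability and uniform diel
#' cue production, the day share should approximate (window length)/24.
#'
#' @param hourly_counts numeric vector of length 24 (or a multiple, for
#'   several days) of blow counts per hour-of-day slot, in order starting at
#'   midnight.
#' @param day_window numeric length-2, start and end hour of the day window
#'   (default \code{c(7.5, 16.5)}, the 07:30--16:30 watch).
#' @param exact_max per-group size at or below which the exact rank-sum
#'   distribution is used; larger groups use the normal approximation with
#'   tie correction.
#' @return list with \code{day_share}, \code{p_value}, and the day/night
#'   hourly count vectors.
#' @export
day_night_comparison <- function(hourly_counts, day_window = c(7.5, 16.5),
                                 exact_max = 20L) {
  n <- length(hourly_counts)
  if (n %% 24 != 0) stop_cfg("hourly counts must cover whole days")
  hour <- rep(seq_len(24) - 1L, n / 24)
  is_day <- hour + 0.5 > day_window[1] & hour + 0.5 <= day_window[2]
  day_counts <- hourly_counts[is_day]
  night_counts <- hourly_counts[!is_day]
  if (length(day_counts) < 2L || length(night_counts) < 2L)
    stop_cfg("need at least 2 hours in each of day and night")
  exact <- max(length(day_counts), length(night_counts)) <= exact_max &&
    !anyDuplicated(hourly_counts)
  p <- suppressWarnings(
    stats::wilcox.test(day_counts, night_counts, exact = exact,
                       correct = TRUE)$p.value)
  # fully tied samples give a 0/0 z-score; the groups are then
  # indistinguishable by ranks, so the two-sided p-value is 1
  if (is.na(p)) p <- 1
  list(day_share = sum(day_counts) / sum(hourly_counts),
       p_value = p, day_counts = day_counts, night_counts = night_counts)
}

#' Frame-contrast visibility metric
#'
#' The detectability of a blow depends on the contrast between the bright
#' blow and the dark sea; a frame's visibility is quantified as the variance
#' across the vertical axis of the per-row mean grey intensity (population
#' variance). Low-visibility frames, where the sea lightens toward the sky,
#' score low.
#'
#' @param frame_intensity_matrix numeric matrix of grey intensities (rows =
#'   image rows).
#' @return the variance score (>= 0).
#' @export
visibility_metric <- function(frame_intensity_matrix) {
  m <- as.matrix(frame_intensity_matrix)
  if (length(m) == 0L) stop_cfg("empty intensity matrix")
  pop_var(rowMeans(m))
}
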