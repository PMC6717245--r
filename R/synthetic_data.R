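#' Configuration for the migration simulator
#'
#' Describes the statistical structure of a simulated gray whale southbound
#' migration past a shore station: per-day whale numbers, swimming speed,
#' direction mix, the offshore-distance distribution, the acoustic calling
#' rate, the blow (respiration) cycle, and the daily observation-effort
#' schedule.
#'
#' @param random_seed integer; one global seed, with per-stage substreams
#'   derived deterministically from it.
#' @param n_whales_per_day nonnegative integer vector, whales per day
#'   (index 1 = first simulated day).
#' @param swim_speed_mps constant swimming speed, m/s; default 1.6, the mean
#'   speed of acoustically tracked migrating gray whales.
#' @param southbound_fraction probability that a whale travels south; scalar
#'   or per-day vector.
#' @param offshore_distribution a list describing the perpendicular
#'   distance-from-shore distribution (metres): either
#'   \code{list(name = "uniform", min =, max =)} or
#'   \code{list(name = "mixture", components = )} where \code{components} is
#'   a data.frame with columns \code{weight, min, max} of uniform pieces.
#'   The default mixture spans 185 m to 9.4 km and places about 53\% of
#'   whales in (500, 2100] m, matching the sighted offshore span and the
#'   proportion in the camera's usable range band.
#' @param call_rate_per_day calls/whale/day: a single number, a per-day
#'   vector, or a function of the day index.
#' @param blow_cycle list with \code{blows_per_bout} (integer range, default
#'   2--4), \code{inter_blow_s} (seconds, default 20--30) and
#'   \code{long_dive_s} (seconds, default 180--240): surfacing bouts of 2--4
#'   blows 20--30 s apart separated by 3--4 min dives.
#' @param effort_schedule list with \code{watch_start_h} and
#'   \code{watch_end_h} (hours, default 7.5 and 16.5, i.e. the 07:30--16:30
#'   visual watch) and optional \code{gap_minutes}, integer minute-of-day
#'   indices with no sensor effort.
#' @param corridor_length_m along-shore length of the study corridor a whale
#'   must cross, metres; default the 2,280 m mean distance through the
#'   hydrophone array.
#' @return an object of class \code{sim_config}.
#' @export
simulation_config <- function(random_seed = 1L,
                              n_whales_per_day = rep(50L, 10L),
                              swim_speed_mps = 1.6,
                              southbound_fraction = 0.9,
                              offshore_distribution = default_offshore_mixture(),
                              call_rate_per_day = 7.5,
                              blow_cycle = list(blows_per_bout = c(2L, 4L),
                                                inter_blow_s = c(20, 30),
                                                long_dive_s = c(180, 240)),
                              effort_schedule = list(watch_start_h = 7.5,
                                                     watch_end_h = 16.5,
                                                     gap_minutes = integer()),
                              corridor_length_m = 2280) {
  if (any(n_whales_per_day < 0)) stop_cfg("whale counts must be >= 0")
  check_number(swim_speed_mps, "swim_speed_mps", 0, strict_lower = TRUE)
  if (any(southbound_fraction < 0 | southbound_fraction > 1))
    stop_cfg("southbound_fraction must be in [0, 1]")
  validate_offshore_distribution(offshore_distribution)
  if (is.numeric(call_rate_per_day) && any(call_rate_per_day < 0))
    stop_cfg("call rate must be >= 0")
  bc <- blow_cycle
  if (any(unlist(bc) <= 0) || bc$blows_per_bout[1] < 1)
    stop_cfg("blow cycle parameters must be positive")
  check_number(corridor_length_m, "corridor_length_m", 0, strict_lower = TRUE)
  structure(list(random_seed = as.integer(random_seed),
                 n_whales_per_day = as.integer(n_whales_per_day),
                 swim_speed_mps = swim_speed_mps,
                 southbound_fraction = southbound_fraction,
                 offshore_distribution = offshore_distribution,
                 call_rate_per_day = call_rate_per_day,
                 blow_cycle = bc,
                 effort_schedule = effort_schedule,
                 corridor_length_m = corridor_length_m),
            class = "sim_config")
}

#' Default offshore-distance mixture
#'
#' Uniform mixture on (185, 9400) m placing 53\% of whales in (500, 2100] m
#' and about two-thirds inshore of the offshore edge of the hydrophone array.
#'
#' @return a mixture distribution list for \code{\link{simulation_config}}.
#' @export
default_offshore_mixture <- function() {
  list(name = "mixture",
       components = data.frame(weight = c(0.13, 0.53, 0.34),
                               min = c(185, 500, 2100),
                               max = c(500, 2100, 9400)))
}

validate_offshore_distribution <- function(d) {
  if (!is.list(d) || is.null(d$name))
    stop_cfg("offshore_distribution must be a named distribution list")
  if (d$name == "uniform") {
    if (is.null(d$min) || is.null(d$max) || d$min >= d$max || d$min < 0)
      stop_cfg("uniform offshore distribution needs 0 <= min < max")
  } else if (d$name == "mixture") {
    cm <- d$components
    if (is.null(cm) || any(cm$weight < 0) || sum(cm$weight) <= 0 ||
        any(cm$min >= cm$max) || any(cm$min < 0))
      stop_cfg("invalid mixture components")
  } else stop_cfg("unknown offshore distribution '%s'", d$name)
  invisible(d)
}

draw_offshore <- function(n, d) {
  if (n == 0L) return(numeric())
  if (d$name == "uniform") return(stats::runif(n, d$min, d$max))
  cm <- d$components
  k <- sample.int(nrow(cm), n, replace = TRUE, prob = cm$weight)
  stats::runif(n, cm$min[k], cm$max[k])
}

rate_at <- function(rate, day) {
  if (is.function(rate)) return(rate(day))
  if (length(rate) == 1L) rep(rate, length(day)) else rate[day]
}

#' Two-term power calling-rate function
#'
#' Convenience constructor for a daily calling rate of the form
#' \eqn{f(x) = a x^b + c} (calls/whale/day, x = day index).
#'
#' @param a,b,c coefficients.
#' @return a function of the day index.
#' @export
call_rate_power <- function(a, b, c) {
  force(a); force(b); force(c)
  function(x) a * x^b + c
}

#' Simulate migrating whale tracks
#'
#' Tracks are straight, shore-parallel lines at constant speed and a fixed
#' offshore distance; each whale enters the study corridor at a uniformly
#' drawn time of day and crosses it in \code{corridor_length_m / speed}
#' seconds.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return data.frame with one row per whale: \code{whale_id, day, direction,
#'   offshore_m, entry_time_s} (seconds since local midnight of its day),
#'   \code{speed_mps, residence_s}.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$random_seed, "tracks"), {
    n_days <- length(config$n_whales_per_day)
    sb <- rep(config$southbound_fraction, length.out = n_days)
    out <- lapply(seq_len(n_days), function(d) {
      n <- config$n_whales_per_day[d]
      if (n == 0L) return(NULL)
      data.frame(
        whale_id = sprintf("d%03d_w%04d", d, seq_len(n)),
        day = d,
        direction = ifelse(stats::runif(n) < sb[d], "south", "north"),
        offshore_m = draw_offshore(n, config$offshore_distribution),
        entry_time_s = stats::runif(n, 0, 86400),
        speed_mps = config$swim_speed_mps,
        residence_s = config$corridor_length_m / config$swim_speed_mps,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(whale_id = character(), day = integer(),
                        direction = character(), offshore_m = numeric(),
                        entry_time_s = numeric(), speed_mps = numeric(),
                        residence_s = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate acoustic calls along whale tracks
#'
#' Each whale produces calls as a Poisson process while inside the study
#' corridor, with per-day rate \code{call_rate_per_day} (calls/whale/day), so
#' the expected count per whale is rate times its residence time. Call
#' positions lie on the track at the emission time.
#'
#' @param tracks output of \code{\link{simulate_tracks}}.
#' @param call_rate_per_day rate spec as in \code{\link{simulation_config}}.
#' @param seed integer seed.
#' @return data.frame of cue events: \code{whale_id, day, direction, time_s,
#'   along_m} (signed along-shore offset from corridor entry), \code{offshore_m,
#'   cue} (\code{"call"}).
#' @export
simulate_calls <- function(tracks, call_rate_per_day, seed = 1L) {
  rates <- rate_at(call_rate_per_day, tracks$day)
  if (any(rates < 0)) stop_cfg("call rate must be >= 0")
  with_seed(stage_seed(seed, "calls"), {
    n_cues <- stats::rpois(nrow(tracks), rates * tracks$residence_s / 86400)
    idx <- rep(seq_len(nrow(tracks)), n_cues)
    if (length(idx) == 0L)
      return(empty_cues("call"))
    dt <- stats::runif(length(idx), 0, tracks$residence_s[idx])
    sgn <- ifelse(tracks$direction[idx] == "south", 1, -1)
    out <- data.frame(whale_id = tracks$whale_id[idx],
                      day = tracks$day[idx],
                      direction = tracks$direction[idx],
                      time_s = tracks$entry_time_s[idx] + dt,
                      along_m = sgn * tracks$speed_mps[idx] * dt,
                      offshore_m = tracks$offshore_m[idx],
                      cue = "call", stringsAsFactors = FALSE)
    out[order(out$whale_id, out$time_s), , drop = FALSE]
  })
}

#' Simulate blows along whale tracks
#'
#' Respiration is a renewal process: a surfacing bout of \code{blows_per_bout}
#' blows separated by \code{inter_blow_s} seconds, then a long dive of
#' \code{long_dive_s} seconds, repeating. Bout size, intervals and dive length
#' are drawn independently and uniformly within their configured ranges.
#'
#' @param tracks output of \code{\link{simulate_tracks}}.
#' @param blow_cycle cycle parameter list as in
#'   \code{\link{simulation_config}}.
#' @param seed integer seed.
#' @param duration_s observation span per whale, seconds; defaults to the
#'   whale's corridor residence time.
#' @return data.frame of cue events with \code{cue = "blow"}; times strictly
#'   increasing within each whale.
#' @export
simulate_blows <- function(tracks, blow_cycle, seed = 1L, duration_s = NULL) {
  bc <- blow_cycle
  with_seed(stage_seed(seed, "blows"), {
    rows <- lapply(seq_len(nrow(tracks)), function(i) {
      dur <- if (is.null(duration_s)) tracks$residence_s[i]
             else rep(duration_s, length.out = nrow(tracks))[i]
      if (dur <= 0) return(NULL)
      t <- stats::runif(1, 0, bc$long_dive_s[2])  # random phase at entry
      times <- numeric(0)
      bouts <- bc$blows_per_bout[1]:bc$blows_per_bout[2]
      while (t < dur) {
        k <- bouts[sample.int(length(bouts), 1L)]
        for (j in seq_len(k)) {
          if (t >= dur) break
          times <- c(times, t)
          # the long dive starts from the bout's last blow
          t <- t + if (j < k)
            stats::runif(1, bc$inter_blow_s[1], bc$inter_blow_s[2])
          else stats::runif(1, bc$long_dive_s[1], bc$long_dive_s[2])
        }
      }
      if (length(times) == 0L) return(NULL)
      sgn <- if (tracks$direction[i] == "south") 1 else -1
      data.frame(whale_id = tracks$whale_id[i], day = tracks$day[i],
                 direction = tracks$direction[i],
                 time_s = tracks$entry_time_s[i] + times,
                 along_m = sgn * tracks$speed_mps[i] * times,
                 offshore_m = tracks$offshore_m[i],
                 cue = "blow", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty_cues("blow") else { rownames(out) <- NULL; out }
  })
}

empty_cues <- function(kind) {
  data.frame(whale_id = character(), day = integer(), direction = character(),
             time_s = numeric(), along_m = numeric(), offshore_m = numeric(),
             cue = character(), stringsAsFactors = FALSE)[0, ]
}

#' Per-minute sensor effort log
#'
#' @param minute_flags logical vector, TRUE where the sensor was on effort
#'   (one element per minute of the analysis period).
#' @return an \code{effort_log} with \code{minute_flags} and \code{p_ne}, the
#'   proportion of time with no effort.
#' @export
effort_log <- function(minute_flags) {
  minute_flags <- as.logical(minute_flags)
  if (anyNA(minute_flags)) stop_cfg("effort flags must be TRUE/FALSE")
  structure(list(minute_flags = minute_flags,
                 p_ne = mean(!minute_flags)),
            class = "effort_log")
}

#' Build a daily effort log from a watch schedule
#'
#' @param schedule list with \code{watch_start_h}, \code{watch_end_h} and
#'   optional \code{gap_minutes} (minute-of-day indices without effort).
#' @param full_day if TRUE the sensor runs all 24 h (gaps still apply), as
#'   for the hydrophones and the infrared camera; if FALSE effort is limited
#'   to the watch window, as for visual observers.
#' @return an \code{\link{effort_log}} covering 1,440 minutes.
#' @export
schedule_effort <- function(schedule, full_day = FALSE) {
  minute <- seq_len(1440) - 1L
  flags <- if (full_day) rep(TRUE, 1440)
           else minute >= schedule$watch_start_h * 60 &
                minute < schedule$watch_end_h * 60
  gaps <- schedule$gap_minutes %||% integer()
  flags[minute %in% gaps] <- FALSE
  effort_log(flags)
}

#' Apply a sensor model and effort log to simulated cues
#'
#' A cue is retained iff it lies in the sensor's spatial domain, falls in an
#' on-effort minute, and passes an independent detection draw. Camera
#' detections get pixel coordinates by inverting the geometry module's
#' pixel-to-range and pixel-to-azimuth mappings (the camera is placed at the
#' corridor's along-shore origin looking straight offshore).
#'
#' @param cues cue events from \code{\link{simulate_calls}} or
#'   \code{\link{simulate_blows}}.
#' @param sensor_model a list: \code{type} one of \code{"acoustic"},
#'   \code{"camera"}, \code{"visual"}; optional \code{p_detect} (constant or
#'   function of the cue data.frame, default 1); optional \code{range_min_m},
#'   \code{range_max_m} bounding offshore distance; for \code{"camera"}, a
#'   \code{geom} (\code{\link{survey_geometry}}) used to clip to the wedge
#'   field of view and to produce pixel coordinates.
#' @param effort an \code{\link{effort_log}} indexed by minute of day (NULL
#'   means continuous effort).
#' @param seed integer seed.
#' @return data.frame of detection records: sensor, time_s, day, range_m,
#'   offshore_m, direction, and pixel_row/pixel_col for camera records.
#' @export
simulate_detections <- function(cues, sensor_model, effort = NULL, seed = 1L) {
  type <- sensor_model$type
  if (is.null(type) || !type %in% c("acoustic", "camera", "visual"))
    stop_cfg("unknown sensor model '%s'", type %||% "<missing>")
  if (nrow(cues) == 0L) return(empty_detections(type))

  keep <- rep(TRUE, nrow(cues))
  rmin <- sensor_model$range_min_m %||% 0
  rmax <- sensor_model$range_max_m %||% Inf
  keep <- keep & cues$offshore_m > rmin & cues$offshore_m <= rmax

  geom <- sensor_model$geom
  if (type == "camera" && !is.null(geom)) {
    half <- tan(geom$camera_hfov_deg / 2 * pi / 180)
    keep <- keep & abs(cues$along_m) <= cues$offshore_m * half
  }
  if (!is.null(effort)) {
    minute <- floor((cues$time_s %% 86400) / 60) + 1L
    keep <- keep & effort$minute_flags[minute]
  }
  p <- sensor_model$p_detect %||% 1
  pvec <- if (is.function(p)) p(cues) else rep(p, nrow(cues))
  keep <- keep & with_seed(stage_seed(seed, paste0("detect_", type)),
                           stats::runif(nrow(cues)) < pvec)

  det <- cues[keep, , drop = FALSE]
  out <- data.frame(sensor = type, time_s = det$time_s, day = det$day,
                    range_m = det$offshore_m, offshore_m = det$offshore_m,
                    direction = det$direction, stringsAsFactors = FALSE)
  if (type == "camera" && !is.null(geom) && nrow(det) > 0L) {
    slant <- sqrt(det$along_m^2 + det$offshore_m^2)
    out$range_m <- slant
    out$pixel_row <- range_to_pixel_row(slant, geom)
    ang <- atan2(det$along_m, det$offshore_m) * 180 / pi  # within +-hfov/2
    e <- geom$camera_edge_azimuths_deg
    mid <- mean(e)
    out$pixel_col <- (mid + ang - e[1]) / (e[2] - e[1]) *
      (geom$image_width_px - 1L)
  }
  rownames(out) <- NULL
  out
}

# inverse of pixel_to_range: pixel row at which a target at surface distance
# d appears (fractional row)
range_to_pixel_row <- function(d, geom) {
  R <- geom$earth_radius_m; h <- geom$camera_height_m
  g <- d / R
  beta <- atan2((R + h) - R * cos(g), R * sin(g))
  dip <- acos(R / (R + h))
  geom$horizon_row_px + (beta - dip) /
    (geom$camera_vfov_deg * pi / 180) * geom$image_height_px
}

empty_detections <- function(type) {
  out <- data.frame(sensor = character(), time_s = numeric(), day = integer(),
                    range_m = numeric(), offshore_m = numeric(),
                    direction = character(), stringsAsFactors = FALSE)
  if (type == "camera") { out$pixel_row <- numeric(); out$pixel_col <- numeric() }
  out
}
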