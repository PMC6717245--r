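#' Run configuration for an end-to-end simulated analysis
#'
#' @param sim a \code{\link{simulation_config}}.
#' @param out_dir output directory for stage artifacts.
#' @param acoustic_p_l probability of localization applied to simulated
#'   calls (constant, (0, 1]).
#' @param acoustic_range_max_m offshore extent of the acoustic search area,
#'   metres.
#' @param blow_range_window_m camera usable range band (near, far), metres.
#' @param pi_level prediction-interval level for the back-estimation stage.
#' @param utc_offset_h local-time offset recorded in the manifest; day
#'   boundaries are local midnight.
#' @return a \code{run_config} list.
#' @export
run_config <- function(sim, out_dir,
                       acoustic_p_l = 0.8,
                       acoustic_range_max_m = 3600,
                       blow_range_window_m = c(500, 2100),
                       pi_level = 0.95,
                       utc_offset_h = -8) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, out_dir = out_dir,
                 acoustic_p_l = acoustic_p_l,
                 acoustic_range_max_m = acoustic_range_max_m,
                 blow_range_window_m = blow_range_window_m,
                 pi_level = pi_level, utc_offset_h = utc_offset_h),
            class = "run_config")
}

#' Orchestrate a full simulate / correct / cue-rate / extrapolate run
#'
#' Executes the stages in order on synthetic data: track and cue simulation,
#' sensor detection with effort, count correction, daily cue rates against
#' the simulation's own daily southbound abundance, a power-model fit where
#' the day coverage allows it, and a back-estimation over the days before
#' the first "visual" day. Every stage writes a CSV/JSON artifact and the
#' run ends with a manifest (configuration echo, seed, package version, and
#' an MD5 checksum per artifact). Identical configuration and seed give
#' byte-identical numeric outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a run report list: per-stage artifact paths, the daily
#'   cue-rate table, the fitted model (or NULL), and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  seed <- sim$random_seed
  paths <- character()
  put <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  stage <- "simulate_tracks"
  report <- tryCatch({
    tracks <- simulate_tracks(sim)
    put(tracks, "tracks.csv")

    stage <- "simulate_cues"
    calls <- simulate_calls(tracks, sim$call_rate_per_day, seed)
    put(calls, "calls.csv")
    blows <- simulate_blows(tracks, sim$blow_cycle, seed)
    put(blows, "blows.csv")

    stage <- "detect"
    eff_ac <- schedule_effort(sim$effort_schedule, full_day = TRUE)
    det_ac <- simulate_detections(
      calls, list(type = "acoustic", p_detect = config$acoustic_p_l,
                  range_max_m = config$acoustic_range_max_m),
      eff_ac, seed)
    put(det_ac, "detections_acoustic.csv")

    stage <- "correct"
    days <- seq_along(sim$n_whales_per_day)
    n_c <- vapply(days, function(d) sum(det_ac$day == d), numeric(1))
    c_N <- vapply(days, function(d) {
      trk <- tracks[tracks$day == d, ]
      if (nrow(trk) == 0L) return(0)
      1 - mean(trk$direction == "south")
    }, numeric(1))
    corrected <- data.frame(
      day = days, raw = n_c,
      corrected = vapply(days, function(d)
        correct_call_count(n_c[d], c_N[d], config$acoustic_p_l,
                           eff_ac$p_ne, day = d)$corrected, numeric(1)))
    put(corrected, "corrected_calls.csv")

    stage <- "cue_rates"
    abund <- data.frame(
      day = days,
      median_whales = vapply(days, function(d)
        sum(tracks$day == d & tracks$direction == "south"), numeric(1)))
    in_area <- tracks$offshore_m <= config$acoustic_range_max_m
    p_sa <- if (nrow(tracks)) mean(in_area) else 1
    t_sa <- acoustic_transit_time(sim$corridor_length_m, sim$swim_speed_mps)
    ok_days <- abund$median_whales > 0
    rates <- daily_cue_rates(corrected[ok_days, ], abund[ok_days, ],
                             p_sa = max(p_sa, 1e-9), t_sa = t_sa)
    put(rates, "cue_rates.csv")

    stage <- "extrapolate"
    model <- NULL
    if (nrow(rates) >= 4L) {
      model <- tryCatch(fit_power_model(rates$day, rates$rate),
                        error = function(e) NULL)
      if (!is.null(model)) {
        mj <- file.path(config$out_dir, "power_model.json")
        jsonlite::write_json(
          list(a = model$a, b = model$b, c = model$c, sse = model$sse,
               dof = model$dof,
               covariance = as.matrix(model$covariance)),
          mj, auto_unbox = TRUE, digits = NA)
        paths[["power_model.json"]] <- mj
      }
    }

    stage <- "manifest"
    manifest <- list(
      seed = seed,
      utc_offset_h = config$utc_offset_h,
      n_days = length(sim$n_whales_per_day),
      n_whales = nrow(tracks),
      package_version = as.character(utils::packageVersion("whalecues")),
      artifacts = lapply(paths, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p)))))
    mp <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)

    list(stage_artifacts = paths, cue_rates = rates, model = model,
         manifest = mp)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial artifacts in %s)",
                 stage, conditionMessage(e), config$out_dir), call. = FALSE)
  })
  invisible(report)
}

#' Validate input CSV files against the expected schemas
#'
#' Schema and invariant checks for the two external inputs: sighting records
#' (\code{timestamp, bearing_deg, range_m, group_size, direction, beaufort,
#' visibility}) and daily abundance (\code{day, median_whales, ci_low,
#' ci_high}). Row-level violations are listed with their row numbers.
#'
#' @param paths named list/vector with elements \code{sightings} and/or
#'   \code{abundance}; paths to CSV files.
#' @return data.frame with columns \code{file, row, message} (zero rows when
#'   everything passes).
#' @export
validate_inputs <- function(paths) {
  errs <- list()
  note <- function(file, row, msg)
    errs[[length(errs) + 1L]] <<- data.frame(file = file, row = row,
                                             message = msg)
  read1 <- function(p) {
    if (!file.exists(p)) stop_cfg("cannot read '%s'", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  if (!is.null(paths$sightings)) {
    f <- paths$sightings
    d <- read1(f)
    need <- c("timestamp", "bearing_deg", "range_m", "group_size",
              "direction", "beaufort", "visibility")
    miss <- setdiff(need, names(d))
    if (length(miss)) note(f, NA, paste("missing columns:",
                                        paste(miss, collapse = ", ")))
    else {
      bad <- which(!(d$bearing_deg >= 0 & d$bearing_deg < 360))
      for (i in bad) note(f, i, "bearing outside [0, 360)")
      for (i in which(d$range_m <= 0)) note(f, i, "range must be > 0")
      for (i in which(d$group_size < 1)) note(f, i, "group size must be >= 1")
      for (i in which(!d$direction %in% c("south", "north", "milling")))
        note(f, i, "direction must be south/north/milling")
      for (i in which(d$beaufort < 0 | d$beaufort > 9))
        note(f, i, "Beaufort outside 0-9")
    }
  }
  if (!is.null(paths$abundance)) {
    f <- paths$abundance
    d <- read1(f)
    need <- c("day", "median_whales", "ci_low", "ci_high")
    miss <- setdiff(need, names(d))
    if (length(miss)) note(f, NA, paste("missing columns:",
                                        paste(miss, collapse = ", ")))
    else {
      for (i in which(d$median_whales < 0)) note(f, i, "negative abundance")
      for (i in which(!(d$ci_low <= d$median_whales &
                          d$median_whales <= d$ci_high)))
        note(f, i, "credibility bounds must bracket the median")
    }
  }
  if (length(errs) == 0L)
    data.frame(file = character(), row = integer(), message = character())
  else do.call(rbind, errs)
}
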