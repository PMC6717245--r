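test_that("track simulation honours counts, seed determinism, and the empty case", {
  cfg0 <- simulation_config(n_whales_per_day = rep(0L, 5))
  expect_equal(nrow(simulate_tracks(cfg0)), 0L)

  cfg <- simulation_config(random_seed = 11L, n_whales_per_day = c(3L, 0L, 7L))
  t1 <- simulate_tracks(cfg)
  t2 <- simulate_tracks(cfg)
  expect_identical(t1, t2)
  expect_equal(as.vector(table(factor(t1$day, levels = 1:3))), c(3, 0, 7))
  expect_true(all(t1$offshore_m > 0))
  expect_true(all(t1$speed_mps > 0))
})

test_that("offshore distances follow the configured distribution (binomial oracle)", {
  cfg <- simulation_config(
    random_seed = 3L, n_whales_per_day = 10000L,
    offshore_distribution = list(name = "uniform", min = 500, max = 3000))
  tr <- simulate_tracks(cfg)
  p_true <- (2100 - 500) / (3000 - 500)           # 0.64
  p_hat <- mean(tr$offshore_m > 500 & tr$offshore_m <= 2100)
  se <- sqrt(p_true * (1 - p_true) / nrow(tr))
  expect_lt(abs(p_hat - p_true), 3 * se)

  expect_error(simulation_config(
    offshore_distribution = list(name = "lognormalish")), "unknown")
})

test_that("southbound direction frequency matches the configured probability", {
  cfg <- simulation_config(random_seed = 5L, n_whales_per_day = 5000L,
                           southbound_fraction = 0.85)
  tr <- simulate_tracks(cfg)
  se <- sqrt(0.85 * 0.15 / nrow(tr))
  expect_lt(abs(mean(tr$direction == "south") - 0.85), 3 * se)
})

test_that("call simulation is Poisson with mean rate x residence (oracle) and handles edge rates", {
  cfg <- simulation_config(random_seed = 21L, n_whales_per_day = 2000L)
  tr <- simulate_tracks(cfg)
  expect_equal(nrow(simulate_calls(tr, 0, seed = 1L)), 0L)
  expect_error(simulate_calls(tr, -1, seed = 1L), "rate")

  r <- 40  # calls/whale/day
  calls <- simulate_calls(tr, r, seed = 21L)
  mu <- nrow(tr) * r * tr$residence_s[1] / 86400
  expect_lt(abs(nrow(calls) - mu), 3 * sqrt(mu))
  # determinism
  expect_identical(calls, simulate_calls(tr, r, seed = 21L))
})

test_that("the two-term power rate function evaluates as configured", {
  f <- call_rate_power(1.22e-6, 3.79, 3.39)
  expect_equal(f(1), 1.22e-6 + 3.39)
  expect_equal(f(1), 3.39, tolerance = 1e-5)
})

test_that("blow renewal process matches the closed-form long-run rate", {
  # degenerate cycle: exactly 3 blows at 25 s spacing then a 210 s dive
  cycle <- list(blows_per_bout = c(3L, 3L), inter_blow_s = c(25, 25),
                long_dive_s = c(210, 210))
  cfg <- simulation_config(random_seed = 2L, n_whales_per_day = 50L)
  tr <- simulate_tracks(cfg)
  bl <- simulate_blows(tr, cycle, seed = 2L, duration_s = 36000)
  rate_hr <- nrow(bl) / (nrow(tr) * 10)
  expect_equal(rate_hr, 3 / (2 * 25 + 210) * 3600, tolerance = 0.02)

  # zero-length observation -> no blows
  expect_equal(nrow(simulate_blows(tr, cycle, seed = 2L, duration_s = 0)), 0L)

  # strictly increasing times per whale
  bl2 <- simulate_blows(tr[1:10, ], simulation_config()$blow_cycle, seed = 9L,
                        duration_s = 7200)
  for (w in unique(bl2$whale_id))
    expect_true(all(diff(bl2$time_s[bl2$whale_id == w]) > 0))
})

test_that("midpoint respiration parameters yield rates inside the observed field range", {
  cycle <- list(blows_per_bout = c(3L, 3L), inter_blow_s = c(25, 25),
                long_dive_s = c(210, 210))
  cfg <- simulation_config(random_seed = 4L, n_whales_per_day = 100L)
  tr <- simulate_tracks(cfg)
  bl <- simulate_blows(tr, cfg$blow_cycle, seed = 4L, duration_s = 3600 * 5)
  rate_hr <- nrow(bl) / (nrow(tr) * 5)
  expect_gt(rate_hr, 27)     # observed blow-rate span: 27-67.2 /whale/hour
  expect_lt(rate_hr, 67.2)
})

test_that("sensor detection respects domain, effort, and never exceeds cue counts", {
  cfg <- simulation_config(random_seed = 31L, n_whales_per_day = 400L,
                           southbound_fraction = 1)
  tr <- simulate_tracks(cfg)
  cues <- simulate_calls(tr, 60, seed = 31L)

  # perfect sensor, full effort: everything in domain is kept
  det <- simulate_detections(cues, list(type = "acoustic", p_detect = 1),
                             effort = NULL, seed = 1L)
  expect_equal(nrow(det), nrow(cues))

  # camera clipped at 2,100 m never reports beyond it
  detc <- simulate_detections(cues, list(type = "camera", p_detect = 1,
                                         range_max_m = 2100), NULL, 1L)
  expect_true(all(detc$offshore_m <= 2100))
  expect_equal(nrow(detc), sum(cues$offshore_m <= 2100))

  # thinning keeps detections <= cues
  detp <- simulate_detections(cues, list(type = "acoustic", p_detect = 0.5),
                              NULL, 1L)
  expect_lte(nrow(detp), nrow(cues))

  expect_error(simulate_detections(cues, list(type = "sonar"), NULL, 1L),
               "unknown sensor")
})

test_that("a 9-of-24-hour effort window captures about 9/24 of uniform cues", {
  cfg <- simulation_config(random_seed = 41L, n_whales_per_day = 3000L)
  tr <- simulate_tracks(cfg)
  cues <- simulate_calls(tr, 80, seed = 41L)
  eff <- schedule_effort(list(watch_start_h = 7.5, watch_end_h = 16.5),
                         full_day = FALSE)
  expect_equal(eff$p_ne, 1 - 9 / 24)
  det <- simulate_detections(cues, list(type = "visual", p_detect = 1),
                             effort = eff, seed = 1L)
  p <- nrow(det) / nrow(cues)
  se <- sqrt((9 / 24) * (15 / 24) / nrow(cues))
  expect_lt(abs(p - 9 / 24), 3 * se)
})

test_that("camera detections carry pixel coordinates that invert the geometry", {
  geom <- survey_geometry()
  cfg <- simulation_config(random_seed = 51L, n_whales_per_day = 2000L,
    offshore_distribution = list(name = "uniform", min = 600, max = 2000))
  tr <- simulate_tracks(cfg)
  cues <- simulate_blows(tr, cfg$blow_cycle, seed = 51L)
  det <- simulate_detections(cues, list(type = "camera", geom = geom,
                                        range_min_m = 500,
                                        range_max_m = 2100), NULL, 1L)
  expect_gt(nrow(det), 5)
  expect_true(all(c("pixel_row", "pixel_col") %in% names(det)))
  # pixel row -> range roundtrip through the forward mapping
  back <- pixel_to_range(det$pixel_row, geom)
  expect_equal(back, det$range_m, tolerance = 1e-6)
  expect_true(all(det$pixel_col >= 0 & det$pixel_col < geom$image_width_px))
})
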