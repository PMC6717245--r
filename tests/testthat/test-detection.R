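make_field <- function(sl, tl, nl, thr = 0.5) {
  localization_field(grid = data.frame(x_m = seq_len(nrow(tl)), y_m = 0),
                     sl_samples = sl, tl = tl, nl = nl,
                     snr_threshold_db = thr)
}

test_that("probability of localization saturates at 0 and 1 and flags missing noise", {
  tl <- matrix(60, nrow = 3, ncol = 4)
  fld_hi <- make_field(sl = rep(200, 5), tl = tl,
                       nl = matrix(80, nrow = 4, ncol = 2))
  expect_equal(probability_of_localization(fld_hi, 1), 1)
  fld_lo <- make_field(sl = rep(100, 5), tl = tl,
                       nl = matrix(80, nrow = 4, ncol = 2))
  expect_equal(probability_of_localization(fld_lo, 1), 0)

  nl_na <- matrix(80, nrow = 4, ncol = 2); nl_na[2, 2] <- NA
  fld_na <- make_field(rep(150, 5), tl, nl_na)
  expect_true(is.na(probability_of_localization(fld_na, 2)))
})

test_that("probability of localization equals exhaustive enumeration (brute-force oracle)", {
  # the hand-set 2-cell, 4-sample instance
  tl <- matrix(c(60, 62, 61, 59, 70, 71, 69, 72), nrow = 2, byrow = TRUE)
  nl <- matrix(c(85, 86, 84, 85), nrow = 4, ncol = 1)
  sl <- c(144, 146, 148, 150)
  fld <- make_field(sl, tl, nl)
  expect_equal(probability_of_localization(fld, 1),
               brute_force_p_l(sl, tl, nl[, 1], 0.5))

  # randomized instances up to 10 cells x 10 samples
  set.seed(7)
  for (k in 1:20) {
    nc <- sample(1:10, 1); ns <- sample(1:10, 1)
    tl <- matrix(runif(nc * 4, 40, 80), nrow = nc)
    nl <- matrix(runif(4 * 3, 70, 100), nrow = 4)
    sl <- runif(ns, 130, 175)
    fld <- make_field(sl, tl, nl)
    m <- sample(1:3, 1)
    expect_equal(probability_of_localization(fld, m),
                 brute_force_p_l(sl, tl, nl[, m], 0.5))
  }
})

test_that("localization probability is monotone in source, loss, and noise levels", {
  set.seed(8)
  tl <- matrix(runif(20, 50, 70), nrow = 5)
  nl <- matrix(runif(4, 80, 95), nrow = 4)
  sl <- runif(10, 140, 160)
  p0 <- probability_of_localization(make_field(sl, tl, nl), 1)
  expect_gte(probability_of_localization(make_field(sl + 5, tl, nl), 1), p0)
  expect_lte(probability_of_localization(make_field(sl, tl + 5, nl), 1), p0)
  expect_lte(probability_of_localization(make_field(sl, tl, nl + 5), 1), p0)
})

test_that("the minimum-localizability effort rule drops low minutes and accounts P_NE", {
  det <- data.frame(minute = c(1, 2, 3, 4), id = 1:4)

  all_ok <- apply_effort_rule(c(0.9, 0.8, 0.7, 0.6), det)
  expect_equal(nrow(all_ok$detections), 4L)
  expect_equal(all_ok$effort$p_ne, 0)

  half <- apply_effort_rule(c(0.9, 0.4, 0.9, 0.4), det)
  expect_equal(half$detections$id, c(1L, 3L))
  expect_equal(half$effort$p_ne, 0.5)

  p <- rep(0.9, 1440); p[sample.int(1440, 36)] <- 0.3
  day <- apply_effort_rule(p, data.frame(minute = integer()))
  expect_equal(day$effort$p_ne, 36 / 1440)
  expect_equal(day$effort$p_ne, 0.025)
})

test_that("call-count correction implements the detection and effort factors", {
  expect_equal(correct_call_count(100, 0.2, 0.8, 0)$corrected, 100)
  expect_equal(correct_call_count(77, 0, 1, 0)$corrected, 77)
  expect_equal(correct_call_count(50, 0, 0.5, 0.5)$corrected, 200)
  expect_error(correct_call_count(10, 0, 0, 0), "> 0")
  expect_error(correct_call_count(10, 0, 0.5, 1), "< 1")
})

test_that("blow-count correction reproduces the four-day survey total", {
  expect_equal(correct_blow_count(55, 0, 1, 0)$corrected, 55)
  expect_equal(correct_blow_count(290, 0, 1, 0.025)$corrected, 297.4,
               tolerance = 1e-3)

  tab <- january_blow_survey()
  p_ne <- 1 - tab$detected_blows / tab$corrected_blows  # implied video gaps
  corr <- mapply(function(n, p) correct_blow_count(n, p_ne = p)$corrected,
                 tab$detected_blows, p_ne)
  expect_equal(sum(tab$detected_blows), 1427)
  expect_equal(sum(corr), 1447, tolerance = 0.05)
})

test_that("per-minute correction sums minute-level inverses and matches the daily form when constant", {
  det <- data.frame(minute = c(1, 1, 2, 3, 3, 3))
  p_const <- rep(0.8, 4)
  by_min <- correct_call_count_by_minute(det, p_const, c_N = 0.1)
  daily <- correct_call_count(6, 0.1, 0.8, 0)
  expect_equal(by_min$corrected, daily$corrected)

  # varying probabilities: hand-computed sum, minute 4 off-effort (< 0.5)
  p_var <- c(0.5, 0.8, 1.0, 0.4)
  got <- correct_call_count_by_minute(det, p_var, c_N = 0)
  hand <- (2 / 0.5 + 1 / 0.8 + 3 / 1.0) / (1 - 0.25)
  expect_equal(got$corrected, hand)

  # detections in the off-effort minute are dropped
  det2 <- rbind(det, data.frame(minute = 4))
  expect_equal(correct_call_count_by_minute(det2, p_var)$raw, 6)
})

test_that("correction identities: unit factors return raw, P_NE scales as 1/(1-P_NE)", {
  set.seed(9)
  for (k in 1:10) {
    n <- rpois(1, 100)
    expect_equal(correct_call_count(n, 0, 1, 0)$corrected, n)
    pne <- runif(1, 0, 0.9)
    expect_equal(correct_blow_count(n, p_ne = pne)$corrected,
                 n / (1 - pne))
  }
})

test_that("effective detection range recovers a known truncation radius", {
  set.seed(10)
  s <- runif(600, 100, 3000)
  d <- s[s <= 2100]                       # camera blind beyond 2.1 km
  res <- effective_detection_range(data.frame(range_m = d),
                                   data.frame(range_m = s))
  expect_false(res$degenerate)
  expect_lt(abs(res$effective_max_range_m - 2100) / 2100, 0.10)
  expect_true(all(diff(res$cumulative_detections$count) >= 0))

  # identical curves: no drop, maximum observed range
  same <- effective_detection_range(data.frame(range_m = s),
                                    data.frame(range_m = s))
  expect_true(same$degenerate)
  expect_equal(same$effective_max_range_m, max(s))

  # all detections at one range: degenerate flag
  one <- effective_detection_range(data.frame(range_m = rep(1500, 50)),
                                   data.frame(range_m = s))
  expect_true(one$degenerate)

  expect_error(effective_detection_range(data.frame(range_m = 1:3),
                                         data.frame(range_m = s)),
               "insufficient")
})

test_that("truncation-radius recovery holds across replicate simulations", {
  set.seed(11)
  ok <- replicate(100, {
    s <- runif(500, 100, 3000)
    d <- s[s <= 2100]
    r <- effective_detection_range(data.frame(range_m = d),
                                   data.frame(range_m = s))
    abs(r$effective_max_range_m - 2100) / 2100 < 0.10
  })
  expect_gte(mean(ok), 0.95)
})

test_that("day/night comparison returns the window share and a rank-sum p-value", {
  flat <- rep(5, 24)
  r <- day_night_comparison(flat)
  expect_equal(r$day_share, 9 / 24)
  expect_equal(r$p_value, 1, tolerance = 1e-6)

  # exact-enumeration oracle on a small day window (4 day vs 20 night hours)
  set.seed(12)
  counts <- sample(1:100, 24)             # distinct -> exact branch
  r2 <- day_night_comparison(counts, day_window = c(2, 6))
  hours <- 0:23
  is_day <- hours + 0.5 > 2 & hours + 0.5 <= 6
  expect_equal(r2$p_value,
               exact_ranksum_p(counts[is_day], counts[!is_day]),
               tolerance = 1e-9)

  expect_error(day_night_comparison(rep(1, 25)), "whole days")
})

test_that("frame-contrast visibility metric is a row-mean population variance", {
  expect_equal(visibility_metric(matrix(7, 10, 10)), 0)
  two_band <- rbind(matrix(10, 5, 8), matrix(30, 5, 8))
  expect_equal(visibility_metric(two_band), 100)
  set.seed(13)
  m <- matrix(runif(200, 0, 255), 20, 10)
  expect_equal(visibility_metric(m + 40), visibility_metric(m))
  expect_error(visibility_metric(matrix(numeric(0), 0, 0)), "empty")
})
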