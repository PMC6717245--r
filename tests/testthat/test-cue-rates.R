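test_that("offshore distribution uses per-pod mean range and last group size", {
  one_pod <- data.frame(pod_id = "A", time_s = c(1, 2),
                        range_m = c(1000, 2000), group_size = c(1, 2),
                        direction = "south", beaufort = 2, visibility = 2)
  d <- build_offshore_distribution(one_pod)
  expect_equal(d$ranges_m, 1500, ignore_attr = TRUE)
  expect_equal(d$weights, 2, ignore_attr = TRUE)

  # Beaufort 5 is excluded (cutoff is strict)
  bft5 <- one_pod; bft5$beaufort <- 5
  expect_error(build_offshore_distribution(bft5), "no sightings")

  # hand-computed five-pod table: B excluded (Beaufort 5), D northbound,
  # E excluded (visibility 6); A -> (1500, 2), C -> (3200, 4)
  d5 <- build_offshore_distribution(five_pod_sightings())
  expect_equal(sort(d5$ranges_m), c(1500, 3200), ignore_attr = TRUE)
  expect_equal(d5$weights[order(d5$ranges_m)], c(2, 4), ignore_attr = TRUE)
})

test_that("interval proportions normalize, vanish off-support, and match the survey table", {
  d <- offshore_distribution(c(1000, 1800, 2500), c(2, 3, 5))
  expect_equal(proportion_in_interval(d, 0, 1e6), 1)
  expect_equal(proportion_in_interval(d, 5000, 6000), 0)
  expect_error(proportion_in_interval(d, 2000, 1000), "r_min < r_max")

  tab <- january_blow_survey()
  within <- sum(tab$whales_within_range)    # 1,041
  total <- sum(tab$median_whales)           # 1,953
  dd <- offshore_distribution(c(1200, 4000), c(within, total - within))
  expect_equal(proportion_in_interval(dd, 500, 2100), 0.533,
               tolerance = 5e-4)
})

test_that("interval proportions are monotone under inclusion and additive over disjoint intervals", {
  set.seed(14)
  d <- offshore_distribution(runif(50, 100, 9000), rpois(50, 3) + 1)
  p1 <- proportion_in_interval(d, 500, 2000)
  p2 <- proportion_in_interval(d, 500, 3000)
  expect_lte(p1, p2)
  expect_equal(proportion_in_interval(d, 500, 2000) +
                 proportion_in_interval(d, 2000, 3000), p2)
})

test_that("southbound proportion is the group-size-weighted complement of c_N", {
  s_all <- data.frame(pod_id = c("A", "B"), group_size = c(3, 2),
                      direction = "south")
  expect_equal(southbound_proportion(s_all)$c_N, 0)

  s_mix <- data.frame(pod_id = letters[1:5], group_size = c(4, 4, 2, 4, 2),
                      direction = c("south", "south", "north", "south",
                                    "milling"))
  # 12 of 16 whales south
  expect_equal(southbound_proportion(s_mix)$c_N, 0.25)

  s82 <- data.frame(pod_id = c("a", "b"), group_size = c(8, 2),
                    direction = c("south", "north"))
  expect_equal(southbound_proportion(s82)$c_N, 0.2)

  expect_true(is.na(southbound_proportion(s_all[0, ])$c_N))
})

test_that("a season's direction series reproduces its construction day by day", {
  # late-season pattern: mostly southbound, then 63-75% in the last 3 days
  shares <- c(rep(0.9, 7), 0.75, 0.7, 0.63)
  season <- lapply(seq_along(shares), function(d) {
    n_s <- round(shares[d] * 100)
    data.frame(pod_id = paste0("p", 1:100),
               group_size = 1,
               direction = c(rep("south", n_s), rep("north", 100 - n_s)))
  })
  got <- vapply(seq_along(season), function(d)
    southbound_proportion(season[[d]], day = d)$southbound_share, numeric(1))
  expect_equal(got, round(shares * 100) / 100)
  expect_true(all(got[1:7] > 0.8))
  expect_true(all(got[8:10] >= 0.63 & got[8:10] <= 0.75))
})

test_that("the cue-rate identity reproduces the published season and four-day rates", {
  k <- granite_canyon_constants()
  t_ac <- acoustic_transit_time(k$array_transit_distance_m, k$swim_speed_mps)

  r_season <- cue_rate(k$season_calls, 2 * k$season_abundance,
                       k$p_sa_array, t_ac, unit = "day")
  expect_equal(round(r_season$rate, 1), 7.5)

  r_aerial <- cue_rate(k$season_calls, 2 * k$season_abundance,
                       k$p_sa_aerial, t_ac, unit = "day")
  expect_equal(round(r_aerial$rate, 1), 5.7)

  r_blow <- cue_rate(1447, 1041, 1, transit_time(1.7, "camera"),
                     unit = "hour")
  expect_equal(round(r_blow$rate), 49)
})

test_that("cue rate is homogeneous in the numerator and inverse in each denominator factor", {
  t_ac <- acoustic_transit_time(2280, 1.6)
  base <- cue_rate(1000, 500, 0.7, t_ac, unit = "day")$rate
  expect_equal(cue_rate(2000, 500, 0.7, t_ac, unit = "day")$rate, 2 * base)
  expect_equal(cue_rate(1000, 1000, 0.7, t_ac, unit = "day")$rate, base / 2)
  expect_equal(cue_rate(1000, 500, 0.35, t_ac, unit = "day")$rate, 2 * base)
  t2 <- acoustic_transit_time(4560, 1.6)
  expect_equal(cue_rate(1000, 500, 0.7, t2, unit = "day")$rate, base / 2)
})

test_that("abundance credibility bounds map to rate bounds with reversed roles", {
  est <- cue_rate(4854, list(median_whales = 2 * 28790,
                             ci_low = 2 * 23620, ci_high = 2 * 39210),
                  0.68, acoustic_transit_time(2280, 1.6), unit = "day")
  expect_lt(est$lower, est$rate)
  expect_gt(est$upper, est$rate)
  # the published uncertainty span for the season rate: 5.5-9.1
  expect_lt(abs(est$lower - 5.5), 0.05)
  expect_lt(abs(est$upper - 9.1), 0.1)
})

test_that("daily cue rates join counts to abundance by day", {
  counts <- data.frame(day = 1:3, corrected = c(100, 200, 300))
  ab <- data.frame(day = 1:3, median_whales = c(50, 50, 100),
                   ci_low = c(40, 40, 80), ci_high = c(60, 60, 120))
  r <- daily_cue_rates(counts, ab, p_sa = 1,
                       t_sa = transit_time(1440, "acoustic"), unit = "day")
  expect_equal(r$rate, c(2, 4, 3))
  expect_true(all(r$lower < r$rate & r$rate < r$upper))
})
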