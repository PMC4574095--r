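test_that("intensity classification follows the cut-point boundaries", {
  got <- classify_intensity(c(0, 100, 101, 2295, 2296, 9000))
  expect_equal(as.character(got),
               c("sedentary", "sedentary", "light", "light", "mvpa", "mvpa"))
  expect_error(classify_intensity(-1), "non-negative")
  # custom cut-points move the boundaries
  cp <- pa_cutpoints(sedentary_max = 50, light_max = 2999)
  expect_equal(as.character(classify_intensity(c(51, 2999, 3000), cp)),
               c("light", "light", "mvpa"))
  expect_error(pa_cutpoints(200, 100), "sedentary_max < light_max")
})

test_that("a fully worn constant day summarises to the definitional values", {
  s <- make_day(rep(500L, 960))
  d <- summarize_day(s, "2005-03-01")
  expect_equal(d$wear_minutes, 960L)
  expect_equal(d$cpm, 500)
  expect_equal(d$minutes_sedentary, 0L)
  expect_equal(d$minutes_light, 960L)
  expect_equal(d$minutes_mvpa, 0L)
  expect_true(d$is_valid)
  expect_false(d$meets_60_mvpa)
})

test_that("an all-zero day has zero wear and is invalid", {
  s <- make_series(rep(0L, 1440))
  d <- summarize_day(s, "2005-03-01")
  expect_equal(d$wear_minutes, 0L)
  expect_false(d$is_valid)
  expect_true(is.na(d$cpm))
})

test_that("a day with 400 wear minutes fails the 500-minute validity rule", {
  w <- rep(0L, 960)
  w[1:400] <- 500L
  d <- summarize_day(make_day(w), "2005-03-01")
  expect_equal(d$wear_minutes, 400L)
  expect_false(d$is_valid)
  expect_equal(d$cpm, 500)
})

test_that("counts inside tolerated interruptions are excluded from wear", {
  # 90-min bout with a 2-min interruption of 80 counts in mid-window
  w <- rep(200L, 960)
  w[301:390] <- 0L
  w[340:341] <- 80L
  d <- summarize_day(make_day(w), "2005-03-01")
  expect_equal(d$wear_minutes, 960L - 90L)
  expect_equal(d$cpm, 200)
})

test_that("wear and intensity metrics ignore counts outside 07:00-22:59", {
  set.seed(17)
  w <- sample(0:3000, 960, replace = TRUE)
  w[w == 0] <- 1L # active through the window
  base <- summarize_day(make_day(w), "2005-03-01")
  # perturb deep-night minutes (00:00-05:00) arbitrarily
  counts <- c(rep(0L, 420), w, rep(0L, 60))
  counts[sample(1:300, 40)] <- sample(1:5000, 40, replace = TRUE)
  pert <- summarize_day(make_series(counts), "2005-03-01")
  expect_equal(pert[, -(1:2)], base[, -(1:2)])
})

test_that("intensity minutes partition wear minutes exactly", {
  set.seed(29)
  for (i in 1:25) {
    w <- sample(0:5000, 960, replace = TRUE)
    # random zero stretches to create non-wear of varying lengths
    st <- sample(1:800, 1); len <- sample(30:200, 1)
    w[st:min(960, st + len)] <- 0L
    d <- summarize_day(make_day(w), "2005-03-01")
    expect_identical(d$minutes_sedentary + d$minutes_light + d$minutes_mvpa,
                     d$wear_minutes)
  }
})

test_that("summarize_day rejects dates outside the series span", {
  s <- make_day(rep(100L, 960))
  expect_error(summarize_day(s, "2005-04-01"), "outside the series span")
})

test_that("non-wear spanning midnight is not fragmented by day slicing", {
  # zeros from 22:01 on day 1 through 00:00 on day 2 (120 min), embedded in
  # an otherwise active recording: detection on the full series keeps the
  # midnight-spanning bout as one interval and removes the 59 window
  # minutes it covers on day 1
  counts <- rep(50L, 2880)
  counts[1322:1441] <- 0L
  s <- make_series(counts)
  nw <- detect_nonwear(s)
  expect_equal(nw$length_minutes, 120L)
  days <- summarize_days(s, nw)
  # day 1 loses its 22:01-22:59 tail (59 window minutes)
  expect_equal(days$wear_minutes[1], 960L - 59L)
  expect_equal(days$wear_minutes[2], 960L)
})

test_that("timepoint aggregation averages daily means over valid days", {
  d <- make_day_rows(cpm = c(600, 800, 700), valid = c(TRUE, TRUE, FALSE))
  tp <- summarize_timepoint(d)
  expect_false(tp$included) # 2 valid days < default threshold of 3
  tp2 <- summarize_timepoint(d, min_valid_days = 2)
  expect_true(tp2$included)
  expect_equal(tp2$mean_cpm, 700)
  expect_equal(tp2$n_valid_days, 2L)
})

test_that("strict and liberal guideline metrics follow their definitions", {
  d <- make_day_rows(cpm = rep(500, 4), mvpa = c(70, 65, 60, 59))
  tp <- summarize_timepoint(d)
  expect_false(tp$strict_guideline)
  expect_equal(tp$pct_days_meeting_guideline, 75)

  d2 <- make_day_rows(cpm = rep(500, 3), mvpa = c(60, 61, 90))
  tp2 <- summarize_timepoint(d2)
  expect_true(tp2$strict_guideline)
  expect_equal(tp2$pct_days_meeting_guideline, 100)

  # percentage-of-time metrics partition to 100
  expect_equal(tp2$pct_sedentary + tp2$pct_light + tp2$pct_mvpa, 100,
               tolerance = 1e-9)
})

test_that("an empty day table yields an exclusion row", {
  tp <- summarize_timepoint(make_day_rows(numeric(0)))
  expect_false(tp$included)
  expect_equal(tp$n_valid_days, 0L)
  expect_true(is.na(tp$mean_cpm))
})

test_that("reduce_cohort tallies the exclusion flow", {
  coh <- simulate_cohort(quiet_config(15, days_per_participant = 3:4))
  red <- reduce_cohort(coh)
  expect_equal(red$counts$timepoints_in, length(coh$series))
  expect_equal(red$counts$timepoints_included +
                 red$counts$timepoints_excluded, red$counts$timepoints_in)
  expect_equal(red$counts$days_valid + red$counts$days_invalid,
               red$counts$days_measured)
  expect_equal(nrow(red$timepoints), length(coh$series))
})
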