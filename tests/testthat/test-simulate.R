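test_that("the same seed reproduces a cohort exactly", {
  c1 <- simulate_cohort(quiet_config(10, seed = 77))
  c2 <- simulate_cohort(quiet_config(10, seed = 77))
  expect_identical(c1$demographics, c2$demographics)
  expect_identical(lapply(c1$series, `[[`, "counts"),
                   lapply(c2$series, `[[`, "counts"))
  expect_identical(c1$truth$timepoints, c2$truth$timepoints)
  c3 <- simulate_cohort(quiet_config(10, seed = 78))
  expect_false(identical(c1$series[[1]]$counts, c3$series[[1]]$counts))
})

test_that("a degenerate all-sedentary zero-count process yields a zero day", {
  sp <- default_state_process(
    transition = matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, byrow = TRUE),
    initial = c(1, 0, 0),
    samplers = list(sedentary = function(n) integer(n),
                    light = function(n) integer(n),
                    mvpa = function(n) integer(n)))
  cfg <- quiet_config(5, state_process = sp, nonwear_bouts_per_day = 0)
  set.seed(1)
  d <- simulate_day(0, cfg)
  expect_true(all(d$counts == 0L))
})

test_that("day-level calibration hits the target cpm", {
  cfg <- quiet_config(5, nonwear_bouts_per_day = 0)
  set.seed(2)
  for (target in c(300, 700, 1100)) {
    d <- simulate_day(target, cfg)
    window <- d$counts[421:1380]
    expect_equal(mean(window), target, tolerance = 0.005 * target)
    expect_true(all(d$counts[c(1:420, 1381:1440)] == 0L))
    expect_true(all(window >= 1L)) # worn minutes always register counts
  }
  expect_error(simulate_day(6000, cfg), "infeasible")
})

test_that("injected non-wear bouts are recovered exactly by detection", {
  cfg <- quiet_config(25, nonwear_bouts_per_day = 1.2,
                      nonwear_duration_range = c(60, 110),
                      days_per_participant = 4:5, seed = 90)
  coh <- simulate_cohort(cfg)
  truth <- coh$truth$nonwear
  expect_gt(nrow(truth), 10)
  key <- paste(coh$demographics$participant_id,
               coh$demographics$timepoint_id)
  for (i in seq_len(nrow(truth))) {
    si <- match(paste(truth$participant_id[i], truth$timepoint_id[i]), key)
    s <- coh$series[[si]]
    nw <- detect_nonwear(s)
    idx <- (truth$day_of_timepoint[i] - 1L) * 1440L + truth$start_minute[i]
    j <- which(nw$start_index == idx)
    expect_length(j, 1L)
    expect_equal(nw$length_minutes[j], truth$length_minutes[i])
  }
})

test_that("participant mean cpm matches the truth manifest", {
  cfg <- quiet_config(60, days_per_participant = 7L, seed = 13)
  coh <- simulate_cohort(cfg)
  red <- reduce_cohort(coh)
  merged <- merge(red$timepoints, coh$truth$timepoints,
                  by = c("participant_id", "timepoint_id"))
  # day-level noise averages down over 7 days; population-level calibration
  # is much tighter than the per-participant scatter
  expect_equal(mean(merged$mean_cpm), mean(merged$true_cpm),
               tolerance = 0.01 * mean(merged$true_cpm))
  expect_lt(mean(abs(merged$mean_cpm - merged$true_cpm)),
            2 * cfg$sigma_day_cpm / sqrt(7))
})

test_that("demographics are internally consistent", {
  cfg <- sim_config(n_participants = 120, seed = 21,
                    proportion_longitudinal = 0.5)
  coh <- simulate_cohort(cfg)
  d <- coh$demographics
  expect_equal(nrow(d), length(coh$series))
  expect_true(all(d$age_years >= cfg$age_range[1] & d$age_years <= 18.9))
  expect_true(all(d$hemisphere[d$country == "Australia"] == "south"))
  expect_true(all(d$hemisphere[d$country == "UK"] == "north"))
  # assigned IOTF category is recoverable from the generated anthropometry
  bmi <- compute_bmi(d$weight_kg, d$height_m)
  cat_got <- as.character(classify_iotf(bmi, d$age_years, d$sex))
  expect_equal(cat_got, coh$truth$timepoints$weight_category)
  # longitudinal participants keep their sex and country across waves
  reps <- names(which(table(d$participant_id) == 2))
  expect_gt(length(reps), 10)
  for (p in reps[1:5]) {
    rows <- d[d$participant_id == p, ]
    expect_equal(rows$sex[1], rows$sex[2])
    expect_equal(rows$country[1], rows$country[2])
    expect_equal(rows$age_years[2] - rows$age_years[1],
                 cfg$timepoint_gap_years, tolerance = 1e-6)
  }
})

test_that("cohort files round-trip through disk", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(quiet_config(4, days_per_participant = 3L,
                                      seed = 31), dir = dir)
  expect_true(file.exists(file.path(dir, "demographics.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  red_mem <- reduce_cohort(coh)
  red_disk <- reduce_cohort(dir)
  o <- order(red_disk$timepoints$participant_id)
  expect_equal(red_disk$timepoints$mean_cpm[o],
               red_mem$timepoints$mean_cpm[order(
                 red_mem$timepoints$participant_id)])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$sex_gap_sd, 0)
})

test_that("strict guideline prevalence never exceeds the liberal metric", {
  for (seed in c(3, 4)) {
    cfg <- sim_config(n_participants = 80, seed = seed)
    red <- reduce_cohort(simulate_cohort(cfg))
    tp <- red$timepoints[red$timepoints$included, ]
    strict <- 100 * mean(tp$strict_guideline)
    liberal <- mean(tp$pct_days_meeting_guideline)
    expect_lte(strict, liberal)
    # and per timepoint: a strict pass means every valid day met the bar
    expect_true(all(tp$pct_days_meeting_guideline[tp$strict_guideline] == 100))
  }
})
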