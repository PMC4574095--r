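# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Quick minute-epoch series starting at local midnight.
make_series <- function(counts, start = "2005-03-01 00:00:00",
                        epoch_seconds = 60, pid = "p1", tid = "t1") {
  epoch_series(pid, tid, start, epoch_seconds, counts)
}

# A full 1440-minute day: zeros overnight, `window_counts` (length 960)
# across 07:00-22:59.
make_day <- function(window_counts, date = "2005-03-01") {
  stopifnot(length(window_counts) == 960L)
  counts <- c(rep(0L, 420L), window_counts, rep(0L, 60L))
  make_series(counts, start = paste(date, "00:00:00"))
}

# Minimal single-effect simulation configs used by simulator tests; small n
# keeps them fast.
quiet_config <- function(n = 20, ..., seed = 42) {
  sim_config(n_participants = n,
             countries = c(pooled = 0),
             sex_gap_sd = 0,
             annual_decline_pct = 0,
             weight_status_deficit = c(overweight = 0, obese = 0),
             season_effect_cpm = 0,
             proportion_longitudinal = 0,
             p_low_wear_day = 0,
             seed = seed, ...)
}

# Hand-built day-summary rows for timepoint aggregation tests.
make_day_rows <- function(cpm, mvpa = rep(120, length(cpm)),
                          valid = rep(TRUE, length(cpm))) {
  n <- length(cpm)
  wear <- rep(960L, n)
  tibble::tibble(
    participant_id = "p1", timepoint_id = "t1",
    date = as.Date("2005-03-01") + seq_len(n) - 1L,
    wear_minutes = ifelse(valid, wear, 300L),
    total_counts = cpm * ifelse(valid, wear, 300L),
    cpm = cpm,
    minutes_sedentary = as.integer(ifelse(valid, wear, 300L) - 100L - mvpa),
    minutes_light = 100L,
    minutes_mvpa = as.integer(mvpa),
    is_valid = valid,
    meets_60_mvpa = mvpa >= 60)
}

# Balanced analysis-record frame with a known additive structure, for the
# regression layer (bypasses the simulator).
make_records <- function(n_per_cell = 25, sex_effect = 0, noise_sd = 1,
                         n_countries = 1, seed = 99) {
  set.seed(seed)
  grid <- expand.grid(sex = c("male", "female"),
                      age_group = c("5-6", "7-8"),
                      country = paste0("c", seq_len(n_countries)),
                      rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  out <- 500 + sex_effect * (grid$sex == "male") +
    stats::rnorm(n, 0, noise_sd)
  tibble::tibble(
    participant_id = sprintf("r%04d", seq_len(n)),
    timepoint_id = "t1",
    mean_cpm = out,
    sex = grid$sex,
    age_group = factor(grid$age_group),
    age_years = ifelse(grid$age_group == "5-6", 5.5, 7.5),
    study_id = paste0("study_", grid$country),
    country = grid$country,
    season = factor(sample(c("summer_half", "winter_half"), n,
                           replace = TRUE)),
    cluster_id = sprintf("r%04d", seq_len(n)))
}
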