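#' Default minute-count state process
#'
#' The minute-level count stream is generated by a first-order Markov chain
#' over the three intensity states (sedentary, light, MVPA) with a count
#' draw per state, diurnally modulated. Sedentary draws are small positive
#' integers (1-100): in this generator a worn minute always registers at
#' least one count, so zero-count runs arise only from injected non-wear or
#' overnight sleep. That makes injected non-wear bouts exactly recoverable
#' and is the one deliberate idealisation relative to real wear data, where
#' true zeros also occur during wear.
#'
#' @param transition 3x3 row-stochastic matrix over (sedentary, light, mvpa).
#' @param initial Initial state probabilities.
#' @param samplers Named list of count samplers, each a `function(n)`
#'   returning `n` non-negative integer counts for that state.
#' @param max_target_cpm Largest day-level cpm target the process can be
#'   calibrated to.
#' @return A classed list consumed by [sim_config()].
#' @export
default_state_process <- function(
    transition = matrix(c(0.80, 0.18, 0.02,
                          0.28, 0.64, 0.08,
                          0.12, 0.48, 0.40),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("sedentary", "light", "mvpa"),
                                        c("sedentary", "light", "mvpa"))),
    initial = c(sedentary = 0.55, light = 0.38, mvpa = 0.07),
    samplers = list(
      sedentary = function(n) pmin(100L, 1L + as.integer(stats::rexp(n, 1 / 30))),
      light = function(n)
        pmin(2295L, pmax(101L, as.integer(round(stats::rlnorm(n, 6.3, 0.55))))),
      mvpa = function(n)
        pmin(15000L, pmax(2296L, as.integer(round(stats::rlnorm(n, 8.1, 0.35)))))),
    max_target_cpm = 5000) {
  if (!is.matrix(transition) || any(dim(transition) != 3L)) {
    stop("transition must be a 3x3 matrix", call. = FALSE)
  }
  if (any(transition < 0) || any(transition > 1) ||
      any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition rows must be probabilities summing to 1", call. = FALSE)
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-8) {
    stop("initial state probabilities must sum to 1", call. = FALSE)
  }
  structure(list(transition = transition, initial = initial,
                 samplers = samplers, max_target_cpm = max_target_cpm),
            class = "state_process")
}

# Double-peaked diurnal shape over the 960-minute waking window (07:00 start),
# normalised to mean 1 so it changes the shape but not the level.
diurnal_profile <- function(w = 960L) {
  t <- seq_len(w)
  f <- 1 + 0.35 * exp(-((t - 90)^2) / (2 * 110^2)) +
           0.35 * exp(-((t - 580)^2) / (2 * 150^2))
  f / mean(f)
}

#' Synthetic cohort configuration
#'
#' Defines the generative model for a pooled multi-country youth
#' accelerometry cohort with known ground truth. A participant's true mean
#' cpm is built additively from a baseline level at age 5, a constant
#' per-year decrement after age 5 (expressed as a percentage of the age-5
#' baseline), a between-country offset, a sex gap, a weight-status deficit
#' applied from `weight_deficit_min_age` onward, a summer/winter season
#' shift, and a participant-level random effect shared across that child's
#' measurement waves. Each measured day adds day-level noise, and the
#' minute-level stream is drawn from the Markov state process and calibrated
#' so the day's worn-window cpm hits the day target.
#'
#' `sex_gap_sd` is the boys-minus-girls difference in *standard-deviation
#' units of the analysed outcome* (participant mean cpm, pooled over both
#' sexes), matching how standardised sex contrasts are reported. The
#' generator converts it to a cpm gap using the known within-sex SD of the
#' outcome, inflating for the gap's own contribution to the pooled variance:
#' `gap_cpm = g * sigma_within / sqrt(1 - g^2/4)`.
#'
#' @param n_participants Number of participants.
#' @param countries Named numeric vector of additive country cpm offsets.
#' @param south_hemisphere Country names located in the southern hemisphere.
#' @param baseline_cpm_age5 Population mean cpm at age 5.
#' @param annual_decline_pct Per-year decline after age 5, as a percentage
#'   of `baseline_cpm_age5`.
#' @param sex_gap_sd Standardised boys-minus-girls gap, in SD units of the
#'   participant-level outcome (see Details). Must lie in (-2, 2).
#' @param weight_status_deficit Named vector `c(overweight=, obese=)`, cpm
#'   deficits relative to normal weight.
#' @param weight_deficit_sex_multiplier Named vector `c(male=, female=)`
#'   scaling the deficit by sex.
#' @param weight_deficit_min_age Age from which the deficit applies.
#' @param weight_prevalence Named probabilities for
#'   normal/overweight/obese.
#' @param age_range Baseline age range (uniform).
#' @param proportion_longitudinal Fraction of participants measured at
#'   `n_timepoints` waves.
#' @param n_timepoints Measurement waves for longitudinal participants.
#' @param timepoint_gap_years Years between waves.
#' @param days_per_participant Vector of possible measured days per
#'   timepoint (sampled uniformly).
#' @param sigma_between_cpm Between-participant SD of true mean cpm.
#' @param sigma_day_cpm Day-to-day SD around the participant mean.
#' @param season_effect_cpm Summer-half minus winter-half cpm difference.
#' @param nonwear_bouts_per_day Poisson rate of injected daytime non-wear
#'   bouts per day (capped at 2).
#' @param nonwear_duration_range Bout length range in minutes (>= 60).
#' @param p_low_wear_day Probability that a day is a low-compliance day
#'   carrying one long non-wear block (length drawn from
#'   `low_wear_duration_range`), leaving it below the 500-minute validity
#'   threshold. The default emulates the roughly one-in-five invalid days
#'   typical of child accelerometry.
#' @param low_wear_duration_range Length range of the low-compliance block.
#' @param interruption_rate Probability a bout contains one tolerated 1-2
#'   minute non-zero interruption run.
#' @param state_process A [default_state_process()] object.
#' @param seed Integer RNG seed; the same seed reproduces the cohort
#'   byte-identically.
#' @return A classed `sim_config` list, including derived truth values
#'   `sex_gap_cpm`, `decrement_cpm_per_year` and `sigma_within_cpm`.
#' @export
sim_config <- function(n_participants = 2000L,
                       countries = c(USA = -50, UK = -20, Australia = 10,
                                     Denmark = 30, Estonia = 40, Norway = 60),
                       south_hemisphere = c("Australia", "Brazil"),
                       baseline_cpm_age5 = 738,
                       annual_decline_pct = 4.2,
                       sex_gap_sd = 0.45,
                       weight_status_deficit = c(overweight = 30, obese = 70),
                       weight_deficit_sex_multiplier = c(male = 1.3,
                                                         female = 0.7),
                       weight_deficit_min_age = 7,
                       weight_prevalence = c(normal = 0.75, overweight = 0.18,
                                             obese = 0.07),
                       age_range = c(5, 15),
                       proportion_longitudinal = 0.25,
                       n_timepoints = 2L,
                       timepoint_gap_years = 2,
                       days_per_participant = 3:7,
                       sigma_between_cpm = 180,
                       sigma_day_cpm = 150,
                       season_effect_cpm = 30,
                       nonwear_bouts_per_day = 0.3,
                       nonwear_duration_range = c(60, 120),
                       p_low_wear_day = 0.19,
                       low_wear_duration_range = c(500, 900),
                       interruption_rate = 0.3,
                       state_process = default_state_process(),
                       seed = 1L) {
  stopifnot(n_participants >= 1, length(countries) >= 1,
            !is.null(names(countries)))
  if (abs(sex_gap_sd) >= 2) {
    stop("sex_gap_sd must lie in (-2, 2)", call. = FALSE)
  }
  probs <- c(weight_prevalence, proportion_longitudinal, interruption_rate,
             p_low_wear_day)
  if (any(probs < 0) || any(probs > 1) ||
      abs(sum(weight_prevalence) - 1) > 1e-8) {
    stop("prevalences/rates must be probabilities (weight_prevalence ",
         "summing to 1)", call. = FALSE)
  }
  if (any(c(sigma_between_cpm, sigma_day_cpm) < 0)) {
    stop("variance parameters must be non-negative", call. = FALSE)
  }
  if (nonwear_duration_range[1] < 60) {
    stop("injected non-wear bouts must be at least 60 minutes", call. = FALSE)
  }
  if (low_wear_duration_range[1] < 461 || low_wear_duration_range[2] > 952) {
    stop("low-wear blocks must be 461-952 minutes so the day is invalid ",
         "yet the block fits the window", call. = FALSE)
  }
  stopifnot(inherits(state_process, "state_process"))
  if (baseline_cpm_age5 > state_process$max_target_cpm) {
    stop("baseline cpm exceeds the state process ceiling (",
         state_process$max_target_cpm, " cpm)", call. = FALSE)
  }

  sigma_within <- sqrt(sigma_between_cpm^2 +
                         sigma_day_cpm^2 * mean(1 / days_per_participant))
  cfg <- list(
    n_participants = as.integer(n_participants),
    countries = countries,
    south_hemisphere = south_hemisphere,
    baseline_cpm_age5 = baseline_cpm_age5,
    annual_decline_pct = annual_decline_pct,
    sex_gap_sd = sex_gap_sd,
    weight_status_deficit = weight_status_deficit,
    weight_deficit_sex_multiplier = weight_deficit_sex_multiplier,
    weight_deficit_min_age = weight_deficit_min_age,
    weight_prevalence = weight_prevalence,
    age_range = age_range,
    proportion_longitudinal = proportion_longitudinal,
    n_timepoints = as.integer(n_timepoints),
    timepoint_gap_years = timepoint_gap_years,
    days_per_participant = as.integer(days_per_participant),
    sigma_between_cpm = sigma_between_cpm,
    sigma_day_cpm = sigma_day_cpm,
    season_effect_cpm = season_effect_cpm,
    nonwear_bouts_per_day = nonwear_bouts_per_day,
    nonwear_duration_range = as.integer(nonwear_duration_range),
    p_low_wear_day = p_low_wear_day,
    low_wear_duration_range = as.integer(low_wear_duration_range),
    interruption_rate = interruption_rate,
    state_process = state_process,
    seed = as.integer(seed),
    # derived truth
    sigma_within_cpm = sigma_within,
    sex_gap_cpm = sex_gap_sd * sigma_within / sqrt(1 - sex_gap_sd^2 / 4),
    decrement_cpm_per_year = annual_decline_pct / 100 * baseline_cpm_age5)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d participants, %d countries, ages %.1f-%.1f, ",
           "seed %d\n  truth: sex gap %.2f SD (%.1f cpm), decline %.1f%%/yr ",
           "(%.1f cpm/yr), country offsets [%g, %g] cpm\n"),
    x$n_participants, length(x$countries), x$age_range[1], x$age_range[2],
    x$seed, x$sex_gap_sd, x$sex_gap_cpm, x$annual_decline_pct,
    x$decrement_cpm_per_year, min(x$countries), max(x$countries)))
  invisible(x)
}

# --- vectorised day engine ---------------------------------------------------
# targets: day-level cpm targets (length N). Returns counts (N x 1440 integer
# matrix, window minutes 421..1380 populated) and the injected non-wear truth.
sim_day_block <- function(targets, config) {
  N <- length(targets)
  W <- 960L
  sp <- config$state_process
  if (any(targets > sp$max_target_cpm)) {
    stop("infeasible day target cpm (", max(targets), " > ceiling ",
         sp$max_target_cpm, ")", call. = FALSE)
  }

  # Markov chain over window minutes, all days in parallel
  cum <- t(apply(sp$transition, 1, cumsum))
  states <- matrix(0L, N, W)
  states[, 1L] <- findInterval(stats::runif(N), cumsum(sp$initial)) + 1L
  states[states[, 1L] > 3L, 1L] <- 3L
  for (t in 2L:W) {
    u <- stats::runif(N)
    m <- cum[states[, t - 1L], , drop = FALSE]
    states[, t] <- 1L + (u > m[, 1L]) + (u > m[, 2L])
  }

  counts <- matrix(0, N, W)
  for (s in 1:3) {
    idx <- which(states == s)
    if (length(idx)) {
      counts[idx] <- sp$samplers[[c("sedentary", "light", "mvpa")[s]]](
        length(idx))
    }
  }
  base_counts_positive <- counts > 0
  counts <- counts * rep(diurnal_profile(W), each = N)

  # inject non-wear bouts (zero runs >= 60 min, optional 1-2 min
  # interruption); low-compliance days get one long block that pushes wear
  # below the validity threshold
  nb <- pmin(2L, stats::rpois(N, config$nonwear_bouts_per_day))
  low_wear <- stats::runif(N) < config$p_low_wear_day
  nw <- matrix(FALSE, N, W)
  tr_day <- integer(0); tr_start <- integer(0); tr_len <- integer(0)
  tr_int <- integer(0)
  int_day <- integer(0); int_col <- integer(0)
  margin <- 4L # wear minutes kept clear of window edges and between bouts
  for (d in which(nb > 0L | low_wear)) {
    placed <- integer(0) # occupied [start, end] pairs
    lens <- c(if (low_wear[d])
                sample(config$low_wear_duration_range[1]:
                         config$low_wear_duration_range[2], 1L),
              if (nb[d] > 0L)
                sample(config$nonwear_duration_range[1]:
                         config$nonwear_duration_range[2], nb[d],
                       replace = TRUE))
    for (len in lens) {
      for (try in 1:8) {
        st <- sample(margin:(W - len - margin + 1L), 1L)
        ok <- TRUE
        if (length(placed)) {
          ps <- placed[c(TRUE, FALSE)]; pe <- placed[c(FALSE, TRUE)]
          ok <- all(st > pe + margin | st + len - 1L < ps - margin)
        }
        if (ok) break
        st <- NA_integer_
      }
      if (is.na(st)) next
      placed <- c(placed, st, st + len - 1L)
      nw[d, st:(st + len - 1L)] <- TRUE
      n_int <- 0L
      if (len >= 62L && stats::runif(1) < config$interruption_rate) {
        ilen <- sample(1:2, 1L)
        ioff <- sample(2:(len - ilen - 1L), 1L)
        n_int <- ilen
        int_day <- c(int_day, rep(d, ilen))
        int_col <- c(int_col, st + ioff - 1L + seq_len(ilen) - 1L)
      }
      tr_day <- c(tr_day, d); tr_start <- c(tr_start, st)
      tr_len <- c(tr_len, len); tr_int <- c(tr_int, n_int)
    }
  }
  counts[nw] <- 0

  # calibrate each day's worn-window cpm to its target
  wear_n <- rowSums(!nw)
  base_sum <- rowSums(counts)
  scale <- ifelse(base_sum > 0, targets * wear_n / base_sum, 0)
  counts <- round(counts * scale)
  clamp <- !nw & base_counts_positive & counts < 1
  counts[clamp] <- 1

  # tolerated interruption minutes: small non-zero counts inside bouts
  if (length(int_day)) {
    counts[cbind(int_day, int_col)] <- sample(20:99, length(int_day),
                                              replace = TRUE)
  }

  full <- matrix(0L, N, 1440L)
  full[, (WINDOW_START_MIN + 1L):(WINDOW_END_MIN + 1L)] <-
    as.integer(counts)
  list(counts = full,
       nonwear = tibble::tibble(
         day = tr_day,
         start_minute = tr_start + WINDOW_START_MIN, # 1-based within day
         length_minutes = tr_len,
         interruption_minutes = tr_int))
}

#' Simulate a single day of minute counts
#'
#' Draws one 1440-minute count day from the configured state process:
#' overnight minutes (outside 07:00-22:59) are zero, worn window minutes
#' follow the diurnally modulated Markov chain, injected non-wear bouts are
#' zero runs of at least 60 minutes (optionally containing a tolerated 1-2
#' minute non-zero interruption), and the worn-window counts are calibrated
#' so the day's cpm over worn minutes equals `target_cpm` up to integer
#' rounding.
#'
#' @param target_cpm Desired cpm over worn window minutes.
#' @param config A [sim_config()].
#' @return List with `counts` (integer vector of length 1440) and `nonwear`
#'   (injected bout truth: `start_minute` within the day, `length_minutes`,
#'   `interruption_minutes`).
#' @export
simulate_day <- function(target_cpm, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), length(target_cpm) == 1L,
            target_cpm >= 0)
  blk <- sim_day_block(target_cpm, config)
  list(counts = blk$counts[1L, ], nonwear = blk$nonwear[, -1L])
}

#' Simulate a cohort of accelerometer recordings with known truth
#'
#' Generates demographics, per-timepoint epoch series and a truth manifest
#' for a multi-country youth cohort under the generative model described in
#' [sim_config()]. Longitudinal participants are re-measured at fixed age
#' gaps with the participant random effect carried across waves, so the
#' clustering the analysis layer corrects for is really present.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory: writes one epoch CSV per
#'   participant-timepoint (`<participant>__<timepoint>.csv`),
#'   `demographics.csv` and `truth.json`.
#' @return An object of class `sim_cohort`: `config`, `demographics`
#'   (tibble, one row per participant-timepoint), `series` (list of
#'   [epoch_series()]) and `truth` (manifest: injected effect sizes, per-
#'   timepoint true cpm, injected non-wear bouts).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_participants

  pid <- sprintf("P%05d", seq_len(np))
  sex <- sample(c("male", "female"), np, replace = TRUE)
  country <- sample(names(config$countries), np, replace = TRUE)
  hemisphere <- ifelse(country %in% config$south_hemisphere, "south", "north")
  age0 <- stats::runif(np, config$age_range[1], config$age_range[2])
  wcat <- sample(names(config$weight_prevalence), np, replace = TRUE,
                 prob = config$weight_prevalence)
  longit <- stats::runif(np) < config$proportion_longitudinal
  b_i <- stats::rnorm(np, 0, config$sigma_between_cpm)
  month <- sample(1:12, np, replace = TRUE)
  height_dev <- stats::rnorm(np, 0, 0.04)
  bmi_u <- stats::runif(np)

  # expand to participant-timepoints
  ntp <- ifelse(longit, config$n_timepoints, 1L)
  p_idx <- rep(seq_len(np), ntp)
  wave <- unlist(lapply(ntp, seq_len), use.names = FALSE)
  age <- pmin(18.9, age0[p_idx] + (wave - 1L) * config$timepoint_gap_years)
  n_tp <- length(p_idx)
  tp_id <- paste0("t", wave)
  season <- assign_season(month[p_idx], hemisphere[p_idx])

  # anthropometry consistent with the assigned IOTF category
  cuts <- iotf_cutoffs()
  ow <- ob <- numeric(n_tp)
  for (s in c("male", "female")) {
    tab <- cuts[cuts$sex == s, ]
    idx <- sex[p_idx] == s
    a <- pmin(age[idx], 18)
    ow[idx] <- stats::approx(tab$age_years, tab$bmi_overweight, a, rule = 2)$y
    ob[idx] <- stats::approx(tab$age_years, tab$bmi_obese, a, rule = 2)$y
  }
  u <- bmi_u[p_idx]
  wc <- wcat[p_idx]
  bmi <- ifelse(wc == "normal", 14.5 + u * (ow - 0.2 - 14.5),
         ifelse(wc == "overweight", ow + u * (ob - 0.1 - ow), ob + u * 5))
  height <- 0.85 + 0.055 * age + height_dev[p_idx]
  weight <- bmi * height^2

  # true participant-timepoint mean cpm
  deficit <- ifelse(age >= config$weight_deficit_min_age & wc != "normal",
                    config$weight_status_deficit[wc] *
                      config$weight_deficit_sex_multiplier[sex[p_idx]], 0)
  mu <- config$baseline_cpm_age5 -
    config$decrement_cpm_per_year * pmax(0, age - 5) +
    config$countries[country[p_idx]] +
    ifelse(sex[p_idx] == "male", 0.5, -0.5) * config$sex_gap_cpm -
    deficit +
    ifelse(season == "summer_half", 0.5, -0.5) * config$season_effect_cpm +
    b_i[p_idx]
  mu <- pmax(80, mu)

  n_days <- sample(config$days_per_participant, n_tp, replace = TRUE)
  year <- 2005L + (wave - 1L) * ceiling(config$timepoint_gap_years)
  date0 <- as.Date(sprintf("%d-%02d-15", year, month[p_idx]))

  # day-level targets, then one vectorised pass over all days
  day_tp <- rep(seq_len(n_tp), n_days)
  day_of_tp <- sequence(n_days)
  targets <- pmax(60, mu[day_tp] +
                    stats::rnorm(length(day_tp), 0, config$sigma_day_cpm))
  blk <- sim_day_block(targets, config)

  series <- vector("list", n_tp)
  row_of_tp <- split(seq_along(day_tp), day_tp)
  origin <- as.POSIXct("1970-01-01", tz = "UTC")
  for (i in seq_len(n_tp)) {
    rows <- row_of_tp[[i]]
    cnts <- as.integer(t(blk$counts[rows, , drop = FALSE]))
    series[[i]] <- epoch_series(
      pid[p_idx[i]], tp_id[i],
      origin + as.numeric(date0[i]) * 86400, 60L, cnts)
  }

  demographics <- tibble::tibble(
    participant_id = pid[p_idx], timepoint_id = tp_id,
    sex = sex[p_idx], age_years = age,
    height_m = height, weight_kg = weight,
    study_id = paste0("study_", country[p_idx]),
    country = country[p_idx], hemisphere = hemisphere[p_idx],
    measurement_month = month[p_idx], measurement_date = date0)

  nw <- blk$nonwear
  truth_nonwear <- tibble::tibble(
    participant_id = pid[p_idx[day_tp[nw$day]]],
    timepoint_id = tp_id[day_tp[nw$day]],
    date = date0[day_tp[nw$day]] + day_of_tp[nw$day] - 1L,
    day_of_timepoint = day_of_tp[nw$day],
    start_minute = nw$start_minute,
    length_minutes = nw$length_minutes,
    interruption_minutes = nw$interruption_minutes)

  truth <- list(
    sex_gap_sd = config$sex_gap_sd,
    sex_gap_cpm = config$sex_gap_cpm,
    annual_decline_pct = config$annual_decline_pct,
    decrement_cpm_per_year = config$decrement_cpm_per_year,
    sigma_within_cpm = config$sigma_within_cpm,
    country_offsets = config$countries,
    timepoints = tibble::tibble(
      participant_id = pid[p_idx], timepoint_id = tp_id,
      true_cpm = unname(mu), n_days = n_days,
      sex = sex[p_idx], age_years = age, country = country[p_idx],
      weight_category = wc, season = as.character(season)),
    nonwear = truth_nonwear)

  cohort <- structure(list(config = config, demographics = demographics,
                           series = series, truth = truth),
                      class = "sim_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d participants, %d timepoints, %d injected non-wear bouts\n",
    x$config$n_participants, length(x$series), nrow(x$truth$nonwear)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One epoch CSV per participant-timepoint plus `demographics.csv` and the
#' truth manifest `truth.json`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  for (s in cohort$series) {
    write_epoch_file(s, file.path(dir, paste0(s$participant_id, "__",
                                              s$timepoint_id, ".csv")))
  }
  data.table::fwrite(cohort$demographics, file.path(dir, "demographics.csv"))
  tr <- cohort$truth
  tr$country_offsets <- as.list(tr$country_offsets)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
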