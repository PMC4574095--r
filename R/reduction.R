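#' Intensity cut-points for minute counts
#'
#' Default thresholds are the Evenson youth cut-points on vertical-axis
#' counts: sedentary at or below 100 cpm, light 101-2295 cpm, and
#' moderate-to-vigorous (MVPA) at or above 2296 cpm.
#'
#' @param sedentary_max Upper bound (inclusive) of the sedentary band.
#' @param light_max Upper bound (inclusive) of the light band; MVPA starts at
#'   `light_max + 1`.
#' @return A classed list used by [classify_intensity()] and
#'   [summarize_days()].
#' @export
pa_cutpoints <- function(sedentary_max = 100L, light_max = 2295L) {
  sedentary_max <- as.integer(sedentary_max)
  light_max <- as.integer(light_max)
  if (is.na(sedentary_max) || is.na(light_max) || sedentary_max < 0L ||
      light_max <= sedentary_max) {
    stop("cut-points must satisfy 0 <= sedentary_max < light_max",
         call. = FALSE)
  }
  structure(list(sedentary_max = sedentary_max, light_max = light_max),
            class = "pa_cutpoints")
}

#' Classify minute counts into intensity categories
#'
#' @param count Vector of non-negative minute counts.
#' @param cutpoints A [pa_cutpoints()] object.
#' @return Factor with levels `sedentary`, `light`, `mvpa`.
#' @examples
#' classify_intensity(c(0, 100, 101, 2295, 2296))
#' @export
classify_intensity <- function(count, cutpoints = pa_cutpoints()) {
  stopifnot(inherits(cutpoints, "pa_cutpoints"))
  if (anyNA(count) || any(count < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  code <- 1L + (count > cutpoints$sedentary_max) + (count > cutpoints$light_max)
  factor(c("sedentary", "light", "mvpa")[code],
         levels = c("sedentary", "light", "mvpa"))
}

# Waking measurement window, minutes of day (0 = midnight): 07:00..22:59,
# i.e. 960 minutes per day.
WINDOW_START_MIN <- 420L
WINDOW_END_MIN <- 1379L

#' Summarise a minute-epoch series into per-day wear and activity metrics
#'
#' For every calendar day the series touches, counts only minutes whose clock
#' time falls in the 07:00-22:59 window (960 minutes). Wear minutes are
#' recorded window minutes outside all non-wear intervals; total counts, cpm
#' and intensity minutes accrue over wear minutes only. A day is valid when
#' it has at least `min_wear_minutes` wear minutes, and meets the daily
#' guideline when MVPA minutes reach `guideline_mvpa_minutes`.
#'
#' `nonwear` should be computed on the full series (see [detect_nonwear()]);
#' the intervals are intersected with each day's window here.
#'
#' @param series An [epoch_series()] at 60 s epochs.
#' @param nonwear Non-wear interval table; computed from `series` by default.
#' @param cutpoints A [pa_cutpoints()] object.
#' @param min_wear_minutes Valid-day threshold, default 500.
#' @param guideline_mvpa_minutes Daily MVPA guideline, default 60.
#' @return A [tibble::tibble] with one row per calendar day: `participant_id`,
#'   `timepoint_id`, `date`, `wear_minutes`, `total_counts`, `cpm`
#'   (`NA` when no wear), `minutes_sedentary`, `minutes_light`,
#'   `minutes_mvpa`, `is_valid`, `meets_60_mvpa`.
#' @export
summarize_days <- function(series, nonwear = detect_nonwear(series),
                           cutpoints = pa_cutpoints(),
                           min_wear_minutes = 500L,
                           guideline_mvpa_minutes = 60L) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_seconds != 60L) {
    stop("day summaries require 60 s epochs; reintegrate() first",
         call. = FALSE)
  }
  counts <- series$counts
  n <- length(counts)
  start_min <- floor(as.numeric(series$start) / 60)
  abs_min <- start_min + seq_len(n) - 1
  mod <- abs_min %% 1440
  day <- abs_min %/% 1440

  nw <- nonwear_mask(nonwear, n)
  in_window <- mod >= WINDOW_START_MIN & mod <= WINDOW_END_MIN
  wear <- in_window & !nw

  sed <- wear & counts <= cutpoints$sedentary_max
  mvpa <- wear & counts > cutpoints$light_max

  # calendar days occupy contiguous index ranges, so aggregate by slicing
  # rather than by factor grouping (hot path for cohort-scale reduction)
  brk <- c(1L, which(diff(day) != 0) + 1L, n + 1L)
  k <- length(brk) - 1L
  days <- day[brk[-length(brk)]]
  wear_minutes <- minutes_sed <- minutes_mvpa <- integer(k)
  total_counts <- numeric(k)
  for (i in seq_len(k)) {
    ix <- brk[i]:(brk[i + 1L] - 1L)
    wear_minutes[i] <- sum(wear[ix])
    total_counts[i] <- sum(counts[ix][wear[ix]])
    minutes_sed[i] <- sum(sed[ix])
    minutes_mvpa[i] <- sum(mvpa[ix])
  }
  cpm <- ifelse(wear_minutes > 0L, total_counts / wear_minutes, NA_real_)
  tibble::new_tibble(list(
    participant_id = rep(series$participant_id, k),
    timepoint_id = rep(series$timepoint_id, k),
    date = as.Date(days, origin = "1970-01-01"),
    wear_minutes = wear_minutes,
    total_counts = total_counts,
    cpm = cpm,
    minutes_sedentary = minutes_sed,
    minutes_light = wear_minutes - minutes_sed - minutes_mvpa,
    minutes_mvpa = minutes_mvpa,
    is_valid = wear_minutes >= min_wear_minutes,
    meets_60_mvpa = minutes_mvpa >= guideline_mvpa_minutes), nrow = k)
}

#' Summarise a single calendar day
#'
#' Convenience wrapper around [summarize_days()] for one date.
#'
#' @inheritParams summarize_days
#' @param date A `Date` (or string) that the series spans.
#' @return One-row day summary tibble.
#' @export
summarize_day <- function(series, date, nonwear = detect_nonwear(series),
                          cutpoints = pa_cutpoints(),
                          min_wear_minutes = 500L,
                          guideline_mvpa_minutes = 60L) {
  date <- as.Date(date)
  all_days <- summarize_days(series, nonwear, cutpoints, min_wear_minutes,
                             guideline_mvpa_minutes)
  row <- all_days[all_days$date == date, ]
  if (nrow(row) == 0L) {
    stop("date ", format(date), " is outside the series span (",
         format(min(all_days$date)), " to ", format(max(all_days$date)), ")",
         call. = FALSE)
  }
  row
}

#' Aggregate day summaries into a participant-timepoint summary
#'
#' Participant-timepoint metrics are unweighted means of daily values over
#' valid days only ("means of daily means", not pooled counts over pooled
#' minutes): mean cpm, mean percentage of wear time per intensity, and mean
#' MVPA minutes. Guideline adherence is reported two ways: the strict flag
#' (at least 60 min of MVPA on *every* valid day) and the liberal percentage
#' of valid days reaching 60 min. A timepoint with fewer than
#' `min_valid_days` valid days is flagged excluded (`included = FALSE`);
#' an empty day table likewise yields an exclusion row.
#'
#' @param days Day summary tibble from [summarize_days()], all from one
#'   participant-timepoint.
#' @param min_valid_days Minimum valid days for inclusion, default 3.
#' @return One-row [tibble::tibble]: ids, `n_days`, `n_valid_days`,
#'   `included`, `mean_cpm`, `pct_sedentary`, `pct_light`, `pct_mvpa`,
#'   `mean_mvpa_minutes`, `strict_guideline`, `pct_days_meeting_guideline`.
#'   Activity metrics are `NA` when no day is valid.
#' @export
summarize_timepoint <- function(days, min_valid_days = 3L) {
  pid <- if (nrow(days)) days$participant_id[1L] else NA_character_
  tid <- if (nrow(days)) days$timepoint_id[1L] else NA_character_
  if (nrow(days)) {
    if (length(unique(days$participant_id)) > 1L ||
        length(unique(days$timepoint_id)) > 1L) {
      stop("`days` must all come from a single participant-timepoint",
           call. = FALSE)
    }
  }
  v <- days[which(days$is_valid), , drop = FALSE]
  nv <- nrow(v)
  has <- nv > 0L
  tibble::new_tibble(list(
    participant_id = pid,
    timepoint_id = tid,
    n_days = nrow(days),
    n_valid_days = nv,
    included = nv >= min_valid_days,
    mean_cpm = if (has) mean(v$cpm) else NA_real_,
    pct_sedentary = if (has) mean(100 * v$minutes_sedentary / v$wear_minutes)
                    else NA_real_,
    pct_light = if (has) mean(100 * v$minutes_light / v$wear_minutes)
                else NA_real_,
    pct_mvpa = if (has) mean(100 * v$minutes_mvpa / v$wear_minutes)
               else NA_real_,
    mean_mvpa_minutes = if (has) mean(v$minutes_mvpa) else NA_real_,
    strict_guideline = if (has) all(v$meets_60_mvpa) else NA,
    pct_days_meeting_guideline = if (has) 100 * mean(v$meets_60_mvpa)
                                 else NA_real_), nrow = 1L)
}

#' Reduce a cohort of epoch series to day and timepoint summaries
#'
#' Runs non-wear detection, day summarisation and timepoint aggregation over
#' every participant-timepoint series, and tallies the exclusion flow:
#' invalid days and timepoints with fewer than `min_valid_days` valid days.
#'
#' @param cohort A [simulate_cohort()] result, a plain list of
#'   [epoch_series()], or a directory of epoch CSVs written by
#'   [simulate_cohort()]/[write_epoch_file()].
#' @param min_valid_days Timepoint inclusion threshold, default 3.
#' @param cutpoints A [pa_cutpoints()] object.
#' @param nonwear_min_window,nonwear_max_interruption,nonwear_max_count
#'   Non-wear rule parameters, see [detect_nonwear()].
#' @return A list of class `reduction_result`: `days` (per-day tibble),
#'   `timepoints` (per-timepoint tibble incl. excluded rows) and `counts`
#'   (exclusion-flow tallies: timepoints in/included/excluded, days
#'   measured/valid/invalid, days with zero wear, percentage invalid).
#' @export
reduce_cohort <- function(cohort, min_valid_days = 3L,
                          cutpoints = pa_cutpoints(),
                          nonwear_min_window = 60L,
                          nonwear_max_interruption = 2L,
                          nonwear_max_count = Inf) {
  series_list <- if (inherits(cohort, "sim_cohort")) {
    cohort$series
  } else if (is.character(cohort) && length(cohort) == 1L) {
    read_epoch_dir(cohort)
  } else if (is.list(cohort) && all(vapply(cohort, inherits, logical(1),
                                           "epoch_series"))) {
    cohort
  } else {
    stop("`cohort` must be a sim_cohort, a list of epoch_series, or a ",
         "directory path", call. = FALSE)
  }

  day_rows <- vector("list", length(series_list))
  tp_rows <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    nw <- detect_nonwear(s, nonwear_min_window, nonwear_max_interruption,
                         nonwear_max_count)
    d <- summarize_days(s, nw, cutpoints)
    day_rows[[i]] <- d
    tp_rows[[i]] <- summarize_timepoint(d, min_valid_days)
  }
  days <- tibble::as_tibble(data.table::rbindlist(day_rows))
  tps <- tibble::as_tibble(data.table::rbindlist(tp_rows))

  counts <- list(
    timepoints_in = nrow(tps),
    timepoints_included = sum(tps$included),
    timepoints_excluded = sum(!tps$included),
    participants_in = length(unique(tps$participant_id)),
    participants_included = length(unique(
      tps$participant_id[tps$included])),
    days_measured = nrow(days),
    days_valid = sum(days$is_valid),
    days_invalid = sum(!days$is_valid),
    days_zero_wear = sum(days$wear_minutes == 0L),
    pct_days_invalid = 100 * mean(!days$is_valid))
  structure(list(days = days, timepoints = tps, counts = counts),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(
    paste0("<reduction_result> %d timepoints (%d participants): %d included",
           ", %d excluded (< min valid days)\n",
           "  days: %d measured, %d valid, %d invalid (%.1f%%; %d zero-wear)\n"),
    ct$timepoints_in, ct$participants_in, ct$timepoints_included,
    ct$timepoints_excluded, ct$days_measured, ct$days_valid, ct$days_invalid,
    ct$pct_days_invalid, ct$days_zero_wear))
  invisible(x)
}

read_epoch_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "demographics.csv"]
  if (!length(files)) stop("no epoch CSVs found in ", dir, call. = FALSE)
  lapply(files, function(f) {
    base <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(base, "__", fixed = TRUE)[[1L]]
    read_epoch_file(f, "csv",
                    participant_id = parts[1L],
                    timepoint_id = if (length(parts) > 1L) parts[2L] else "t1")
  })
}
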