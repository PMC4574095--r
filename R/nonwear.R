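#' Detect device non-wear in a minute-epoch count series
#'
#' Non-wear is a maximal run of at least `min_window_minutes` zero-count
#' minutes within which interruptions -- runs of non-zero minutes of length at
#' most `max_interruption_minutes` -- are tolerated. Tolerated interruption
#' minutes count toward the interval length and are themselves flagged
#' non-wear. A non-zero run longer than the tolerance terminates the
#' interval, and an interval can neither begin nor end on a tolerated
#' non-zero minute. The number of tolerated interruption runs inside one
#' interval is not limited, only each run's length.
#'
#' By default an interruption has no magnitude ceiling: any non-zero run of
#' at most 2 minutes is tolerated, whatever its counts. The stricter variant
#' in which interruption minutes must also stay below a count ceiling
#' (the Troiano-style `< 100` rule) is available through
#' `interruption_max_count`.
#'
#' Detection should run over the whole recording rather than per-day slices,
#' so a bout spanning midnight is not split into sub-threshold fragments; the
#' day summariser then intersects the intervals with each day's waking
#' window.
#'
#' @param x An [epoch_series()] at 60 s epochs, or a bare vector of
#'   non-negative minute counts.
#' @param min_window_minutes Minimum qualifying interval length. Default 60.
#' @param max_interruption_minutes Maximum tolerated non-zero run length
#'   inside an interval. Default 2.
#' @param interruption_max_count Optional count ceiling for tolerated
#'   interruption minutes; `Inf` (default) disables the ceiling.
#' @return A [tibble::tibble] with one row per interval: `start_index`
#'   (1-based minute index), `length_minutes`, `end_index`. Intervals are
#'   disjoint, maximal and in increasing order.
#' @examples
#' detect_nonwear(c(rep(0, 59), 50, rep(0, 59))) # one 119-min interval
#' @export
detect_nonwear <- function(x, min_window_minutes = 60L,
                           max_interruption_minutes = 2L,
                           interruption_max_count = Inf) {
  if (inherits(x, "epoch_series")) {
    if (x$epoch_seconds != 60L) {
      stop("non-wear detection requires 60 s epochs; reintegrate() first",
           call. = FALSE)
    }
    counts <- x$counts
  } else {
    counts <- validate_counts(x)
  }
  n <- length(counts)
  if (n == 0L) {
    return(tibble::new_tibble(list(start_index = integer(0),
                                   length_minutes = integer(0),
                                   end_index = integer(0)), nrow = 0L))
  }

  r <- rle(counts == 0L)
  nr <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tol <- !r$values & r$lengths <= max_interruption_minutes
  if (is.finite(interruption_max_count)) {
    for (i in which(tol)) {
      if (max(counts[starts[i]:ends[i]]) >= interruption_max_count) {
        tol[i] <- FALSE
      }
    }
  }

  out_start <- integer(0)
  out_end <- integer(0)
  i <- 1L
  while (i <= nr) {
    if (!r$values[i]) { i <- i + 1L; next }
    j <- i
    while (j + 2L <= nr && tol[j + 1L] && r$values[j + 2L]) j <- j + 2L
    len <- ends[j] - starts[i] + 1L
    if (len >= min_window_minutes) {
      out_start <- c(out_start, starts[i])
      out_end <- c(out_end, ends[j])
    }
    i <- j + 1L
  }
  tibble::new_tibble(list(start_index = out_start,
                          length_minutes = out_end - out_start + 1L,
                          end_index = out_end), nrow = length(out_start))
}

#' Expand non-wear intervals to a per-minute logical mask
#'
#' @param nonwear Interval table from [detect_nonwear()].
#' @param n Series length in minutes.
#' @return Logical vector of length `n`, `TRUE` on non-wear minutes.
#' @export
nonwear_mask <- function(nonwear, n) {
  m <- logical(n)
  if (nrow(nonwear)) {
    for (i in seq_len(nrow(nonwear))) {
      m[nonwear$start_index[i]:nonwear$end_index[i]] <- TRUE
    }
  }
  m
}
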