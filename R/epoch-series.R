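#' Construct an epoch count series
#'
#' An `epoch_series` holds one participant-timepoint's accelerometer count
#' stream at a fixed epoch length. The series is gap-free by construction:
#' epoch `k` (1-based) covers the interval starting at
#' `start + (k - 1) * epoch_seconds`.
#'
#' @param participant_id,timepoint_id Opaque identifier strings.
#' @param start Start of the first epoch, a `POSIXct` (interpreted as local
#'   clock time; stored in UTC to keep arithmetic timezone-free) or a string
#'   parseable by [as.POSIXct()].
#' @param epoch_seconds Positive integer epoch length. Must divide 60 so the
#'   series can be reintegrated to minute epochs.
#' @param counts Vector of non-negative integer vertical-axis counts, one per
#'   epoch.
#'
#' @return An object of class `epoch_series`.
#' @seealso [read_epoch_file()], [reintegrate()], [detect_nonwear()]
#' @export
epoch_series <- function(participant_id, timepoint_id, start, epoch_seconds,
                         counts) {
  if (is.character(start)) start <- parse_timestamp(start)
  if (!inherits(start, "POSIXct")) {
    stop("`start` must be a POSIXct timestamp or an ISO-8601 string",
         call. = FALSE)
  }
  attr(start, "tzone") <- "UTC"
  epoch_seconds <- as.integer(epoch_seconds)
  if (length(epoch_seconds) != 1L || is.na(epoch_seconds) ||
      epoch_seconds < 1L) {
    stop("`epoch_seconds` must be a single positive integer", call. = FALSE)
  }
  if (60L %% epoch_seconds != 0L && epoch_seconds != 60L) {
    stop("`epoch_seconds` must divide 60 (or equal 60)", call. = FALSE)
  }
  counts <- validate_counts(counts)
  structure(
    list(participant_id = as.character(participant_id),
         timepoint_id = as.character(timepoint_id),
         start = start,
         epoch_seconds = epoch_seconds,
         counts = counts),
    class = "epoch_series")
}

validate_counts <- function(counts) {
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    stop("counts must be non-negative (first negative at row ",
         which(counts < 0)[1L], ")", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integer-valued (first fractional at row ",
         which(counts != round(counts))[1L], ")", call. = FALSE)
  }
  as.integer(counts)
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %s / %s: %d epochs of %d s starting %s (total %s counts)\n",
    x$participant_id, x$timepoint_id, length(x$counts), x$epoch_seconds,
    format(x$start, "%Y-%m-%d %H:%M:%S"),
    format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Epoch timestamps of a series
#'
#' @param series An [epoch_series()].
#' @return `POSIXct` vector, one timestamp per epoch (epoch start times).
#' @export
epoch_timestamps <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  series$start + (seq_along(series$counts) - 1L) * series$epoch_seconds
}

#' Read an epoch count file
#'
#' Two dialects are supported. `"csv"` is a headed CSV with columns
#' `timestamp` (ISO-8601 local clock time) and `counts`, one row per epoch;
#' the epoch length is inferred from the timestamp spacing. `"raw"` is a
#' headerless single-column count export whose start time and epoch length
#' come either from a JSON sidecar file `<path>.meta.json` (keys `start`,
#' `epoch_seconds`, optionally `participant_id`, `timepoint_id`) or from the
#' `start` / `epoch_seconds` arguments.
#'
#' Timestamps in the `"csv"` dialect must be evenly spaced; a jump raises a
#' gap error naming the first offending row rather than silently zero-filling,
#' because a filled gap would be indistinguishable from device non-wear.
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"raw"`.
#' @param participant_id,timepoint_id Identifiers; default to the file name.
#' @param start,epoch_seconds Metadata for the `"raw"` dialect when no sidecar
#'   is present.
#' @return An [epoch_series()].
#' @export
read_epoch_file <- function(path, dialect = c("csv", "raw"),
                            participant_id = NULL, timepoint_id = NULL,
                            start = NULL, epoch_seconds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  base <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(participant_id)) participant_id <- base
  if (is.null(timepoint_id)) timepoint_id <- "t1"

  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("timestamp", "counts") %in% names(df))) {
      stop("epoch CSV must have columns 'timestamp' and 'counts'",
           call. = FALSE)
    }
    ts <- parse_timestamp(df$timestamp)
    if (anyNA(ts)) {
      stop("unparseable timestamp at row ", which(is.na(ts))[1L],
           call. = FALSE)
    }
    if (nrow(df) > 1L) {
      sp <- diff(as.numeric(ts)) # seconds
      bad <- which(abs(sp - sp[1L]) > 1e-6)
      if (length(bad)) {
        stop("gap in epoch series: spacing changes at row ", bad[1L] + 1L,
             " (expected ", sp[1L], " s, found ", sp[bad[1L]], " s)",
             call. = FALSE)
      }
      ep <- sp[1L]
      if (ep <= 0 || ep != round(ep)) {
        stop("invalid epoch spacing of ", ep, " s", call. = FALSE)
      }
    } else {
      ep <- if (is.null(epoch_seconds)) 60L else epoch_seconds
    }
    return(epoch_series(participant_id, timepoint_id, ts[1L], ep, df$counts))
  }

  # raw dialect: headerless counts + sidecar metadata
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    start <- meta$start %||% start
    epoch_seconds <- meta$epoch_seconds %||% epoch_seconds
    participant_id <- meta$participant_id %||% participant_id
    timepoint_id <- meta$timepoint_id %||% timepoint_id
  }
  if (is.null(start) || is.null(epoch_seconds)) {
    stop("raw dialect needs `start` and `epoch_seconds` (argument or ",
         "sidecar ", basename(sidecar), ")", call. = FALSE)
  }
  counts <- utils::read.csv(path, header = FALSE)[[1L]]
  epoch_series(participant_id, timepoint_id, start, epoch_seconds, counts)
}

#' Write a 60 s epoch series as CSV
#'
#' Emits the headed `timestamp,counts` dialect read by [read_epoch_file()].
#' Only minute-epoch series are written; reintegrate first.
#'
#' @param series An [epoch_series()] at 60 s epochs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_file <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_seconds != 60L) {
    stop("writer emits 60 s epochs only; call reintegrate() first",
         call. = FALSE)
  }
  df <- data.frame(
    timestamp = format(epoch_timestamps(series), "%Y-%m-%dT%H:%M:%S"),
    counts = series$counts)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Reintegrate an epoch series to a coarser epoch
#'
#' Sums blocks of consecutive fine epochs into `target_epoch_seconds` epochs
#' (the standard harmonisation step when pooling studies recorded at 5-30 s
#' epochs). Blocks are anchored at the series start, not at clock-minute
#' boundaries; if the start is not on a whole target epoch it is rounded down
#' to the containing one with a warning. A trailing partial block is dropped
#' (zero-padding would fabricate wear time) with a conservation warning when
#' the dropped epochs carry counts.
#'
#' @param series An [epoch_series()].
#' @param target_epoch_seconds Target epoch length; must be a multiple of the
#'   series epoch length. Default 60.
#' @return An [epoch_series()] at the target epoch length.
#' @examples
#' s <- epoch_series("p1", "t1", "2005-03-01 07:00:00", 15, c(10, 20, 30, 40))
#' reintegrate(s)$counts # 100
#' @export
reintegrate <- function(series, target_epoch_seconds = 60L) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch_seconds <- as.integer(target_epoch_seconds)
  ep <- series$epoch_seconds
  if (target_epoch_seconds == ep) return(series)
  if (target_epoch_seconds < ep || target_epoch_seconds %% ep != 0L) {
    stop("target epoch (", target_epoch_seconds, " s) must be an integer ",
         "multiple of the series epoch (", ep, " s)", call. = FALSE)
  }
  k <- target_epoch_seconds %/% ep
  n <- length(series$counts)
  n_blocks <- n %/% k
  start <- series$start
  off <- as.numeric(start) %% target_epoch_seconds
  if (off != 0) {
    start <- start - off
    warning("series start not aligned to a whole ", target_epoch_seconds,
            " s epoch; rounded down by ", off, " s", call. = FALSE)
  }
  dropped <- if (n_blocks * k < n) series$counts[(n_blocks * k + 1L):n]
             else integer(0)
  if (length(dropped)) {
    warning("dropped trailing partial block of ", length(dropped),
            " epoch(s) carrying ", sum(dropped), " counts", call. = FALSE)
  }
  sums <- if (n_blocks > 0L) {
    as.integer(colSums(matrix(series$counts[seq_len(n_blocks * k)], nrow = k)))
  } else integer(0)
  epoch_series(series$participant_id, series$timepoint_id, start,
               target_epoch_seconds, sums)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 timestamps with either a "T" or a space separator
parse_timestamp <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%d"))
}
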