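#' Construct a glucose series
#'
#' The container consumed by every analysis in the package: a uniformly (or
#' nominally uniformly) sampled glucose trace.  Timestamps are stored at
#' second resolution as seconds since the epoch; the analyses themselves use
#' only `values` and `dt`.
#'
#' @param values numeric vector of glucose concentrations (mmol/L), all
#'   finite and positive, length at least 2.
#' @param dt sampling interval in seconds (nominal 300 for a 5-minute CGM).
#' @param timestamps optional vector of times (`POSIXct` or numeric seconds
#'   since epoch), strictly increasing and the same length as `values`.  When
#'   omitted, a uniform grid starting at 0 with step `dt` is used.
#' @param label free-text period identifier (e.g. `"Period 1"`).
#' @return An object of class `glucose_series`: a list with elements
#'   `timestamps` (numeric seconds), `values`, `dt`, `label`.
#' @examples
#' gs <- glucose_series(c(5.0, 5.2, 5.1), dt = 300)
#' gs
#' @export
glucose_series <- function(values, dt = 300, timestamps = NULL, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("insufficient data: a glucose series needs at least 2 readings", call. = FALSE)
  if (!all(is.finite(values)) || any(values <= 0))
    stop("glucose values must all be finite and > 0 (mmol/L)", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number of seconds", call. = FALSE)
  if (is.null(timestamps)) {
    timestamps <- (seq_along(values) - 1) * dt
  } else {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != length(values))
      stop("timestamps and values must have the same length", call. = FALSE)
    if (any(diff(timestamps) <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(timestamps = round(timestamps), values = values,
                 dt = dt, label = as.character(label)),
            class = "glucose_series")
}

#' @export
print.glucose_series <- function(x, ...) {
  n <- length(x$values)
  cat("<glucose_series>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat(sprintf("  %d readings, dt = %g s (%.1f h span)\n",
              n, x$dt, (x$timestamps[n] - x$timestamps[1]) / 3600))
  cat(sprintf("  glucose range %.2f - %.2f mmol/L, mean %.2f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$values)

# Pull the numeric vector out of either a glucose_series or a plain vector.
series_values <- function(x) {
  if (inherits(x, "glucose_series")) x$values else as.numeric(x)
}

is_uniform <- function(series, tol = 1e-6) {
  d <- diff(series$timestamps)
  all(abs(d - series$dt) <= tol * series$dt)
}

#' Read a CGM recording from CSV
#'
#' Reads timestamped glucose readings, sorts them by time, collapses duplicate
#' timestamps by their mean, and returns a [glucose_series()].  Timestamps may
#' be ISO-8601 date-times or numeric epoch seconds.  The nominal sampling
#' interval is taken as the median gap; use [regularize()] to enforce a
#' uniform grid.
#'
#' @param path CSV file path.
#' @param time_col,value_col column names holding the timestamp and the
#'   glucose value (mmol/L).
#' @param label period label; defaults to the file name without extension.
#' @param tz time zone used to parse ISO-8601 timestamps.
#' @return A [glucose_series()].
#' @export
read_cgm_csv <- function(path, time_col = "timestamp",
                         value_col = "glucose_mmol_per_L",
                         label = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(time_col, value_col) %in% names(df)))
    stop(sprintf("format error: columns '%s' and '%s' required, found: %s",
                 time_col, value_col, paste(names(df), collapse = ", ")),
         call. = FALSE)
  traw <- df[[time_col]]
  tnum <- suppressWarnings(as.numeric(traw))
  if (all(is.finite(tnum))) {
    tt <- tnum
  } else {
    tt <- as.numeric(as.POSIXct(as.character(traw), tz = tz,
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS",
                                               "%Y-%m-%d %H:%M",
                                               "%Y/%m/%d %H:%M:%OS")))
    if (any(is.na(tt)))
      stop("format error: unparseable timestamps in column '", time_col, "'",
           call. = FALSE)
  }
  vals <- as.numeric(df[[value_col]])
  keep <- is.finite(tt) & is.finite(vals)
  tt <- tt[keep]; vals <- vals[keep]
  if (length(tt) < 2L)
    stop("insufficient data: fewer than 2 valid rows in ", path, call. = FALSE)
  o <- order(tt)
  tt <- tt[o]; vals <- vals[o]
  # collapse duplicate timestamps by mean
  if (anyDuplicated(tt)) {
    vals <- as.numeric(tapply(vals, tt, mean))
    tt <- sort(unique(tt))
  }
  dt <- median(diff(tt))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  glucose_series(vals, dt = dt, timestamps = tt, label = label)
}

#' Write a glucose series to CSV
#'
#' Serializes with header `timestamp,glucose_mmol_per_L`; timestamps are
#' written as epoch seconds so the file round-trips through [read_cgm_csv()].
#'
#' @param series a [glucose_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  df <- data.frame(timestamp = series$timestamps,
                   glucose_mmol_per_L = series$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regularize a glucose series onto a uniform grid
#'
#' Snaps readings onto a uniform `dt` grid and fills short gaps by linear
#' interpolation.  Gaps longer than `max_gap` consecutive missing points raise
#' an error: the fractal estimators downstream assume a contiguous record, and
#' interpolating across long holes would fabricate low-frequency structure.
#'
#' @param series a [glucose_series()].
#' @param dt target sampling interval (seconds); defaults to the series' own.
#' @param max_gap maximum run of missing grid points to fill by linear
#'   interpolation (default 2, i.e. 10 minutes at 5-minute sampling).
#' @return A [glucose_series()] whose consecutive timestamp gaps all equal `dt`.
#' @export
regularize <- function(series, dt = series$dt, max_gap = 2) {
  stopifnot(inherits(series, "glucose_series"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  tt <- series$timestamps
  if (is_uniform(series) && abs(dt - series$dt) < 1e-9) return(series)
  idx <- as.integer(round((tt - tt[1]) / dt)) + 1L
  n_grid <- idx[length(idx)]
  vals <- rep(NA_real_, n_grid)
  # duplicate grid cells (timestamp jitter) collapse by mean
  agg <- tapply(series$values, idx, mean)
  vals[as.integer(names(agg))] <- as.numeric(agg)
  if (anyNA(vals)) {
    r <- rle(is.na(vals))
    runs <- cumsum(c(1L, r$lengths))
    bad <- which(r$values & r$lengths > max_gap)
    if (length(bad)) {
      i0 <- runs[bad[1]]
      span <- r$lengths[bad[1]] * dt
      stop(sprintf(
        "contiguity error: gap of %d missing points (%.0f s, from t=%.0f s) exceeds max_gap=%d",
        r$lengths[bad[1]], span, tt[1] + (i0 - 1) * dt, max_gap), call. = FALSE)
    }
    filled <- approx(x = which(!is.na(vals)), y = vals[!is.na(vals)],
                     xout = seq_len(n_grid), method = "linear")$y
    vals <- filled
  }
  glucose_series(vals, dt = dt, timestamps = tt[1] + (seq_len(n_grid) - 1) * dt,
                 label = series$label)
}
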