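#' Uniformly sampled time series
#'
#' The universal signal carrier used throughout the package: local field
#' potentials, vertical ground-reaction forces, gyroscope angular velocities
#' and stimulation amplitude traces are all `ts_series` objects. Sampling is
#' uniform; no per-sample timestamps are stored.
#'
#' @param values Numeric vector of samples (all finite).
#' @param rate Sampling rate in Hz (> 0).
#' @param start Start time in seconds of the first sample.
#' @param units Free-text unit label (e.g. `"mV"`, `"%BW"`, `"deg/s"`).
#' @param label Free-text channel label.
#' @return An object of class `ts_series`.
#' @export
time_series <- function(values, rate, start = 0, units = "", label = "") {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  if (length(values) && any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  structure(
    list(values = values, rate = rate, start = start,
         units = units, label = label),
    class = "ts_series"
  )
}

#' @export
print.ts_series <- function(x, ...) {
  cat(sprintf("<ts_series> %s: %d samples @ %g Hz, t = [%g, %g] s %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$rate, x$start,
              x$start + max(length(x$values) - 1L, 0L) / x$rate,
              if (nzchar(x$units)) paste0("[", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a time series
#' @param x A `ts_series`.
#' @return Numeric vector of times in seconds, one per sample.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "ts_series"))
  if (!length(x$values)) return(numeric(0))
  x$start + (seq_along(x$values) - 1L) / x$rate
}

#' Duration of a time series in seconds
#' @param x A `ts_series`.
#' @export
ts_duration <- function(x) length(x$values) / x$rate

#' Multi-channel series sharing a clock
#'
#' Named set of [time_series()] channels with identical rate, start time and
#' length, plus free-form metadata (hemisphere, sensor placement, ...).
#'
#' @param channels Named list of `ts_series`.
#' @param meta Named list of metadata.
#' @return An object of class `mc_series`.
#' @export
multi_channel <- function(channels, meta = list()) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a non-empty named list", call. = FALSE)
  if (!all(vapply(channels, inherits, logical(1), "ts_series")))
    stop("all channels must be `ts_series` objects", call. = FALSE)
  rates <- vapply(channels, function(ch) ch$rate, numeric(1))
  lens <- vapply(channels, function(ch) length(ch$values), integer(1))
  starts <- vapply(channels, function(ch) ch$start, numeric(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L ||
      diff(range(starts)) > 1e-9)
    stop("channels must share rate, length and start time", call. = FALSE)
  structure(list(channels = channels, meta = meta), class = "mc_series")
}

#' @export
print.mc_series <- function(x, ...) {
  ch <- x$channels[[1L]]
  cat(sprintf("<mc_series> %d channel(s) [%s]: %d samples @ %g Hz\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              length(ch$values), ch$rate))
  invisible(x)
}

# maximum tolerated timestamp jitter when inferring the rate from a time column
TIME_JITTER_S <- 1e-6

#' Read a multi-channel time-series CSV
#'
#' Expects a comma-separated file with a header row. If a `time_s` column is
#' present the sampling rate is inferred from the median time increment and
#' timestamps are checked for uniformity; otherwise `rate` must be supplied.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz, required when the file has no `time_s`
#'   column.
#' @return An [multi_channel()] object.
#' @export
read_timeseries_csv <- function(path, rate = NULL) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !grepl("[A-Za-z]", header))
    stop("missing header row in ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  has_time <- "time_s" %in% names(df)
  if (!has_time && is.null(rate))
    stop("no `time_s` column and no `rate` supplied", call. = FALSE)
  if (has_time) {
    tms <- df[["time_s"]]
    if (nrow(df) >= 2L) {
      dt <- diff(tms)
      if (any(dt <= 0))
        stop("`time_s` must be strictly increasing", call. = FALSE)
      med <- stats::median(dt)
      if (any(abs(dt - med) > TIME_JITTER_S))
        stop("non-uniform timestamps (jitter > 1e-6 s)", call. = FALSE)
      rate <- 1 / med
      start <- tms[1L]
    } else {
      if (is.null(rate)) rate <- 1
      start <- if (nrow(df)) tms[1L] else 0
    }
    df[["time_s"]] <- NULL
  } else {
    start <- 0
  }
  if (!ncol(df)) stop("no data channels in ", path, call. = FALSE)
  channels <- lapply(names(df), function(nm)
    time_series(df[[nm]], rate = rate, start = start, label = nm))
  names(channels) <- names(df)
  multi_channel(channels)
}

#' Write a multi-channel time-series CSV
#'
#' Writes a `time_s` column followed by one column per channel; the dialect is
#' comma-separated, `.` decimal, UTF-8. [read_timeseries_csv()] round-trips
#' the samples to better than 1e-9 relative tolerance.
#'
#' @param series An [multi_channel()] or single [time_series()].
#' @param path Output file path.
#' @export
write_timeseries_csv <- function(series, path) {
  if (inherits(series, "ts_series")) {
    nm <- if (nzchar(series$label)) series$label else "value"
    series <- multi_channel(stats::setNames(list(series), nm))
  }
  stopifnot(inherits(series, "mc_series"))
  tms <- ts_time(series$channels[[1L]])
  df <- data.frame(time_s = tms, check.names = FALSE)
  for (nm in names(series$channels)) df[[nm]] <- series$channels[[nm]]$values
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
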