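#' Uniformly sampled time series
#'
#' The basic container passed between all processing stages: a numeric
#' vector of samples together with its sampling rate in Hz and a free-text
#' label.
#'
#' @param values numeric vector of samples (finite, length >= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param label free-text description carried through processing.
#' @return an object of class `ppg_ts` with fields `values`, `fs`, `label`.
#' @examples
#' x <- ppg_ts(sin(2 * pi * 0.25 * seq(0, 60, by = 0.04)), fs = 25)
#' duration(x)
#' @export
ppg_ts <- function(values, fs, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time series must hold at least one sample")
  if (!all(is.finite(values))) stop("time series values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate 'fs' must be a single positive number")
  structure(list(values = values, fs = as.numeric(fs),
                 label = as.character(label)),
            class = "ppg_ts")
}

#' @export
print.ppg_ts <- function(x, ...) {
  cat(sprintf("<ppg_ts> %s: %d samples @ %g Hz (%.2f s)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$values), x$fs, duration(x)))
  invisible(x)
}

#' @export
length.ppg_ts <- function(x) length(x$values)

#' Duration of a time series in seconds
#' @param x a `ppg_ts`.
#' @return duration in seconds (`length / fs`).
#' @export
duration <- function(x) length(x$values) / x$fs

#' Sample times of a uniformly sampled series
#' @param x a `ppg_ts`.
#' @param t0 time of the first sample in seconds.
#' @return numeric vector of times in seconds.
#' @export
ts_time <- function(x, t0 = 0) t0 + (seq_along(x$values) - 1) / x$fs

#' Unevenly sampled event series
#'
#' Holds (time, value) pairs at strictly increasing times, such as beat
#' maxima or inter-beat intervals, before resampling onto a uniform grid.
#'
#' @param times strictly increasing numeric vector of times in seconds.
#' @param values numeric vector, same length as `times`.
#' @return an object of class `event_series`.
#' @export
event_series <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = times, values = values), class = "event_series")
}

#' @export
length.event_series <- function(x) length(x$times)

#' Segment a signal into overlapping windows
#'
#' Splits a series of length `T` into `S = floor((T - M) / K) + 1` windows
#' of `M` samples, adjacent windows shifted by `K` samples (overlap
#' `M - K`).  Window `j` (0-based) starts at sample offset `j * K`.
#'
#' @param ts a `ppg_ts`.
#' @param M window length in samples.
#' @param K shift between adjacent windows in samples.
#' @return a list of `ppg_ts` windows; each carries attributes `index`
#'   (0-based window index) and `start` (0-based sample offset).
#' @examples
#' w <- segment_signal(ppg_ts(rnorm(250), 25), M = 100, K = 50)
#' length(w)  # 4 windows
#' @export
segment_signal <- function(ts, M, K) {
  stopifnot(inherits(ts, "ppg_ts"))
  Tn <- length(ts$values)
  M <- as.integer(M); K <- as.integer(K)
  if (K <= 0L) stop("invalid shift: K must be >= 1")
  if (M > Tn) stop("window longer than signal")
  S <- (Tn - M) %/% K + 1L
  lapply(seq_len(S) - 1L, function(j) {
    w <- ppg_ts(ts$values[(j * K + 1L):(j * K + M)], ts$fs, ts$label)
    attr(w, "index") <- j
    attr(w, "start") <- j * K
    w
  })
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-backward (zero phase), so peak and trough timing is preserved
#' for downstream morphological analysis.
#'
#' @param ts a `ppg_ts`.
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param order filter design order (a band-pass of design order `n` has
#'   `2n` poles, the usual design convention).
#' @return filtered `ppg_ts`, same length and fs.
#' @export
bandpass <- function(ts, low, high, order = 4L) {
  stopifnot(inherits(ts, "ppg_ts"))
  nyq <- ts$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  ppg_ts(signal::filtfilt(bf, ts$values), ts$fs, ts$label)
}

#' Rescale a series onto the [-1, 1] amplitude range
#'
#' Affine map sending the minimum to -1 and the maximum to +1.
#'
#' @param ts a `ppg_ts`.
#' @return normalized `ppg_ts`.
#' @export
normalize_range <- function(ts) {
  stopifnot(inherits(ts, "ppg_ts"))
  rng <- range(ts$values)
  if (diff(rng) <= 0) stop("degenerate range: constant signal")
  ppg_ts(2 * (ts$values - rng[1]) / diff(rng) - 1, ts$fs, ts$label)
}

#' Artifact reduction: spline-derivative resampling
#'
#' Fits a cubic spline through the points of an event series (or a
#' uniform series) and evaluates the spline's first derivative on a
#' uniform grid, implementing the operator
#' \eqn{\Pi(x) = \mathrm{Deriv}(\mathrm{Spline}(x))}.  Taking the
#' derivative suppresses slow drift while resampling puts beat-by-beat
#' features on a regular grid suitable for spectral analysis.
#'
#' @param series an `event_series` or a `ppg_ts`.
#' @param out_fs output sampling rate in Hz for the uniform grid.
#' @param t0 time of the first input sample when `series` is a `ppg_ts`.
#' @param deriv derivative order evaluated on the grid: 1 (default)
#'   gives the operator as defined; 0 gives plain spline resampling for
#'   series that are already trend-free.
#' @return a `ppg_ts` at `out_fs` spanning the input's time range.
#' @export
artifact_reduce <- function(series, out_fs = 8, t0 = 0, deriv = 1L) {
  if (inherits(series, "ppg_ts")) {
    series <- event_series(ts_time(series, t0), series$values)
  }
  stopifnot(inherits(series, "event_series"))
  if (length(series$times) < 4L)
    stop("insufficient points for spline (need >= 4)")
  sf <- stats::splinefun(series$times, series$values, method = "fmm")
  grid <- seq(series$times[1], series$times[length(series$times)],
              by = 1 / out_fs)
  ppg_ts(sf(grid, deriv = deriv), out_fs, "artifact-reduced")
}

#' Read a time series from disk
#'
#' Two supported formats: `"csv"`, a two-column delimited text file
#' `(time_s, value)` with an optional single header line, where the
#' sampling rate is inferred from the time column (which must be uniform
#' to within 1% jitter); and `"rds"`, a serialized `ppg_ts`.
#'
#' @param path file path.
#' @param format `"csv"` or `"rds"` (default: guessed from the extension).
#' @return a `ppg_ts`.
#' @export
read_series <- function(path, format = c("auto", "csv", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  if (format == "rds") {
    obj <- readRDS(path)
    if (!inherits(obj, "ppg_ts")) stop("rds file does not hold a ppg_ts")
    return(obj)
  }
  first <- readLines(path, n = 1L)
  skip <- if (grepl("[A-Za-z]", first)) 1L else 0L
  tab <- utils::read.csv(path, header = FALSE, skip = skip)
  if (ncol(tab) < 2L) stop("expected two columns: time_s, value")
  tm <- as.numeric(tab[[1]]); val <- as.numeric(tab[[2]])
  if (any(diff(tm) <= 0)) stop("non-monotone time column")
  dt <- diff(tm)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step)
    stop("time column is not uniform (> 1% jitter); resample before loading")
  ppg_ts(val, fs = 1 / step, label = basename(path))
}

#' Write a time series to disk
#'
#' @param ts a `ppg_ts`.
#' @param path file path.
#' @param format `"csv"` (two columns `time_s,value` with header) or
#'   `"rds"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(ts, path, format = c("auto", "csv", "rds")) {
  stopifnot(inherits(ts, "ppg_ts"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  if (format == "rds") {
    saveRDS(ts, path)
  } else {
    utils::write.csv(data.frame(time_s = ts_time(ts), value = ts$values),
                     path, row.names = FALSE)
  }
  invisible(path)
}
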