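#' Quality screening of a respiratory reference signal
#'
#' Reproduces the reliability screen applied to thoracic-impedance
#' respiratory references before they are trusted as ground truth: the
#' signal is band-pass filtered (second-order Butterworth, 0.1-0.5 Hz),
#' normalized onto `[-1, 1]`, and its peaks and troughs detected.  Two
#' dispersion statistics are computed — `sigma1`, the standard deviation
#' of successive peak-to-peak time intervals in seconds, and `sigma2`,
#' the standard deviation of trough heights in normalized units.  A
#' signal is accepted only if it lasts at least 30 s, `sigma1 <= 1` and
#' `sigma2 <= 0.2`; otherwise it is rejected as corrupted.
#'
#' Peaks and troughs are local extrema separated by at least 1 s (half
#' the period of the band's 0.5 Hz upper edge), preventing
#' double-counting within one breath.
#'
#' @param ts a `ppg_ts` respiratory signal.
#' @param band filtering band in Hz.
#' @param order Butterworth design order.
#' @param min_duration minimum accepted duration in seconds.
#' @param sigma1_max,sigma2_max rejection thresholds.
#' @param edge_trim_s seconds discarded from each end of the filtered
#'   signal before normalization and extrema detection, suppressing
#'   filter start-up transients that would otherwise inflate the trough
#'   statistics (skipped when the signal is too short to spare them).
#' @return an object of class `qc_report`: list with `sigma1`, `sigma2`,
#'   `duration`, `accepted`, `reason`.
#' @export
qc_respiratory <- function(ts, band = freq_band(0.1, 0.5), order = 2L,
                           min_duration = 30, sigma1_max = 1,
                           sigma2_max = 0.2, edge_trim_s = 5) {
  stopifnot(inherits(ts, "ppg_ts"))
  dur <- duration(ts)
  report <- function(s1, s2, accepted, reason) {
    structure(list(sigma1 = s1, sigma2 = s2, duration = dur,
                   accepted = accepted, reason = reason),
              class = "qc_report")
  }
  if (dur < min_duration)
    return(report(NA_real_, NA_real_, FALSE, "duration"))
  filt <- tryCatch(bandpass(ts, band$lo, band$hi, order = order),
                   error = function(e) NULL)
  if (is.null(filt) || diff(range(filt$values)) <= 0)
    return(report(NA_real_, NA_real_, FALSE, "no breathing cycles"))
  trim <- round(edge_trim_s * ts$fs)
  if (length(filt$values) > 2 * trim + 10 * ts$fs && trim > 0) {
    filt <- ppg_ts(filt$values[(trim + 1):(length(filt$values) - trim)],
                   ts$fs)
  }
  norm <- normalize_range(filt)
  min_dist <- max(1L, round(ts$fs * 1))   # >= 1 s apart
  # breaths must rise above (troughs fall below) the signal midline;
  # small band-pass ringing in breathing pauses is not counted
  pk <- pracma::findpeaks(norm$values, minpeakdistance = min_dist,
                          minpeakheight = 0)
  tr <- pracma::findpeaks(-norm$values, minpeakdistance = min_dist,
                          minpeakheight = 0)
  if (is.null(pk) || nrow(pk) < 2L)
    return(report(NA_real_, NA_real_, FALSE, "no breathing cycles"))
  peak_t <- sort(pk[, 2]) / ts$fs
  s1 <- if (length(peak_t) >= 3L) stats::sd(diff(peak_t)) else 0
  s2 <- if (!is.null(tr) && nrow(tr) >= 2L) stats::sd(-tr[, 1]) else 0
  ok <- s1 <= sigma1_max && s2 <= sigma2_max
  report(s1, s2, ok,
         if (ok) "accepted"
         else if (s1 > sigma1_max) "sigma1" else "sigma2")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %s (%s) | duration %.1f s, sigma1 %s s, sigma2 %s\n",
    if (x$accepted) "ACCEPTED" else "REJECTED", x$reason, x$duration,
    format(signif(x$sigma1, 3)), format(signif(x$sigma2, 3))))
  invisible(x)
}
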