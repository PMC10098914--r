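#' Frequency band
#'
#' @param lo,hi band edges in Hz, `0 <= lo < hi`.
#' @return an object of class `freq_band`.
#' @export
freq_band <- function(lo, hi) {
  if (!(lo >= 0 && lo < hi)) stop("invalid band: need 0 <= lo < hi")
  structure(list(lo = lo, hi = hi), class = "freq_band")
}

#' Periodogram power spectral density
#'
#' Periodogram of the mean-removed series with a rectangular window,
#' zero-padded to four times the series length so that the frequency
#' grid is fine enough to avoid quantizing the picked respiratory rate.
#'
#' @param ts a `ppg_ts` (length >= 32).
#' @param pad zero-padding factor (default 4).
#' @return an object of class `psd_est`: list with `freqs` (Hz,
#'   ascending from 0) and `power` (non-negative).
#' @export
periodogram <- function(ts, pad = 4L) {
  stopifnot(inherits(ts, "ppg_ts"))
  x <- ts$values - mean(ts$values)
  n <- length(x)
  if (n < 32L) stop("series too short for a periodogram (need >= 32)")
  nfft <- pad * n
  X <- stats::fft(c(x, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  structure(list(freqs = (half - 1L) * ts$fs / nfft,
                 power = Mod(X[half])^2 / (n * ts$fs)),
            class = "psd_est")
}

#' Heart-rate estimate from the cardiac spectral band
#'
#' Peak of the periodogram restricted to the cardiac band
#' `[0.7, 3.0]` Hz (42-180 beats/min).  If the in-band peak is
#' negligible against the spectrum's global maximum the signal is judged
#' to carry no cardiac content and `NA` is returned, which makes
#' downstream band selection fall back to a fixed respiratory band.
#'
#' @param ts a `ppg_ts` containing cardiac content.
#' @param cardiac_band search band in Hz.
#' @param min_rel_power minimum in-band peak power as a fraction of the
#'   global spectral maximum for the estimate to count as defined.
#' @return heart rate in Hz, or `NA_real_` when undefined.
#' @export
estimate_hr <- function(ts, cardiac_band = freq_band(0.7, 3.0),
                        min_rel_power = 0.05) {
  psd <- periodogram(ts)
  sel <- psd$freqs >= cardiac_band$lo & psd$freqs <= cardiac_band$hi
  if (!any(sel)) return(NA_real_)
  pk <- which.max(psd$power[sel])
  if (max(psd$power) <= 0 ||
      psd$power[sel][pk] < min_rel_power * max(psd$power))
    return(NA_real_)
  psd$freqs[sel][pk]
}

#' Heart-rate adaptive respiratory search band
#'
#' Builds the band in which the respiratory peak is picked:
#' `[0.1, min(0.6, hr / 2)]` Hz when the heart rate is known — keeping
#' respiration below the first cardiac harmonic and capping plausible
#' resting rates at 36 breaths/min — and the fixed screening band
#' `[0.1, 0.5]` Hz when it is not.
#'
#' @param hr heart rate in Hz, or `NA` when undefined.
#' @param lo lower edge in Hz.
#' @param hi_cap upper cap in Hz.
#' @param fallback_hi upper edge used when `hr` is undefined.
#' @return a `freq_band`.
#' @export
adaptive_band <- function(hr, lo = 0.1, hi_cap = 0.6, fallback_hi = 0.5) {
  if (is.na(hr)) return(freq_band(lo, fallback_hi))
  freq_band(lo, min(hi_cap, hr / 2))
}

#' Pick the respiratory rate from a power spectrum
#'
#' The most prominent (highest-power) spectral peak inside the band,
#' converted to breaths/min.
#'
#' @param psd a `psd_est`.
#' @param band a `freq_band`.
#' @return list with `rr_bpm` (60 x peak frequency), `freq_hz` and
#'   `peak_power`; all `NA` when the band holds no grid point.
#' @export
pick_rr <- function(psd, band) {
  stopifnot(inherits(psd, "psd_est"), inherits(band, "freq_band"))
  sel <- psd$freqs >= band$lo & psd$freqs <= band$hi
  if (!any(sel) || max(psd$power[sel]) <= 0)
    return(list(rr_bpm = NA_real_, freq_hz = NA_real_,
                peak_power = NA_real_))
  pk <- which.max(psd$power[sel])
  f <- psd$freqs[sel][pk]
  list(rr_bpm = 60 * f, freq_hz = f, peak_power = psd$power[sel][pk])
}

#' Aggregate per-window RR estimates into a per-video value
#'
#' The median of the defined window estimates — robust against the
#' occasional window where an estimator locks onto an artifact.
#'
#' @param rr_values numeric vector of per-window RR values in
#'   breaths/min (NAs tolerated).
#' @return the median in breaths/min, or `NA_real_` when no window
#'   produced a defined estimate.
#' @export
aggregate_video <- function(rr_values) {
  v <- rr_values[!is.na(rr_values)]
  if (length(v) == 0L) return(NA_real_)
  stats::median(v)
}
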