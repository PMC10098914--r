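#' Configuration for the synthetic PPG simulator
#'
#' Describes a simulated recording: a quasi-periodic cardiac pulse train
#' carrying up to three respiratory modulations — baseline intensity
#' (RIIV), pulse amplitude (RIAV) and beat frequency via respiratory
#' sinus arrhythmia (RIFV) — locked to a known breathing frequency, plus
#' a matched respiratory reference waveform.
#'
#' The defaults mirror a camera-based acquisition: PPG at 25 Hz (video
#' frame rate), respiratory reference at 1000 Hz (physiological DAQ),
#' heart rate 72 beats/min, breathing 15 breaths/min.
#'
#' @param duration recording length in seconds (>= 30 for QC-passing
#'   references).
#' @param fs_ppg PPG sampling rate in Hz.
#' @param fs_resp respiratory reference sampling rate in Hz.
#' @param f_resp breathing frequency in Hz (true RR / 60); must be below
#'   `f_heart / 2`.
#' @param f_heart base heart frequency in Hz.
#' @param a_riiv,a_riav,a_rifv fractional modulation depths in `[0, 1)`
#'   for the baseline, amplitude and frequency mechanisms.
#' @param snr_db additive white-noise level in dB relative to the pulse
#'   train's RMS (`Inf` = noise-free).
#' @param phi_a,phi_i phase offsets (radians) of the amplitude and
#'   baseline modulations relative to respiration.
#' @param seed integer RNG seed; the simulator is fully deterministic
#'   given the configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration = 60, fs_ppg = 25, fs_resp = 1000,
                         f_resp = 0.25, f_heart = 1.2, a_riiv = 0,
                         a_riav = 0, a_rifv = 0, snr_db = Inf,
                         phi_a = 0, phi_i = 0, seed = 1L) {
  if (!(f_resp > 0 && f_resp < f_heart / 2))
    stop("need 0 < f_resp < f_heart / 2")
  depths <- c(a_riiv, a_riav, a_rifv)
  if (any(depths < 0 | depths >= 1)) stop("modulation depths must be in [0, 1)")
  if (duration <= 0) stop("duration must be positive")
  structure(list(duration = duration, fs_ppg = fs_ppg,
                 fs_resp = fs_resp, f_resp = f_resp, f_heart = f_heart,
                 a_riiv = a_riiv, a_riav = a_riav, a_rifv = a_rifv,
                 snr_db = snr_db, phi_a = phi_a, phi_i = phi_i,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Asymmetric two-lobe beat template: sharp systolic Gaussian plus a
# broader, smaller diastolic lobe 0.25 s later.
beat_template <- function(tau, sys_width = 0.08, dia_width = 0.25,
                          dia_height = 0.4, dia_offset = 0.25) {
  exp(-tau^2 / (2 * sys_width^2)) +
    dia_height * exp(-(tau - dia_offset)^2 / (2 * dia_width^2))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic PPG recording with known respiratory modulation
#'
#' The instantaneous heart frequency is
#' `f_h(t) = f_heart (1 + a_rifv sin(2 pi f_resp t))`; integrating it
#' gives the beat phase, whose integer crossings are the beat times.
#' A two-lobe beat template is placed at every beat, the pulse train is
#' multiplied by the amplitude modulation
#' `1 + a_riav sin(2 pi f_resp t + phi_a)`, the baseline term
#' `a_riiv sin(2 pi f_resp t + phi_i)` is added, and white Gaussian
#' noise at the configured SNR (relative to the pulse train's RMS) is
#' superimposed.  The respiratory reference channel is
#' `sin(2 pi f_resp t)` sampled at `fs_resp`.
#'
#' @param cfg a `synth_config`.
#' @return an object of class `synth_record`: list with `ppg` and
#'   `respiration` (`ppg_ts`), `true_rr` and `true_hr` (per minute),
#'   `beat_times` (seconds) and `config`.
#' @examples
#' rec <- generate_ppg(synth_config(duration = 40, a_riiv = 0.3))
#' rec$true_rr
#' @export
generate_ppg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    # beat times from integer crossings of the integrated heart phase,
    # computed on a fine grid for accurate crossing interpolation
    fs_fine <- max(200, 8 * cfg$fs_ppg)
    tf <- seq(0, cfg$duration, by = 1 / fs_fine)
    f_h <- cfg$f_heart * (1 + cfg$a_rifv * sin(2 * pi * cfg$f_resp * tf))
    phase <- cumsum(f_h) / fs_fine
    n_beats <- floor(phase[length(phase)])
    beat_times <- stats::approx(phase, tf, xout = seq_len(n_beats))$y

    t <- seq(0, cfg$duration - 1 / cfg$fs_ppg, by = 1 / cfg$fs_ppg)
    pulse <- numeric(length(t))
    for (tb in beat_times) {
      near <- which(abs(t - tb) < 1.5)   # template support
      pulse[near] <- pulse[near] + beat_template(t[near] - tb)
    }
    amp <- 1 + cfg$a_riav * sin(2 * pi * cfg$f_resp * t + cfg$phi_a)
    base <- cfg$a_riiv * sin(2 * pi * cfg$f_resp * t + cfg$phi_i)
    clean <- pulse * amp + base
    noise <- if (is.finite(cfg$snr_db)) {
      sd_n <- sqrt(mean(pulse^2)) / 10^(cfg$snr_db / 20)
      stats::rnorm(length(t), sd = sd_n)
    } else 0
    tr <- seq(0, cfg$duration - 1 / cfg$fs_resp, by = 1 / cfg$fs_resp)
    structure(list(
      ppg = ppg_ts(clean + noise, cfg$fs_ppg, "synthetic PPG"),
      respiration = ppg_ts(sin(2 * pi * cfg$f_resp * tr), cfg$fs_resp,
                           "synthetic respiration"),
      true_rr = 60 * cfg$f_resp, true_hr = 60 * cfg$f_heart,
      beat_times = beat_times, config = cfg),
      class = "synth_record")
  })
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf(
    "<synth_record> %.0f s PPG @ %g Hz | true RR %.1f bpm, HR %.1f bpm, %d beats\n",
    duration(x$ppg), x$ppg$fs, x$true_rr, x$true_hr,
    length(x$beat_times)))
  invisible(x)
}

#' Generate a corrupted respiratory reference for QC testing
#'
#' Builds a breathing waveform whose breath-to-breath intervals have
#' standard deviation `jitter_s` (seconds) and whose trough depths are
#' perturbed with standard deviation `trough_noise` (on the normalized
#' amplitude scale), exercising the two rejection statistics of
#' [qc_respiratory()].
#'
#' Interval corruption mixes two disturbances seen in real corrupted
#' thoracic traces: breath-to-breath irregularity (Gaussian, floored at
#' 0.6 of the breath period — faster cycles are not resolvable
#' breathing) and occasional prolonged apneic intervals (probability
#' 0.25 per breath).  The two components are calibrated so the total
#' interval standard deviation equals `jitter_s`
#' (\eqn{0.533^2 + 0.25 \cdot 0.75 \cdot 1.954^2 \approx 1}).  Each
#' breath is an in-band raised-cosine inhalation bump centred at its
#' breath time, so the injected timing dispersion survives the
#' screening band-pass.
#'
#' @param cfg a `synth_config` (breathing frequency and duration used).
#' @param jitter_s standard deviation of breath intervals in seconds.
#' @param trough_noise standard deviation of per-cycle trough-depth
#'   perturbations.
#' @return a `ppg_ts` at `cfg$fs_resp`.
#' @export
generate_corrupted_respiration <- function(cfg, jitter_s = 0,
                                           trough_noise = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 7919L, {
    period <- 1 / cfg$f_resp
    n_breaths <- ceiling(2 * cfg$duration / period) + 10L
    base <- pmax(stats::rnorm(n_breaths, period, 0.533 * jitter_s),
                 0.6 * period)
    pause <- 1.954 * jitter_s * stats::rbinom(n_breaths, 1L, 0.25)
    iv <- base + pause
    peaks <- cumsum(iv)
    peaks <- peaks[peaks < cfg$duration + period]
    t <- seq(0, cfg$duration - 1 / cfg$fs_resp, by = 1 / cfg$fs_resp)
    w <- 0.35 * period
    bump <- function(centers, width, amps) {
      out <- numeric(length(t))
      for (k in seq_along(centers)) {
        span <- which(abs(t - centers[k]) < width)
        out[span] <- out[span] +
          amps[k] * 0.5 * (1 + cos(pi * (t[span] - centers[k]) / width))
      }
      out
    }
    resp <- bump(peaks, w, rep(1, length(peaks)))
    if (trough_noise > 0) {
      mids <- (peaks[-length(peaks)] + peaks[-1]) / 2
      delta <- stats::rnorm(length(mids), sd = trough_noise)
      resp <- resp + bump(mids, w, -delta)
    }
    ppg_ts(resp, cfg$fs_resp, "synthetic corrupted respiration")
  })
}
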