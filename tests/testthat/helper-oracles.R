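# Shared fixtures and independent oracles used across the suite.

sine_ts <- function(f, dur, fs, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ppg_ts(amp * sin(2 * pi * f * t + phase), fs)
}

# Brute-force anti-diagonal averaging: the O(L*K) double loop the fast
# implementation must agree with.
hankelize_bruteforce <- function(Xi) {
  L <- nrow(Xi); K <- ncol(Xi)
  z <- numeric(L + K - 1)
  for (s in seq_along(z)) {
    acc <- 0; cnt <- 0
    for (i in seq_len(L)) {
      j <- s - i + 1
      if (j >= 1 && j <= K) { acc <- acc + Xi[i, j]; cnt <- cnt + 1 }
    }
    z[s] <- acc / cnt
  }
  z
}

# Exhaustive scan: does any interior triplet of the retained turning
# points still have two same-sign slopes?
has_same_sign_triplet <- function(times, values) {
  o <- order(times)
  v <- values[o]
  if (length(v) < 3) return(FALSE)
  rho <- sign(diff(v))
  any(rho[-length(rho)] * rho[-1] > 0)
}

# All turning points of a segmentation, interleaved in time order.
tp_interleaved <- function(tp) {
  tt <- c(tp$maxima$times, tp$minima$times)
  vv <- c(tp$maxima$values, tp$minima$values)
  mm <- c(rep(TRUE, length(tp$maxima$times)),
          rep(FALSE, length(tp$minima$times)))
  o <- order(tt)
  list(times = tt[o], values = vv[o], is_max = mm[o])
}

dominant_freq <- function(ts, lo = 0, hi = Inf) {
  psd <- periodogram(ts)
  sel <- psd$freqs >= lo & psd$freqs <= hi
  psd$freqs[sel][which.max(psd$power[sel])]
}
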