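#' @keywords internal
#' Indices of strict local maxima/minima by neighbour comparison.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  core <- 2:(n - 1)
  d1 <- x[core] - x[core - 1L]
  d2 <- x[core] - x[core + 1L]
  list(max = core[d1 > 0 & d2 > 0], min = core[d1 < 0 & d2 < 0])
}

# Cubic-spline envelope through extrema, mirror-extending the first and
# last two extrema about the series ends to damp end swings.
envelope_spline <- function(idx, val, n) {
  if (length(idx) >= 2L) {
    k <- min(2L, length(idx))
    left_i <- 2 - idx[seq_len(k)]           # reflect about sample 1
    right_i <- 2L * n - idx[length(idx) - seq_len(k) + 1L]
    idx <- c(rev(left_i), idx, rev(right_i))
    val <- c(rev(val[seq_len(k)]), val,
             rev(val[length(val) - seq_len(k) + 1L]))
  }
  o <- order(idx)
  idx <- idx[o]; val <- val[o]
  dup <- duplicated(idx)
  sf <- stats::splinefun(idx[!dup], val[!dup], method = "fmm")
  sf(seq_len(n))
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the mean of the upper and lower cubic-spline
#' envelopes of the working series until the candidate is locally
#' symmetric.  Convergence is declared when the sample-wise squared
#' relative change between consecutive candidates,
#' \eqn{\sum_t (d_i(t) - d_{i-1}(t))^2 / d_{i-1}(t)^2}, drops to the
#' threshold or below (evaluated from the second iteration on, with a
#' small guard added to the denominator at zero crossings).
#'
#' @param v a `ppg_ts` with at least 2 maxima and 2 minima.
#' @param sd_threshold stopping threshold on the relative-change sum
#'   (default 0.1).
#' @param max_iter iteration cap ensuring termination (default 50).
#' @return a `ppg_ts` holding the extracted IMF.
#' @export
sift <- function(v, sd_threshold = 0.1, max_iter = 50L) {
  stopifnot(inherits(v, "ppg_ts"))
  x <- v$values
  n <- length(x)
  ex <- local_extrema(x)
  if (length(ex$max) < 2L || length(ex$min) < 2L)
    stop("cannot sift: fewer than 2 maxima or 2 minima")
  d_prev <- NULL
  d <- x
  for (i in seq_len(max_iter)) {
    ex <- local_extrema(d)
    if (length(ex$max) < 2L || length(ex$min) < 2L) break
    eu <- envelope_spline(ex$max, d[ex$max], n)
    el <- envelope_spline(ex$min, d[ex$min], n)
    m <- (eu + el) / 2
    d_new <- d - m
    if (!is.null(d_prev)) {
      sd_i <- sum((d_new - d)^2 / (d^2 + 1e-12))
      if (sd_i <= sd_threshold) { d <- d_new; break }
    }
    d_prev <- d
    d <- d_new
  }
  ppg_ts(d, v$fs, "IMF")
}

#' Empirical mode decomposition of a window
#'
#' Iteratively sifts the running residual, peeling off intrinsic mode
#' functions from fastest to slowest, until the residual is monotone (or
#' has fewer than two local maxima or minima) or the IMF cap is reached.
#' The decomposition is purely subtractive, so the IMFs and residual sum
#' back to the input exactly (to floating-point accuracy).
#'
#' @param w a `ppg_ts` window (>= 64 samples).
#' @param max_imfs maximum number of IMFs to extract (default 4).
#' @param sd_threshold,max_iter passed to [sift()].
#' @return an object of class `emd_result`: list with `imfs` (list of
#'   `ppg_ts`, possibly empty) and `residual` (`ppg_ts`).
#' @export
emd_decompose <- function(w, max_imfs = 4L, sd_threshold = 0.1,
                          max_iter = 50L) {
  stopifnot(inherits(w, "ppg_ts"))
  if (length(w$values) < 64L) stop("window too short for decomposition")
  resid <- w$values
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ex <- local_extrema(resid)
    if (length(ex$max) < 2L || length(ex$min) < 2L) break
    h <- sift(ppg_ts(resid, w$fs), sd_threshold = sd_threshold,
              max_iter = max_iter)
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h$values
  }
  structure(list(imfs = imfs, residual = ppg_ts(resid, w$fs, "residual")),
            class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("<emd_result> %d IMF(s) + residual (%d samples @ %g Hz)\n",
              length(x$imfs), length(x$residual$values), x$residual$fs))
  invisible(x)
}

#' Respiratory rate from an EMD decomposition
#'
#' Each IMF is (optionally) artifact-reduced, its periodogram taken, and
#' the most powerful in-band peak converted to breaths/min.  The overall
#' estimate `RR_EMD` is the per-IMF estimate whose in-band peak carries
#' the greatest power.
#'
#' @param res an `emd_result`.
#' @param band a `freq_band` restricting the respiratory search range.
#' @param n_report how many leading per-IMF estimates to report
#'   individually (default 3; all IMFs still compete for `RR_EMD`).
#' @param postprocess apply the artifact-reduction operator to each IMF
#'   before spectral estimation (default TRUE).
#' @return a data frame with columns `estimator`, `rr_bpm`, `peak_power`;
#'   rows `RR_IMF1..n_report` and `RR_EMD`.  Estimates with no in-band
#'   peak are `NA`.
#' @export
rr_from_emd <- function(res, band = freq_band(0.1, 0.5), n_report = 3L,
                        postprocess = TRUE) {
  stopifnot(inherits(res, "emd_result"))
  if (length(res$imfs) < 1L) stop("no IMFs to estimate from")
  per <- lapply(res$imfs, function(h) {
    ts <- if (postprocess)
      tryCatch(artifact_reduce(h, out_fs = h$fs), error = function(e) h)
    else h
    tryCatch(pick_rr(periodogram(ts), band),
             error = function(e) list(rr_bpm = NA_real_,
                                      peak_power = NA_real_))
  })
  rr <- vapply(per, function(p) p$rr_bpm, numeric(1))
  pw <- vapply(per, function(p) p$peak_power, numeric(1))
  best <- if (all(is.na(pw))) NA_integer_ else which.max(pw)
  k <- min(n_report, length(rr))
  data.frame(
    estimator = c(paste0("RR_IMF", seq_len(k)), "RR_EMD"),
    rr_bpm = c(rr[seq_len(k)],
               if (is.na(best)) NA_real_ else rr[best]),
    peak_power = c(pw[seq_len(k)],
                   if (is.na(best)) NA_real_ else pw[best]),
    stringsAsFactors = FALSE
  )
}
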