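#' Incremental merge segmentation of a PPG window
#'
#' Locates pulse extrema by slope-sign merging.  The window is reduced to
#' a set of strided points `y_k = x(m k)`; the slope of each sub-segment
#' between consecutive retained points is computed, and the central point
#' of every triplet whose two slopes share a sign is removed, repeatedly,
#' until every surviving interior point is a genuine turning point.
#' Monotone runs are thereby merged into single line segments whose
#' endpoints are the pulse maxima and minima.
#'
#' @param w a `ppg_ts` window (typically from [segment_signal()]).
#' @param m stride in samples between candidate points (integer >= 1,
#'   `< length(w)`).  Default 1 keeps every sample; at high sampling
#'   rates a larger stride keeps roughly 25 points per second.
#' @param t0 time of the window's first sample in seconds (defaults to
#'   the `start` attribute set by [segment_signal()], if present).
#' @param min_prominence peak-detection screen applied to the merged
#'   turning points: adjacent max/min pairs whose excursion falls below
#'   this fraction of the median excursion are treated as ripples (noise
#'   or dicrotic wiggles riding on a pulse) and removed, keeping one
#'   turning point per genuine pulse phase.  Set to 0 to keep every
#'   turning point of the merge.
#' @param refine refine each extremum's time and value to sub-sample
#'   precision by the vertex of the parabola through it and its two
#'   strided neighbours (symmetric extrema are left untouched).
#' @return an object of class `turning_points`: a list with
#'   `maxima` and `minima` (`event_series` of peak/trough times and
#'   values) and the logical flag `no_pulses`.
#' @examples
#' tp <- ims_segment(ppg_ts(c(0, 2, 0, 2, 0), 1), m = 1)
#' tp$maxima$values  # both peaks at 2
#' @export
ims_segment <- function(w, m = 1L, t0 = NULL, min_prominence = 0.3,
                        refine = TRUE) {
  stopifnot(inherits(w, "ppg_ts"))
  m <- as.integer(m)
  M <- length(w$values)
  if (m < 1L || m >= M) stop("stride m must satisfy 1 <= m < window length")
  if (is.null(t0)) {
    st <- attr(w, "start")
    t0 <- if (is.null(st)) 0 else st / w$fs
  }
  idx <- seq.int(1L, M, by = m)
  if (length(idx) < 3L) stop("window too short to hold 3 strided points")
  y <- w$values[idx]

  # iterative triplet removal: drop central points of same-sign slope pairs
  keep <- seq_along(y)
  repeat {
    if (length(keep) < 3L) break
    rho <- sign(diff(y[keep]))
    same <- which(rho[-length(rho)] * rho[-1] > 0)  # interior point same+1
    if (length(same) == 0L) break
    keep <- keep[-(same + 1L)]
  }

  interior <- keep[-c(1L, length(keep))]
  if (length(keep) < 3L || length(interior) == 0L) {
    tp <- list(maxima = event_series(numeric(0), numeric(0)),
               minima = event_series(numeric(0), numeric(0)),
               no_pulses = TRUE)
    class(tp) <- "turning_points"
    return(tp)
  }
  pos <- match(interior, keep)
  is_max <- y[interior] > y[keep[pos - 1L]] & y[interior] > y[keep[pos + 1L]]
  # the retained-set endpoints are turning points too (first/last trough
  # or crest of the pulse train), classified against their one neighbour
  ends <- keep[c(1L, length(keep))]
  end_is_max <- c(y[ends[1]] > y[keep[2L]],
                  y[ends[2]] > y[keep[length(keep) - 1L]])
  all_idx <- c(ends[1], interior, ends[2])
  all_max <- c(end_is_max[1], is_max, end_is_max[2])
  tms <- t0 + (idx[all_idx] - 1L) / w$fs
  val <- y[all_idx]
  if (min_prominence > 0) {
    pr <- prune_ripples(tms, val, all_max, min_prominence,
                        strided_idx = all_idx)
    tms <- pr$times; val <- pr$values; all_max <- pr$is_max
    all_idx <- pr$strided_idx
  }
  if (refine) {
    # sub-sample vertex of the parabola through each extremum and its
    # strided neighbours; at 25 Hz the +-half-sample quantization would
    # otherwise dominate the beat-interval series
    dt <- m / w$fs
    raw <- tms
    for (p in seq_along(all_idx)) {
      i <- all_idx[p]
      if (i <= 1L || i >= length(y)) next
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      if (abs(denom) < .Machine$double.eps) next
      off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
      off <- max(-0.5, min(0.5, off))
      tms[p] <- tms[p] + off * dt
      val[p] <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * off
    }
    # refinement must not let neighbouring extrema touch or cross
    bad <- which(diff(tms) <= 0)
    while (length(bad) > 0L) {
      tms[c(bad, bad + 1L)] <- raw[c(bad, bad + 1L)]
      bad <- which(diff(tms) <= 0)
    }
  }
  tp <- list(
    maxima = event_series(tms[all_max], val[all_max]),
    minima = event_series(tms[!all_max], val[!all_max]),
    no_pulses = FALSE
  )
  class(tp) <- "turning_points"
  tp
}

# Remove low-excursion ripple pairs from an alternating extrema
# sequence; after each removal, adjacent extrema of the same kind are
# merged keeping the more extreme one, preserving alternation.
prune_ripples <- function(times, values, is_max, q,
                          strided_idx = seq_along(values)) {
  drop_at <- function(at) {
    times <<- times[-at]; values <<- values[-at]
    is_max <<- is_max[-at]; strided_idx <<- strided_idx[-at]
  }
  repeat {
    if (length(values) < 3L) break
    exc <- abs(diff(values))
    # reference excursion is the mean, which (unlike the median) still
    # reflects the genuine pulse swings when ripples outnumber them,
    # and grows as ripples are removed so the screen converges
    small <- which(exc < q * mean(exc))
    if (length(small) == 0L) break
    i <- small[which.min(exc[small])]
    drop_at(c(i, i + 1L))
    j <- 1L
    while (j < length(values)) {
      if (is_max[j] == is_max[j + 1L]) {
        drop_at(if (is_max[j] == (values[j] >= values[j + 1L]))
          j + 1L else j)
      } else j <- j + 1L
    }
  }
  list(times = times, values = values, is_max = is_max,
       strided_idx = strided_idx)
}

#' @export
print.turning_points <- function(x, ...) {
  cat(sprintf("<turning_points> %d maxima, %d minima%s\n",
              length(x$maxima), length(x$minima),
              if (isTRUE(x$no_pulses)) " [no pulses detected]" else ""))
  invisible(x)
}

#' Respiratory-induced intensity variation (baseline modulation)
#'
#' The series of pulse maximum values, passed through the
#' artifact-reduction operator (spline derivative on a uniform grid).
#' Intra-thoracic pressure swings modulate venous return and hence the
#' PPG baseline, so the peak-value envelope tracks respiration.
#'
#' @param tp a `turning_points` object.
#' @param out_fs output sampling rate in Hz.
#' @return a `ppg_ts` (the RIIV waveform).
#' @export
extract_riiv <- function(tp, out_fs = 8) {
  stopifnot(inherits(tp, "turning_points"))
  if (length(tp$maxima) < 4L) stop("insufficient beats: need >= 4 maxima")
  artifact_reduce(tp$maxima, out_fs = out_fs)
}

#' Respiratory-induced amplitude variation (pulse-strength modulation)
#'
#' Each pulse maximum is paired with the immediately preceding minimum
#' (the foot of the systolic upslope); the max-minus-min differences,
#' timestamped at the maxima, are passed through artifact reduction.
#' Unpaired extrema at the window boundaries are dropped.
#'
#' @inheritParams extract_riiv
#' @return a `ppg_ts` (the RIAV waveform).
#' @export
extract_riav <- function(tp, out_fs = 8) {
  stopifnot(inherits(tp, "turning_points"))
  tmax <- tp$maxima$times; vmax <- tp$maxima$values
  tmin <- tp$minima$times; vmin <- tp$minima$values
  if (length(tmax) == 0L || length(tmin) == 0L)
    stop("insufficient beats: need paired extrema")
  prev <- findInterval(tmax, tmin)   # index of last minimum before each max
  ok <- prev >= 1L
  if (sum(ok) < 4L) stop("insufficient beats: need >= 4 max-min pairs")
  amp <- vmax[ok] - vmin[prev[ok]]
  artifact_reduce(event_series(tmax[ok], amp), out_fs = out_fs)
}

#' Respiratory-induced frequency variation (respiratory sinus arrhythmia)
#'
#' The tachogram of absolute time intervals between consecutive pulse
#' minima, timestamped at the interval midpoints, passed through
#' artifact reduction.  Heart rate quickens on inspiration and slows on
#' expiration, so beat-to-beat intervals oscillate at the breathing
#' frequency.
#'
#' @inheritParams extract_riiv
#' @param landmark beat landmark whose successive intervals form the
#'   tachogram: `"minima"` (pulse feet) or `"maxima"` (systolic peaks).
#'   The peak is the sharpest feature of the pulse, so peak intervals
#'   are the more noise-robust carrier of the same beat-to-beat timing.
#' @param interval_tol relative deviation from the median beat interval
#'   beyond which an interval is discarded as an ectopic/detection
#'   artifact (standard tachogram screening); `Inf` disables.
#' @param differentiate apply the full artifact-reduction operator
#'   (spline derivative).  The tachogram is itself a differenced
#'   quantity with no baseline trend, and differentiating it amplifies
#'   beat-timing jitter quadratically with frequency, so the spline
#'   resampling alone (`FALSE`) preserves slow breathing peaks better;
#'   `TRUE` keeps the operator exactly as for the other two channels.
#' @return a `ppg_ts` (the RIFV waveform).
#' @export
extract_rifv <- function(tp, out_fs = 8,
                         landmark = c("minima", "maxima"),
                         interval_tol = 0.4, differentiate = TRUE) {
  stopifnot(inherits(tp, "turning_points"))
  landmark <- match.arg(landmark)
  tl <- if (landmark == "minima") tp$minima$times else tp$maxima$times
  if (length(tl) < 5L)
    stop(sprintf("insufficient beats: need >= 5 %s", landmark))
  iv <- abs(diff(tl))
  mid <- (tl[-length(tl)] + tl[-1]) / 2
  if (is.finite(interval_tol)) {
    med <- stats::median(iv)
    ok <- abs(iv - med) <= interval_tol * med
    iv <- iv[ok]; mid <- mid[ok]
  }
  if (length(iv) < 4L) stop("insufficient beats after interval screening")
  artifact_reduce(event_series(mid, iv), out_fs = out_fs,
                  deriv = if (differentiate) 1L else 0L)
}

#' Extract all three respiratory-induced variations from a window
#'
#' Convenience wrapper running [ims_segment()] then the three RIV
#' extractors, returning `NULL` for any waveform whose beat support is
#' insufficient.
#'
#' @inheritParams ims_segment
#' @param out_fs output rate of the RIV waveforms in Hz.
#' @param rifv_landmark beat landmark for the tachogram (see
#'   [extract_rifv()]).
#' @param rifv_differentiate apply the spline derivative to the
#'   tachogram (see [extract_rifv()]).
#' @return a list of class `riv_set` with elements `riiv`, `riav`,
#'   `rifv` (each `ppg_ts` or `NULL`) and the `turning_points`.
#' @export
extract_rivs <- function(w, m = 1L, out_fs = 8, t0 = NULL,
                         min_prominence = 0.3,
                         rifv_landmark = "minima",
                         rifv_differentiate = TRUE) {
  tp <- ims_segment(w, m = m, t0 = t0, min_prominence = min_prominence)
  grab <- function(f, ...) tryCatch(f(tp, out_fs = out_fs, ...),
                                    error = function(e) NULL)
  out <- list(riiv = grab(extract_riiv), riav = grab(extract_riav),
              rifv = grab(extract_rifv, landmark = rifv_landmark,
                          differentiate = rifv_differentiate),
              turning_points = tp)
  class(out) <- "riv_set"
  out
}

#' Fuse the three RIV channels into a single RR estimate or waveform
#'
#' Modes `"avg"` and `"median"` combine the three per-channel RR values
#' (breaths/min) arithmetically.  Mode `"pca"` treats the three
#' standardized RIV waveforms as realizations of the common respiratory
#' trend, truncates them to a common grid, and returns the first
#' principal component as a fused waveform for spectral RR estimation;
#' its sign is oriented to correlate positively with the RIIV channel.
#'
#' @param rivs a `riv_set` (required for `mode = "pca"`).
#' @param rr_per_riv numeric vector of the three per-channel RR values in
#'   breaths/min, in the order (riiv, riav, rifv); required for
#'   `"avg"`/`"median"`.
#' @param mode `"avg"`, `"median"` or `"pca"`.
#' @return a single RR value (breaths/min) for `"avg"`/`"median"`; a
#'   fused `ppg_ts` with attribute `explained` (fraction of variance on
#'   PC1) for `"pca"`.
#' @export
fuse_rivs <- function(rivs = NULL, rr_per_riv = NULL,
                      mode = c("avg", "median", "pca")) {
  mode <- match.arg(mode)
  if (mode %in% c("avg", "median")) {
    if (is.null(rr_per_riv) || length(rr_per_riv) != 3L)
      stop("avg/median fusion needs the three per-channel RR values")
    if (anyNA(rr_per_riv)) stop("fusion skipped: missing channel estimate")
    return(if (mode == "avg") mean(rr_per_riv) else
             stats::median(rr_per_riv))
  }
  stopifnot(inherits(rivs, "riv_set"))
  chans <- rivs[c("riiv", "riav", "rifv")]
  if (any(vapply(chans, is.null, logical(1))))
    stop("fusion skipped: missing RIV channel")
  n <- min(vapply(chans, length, integer(1)))
  fs <- chans$riiv$fs
  mat <- vapply(chans, function(ch) {
    v <- ch$values[seq_len(n)]
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v - mean(v)
  }, numeric(n))
  pc <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
  fused <- pc$x[, 1]
  if (stats::sd(fused) > 0 && stats::sd(mat[, 1]) > 0 &&
      stats::cor(fused, mat[, 1]) < 0) fused <- -fused
  out <- ppg_ts(fused, fs, "RIV PCA fusion")
  attr(out, "explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}
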