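#' Pipeline configuration
#'
#' Collects every tunable of the estimation pipeline with the study
#' defaults: 30 s windows shifted by 1 s, a fourth-order 0.18-1.0 Hz
#' Butterworth pre-filter for the decomposition methods, a sifting
#' threshold of 0.1 with at most 4 IMFs, and 3 retained SSA components
#' with embedding length 17.  The morphological (IMS) branch needs the
#' cardiac pulses it segments, so it uses a wider pre-filter band whose
#' upper edge keeps the heart rate and its first harmonic
#' (`ims_high` Hz, capped below Nyquist).
#'
#' @param window_s window length in seconds.
#' @param shift_s shift between windows in seconds.
#' @param pre_band numeric `c(lo, hi)` Hz pre-filter band for EMD/SSA.
#' @param pre_order pre-filter design order.
#' @param ims_band numeric `c(lo, hi)` Hz pre-filter band for the IMS
#'   branch; the upper edge is additionally capped below Nyquist.
#' @param stride_rate target rate of IMS strided points per second (the
#'   stride `m` is chosen as `max(1, round(fs / stride_rate))`).
#' @param L SSA embedding length in samples.
#' @param n_eofs retained SSA components.
#' @param max_imfs IMF cap.
#' @param sd_threshold sifting stop threshold.
#' @param riv_fs uniform resampling rate in Hz for artifact-reduced
#'   event series.
#' @param band_lo,band_cap,band_fallback_hi adaptive respiratory band
#'   parameters in Hz (see [adaptive_band()]).
#' @param seed integer seed controlling any randomized step.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 30, shift_s = 1,
                            pre_band = c(0.18, 1.0), pre_order = 4L,
                            ims_band = c(0.08, 2.5), stride_rate = 25,
                            L = 17L,
                            n_eofs = 3L, max_imfs = 4L,
                            sd_threshold = 0.1, riv_fs = 8,
                            band_lo = 0.1, band_cap = 0.6,
                            band_fallback_hi = 0.5, seed = 1L) {
  structure(list(window_s = window_s, shift_s = shift_s,
                 pre_band = pre_band, pre_order = as.integer(pre_order),
                 ims_band = ims_band, stride_rate = stride_rate,
                 L = as.integer(L), n_eofs = as.integer(n_eofs),
                 max_imfs = as.integer(max_imfs),
                 sd_threshold = sd_threshold, riv_fs = riv_fs,
                 band_lo = band_lo, band_cap = band_cap,
                 band_fallback_hi = band_fallback_hi,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Labels of the estimators the pipeline produces
#' @return character vector of the 14 estimator labels.
#' @export
estimator_labels <- function() {
  c("RR_avg", "RR_median", "RR_PCA", "RR_RIFV", "RR_RIIV", "RR_RIAV",
    "RR_EMD", "RR_IMF1", "RR_IMF2", "RR_IMF3",
    "RR_SSA", "RR_EOF1", "RR_EOF2", "RR_EOF3")
}

# One window through all three method families.  Returns a named numeric
# vector over estimator_labels(); undefined estimates are NA.
estimate_window <- function(w, cfg, methods = c("ims", "emd", "ssa")) {
  out <- stats::setNames(rep(NA_real_, length(estimator_labels())),
                         estimator_labels())
  hr <- tryCatch(estimate_hr(w), error = function(e) NA_real_)
  band <- adaptive_band(hr, lo = cfg$band_lo, hi_cap = cfg$band_cap,
                        fallback_hi = cfg$band_fallback_hi)
  rr_of <- function(ts) {
    if (is.null(ts)) return(NA_real_)
    tryCatch(pick_rr(periodogram(ts), band)$rr_bpm,
             error = function(e) NA_real_)
  }

  if ("ims" %in% methods) {
    ims_w <- tryCatch(
      bandpass(w, cfg$ims_band[1],
               min(cfg$ims_band[2], 0.45 * w$fs),
               order = cfg$pre_order),
      error = function(e) NULL)
    if (!is.null(ims_w)) {
      attr(ims_w, "start") <- attr(w, "start")
      m <- max(1L, round(w$fs / cfg$stride_rate))
      rivs <- tryCatch(
        extract_rivs(ims_w, m = m, out_fs = cfg$riv_fs,
                     rifv_landmark = "maxima",
                     rifv_differentiate = FALSE),
        error = function(e) NULL)
      if (!is.null(rivs)) {
        out["RR_RIIV"] <- rr_of(rivs$riiv)
        out["RR_RIAV"] <- rr_of(rivs$riav)
        out["RR_RIFV"] <- rr_of(rivs$rifv)
        triplet <- out[c("RR_RIIV", "RR_RIAV", "RR_RIFV")]
        if (!anyNA(triplet)) {
          out["RR_avg"] <- fuse_rivs(rr_per_riv = triplet, mode = "avg")
          out["RR_median"] <- fuse_rivs(rr_per_riv = triplet,
                                        mode = "median")
        }
        out["RR_PCA"] <- tryCatch(
          rr_of(fuse_rivs(rivs = rivs, mode = "pca")),
          error = function(e) NA_real_)
      }
    }
  }

  filt <- tryCatch(
    bandpass(w, cfg$pre_band[1], cfg$pre_band[2],
             order = cfg$pre_order),
    error = function(e) NULL)

  if ("emd" %in% methods && !is.null(filt)) {
    tab <- tryCatch({
      dec <- emd_decompose(filt, max_imfs = cfg$max_imfs,
                           sd_threshold = cfg$sd_threshold)
      rr_from_emd(dec, band)
    }, error = function(e) NULL)
    if (!is.null(tab))
      out[tab$estimator[tab$estimator %in% names(out)]] <-
        tab$rr_bpm[tab$estimator %in% names(out)]
  }

  if ("ssa" %in% methods && !is.null(filt)) {
    tab <- tryCatch({
      res <- ssa_components(filt, L = cfg$L, n_keep = cfg$n_eofs)
      rr_from_ssa(res, band)
    }, error = function(e) NULL)
    if (!is.null(tab))
      out[tab$estimator[tab$estimator %in% names(out)]] <-
        tab$rr_bpm[tab$estimator %in% names(out)]
  }
  out
}

#' Run the RR estimation pipeline over one or more PPG recordings
#'
#' For every recording: window the signal, and per window run the
#' requested method families — morphological RIV extraction with
#' mean/median/PCA fusion, empirical mode decomposition, singular
#' spectrum analysis — picking each estimate as the dominant
#' periodogram peak inside a heart-rate adaptive respiratory band.
#' Window-level failures (e.g., no detectable pulses) are recorded as
#' `NA` and never abort the run.
#'
#' @param recordings a `ppg_ts` or a (possibly named) list of them, one
#'   per video.
#' @param cfg a `pipeline_config`.
#' @param methods subset of `c("ims", "emd", "ssa")`.
#' @param verbose emit a per-video summary message.
#' @return list with `windows` (long data frame: `video_id`, `window_j`,
#'   `estimator`, `rr_bpm`) and `videos` (wide data frame: `video_id`
#'   plus one column per estimator, median-aggregated over windows).
#' @export
run_estimate <- function(recordings, cfg = pipeline_config(),
                         methods = c("ims", "emd", "ssa"),
                         verbose = FALSE) {
  if (inherits(recordings, "ppg_ts")) recordings <- list(recordings)
  if (is.null(names(recordings)) || any(!nzchar(names(recordings))))
    names(recordings) <- sprintf("video%03d", seq_along(recordings))
  win_rows <- list(); vid_rows <- list()
  for (vid in names(recordings)) {
    ts <- recordings[[vid]]
    M <- round(cfg$window_s * ts$fs)
    K <- max(1L, round(cfg$shift_s * ts$fs))
    wins <- segment_signal(ts, M = M, K = K)
    est <- vapply(wins, estimate_window, cfg = cfg, methods = methods,
                  FUN.VALUE = numeric(length(estimator_labels())))
    # est: estimators x windows
    win_rows[[vid]] <- data.frame(
      video_id = vid,
      window_j = rep(seq_along(wins) - 1L, each = nrow(est)),
      estimator = rep(rownames(est), times = ncol(est)),
      rr_bpm = as.vector(est), stringsAsFactors = FALSE)
    agg <- apply(est, 1, aggregate_video)
    vid_rows[[vid]] <- data.frame(video_id = vid, t(agg),
                                  stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("%s: %d windows, %d/%d estimators defined", vid,
                      ncol(est), sum(!is.na(agg)), length(agg)))
  }
  list(windows = do.call(rbind, c(win_rows, make.row.names = FALSE)),
       videos = do.call(rbind, c(vid_rows, make.row.names = FALSE)))
}

#' Reference respiratory rate from a ground-truth waveform
#'
#' Applies the reference screening pipeline (0.1-0.5 Hz second-order
#' band-pass, range normalization) and picks the dominant periodogram
#' peak in the fixed 0.1-0.5 Hz band.
#'
#' @param ts a `ppg_ts` respiratory reference.
#' @return RR in breaths/min.
#' @export
reference_rr <- function(ts) {
  proc <- normalize_range(bandpass(ts, 0.1, 0.5, order = 2L))
  pick_rr(periodogram(proc), freq_band(0.1, 0.5))$rr_bpm
}

#' Evaluate per-video estimates against reference respiratory rates
#'
#' Joins the per-video estimate table with the reference table and runs
#' the full evaluation battery: MAE/RMSE, Friedman/Nemenyi rank
#' comparison with critical difference, per-estimator median error with
#' bootstrap CI, robust effect sizes, and Bland-Altman agreement for
#' each estimator.
#'
#' @param videos wide per-video estimate table from [run_estimate()].
#' @param references data frame with columns `video_id` and `rr_bpm`.
#' @param metric ranking metric, `"mae"` or `"rmse"`.
#' @param alpha significance level.
#' @param seed bootstrap seed.
#' @return list with `summary` (per-estimator table),
#'   `rank_comparison`, `gate`, `bland_altman` (named list, one per
#'   estimator), `n_videos`.
#' @export
run_evaluate <- function(videos, references, metric = "mae",
                         alpha = 0.05, seed = 1L) {
  stopifnot(all(c("video_id", "rr_bpm") %in% names(references)))
  merged <- merge(videos, references, by = "video_id")
  unmatched <- setdiff(videos$video_id, references$video_id)
  if (length(unmatched) > 0L)
    warning("unmatched video ids dropped: ",
            paste(unmatched, collapse = ", "))
  cols <- intersect(estimator_labels(), names(merged))
  keep <- stats::complete.cases(merged[, c(cols, "rr_bpm")])
  merged <- merged[keep, ]
  if (nrow(merged) == 0L) stop("no complete video/reference pairs")
  est <- as.matrix(merged[, cols])
  ref <- merged$rr_bpm
  ev <- evaluate_estimators(est, ref, metric = metric, alpha = alpha,
                            seed = seed)
  ba <- lapply(stats::setNames(cols, cols), function(cn) {
    if (nrow(merged) >= 3L) bland_altman(merged[[cn]], ref) else NULL
  })
  list(summary = ev$table, rank_comparison = ev$rank_comparison,
       gate = ev$gate, bland_altman = ba, n_videos = nrow(merged))
}

#' Write a results table with a provenance header
#'
#' Prepends comment lines recording the package version, seed and a
#' digest of the configuration, so every output file can be traced to
#' the run that produced it.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param cfg a `pipeline_config` (or any list) to digest.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, cfg = NULL) {
  hdr <- c(
    sprintf("# ppgrr %s",
            as.character(utils::packageVersion("ppgrr"))),
    if (!is.null(cfg))
      sprintf("# config: %s",
              paste(names(unlist(cfg)), unlist(cfg), sep = "=",
                    collapse = " ")))
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(df, path, append = TRUE, sep = ",",
                       row.names = FALSE, quote = FALSE))
  invisible(path)
}
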