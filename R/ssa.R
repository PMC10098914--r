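#' Lag-embed a window into its trajectory matrix
#'
#' Maps a series of length `M` into the `L x (M - L + 1)` Hankel
#' trajectory matrix whose column `i` is the lagged vector
#' `(x[i], ..., x[i + L - 1])`.
#'
#' @param w a `ppg_ts` window or numeric vector.
#' @param L embedding window length in samples, `1 < L <= M`.
#' @return numeric matrix of dimension `L x (M - L + 1)`.
#' @examples
#' ssa_embed(c(1, 2, 3, 4), L = 2)  # rbind(1:3, 2:4)
#' @export
ssa_embed <- function(w, L) {
  x <- if (inherits(w, "ppg_ts")) w$values else as.numeric(w)
  M <- length(x)
  L <- as.integer(L)
  if (L <= 1L || L > M) stop("invalid embedding: need 1 < L <= M")
  K <- M - L + 1L
  outer(seq_len(L), seq_len(K), function(i, j) x[i + j - 1L])
}

#' Singular value decomposition of a trajectory matrix
#'
#' Decomposes the trajectory matrix into its singular triplets.  The
#' left singular vectors are the empirical orthogonal functions (EOFs);
#' the rank-1 elementary matrices \eqn{X_i = \lambda_i U_i V_i^T} sum
#' back to the trajectory matrix.  Each EOF's sign is oriented so its
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param X trajectory matrix from [ssa_embed()].
#' @return an object of class `ssa_decomp`: list with `d` (rank bound
#'   `min(dim(X))`), `singular_values` (non-increasing), `U` (EOFs as
#'   columns) and `V`.
#' @export
ssa_decompose <- function(X) {
  stopifnot(is.matrix(X))
  sv <- svd(X)
  flip <- apply(sv$u, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  sv$u <- sweep(sv$u, 2, flip, `*`)
  sv$v <- sweep(sv$v, 2, flip, `*`)
  structure(list(d = min(dim(X)), singular_values = sv$d,
                 U = sv$u, V = sv$v),
            class = "ssa_decomp")
}

#' Elementary matrix of one singular triplet
#' @param dec an `ssa_decomp`.
#' @param i triplet index.
#' @return rank-1 matrix \eqn{\lambda_i U_i V_i^T}.
#' @export
elementary_matrix <- function(dec, i) {
  stopifnot(inherits(dec, "ssa_decomp"), i >= 1, i <= dec$d)
  dec$singular_values[i] * tcrossprod(dec$U[, i], dec$V[, i])
}

#' Hankelization (diagonal averaging) of a trajectory-shaped matrix
#'
#' Projects a matrix back onto a series of length `M = L + K - 1` by
#' averaging the entries along each anti-diagonal (`i + j` constant).
#'
#' @param Xi numeric matrix.
#' @return numeric vector of length `nrow + ncol - 1`.
#' @examples
#' hankelize(matrix(c(1, 5, 3, 7), 2))  # c(1, 4, 7)
#' @export
hankelize <- function(Xi) {
  stopifnot(is.matrix(Xi))
  L <- nrow(Xi); K <- ncol(Xi)
  # entry (i, j) lies on anti-diagonal t = i + j - 1
  t_of <- as.vector(row(Xi) + col(Xi) - 1L)
  sums <- tapply(as.vector(Xi), t_of, sum)
  counts <- tabulate(t_of, nbins = L + K - 1L)
  as.numeric(sums) / counts
}

#' Singular spectrum analysis of a window
#'
#' Full pipeline: embedding, SVD, per-triplet Hankelization.  No
#' grouping of components is performed — every singular triplet is
#' reconstructed individually, and the first `n_keep` components are
#' marked for respiratory-rate use.
#'
#' @param w a `ppg_ts` window.
#' @param L embedding length in samples (default 17).
#' @param n_keep number of leading components used downstream
#'   (default 3).
#' @return an object of class `ssa_result`: list with `singular_values`,
#'   `eofs` (matrix, EOFs as columns), `components` (list of `ppg_ts`
#'   of length `d`), `n_keep`, `fs`.
#' @export
ssa_components <- function(w, L = 17L, n_keep = 3L) {
  stopifnot(inherits(w, "ppg_ts"))
  X <- ssa_embed(w, L)
  dec <- ssa_decompose(X)
  comps <- lapply(seq_len(dec$d), function(i) {
    ppg_ts(hankelize(elementary_matrix(dec, i)), w$fs,
           sprintf("EOF%d component", i))
  })
  structure(list(singular_values = dec$singular_values, eofs = dec$U,
                 components = comps, n_keep = as.integer(n_keep),
                 fs = w$fs),
            class = "ssa_result")
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf("<ssa_result> %d components, leading singular values: %s\n",
              length(x$components),
              paste(signif(utils::head(x$singular_values, 3), 4),
                    collapse = ", ")))
  invisible(x)
}

#' Respiratory rate from an SSA decomposition
#'
#' The first `n_keep` reconstructed components are (optionally)
#' artifact-reduced, their periodograms taken, and the most powerful
#' in-band peak of each converted to breaths/min.  The overall estimate
#' `RR_SSA` is the per-component estimate whose in-band peak carries the
#' greatest power (set `select = "frequency"` to take the highest
#' frequency instead).
#'
#' @param res an `ssa_result` with at least 3 components.
#' @param band a `freq_band` restricting the respiratory search range.
#' @param select tie-break rule for `RR_SSA`: `"power"` (default) or
#'   `"frequency"`.
#' @param postprocess apply artifact reduction before spectral
#'   estimation (default TRUE).
#' @return a data frame with columns `estimator`, `rr_bpm`,
#'   `peak_power`; rows `RR_EOF1..n_keep` and `RR_SSA`.
#' @export
rr_from_ssa <- function(res, band = freq_band(0.1, 0.5),
                        select = c("power", "frequency"),
                        postprocess = TRUE) {
  stopifnot(inherits(res, "ssa_result"))
  select <- match.arg(select)
  k <- min(res$n_keep, length(res$components))
  if (length(res$components) < 3L) stop("need >= 3 components")
  per <- lapply(res$components[seq_len(k)], function(z) {
    ts <- if (postprocess)
      tryCatch(artifact_reduce(z, out_fs = z$fs), error = function(e) z)
    else z
    tryCatch(pick_rr(periodogram(ts), band),
             error = function(e) list(rr_bpm = NA_real_,
                                      peak_power = NA_real_))
  })
  rr <- vapply(per, function(p) p$rr_bpm, numeric(1))
  pw <- vapply(per, function(p) p$peak_power, numeric(1))
  best <- if (all(is.na(pw))) NA_integer_
          else if (select == "power") which.max(pw)
          else which.max(rr)
  data.frame(
    estimator = c(paste0("RR_EOF", seq_len(k)), "RR_SSA"),
    rr_bpm = c(rr, if (is.na(best)) NA_real_ else rr[best]),
    peak_power = c(pw, if (is.na(best)) NA_real_ else pw[best]),
    stringsAsFactors = FALSE
  )
}
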