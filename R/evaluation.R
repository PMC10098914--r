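#' Mean absolute error between paired RR estimates and references
#'
#' @param estimates,references numeric vectors of equal length
#'   (breaths/min), paired by video.
#' @return MAE in breaths/min.
#' @export
mae <- function(estimates, references) {
  stopifnot(length(estimates) == length(references),
            length(estimates) >= 1L)
  mean(abs(estimates - references))
}

#' Root mean squared error between paired RR estimates and references
#'
#' @inheritParams mae
#' @return RMSE in breaths/min.
#' @export
rmse <- function(estimates, references) {
  stopifnot(length(estimates) == length(references),
            length(estimates) >= 1L)
  sqrt(mean((estimates - references)^2))
}

#' Bland-Altman agreement analysis
#'
#' Pairs each estimate with its reference, forming the per-pair mean
#' `(est + ref) / 2` and difference `est - ref`.  Reports the bias (mean
#' difference), the 95% limits of agreement `bias +/- 1.96 sd(diff)`,
#' and the ordinary-least-squares slope of differences on means, which
#' exposes proportional bias (an estimator that under-reads slow and
#' over-reads fast breathing shows a positive slope).
#'
#' @inheritParams mae
#' @return an object of class `bland_altman`: list with `means`,
#'   `diffs`, `bias`, `loa_lo`, `loa_hi`, `trend_slope`,
#'   `trend_p` (slope p-value; `NA` when degenerate).
#' @export
bland_altman <- function(estimates, references) {
  stopifnot(length(estimates) == length(references),
            length(estimates) >= 3L)
  means <- (estimates + references) / 2
  diffs <- estimates - references
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  slope <- NA_real_; pval <- NA_real_
  if (stats::var(means) > 0) {
    fit <- stats::lm(diffs ~ means)
    slope <- unname(stats::coef(fit)[2])
    if (stats::var(diffs) > 0) {
      pval <- summary(fit)$coefficients[2, 4]
    } else {
      pval <- NA_real_
    }
  }
  structure(list(means = means, diffs = diffs, bias = bias,
                 loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s,
                 trend_slope = slope, trend_p = pval),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.3f, LoA [%.3f, %.3f], trend slope %s\n",
    x$bias, x$loa_lo, x$loa_hi, format(signif(x$trend_slope, 3))))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of pair (breaths/min)",
                 ylab = "difference (breaths/min)", ...)
  graphics::abline(h = c(x$bias, x$loa_lo, x$loa_hi),
                   lty = c(1, 2, 2), col = "grey30")
  invisible(x)
}

#' Normality and homogeneity gate for the estimator comparison
#'
#' Applies the Shapiro-Wilk test to each estimator's error population
#' and Levene's test (via `car`, when available) across populations.
#' If normality is rejected for at least one population at the given
#' level, the comparison must take the nonparametric path
#' (Friedman/Nemenyi) rather than a parametric ANOVA.
#'
#' @param populations numeric matrix, one column per estimator, one row
#'   per video.
#' @param alpha significance level for the gate.
#' @return list with `shapiro_p` (per column; `NA` for degenerate
#'   constant columns), `levene_p` (or `NA` if `car` is unavailable),
#'   `nonparametric` (flag), `degenerate` (logical per column).
#' @export
normality_gate <- function(populations, alpha = 0.05) {
  populations <- as.matrix(populations)
  shapiro_p <- apply(populations, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    stats::shapiro.test(col)$p.value
  })
  degenerate <- is.na(shapiro_p)
  levene_p <- NA_real_
  if (requireNamespace("car", quietly = TRUE)) {
    long <- data.frame(
      value = as.vector(populations),
      group = factor(rep(seq_len(ncol(populations)),
                         each = nrow(populations))))
    levene_p <- car::leveneTest(value ~ group, data = long)[1, "Pr(>F)"]
  }
  list(shapiro_p = shapiro_p, levene_p = levene_p,
       nonparametric = any(shapiro_p < alpha, na.rm = TRUE) ||
         any(degenerate),
       degenerate = degenerate)
}

#' Friedman omnibus test with Nemenyi post hoc analysis
#'
#' Ranks the estimators within each video (midranks on ties; rank 1 =
#' smallest error = best), runs the Friedman test across the `k`
#' estimators on `N` videos, computes the pairwise Nemenyi p-values from
#' the Studentized range distribution, and the critical difference
#' \eqn{CD = q_{\alpha,k} \sqrt{k (k + 1) / (6 N)}} (with
#' \eqn{q_{\alpha,k}} the Studentized range quantile divided by
#' \eqn{\sqrt 2}) for critical-difference diagrams: estimators whose
#' average ranks differ by less than CD cannot be called significantly
#' different.
#'
#' @param populations numeric matrix of per-video error values, one
#'   column per estimator (>= 3), one row per video (>= 10).
#' @param alpha significance level for the critical difference.
#' @return an object of class `rank_comparison`: list with `avg_ranks`,
#'   `friedman_stat`, `friedman_p`, `nemenyi_p` (k x k matrix), `cd`,
#'   `alpha`, `n`, `k`.
#' @export
friedman_nemenyi <- function(populations, alpha = 0.05) {
  populations <- as.matrix(populations)
  k <- ncol(populations); n <- nrow(populations)
  if (k < 3L) stop("need at least 3 estimators")
  if (n < 10L) stop("need at least 10 paired samples")
  ranks <- t(apply(populations, 1, rank))
  avg <- colMeans(ranks)
  ft <- stats::friedman.test(populations)
  if (is.nan(ft$statistic)) {
    # every row fully tied: no evidence of any difference
    ft$statistic[] <- 0; ft$p.value <- 1
  }
  se <- sqrt(k * (k + 1) / (6 * n))
  nem <- matrix(NA_real_, k, k,
                dimnames = list(colnames(populations),
                                colnames(populations)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { nem[i, j] <- 1; next }
    q <- abs(avg[i] - avg[j]) / se * sqrt(2)
    nem[i, j] <- stats::ptukey(q, nmeans = k, df = Inf,
                               lower.tail = FALSE)
  }
  cd <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2) * se
  structure(list(avg_ranks = avg,
                 friedman_stat = unname(ft$statistic),
                 friedman_p = ft$p.value, nemenyi_p = nem, cd = cd,
                 alpha = alpha, n = n, k = k),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf(
    "<rank_comparison> k = %d estimators, N = %d | Friedman chi^2 = %.2f (p = %.3g) | CD(%.2g) = %.3f\n",
    x$k, x$n, x$friedman_stat, x$friedman_p, x$alpha, x$cd))
  ord <- order(x$avg_ranks)
  cat("  average ranks (best first):\n")
  for (i in ord)
    cat(sprintf("    %s: %.2f\n",
                if (is.null(names(x$avg_ranks))) paste0("col", i)
                else names(x$avg_ranks)[i], x$avg_ranks[i]))
  invisible(x)
}

#' @export
plot.rank_comparison <- function(x, ...) {
  ord <- order(x$avg_ranks)
  graphics::dotchart(x$avg_ranks[ord],
                     labels = if (is.null(names(x$avg_ranks)))
                       paste0("col", ord) else names(x$avg_ranks)[ord],
                     xlab = "average rank (lower = better)", ...)
  graphics::abline(v = min(x$avg_ranks) + x$cd, lty = 2, col = "grey30")
  invisible(x)
}

#' Robust standardized effect size between two error populations
#'
#' A median-based analogue of Cohen's d: the difference of medians over
#' the pooled consistency-scaled median absolute deviation,
#' \deqn{\gamma = \frac{\mathrm{med}(b) - \mathrm{med}(a)}
#'   {\sqrt{((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)}},}
#' with \eqn{s = 1.4826 \cdot \mathrm{MAD}} so that \eqn{s} estimates
#' the standard deviation under normality.  The magnitude label follows
#' the conventional thresholds: negligible (< 0.2), small (< 0.5),
#' medium (< 0.8), large (>= 0.8), on \eqn{|\gamma|}.
#'
#' @param a,b numeric samples (>= 10 values each).
#' @return list with `gamma` and `magnitude`; `gamma` is `NA` and the
#'   magnitude `"undefined"` when the pooled spread is zero.
#' @export
akinshin_gamma <- function(a, b) {
  stopifnot(length(a) >= 10L, length(b) >= 10L)
  sa <- stats::mad(a); sb <- stats::mad(b)
  na <- length(a); nb <- length(b)
  pooled <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
  if (pooled <= 0)
    return(list(gamma = NA_real_, magnitude = "undefined"))
  g <- (stats::median(b) - stats::median(a)) / pooled
  list(gamma = g, magnitude = gamma_magnitude(g))
}

#' Magnitude label for a standardized effect size
#'
#' @param gamma effect-size value (sign ignored).
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
gamma_magnitude <- function(gamma) {
  vapply(abs(gamma), function(g) {
    if (is.na(g)) "undefined"
    else if (g < 0.2) "negligible"
    else if (g < 0.5) "small"
    else if (g < 0.8) "medium"
    else "large"
  }, character(1))
}

#' Median with bootstrap percentile confidence interval
#'
#' @param sample numeric vector.
#' @param conf confidence level.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for reproducible intervals.
#' @return list with `median`, `ci_lo`, `ci_hi`.
#' @export
median_ci <- function(sample, conf = 0.95, n_boot = 2000L, seed = 1L) {
  stopifnot(length(sample) >= 1L)
  med <- stats::median(sample)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample[sample.int(length(sample), replace = TRUE)])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(median = med, ci_lo = qs[1], ci_hi = qs[2])
}

#' Full evaluation table for a set of estimators
#'
#' Runs the error metrics, rank comparison and effect sizes across a
#' per-video estimate table, producing the summary a method-comparison
#' study reports: per-estimator MAE/RMSE, average rank, median error
#' with bootstrap CI, and effect size against the best-ranked estimator.
#'
#' @param estimates numeric matrix of per-video RR estimates, one column
#'   per estimator (named), one row per video.
#' @param references numeric vector of reference RR values, one per
#'   video.
#' @param metric `"mae"` or `"rmse"` error populations for ranking (the
#'   per-video population is the absolute error; squared error for
#'   `"rmse"`-flavoured ranking).
#' @param alpha significance level.
#' @param seed seed for the bootstrap CIs.
#' @return list with `table` (data frame: estimator, mae, rmse, rank,
#'   med, ci_lo, ci_hi, gamma, magnitude), `rank_comparison`, `gate`.
#' @export
evaluate_estimators <- function(estimates, references,
                                metric = c("mae", "rmse"), alpha = 0.05,
                                seed = 1L) {
  metric <- match.arg(metric)
  estimates <- as.matrix(estimates)
  stopifnot(nrow(estimates) == length(references))
  errs <- abs(estimates - references)
  pop <- if (metric == "rmse") sqrt(errs^2) else errs
  gate <- normality_gate(pop, alpha = alpha)
  rc <- friedman_nemenyi(pop, alpha = alpha)
  best <- which.min(rc$avg_ranks)
  rows <- lapply(seq_len(ncol(estimates)), function(i) {
    ci <- median_ci(pop[, i], seed = seed + i)
    g <- akinshin_gamma(pop[, i], pop[, best])
    data.frame(estimator = colnames(estimates)[i],
               mae = mae(estimates[, i], references),
               rmse = rmse(estimates[, i], references),
               rank = rc$avg_ranks[i], med = ci$median,
               ci_lo = ci$ci_lo, ci_hi = ci$ci_hi, gamma = g$gamma,
               magnitude = g$magnitude, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  list(table = tab, rank_comparison = rc, gate = gate)
}
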