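# Agreement statistics between two measurement methods: Pearson
# correlation, two-way random single-measure absolute-agreement ICC with an
# F-based confidence interval, Bland-Altman limits of agreement, RMSE with
# signed bias decomposition, and the coefficient of variation.

#' Paired measurements container
#'
#' @param reference,method numeric vectors of the same length (>= 3 pairs),
#'   finite values only.
#' @param labels optional case labels.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(reference, method, labels = NULL) {
  if (length(reference) != length(method))
    stop("reference and method must have the same length")
  if (length(reference) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(reference)) || !all(is.finite(method)))
    stop("measurements must be finite")
  if (is.null(labels)) labels <- as.character(seq_along(reference))
  structure(list(reference = as.numeric(reference),
                 method = as.numeric(method), labels = labels,
                 n = length(reference)),
            class = "paired_measurements")
}

#' Pearson correlation with confidence interval
#'
#' @param pairs a [paired_measurements()].
#' @param conf_level confidence level for the Fisher-z interval.
#' @return `list(r, conf_int, p_value, n)`.
#' @export
pearson_correlation <- function(pairs, conf_level = 0.95) {
  stopifnot(inherits(pairs, "paired_measurements"))
  ct <- cor.test(pairs$reference, pairs$method, method = "pearson",
                 conf.level = conf_level)
  list(r = unname(ct$estimate), conf_int = as.numeric(ct$conf.int),
       p_value = ct$p.value, n = pairs$n)
}

#' Intraclass correlation for absolute agreement
#'
#' Single-measure two-way random-effects ICC for absolute agreement,
#' ICC(2,1) in the Shrout-Fleiss scheme / ICC(A,1) in McGraw-Wong:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from the two-way
#' mean squares, with the F-based confidence bounds of McGraw & Wong and a
#' p-value from `F = MSR / MSE` on `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param pairs a [paired_measurements()] (the two raters are `reference`
#'   and `method`).
#' @param conf_level confidence level of the interval.
#' @return `list(icc, conf_int, p_value, n, k)`.
#' @export
icc_agreement <- function(pairs, conf_level = 0.95) {
  stopifnot(inherits(pairs, "paired_measurements"))
  x <- cbind(pairs$reference, pairs$method)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)

  Fstat <- MSR / MSE
  p <- pf(Fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, conf_int = c(lower, upper), p_value = p, n = n, k = k)
}

#' Bland-Altman analysis
#'
#' Differences are `reference - method`; limits of agreement are the mean
#' difference plus/minus 1.96 standard deviations.
#'
#' @param pairs a [paired_measurements()].
#' @return `list(means, differences, mean_diff, sd_diff, loa_lower,
#'   loa_upper)`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$reference - pairs$method
  m <- (pairs$reference + pairs$method) / 2
  md <- mean(d); s <- sd(d)
  list(means = m, differences = d, mean_diff = md, sd_diff = s,
       loa_lower = md - 1.96 * s, loa_upper = md + 1.96 * s)
}

#' Bland-Altman plot
#'
#' Base-graphics scatter of per-case differences against means with the
#' mean-difference line and the 95% limits of agreement.
#'
#' @param pairs a [paired_measurements()].
#' @param ... passed to [graphics::plot()].
#' @return The [bland_altman()] list, invisibly.
#' @export
plot_bland_altman <- function(pairs, ...) {
  ba <- bland_altman(pairs)
  graphics::plot(ba$means, ba$differences,
                 xlab = "Mean of methods", ylab = "Difference (reference - method)",
                 ...)
  graphics::abline(h = ba$mean_diff, lty = 1)
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2)
  invisible(ba)
}

#' Root-mean-square error and signed biases
#'
#' Differences are `reference - method`. The positive bias is the mean of
#' the positive differences (method underestimates), the negative bias the
#' mean magnitude of the negative differences (method overestimates); each
#' is 0 when no difference of that sign exists.
#'
#' @param pairs a [paired_measurements()].
#' @return `list(rmse, mean_bias, pos_bias, neg_bias, n_pos, n_neg)`.
#' @export
rmse_and_bias <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$reference - pairs$method
  pos <- d[d > 0]; neg <- d[d < 0]
  list(rmse = sqrt(mean(d^2)), mean_bias = mean(d),
       pos_bias = if (length(pos)) mean(pos) else 0,
       neg_bias = if (length(neg)) mean(abs(neg)) else 0,
       n_pos = length(pos), n_neg = length(neg))
}

#' Coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation,
#' expressed as a percentage.
#'
#' @param x numeric vector (>= 2 finite values, nonzero mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2 || !all(is.finite(x))) stop("need >= 2 finite values")
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * sd(x) / m
}

#' Coefficient of variation from summary moments
#'
#' @param mean,sd sample mean (nonzero) and standard deviation.
#' @return `100 * sd / mean`.
#' @export
cv_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || !is.finite(sd) || mean == 0)
    stop("mean must be finite and nonzero, sd finite")
  100 * sd / mean
}

#' Full agreement summary between two methods
#'
#' @param pairs a [paired_measurements()].
#' @param conf_level confidence level used throughout.
#' @return An object of class `agreement_summary` bundling
#'   [pearson_correlation()], [icc_agreement()], [bland_altman()],
#'   [rmse_and_bias()] and per-method CVs.
#' @export
agreement_summary <- function(pairs, conf_level = 0.95) {
  stopifnot(inherits(pairs, "paired_measurements"))
  structure(list(pearson = pearson_correlation(pairs, conf_level),
                 icc = icc_agreement(pairs, conf_level),
                 bland_altman = bland_altman(pairs),
                 error = rmse_and_bias(pairs),
                 cv_reference = coefficient_of_variation(pairs$reference),
                 cv_method = coefficient_of_variation(pairs$method),
                 n = pairs$n),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  Pearson r: %.4f (%.4f, %.4f)\n", x$pearson$r,
              x$pearson$conf_int[1], x$pearson$conf_int[2]))
  cat(sprintf("  ICC(2,1):  %.4f (%.4f, %.4f)\n", x$icc$icc,
              x$icc$conf_int[1], x$icc$conf_int[2]))
  cat(sprintf("  Bland-Altman: mean diff %.3f, LoA (%.3f, %.3f)\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  cat(sprintf("  RMSE %.3f, +bias %.3f (n=%d), -bias %.3f (n=%d)\n",
              x$error$rmse, x$error$pos_bias, x$error$n_pos,
              x$error$neg_bias, x$error$n_neg))
  cat(sprintf("  CV: reference %.1f%%, method %.1f%%\n",
              x$cv_reference, x$cv_method))
  invisible(x)
}
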