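# Scaling-statistics layer: power-law fits in double-logarithmic space,
# case-resampling bootstrap confidence intervals, competing linear and
# logarithmic models, two-variable regressions, correlations, binned means.

check_pairs <- function(d, V) {
  if (length(d) != length(V)) stop("'d' and 'V' must be paired",
                                   call. = FALSE)
  if (length(d) < 3L) stop("insufficient data: need n >= 3", call. = FALSE)
  if (any(!is.finite(d) | !is.finite(V) | d <= 0 | V <= 0)) {
    stop("values must be positive and finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Fit a power law d = c * V^alpha
#'
#' Ordinary least squares of log10(d) on log10(V); the slope is the scaling
#' exponent alpha and the intercept the log10 prefactor. Residual sums of
#' squares are reported both in log space (the fitting space) and in
#' diameter space. An optional case-resampling bootstrap percentile
#' confidence interval for the slope can be attached.
#'
#' @param d Diameters, um (positive).
#' @param V Volumes, fL (positive).
#' @param n_boot Number of bootstrap resamples for the slope CI (0 = none;
#'   the published analyses use 50,000).
#' @param level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `power_law_fit`: `slope`, `intercept`,
#'   `ci_lo`, `ci_hi`, `n`, `ssr_log_space`, `ssr_linear_space`.
#' @export
fit_power_law <- function(d, V, n_boot = 0L, level = 0.95, seed = NULL) {
  check_pairs(d, V)
  lx <- log10(V); ly <- log10(d)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  intercept <- mean(ly) - slope * mean(lx)
  pred_log <- intercept + slope * lx
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) ci <- bootstrap_ci(d, V, n_boot = n_boot, level = level,
                                      seed = seed)
  structure(list(slope = slope, intercept = intercept,
                 ci_lo = ci[[1]], ci_hi = ci[[2]], n = length(d),
                 ssr_log_space = sum((ly - pred_log)^2),
                 ssr_linear_space = sum((d - 10^pred_log)^2),
                 n_boot = as.integer(n_boot), level = level),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: d = %.4g * V^%.4f (n = %d)\n",
              10^x$intercept, x$slope, x$n))
  if (!is.na(x$ci_lo)) {
    cat(sprintf("  %.0f%% bootstrap CI for the exponent: [%.4f, %.4f] (%d resamples)\n",
                100 * x$level, x$ci_lo, x$ci_hi, x$n_boot))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the scaling exponent
#'
#' Case resampling of cells with replacement; for each resample the log-log
#' OLS slope is recomputed and the percentile interval of the slope
#' distribution returned. Deterministic under `seed`. Resampling is done in
#' chunks so memory stays bounded at the published 50,000 resamples.
#'
#' @inheritParams fit_power_law
#' @param n_boot Number of resamples.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(d, V, n_boot = 50000L, level = 0.95, seed = NULL) {
  check_pairs(d, V)
  n_boot <- check_count(n_boot, "n_boot")
  if (!is.null(seed)) set.seed(seed)
  lx <- log10(V); ly <- log10(d)
  n <- length(lx)
  slopes <- numeric(n_boot)
  done <- 0L
  chunk <- 5000L
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    idx <- sample.int(n, n * k, replace = TRUE)
    X <- matrix(lx[idx], nrow = n)
    Y <- matrix(ly[idx], nrow = n)
    mx <- colMeans(X); my <- colMeans(Y)
    sxy <- colMeans(X * Y) - mx * my
    sxx <- colMeans(X * X) - mx^2
    slopes[done + seq_len(k)] <- sxy / sxx
    done <- done + k
  }
  a <- (1 - level) / 2
  q <- stats::quantile(slopes, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  c(lo = q[1], hi = q[2])
}

#' Compare power, linear and logarithmic models of d(V)
#'
#' Fits `d = c * V^alpha` (via log-log OLS), `d = a + b * V` (OLS) and
#' `d = a + b * log10(V)` (OLS), and compares their residual sums of
#' squares. The comparison is decided in diameter (linear) space for all
#' three models so the residuals share units; the log-space SSR of the
#' power law is reported as well.
#'
#' @inheritParams fit_power_law
#' @return An object of class `model_comparison`: per-model coefficients
#'   and SSR, and the `winner` id (`"power"`, `"linear"`, `"log"`).
#' @export
compare_models <- function(d, V) {
  check_pairs(d, V)
  pw <- fit_power_law(d, V)
  lin <- stats::lm(d ~ V)
  lg <- stats::lm(d ~ log10(V))
  ssr <- c(power = pw$ssr_linear_space,
           linear = sum(stats::residuals(lin)^2),
           log = sum(stats::residuals(lg)^2))
  models <- list(
    power = list(prefactor = 10^pw$intercept, exponent = pw$slope,
                 ssr = unname(ssr["power"]),
                 ssr_log_space = pw$ssr_log_space),
    linear = list(offset = unname(stats::coef(lin)[1]),
                  slope = unname(stats::coef(lin)[2]),
                  ssr = unname(ssr["linear"])),
    log = list(offset = unname(stats::coef(lg)[1]),
               slope = unname(stats::coef(lg)[2]),
               ssr = unname(ssr["log"])))
  structure(list(models = models,
                 winner = names(ssr)[which.min(ssr)],
                 n = length(d)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (n = %d), SSR in diameter space:\n", x$n))
  cat(sprintf("  power : d = %.3f * V^%.3f   SSR = %.4g\n",
              x$models$power$prefactor, x$models$power$exponent,
              x$models$power$ssr))
  cat(sprintf("  linear: d = %.3f + %.3g * V  SSR = %.4g\n",
              x$models$linear$offset, x$models$linear$slope,
              x$models$linear$ssr))
  cat(sprintf("  log   : d = %.3f + %.3f * log10(V)  SSR = %.4g\n",
              x$models$log$offset, x$models$log$slope, x$models$log$ssr))
  cat("  winner:", x$winner, "\n")
  invisible(x)
}

#' Two-variable linear regression with constant offset
#'
#' OLS of `y` on two predictors plus an intercept, with two-sided t-based
#' (Wald) p-values per coefficient under homoscedastic normal errors — the
#' generalized-linear-fit convention. Used with predictors `V^(1/3)` and
#' `L / V^(1/3)` (or `R_C / V^(1/3)`) to separate the contributions of cell
#' size and shape.
#'
#' @param y Response vector.
#' @param x1,x2 Predictor vectors.
#' @return An object of class `regression_result`: `coefficients` (named:
#'   offset, x1, x2), `p_values`, `n`.
#' @export
two_var_regression <- function(y, x1, x2) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n)
  if (n <= 3L) stop("insufficient data: need n > 3", call. = FALSE)
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) {
    stop("collinear predictors: design matrix is rank-deficient",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x1 + x2)
  sm <- summary(fit)$coefficients
  structure(list(coefficients = c(offset = unname(sm[1, 1]),
                                  x1 = unname(sm[2, 1]),
                                  x2 = unname(sm[3, 1])),
                 p_values = c(offset = unname(sm[1, 4]),
                              x1 = unname(sm[2, 4]),
                              x2 = unname(sm[3, 4])),
                 n = n),
            class = "regression_result")
}

#' Pearson correlation with p-value
#'
#' Pearson correlation coefficient with its two-sided t-test p-value.
#'
#' @param x,y Paired numeric vectors (n >= 3, non-zero variance).
#' @return A list with `R`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("insufficient data: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Binned means with standard errors
#'
#' Arithmetic mean of `x` and `y` and the standard error of the mean of `y`
#' per bin of `x`. Empty bins are omitted; singleton bins report SE = 0 and
#' are flagged.
#'
#' @param x,y Paired numeric vectors.
#' @param bin_edges Increasing vector of bin edges (values outside are
#'   dropped).
#' @return Data frame with columns `bin`, `mean_x`, `mean_y`, `se_y`, `n`,
#'   `singleton`.
#' @export
binned_means <- function(x, y, bin_edges) {
  stopifnot(length(x) == length(y), length(bin_edges) >= 2L,
            !is.unsorted(bin_edges, strictly = TRUE))
  bin <- cut(x, bin_edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  if (!any(keep)) stop("no data in any bin", call. = FALSE)
  x <- x[keep]; y <- y[keep]; bin <- bin[keep]
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    xb <- x[bin == b]; yb <- y[bin == b]
    n <- length(yb)
    data.frame(bin = b, mean_x = mean(xb), mean_y = mean(yb),
               se_y = if (n > 1L) stats::sd(yb) / sqrt(n) else 0,
               n = n, singleton = n == 1L)
  }))
  rownames(out) <- NULL
  out
}
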