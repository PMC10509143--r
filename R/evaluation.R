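#' Regression error metrics for Hb-loss predictions
#'
#' `mae()` is the mean absolute error `(1/n) * sum(|yhat - y|)` (mg);
#' `mape()` is the mean absolute percentage error
#' `(100/n) * sum(|yhat - y| / y)` (percent), defined only for strictly
#' positive actual values; `r2()` is the coefficient of determination
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, which is 1 for a perfect
#' prediction, 0 for the mean predictor and negative for anything worse.
#'
#' @param actual,predicted equal-length numeric vectors (mg).
#' @return A single number.
#' @export
mae <- function(actual, predicted) {
  check_pairs(actual, predicted)
  mean(abs(predicted - actual))
}

#' @rdname mae
#' @export
mape <- function(actual, predicted) {
  check_pairs(actual, predicted)
  zero <- which(actual == 0)
  if (length(zero) > 0L) {
    stop(sprintf(paste0("MAPE is undefined when an actual value is 0 ",
                        "(first offending index: %d)"), zero[1]),
         call. = FALSE)
  }
  100 * mean(abs((predicted - actual) / actual))
}

#' @rdname mae
#' @export
r2 <- function(actual, predicted) {
  check_pairs(actual, predicted)
  if (length(actual) < 2L) {
    stop("R^2 needs at least 2 observations", call. = FALSE)
  }
  tss <- sum((actual - mean(actual))^2)
  if (tss == 0) {
    stop("R^2 is undefined when all actual values are equal (zero total sum ",
         "of squares)", call. = FALSE)
  }
  1 - sum((actual - predicted)^2) / tss
}

check_pairs <- function(actual, predicted) {
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  if (length(actual) != length(predicted)) {
    stop(sprintf("length mismatch: %d actual vs %d predicted",
                 length(actual), length(predicted)), call. = FALSE)
  }
  invisible(TRUE)
}

#' All three error metrics at once
#'
#' @inheritParams mae
#' @return Object of class `metric_set`: list with `mae` (mg), `mape`
#'   (percent) and `r2`.
#' @export
metric_set <- function(actual, predicted) {
  structure(list(mae = mae(actual, predicted),
                 mape = mape(actual, predicted),
                 r2 = r2(actual, predicted),
                 n = length(actual)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("MAE %.4g mg | MAPE %.4g%% | R^2 %.4g (n = %d)\n",
              x$mae, x$mape, x$r2, x$n))
  invisible(x)
}

#' Bland--Altman agreement analysis
#'
#' Quantifies the agreement between predicted and actual Hb losses through
#' the paired differences `d_i = predicted_i - actual_i`: the bias is
#' `mean(d)`, and the limits of agreement (LOA) are `bias +/- z * sd(d)`
#' (sample SD, divisor n-1), the interval expected to contain about 95% of
#' differences at the default `z = 1.96`. With `loa_mode = "percentile"` the
#' LOA are instead the empirical 2.5th/97.5th percentiles of the
#' differences (a distribution-free alternative).
#'
#' Two confidence-interval dialects are available for the bias and both LOA:
#' `ci_mode = "pooled"` (default) uses the half-width `z * sd / sqrt(n)` for
#' all three intervals, the convention under which the three printed CIs of
#' a report share one width; `ci_mode = "textbook"` keeps
#' `z * sd / sqrt(n)` for the bias but inflates the LOA half-widths by
#' `sqrt(3)`, the classical large-sample variance of `mean +/- z * sd`.
#'
#' @param predicted,actual equal-length numeric vectors (mg).
#' @param z normal quantile for the limits (default 1.96).
#' @param loa_mode `"parametric"` (bias +/- z*sd) or `"percentile"`.
#' @param ci_mode `"pooled"` or `"textbook"` (see Details).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper` (each
#'   `c(lo, hi)`, mg), `n`, plus the modes used. In parametric mode the
#'   limits satisfy `loa_lower + loa_upper == 2 * bias` exactly.
#' @export
bland_altman <- function(predicted, actual, z = 1.96,
                         loa_mode = c("parametric", "percentile"),
                         ci_mode = c("pooled", "textbook")) {
  check_pairs(actual, predicted)
  loa_mode <- match.arg(loa_mode)
  ci_mode <- match.arg(ci_mode)
  n <- length(actual)
  if (n < 3L) {
    stop("Bland-Altman analysis needs at least 3 paired observations",
         call. = FALSE)
  }
  d <- predicted - actual
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  if (loa_mode == "parametric") {
    loa_lower <- bias - z * sd_diff
    loa_upper <- bias + z * sd_diff
  } else {
    qs <- unname(stats::quantile(d, c(0.025, 0.975), type = 7))
    loa_lower <- qs[1]
    loa_upper <- qs[2]
  }
  hw_bias <- z * sd_diff / sqrt(n)
  hw_loa <- if (ci_mode == "pooled") hw_bias else hw_bias * sqrt(3)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_lower = loa_lower, loa_upper = loa_upper,
         ci_bias = c(bias - hw_bias, bias + hw_bias),
         ci_loa_lower = c(loa_lower - hw_loa, loa_lower + hw_loa),
         ci_loa_upper = c(loa_upper - hw_loa, loa_upper + hw_loa),
         n = n, z = z, loa_mode = loa_mode, ci_mode = ci_mode,
         differences = d, means = (predicted + actual) / 2),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.4g (95%% CI %.4g, %.4g)", v, ci[1], ci[2])
  cat(sprintf("Bland-Altman agreement (n = %d, %s LOA)\n", x$n, x$loa_mode))
  cat("  Bias:      ", fmt(x$bias, x$ci_bias), "mg\n")
  cat("  Lower LOA: ", fmt(x$loa_lower, x$ci_loa_lower), "mg\n")
  cat("  Upper LOA: ", fmt(x$loa_upper, x$ci_loa_upper), "mg\n")
  invisible(x)
}

#' Bland--Altman scatter of differences against means
#'
#' Draws the paired differences against the pair means with horizontal lines
#' at the bias and both limits of agreement.
#'
#' @param x a [bland_altman()] report.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of predicted and actual Hb loss (mg)",
                 ylab = "Predicted - actual (mg)", pch = 16,
                 col = grDevices::adjustcolor("black", 0.6), ...)
  graphics::abline(h = x$bias, col = "red", lty = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "blue", lty = 2)
  invisible(x)
}

#' Recover the unprinted limit of agreement from its mirror
#'
#' In parametric Bland--Altman analysis the limits are symmetric about the
#' bias, so either limit determines the other:
#' `other = 2 * bias - known_limit`. Useful for checking the internal
#' consistency of reported agreement tables.
#'
#' @param bias mean difference (mg).
#' @param known_limit one limit of agreement (mg).
#' @return The mirrored limit (mg).
#' @examples
#' ba_mirror_limit(1.343, 32.5)  # -29.814
#' @export
ba_mirror_limit <- function(bias, known_limit) 2 * bias - known_limit

#' Pairwise model-performance comparison table
#'
#' For every ordered pair of models, tabulates how much the second model
#' improves on the first: a drop in MAE (mg) and MAPE (percentage points)
#' and a rise in R^2 are positive improvements.
#'
#' @param metrics named list of [metric_set()] objects (>= 2 models).
#' @return data.frame with columns `baseline`, `model`,
#'   `mae_improvement_mg`, `mape_improvement_pct`, `r2_improvement`.
#' @export
compare_models <- function(metrics) {
  if (length(metrics) < 2L) {
    stop("need at least two models to compare", call. = FALSE)
  }
  nms <- names(metrics)
  if (is.null(nms) || any(nms == "")) {
    stop("`metrics` must be a named list", call. = FALSE)
  }
  rows <- list()
  for (a in nms) for (b in nms) {
    rows[[length(rows) + 1L]] <- data.frame(
      baseline = a, model = b,
      mae_improvement_mg = metrics[[a]]$mae - metrics[[b]]$mae,
      mape_improvement_pct = metrics[[a]]$mape - metrics[[b]]$mape,
      r2_improvement = metrics[[b]]$r2 - metrics[[a]]$r2,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
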