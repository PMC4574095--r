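#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-country (or per-study) effect estimates with the moment-based
#' DerSimonian-Laird estimator. With fixed-effect weights
#' \eqn{w_i = 1/SE_i^2} and \eqn{\theta_F = \sum w_i \theta_i / \sum w_i}:
#' \deqn{Q = \sum w_i (\theta_i - \theta_F)^2, \qquad
#'       \tau^2 = \max\!\left(0, \frac{Q - (k-1)}
#'                 {\sum w_i - \sum w_i^2 / \sum w_i}\right),}
#' random-effects weights \eqn{w_i^* = 1/(SE_i^2 + \tau^2)} give the pooled
#' estimate, \eqn{I^2 = \max(0, 100\,(Q - (k-1))/Q)} quantifies the share of
#' total variation due to between-group heterogeneity, and the heterogeneity
#' p-value comes from the chi-square distribution with k-1 degrees of
#' freedom. When \eqn{\tau^2 = 0} the pooling reduces to the fixed-effect
#' inverse-variance average.
#'
#' @param estimate Numeric vector of group estimates (length k >= 2).
#' @param se Positive standard errors, same length.
#' @param labels Optional group labels.
#' @return An object of class `meta_result`: `groups` tibble (label,
#'   estimate, se, 95% CI, fixed and random weight percentages), `pooled`,
#'   `pooled_se`, `ci_low`, `ci_high`, `k`, `Q`, `df`, `tau2`, `I2`,
#'   `p_heterogeneity`.
#' @examples
#' meta_analyze(c(0.2, 0.6), c(0.1, 0.1)) # Q = 8, I2 = 87.5, pooled = 0.4
#' @export
meta_analyze <- function(estimate, se, labels = NULL) {
  k <- length(estimate)
  if (k < 2L) stop("need at least 2 groups to pool", call. = FALSE)
  if (length(se) != k) stop("estimate and se lengths differ", call. = FALSE)
  if (anyNA(estimate) || anyNA(se) || any(se <= 0)) {
    stop("estimates must be non-missing and SEs strictly positive",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("group", seq_len(k))

  w <- 1 / se^2
  theta_f <- sum(w * estimate) / sum(w)
  Q <- sum(w * (estimate - theta_f)^2)
  df <- k - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  I2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * estimate) / sum(wr)
  pooled_se <- sqrt(1 / sum(wr))
  p_het <- stats::pchisq(Q, df, lower.tail = FALSE)

  structure(
    list(groups = tibble::tibble(
           label = labels, estimate = estimate, se = se,
           ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
           weight_fixed_pct = 100 * w / sum(w),
           weight_random_pct = 100 * wr / sum(wr)),
         pooled = pooled, pooled_se = pooled_se,
         ci_low = pooled - 1.96 * pooled_se,
         ci_high = pooled + 1.96 * pooled_se,
         k = k, Q = Q, df = df, tau2 = tau2, I2 = I2,
         p_heterogeneity = p_het),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("<meta_result> k = %d groups, random-effects (DL)\n", x$k))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-12s %+.*f [%+.*f, %+.*f]  w = %.1f%%\n",
                g$label[i], digits, g$estimate[i], digits, g$ci_low[i],
                digits, g$ci_high[i], g$weight_random_pct[i]))
  }
  cat(sprintf("  pooled       %+.*f [%+.*f, %+.*f]\n", digits, x$pooled,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  Q = %.3f (df = %d, p = %.3g), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$p_heterogeneity, x$tau2, x$I2))
  invisible(x)
}

#' Forest-plot data table for a meta-analysis
#'
#' Flattens a `meta_result` into a CSV-ready table: one row per group plus a
#' pooled row, with estimate, SE, CI bounds and random-effects weights;
#' heterogeneity statistics ride along as columns on the pooled row.
#'
#' @param x A `meta_result`.
#' @return A tibble.
#' @export
forest_data <- function(x) {
  stopifnot(inherits(x, "meta_result"))
  g <- x$groups
  pooled <- tibble::tibble(
    label = "pooled (RE)", estimate = x$pooled, se = x$pooled_se,
    ci_low = x$ci_low, ci_high = x$ci_high,
    weight_fixed_pct = NA_real_, weight_random_pct = 100,
    Q = x$Q, df = as.numeric(x$df), tau2 = x$tau2, I2 = x$I2,
    p_heterogeneity = x$p_heterogeneity)
  g$Q <- NA_real_; g$df <- NA_real_; g$tau2 <- NA_real_; g$I2 <- NA_real_
  g$p_heterogeneity <- NA_real_
  rbind(g, pooled)
}
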