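# Rest-stress cohort statistics: Shapiro-Wilk-gated paired comparisons and
# correlations, dual-form (mean +/- SD vs median [IQR]) descriptives, and
# the correlation-strength classification. Two-sided tests at alpha = 0.05
# throughout; no multiple-testing correction.

#' Relative rest-to-stress difference, percent
#'
#' `(stress - rest) / rest * 100`. Undefined where `rest == 0`; such
#' entries are returned as `NA` with a warning rather than an error, so a
#' single degenerate subject does not abort a cohort run.
#'
#' @param rest,stress Numeric vectors, same units.
#' @return Percent change, same length.
#' @export
relative_difference <- function(rest, stress) {
  stopifnot(length(rest) == length(stress))
  out <- (stress - rest) / rest * 100
  if (any(rest == 0, na.rm = TRUE)) {
    warning("relative difference undefined where rest == 0; returning NA")
    out[rest == 0] <- NA_real_
  }
  out
}

#' Shapiro-Wilk normality gate
#'
#' @param values Numeric, n >= 3 after removing `NA`.
#' @param alpha Gate level.
#' @return List with `p_value` and `is_normal` (`p >= alpha`). A constant
#'   vector is degenerate for the test and is reported as non-normal with
#'   `p_value = NA`.
#' @export
normality_test <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("normality test needs at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0)
    return(list(p_value = NA_real_, is_normal = FALSE))
  p <- stats::shapiro.test(values)$p.value
  list(p_value = p, is_normal = p >= alpha)
}

iqr_bounds <- function(x) stats::quantile(x, c(0.25, 0.75), names = FALSE,
                                          type = 7)

#' Dual-form descriptive summary
#'
#' Reports mean +/- SD when the sample passes the Shapiro-Wilk gate, and
#' median [IQR] otherwise; samples too small for the gate (n < 3) default
#' to the median form. Sample (n - 1) SD.
#'
#' @param values Numeric vector.
#' @param alpha Normality gate level.
#' @return List with `n`, `form` (`"mean_sd"` or `"median_iqr"`), `mean`,
#'   `sd`, `median`, `iqr` (length-2 quartiles), `normality_p`, and
#'   `label`, a formatted `"m +/- s"` / `"med [q1-q3]"` string.
#' @export
describe <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("cannot describe an empty sample", call. = FALSE)
  gate <- if (n >= 3L) normality_test(values, alpha)
  else list(p_value = NA_real_, is_normal = FALSE)
  q <- iqr_bounds(values)
  form <- if (gate$is_normal) "mean_sd" else "median_iqr"
  label <- if (form == "mean_sd")
    sprintf("%.3g ± %.3g", mean(values), stats::sd(values))
  else sprintf("%.3g [%.3g-%.3g]", stats::median(values), q[1], q[2])
  list(n = n, form = form, mean = mean(values), sd = stats::sd(values),
       median = stats::median(values), iqr = q,
       normality_p = gate$p_value, label = label)
}

#' Paired rest-stress comparison with normality-gated test choice
#'
#' Computes per-subject differences `d = stress - rest`, gates on the
#' Shapiro-Wilk test of `d`: paired t-test when normal, Wilcoxon
#' signed-rank otherwise (exact distribution for n <= 25, normal
#' approximation with continuity correction above). The difference and the
#' relative difference are summarised in the matching dual form. When all
#' differences are zero both tests are degenerate; p = 1 is returned with
#' a warning.
#'
#' @param rest,stress Paired numeric vectors; pairs with `NA` are dropped.
#' @param alpha Normality gate level.
#' @return An object of class `comparison_result`: list with `n`,
#'   `test_used`, `p_value`, `normality_p`, `diff` and `relative_diff`
#'   ([describe()] summaries of d and of the percent difference).
#' @export
paired_compare <- function(rest, stress, alpha = 0.05) {
  stopifnot(length(rest) == length(stress))
  keep <- !is.na(rest) & !is.na(stress)
  rest <- rest[keep]; stress <- stress[keep]
  n <- length(rest)
  if (n < 3L) stop("paired comparison needs at least 3 pairs", call. = FALSE)
  d <- stress - rest
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    res <- list(n = n, test_used = "none_degenerate", p_value = 1,
                normality_p = NA_real_,
                diff = describe(d), relative_diff = NULL)
    class(res) <- "comparison_result"
    return(res)
  }
  gate <- normality_test(d, alpha)
  if (isTRUE(gate$is_normal)) {
    test_used <- "paired_t"
    p <- stats::t.test(stress, rest, paired = TRUE)$p.value
  } else {
    test_used <- "wilcoxon_signed_rank"
    p <- suppressWarnings(
      stats::wilcox.test(stress, rest, paired = TRUE,
                         exact = n <= 25, correct = TRUE))$p.value
  }
  rel <- suppressWarnings(relative_difference(rest, stress))
  res <- list(n = n, test_used = test_used, p_value = p,
              normality_p = gate$p_value,
              diff = describe(d, alpha),
              relative_diff = if (all(is.na(rel))) NULL
                              else describe(rel[!is.na(rel)], alpha))
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("paired comparison (n = %d): %s, p = %.3g\n",
              x$n, x$test_used, x$p_value))
  cat(sprintf("  difference: %s\n", x$diff$label))
  if (!is.null(x$relative_diff))
    cat(sprintf("  relative difference: %s %%\n", x$relative_diff$label))
  invisible(x)
}

#' Correlation-strength classification
#'
#' Classifies |r|: > 0.95 excellent; (0.85, 0.95] strong; (0.70, 0.85]
#' good; [0.5, 0.70] moderate; < 0.5 poor. Values exactly on a boundary
#' fall in the lower-strength interval.
#'
#' @param r Correlation coefficient, |r| <= 1.
#' @return One of `"excellent"`, `"strong"`, `"good"`, `"moderate"`,
#'   `"poor"`.
#' @export
classify_correlation <- function(r) {
  if (!is.finite(r) || abs(r) > 1)
    stop("correlation coefficient must lie in [-1, 1]", call. = FALSE)
  a <- abs(r)
  if (a > 0.95) "excellent"
  else if (a > 0.85) "strong"
  else if (a > 0.70) "good"
  else if (a >= 0.5) "moderate"
  else "poor"
}

#' Normality-gated correlation
#'
#' By default, Pearson's correlation when both variables pass the
#' Shapiro-Wilk gate and Spearman's rank correlation otherwise; two-sided
#' p-value and strength classification of |r|. The gate can be bypassed by
#' requesting a method explicitly.
#'
#' @param x,y Paired numeric vectors; pairs with `NA` are dropped.
#' @param alpha Normality gate level.
#' @param method `"auto"` (gate on normality), `"pearson"` or
#'   `"spearman"`.
#' @return An object of class `correlation_result`: list with `n`, `r`,
#'   `p_value`, `method` (`"pearson"` / `"spearman"`) and
#'   `strength_label`.
#' @export
correlate <- function(x, y, alpha = 0.05,
                      method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("correlation needs at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a zero-variance variable",
         call. = FALSE)
  if (method == "auto")
    method <- if (normality_test(x, alpha)$is_normal &&
                  normality_test(y, alpha)$is_normal) "pearson"
              else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  res <- list(n = n, r = unname(ct$estimate), p_value = ct$p.value,
              method = method,
              strength_label = classify_correlation(unname(ct$estimate)))
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation (n = %d): r = %.3f (%s), p = %.3g\n",
              x$method, x$n, x$r, x$strength_label, x$p_value))
  invisible(x)
}
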