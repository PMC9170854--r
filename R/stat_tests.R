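stat_test_result <- function(test_name, statistic, p_value, alpha,
                             transform = "raw", df = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = if (is.null(df)) NA_real_ else unname(df),
                 p_value = unname(p_value), alpha = alpha,
                 reject = unname(p_value) < alpha, transform = transform),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s data): %s at alpha = %g\n",
              x$test_name, x$statistic, x$p_value, x$transform,
              if (x$reject) "reject normality/null" else "no rejection",
              x$alpha))
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a sample against a normal distribution, runnable on
#' raw or log-transformed data. By default the normal's mean and SD are
#' estimated from the sample and the classical asymptotic KS p-value is
#' reported; the Lilliefors correction (which accounts for the estimated
#' parameters) is available behind the `lilliefors` flag.
#'
#' @param values numeric sample (>= 5 values unless `mean` and `sd` are both
#'   supplied).
#' @param transform `"raw"` or `"log"`; log requires strictly positive data.
#' @param mean,sd optional reference-normal parameters; when supplied the
#'   sample-size guard is relaxed.
#' @param alpha significance level (default 0.05).
#' @param lilliefors use `nortest::lillie.test()` instead of the plain KS
#'   test.
#' @return a `stat_test_result` with the D statistic and p-value.
#' @export
ks_normality <- function(values, transform = c("raw", "log"),
                         mean = NULL, sd = NULL, alpha = 0.05,
                         lilliefors = FALSE) {
  transform <- match.arg(transform)
  if (transform == "log") {
    if (any(values <= 0))
      stop("log transform requires strictly positive values")
    values <- log(values)
  }
  supplied <- !is.null(mean) && !is.null(sd)
  if (!supplied && length(values) < 5L)
    stop("at least 5 values are required when the normal parameters are estimated")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the Lilliefors variant requires the 'nortest' package")
    ks <- nortest::lillie.test(values)
  } else {
    m <- if (supplied) mean else base::mean(values)
    s <- if (supplied) sd else stats::sd(values)
    ks <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean = m, sd = s, exact = FALSE))
  }
  stat_test_result("ks_normality", ks$statistic, ks$p.value, alpha, transform)
}

#' Welch two-sample t-test
#'
#' Two-sample t-test assuming unequal variances (Welch-Satterthwaite degrees
#' of freedom), two-sided.
#'
#' @param a,b numeric samples, each with >= 2 values.
#' @param alpha significance level (default 0.05).
#' @return a `stat_test_result` with the t statistic, df and p-value.
#' @export
welch_t_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  stat_test_result("welch_t", tt$statistic, tt$p.value, alpha,
                   df = tt$parameter)
}

#' Pairwise comparisons of full-length CoV estimates
#'
#' Welch tests on the per-subset estimate populations from
#' [estimate_at_full_length()]: (i) adjacent sphere pairs within each metric
#' (5 pairs x 5 metrics) and (ii) all metric pairs within each sphere
#' (10 pairs x 6 spheres). No multiple-testing correction is applied to the
#' significance flag; a Holm-adjusted p-value column (within each comparison
#' family) is emitted alongside for transparency.
#'
#' @param aggregates result of [estimate_at_full_length()].
#' @param alpha significance level (default 0.05).
#' @return data.frame of comparisons with t, df, p, `significant` and
#'   `p_holm`.
#' @export
compare_table <- function(aggregates, alpha = 0.05) {
  est <- aggregates$estimates
  metrics <- sort(unique(est$metric))
  spheres <- unique(est$sphere_id)
  diam <- as.numeric(sub("mm$", "", spheres))
  spheres <- spheres[order(diam)]
  if (length(metrics) < 2L || length(spheres) < 2L)
    stop("compare_table needs at least two metrics and two spheres")
  pop <- function(m, s) est$sd2_percent[est$metric == m & est$sphere_id == s]
  rows <- list()
  # adjacent sphere pairs, per metric
  for (m in metrics) for (i in seq_len(length(spheres) - 1L)) {
    tt <- welch_t_test(pop(m, spheres[i]), pop(m, spheres[i + 1]), alpha)
    rows[[length(rows) + 1]] <- data.frame(
      family = "adjacent_spheres", metric_a = m, metric_b = m,
      sphere_a = spheres[i], sphere_b = spheres[i + 1],
      t = tt$statistic, df = tt$df, p_value = tt$p_value,
      stringsAsFactors = FALSE)
  }
  # all metric pairs, per sphere
  for (s in spheres) for (i in seq_len(length(metrics) - 1L))
    for (j in (i + 1L):length(metrics)) {
      tt <- welch_t_test(pop(metrics[i], s), pop(metrics[j], s), alpha)
      rows[[length(rows) + 1]] <- data.frame(
        family = "metric_pairs", metric_a = metrics[i], metric_b = metrics[j],
        sphere_a = s, sphere_b = s,
        t = tt$statistic, df = tt$df, p_value = tt$p_value,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$p_holm <- NA_real_
  for (fam in unique(out$family)) {
    idx <- out$family == fam
    out$p_holm[idx] <- stats::p.adjust(out$p_value[idx], method = "holm")
  }
  rownames(out) <- NULL
  out
}
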