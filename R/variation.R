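#' Coefficient of variation of a sample
#'
#' The standard deviation divided by the mean, in percent. The sample
#' standard deviation (n - 1 denominator) is used.
#'
#' @param values numeric vector, length >= 2, with non-zero mean.
#' @return list with `mean`, `sd` and `cov_percent`.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L)
    stop("at least 2 values are required to compute a standard deviation")
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  s <- stats::sd(values)
  list(mean = m, sd = s, cov_percent = 100 * s / m)
}

#' Extrapolate a standard deviation across reconstruction lengths
#'
#' The inverse square-root law of counting statistics:
#' `SD2 = SD1 * sqrt(RL1 / RL2)`. Because the law is a pure ratio it applies
#' identically to a raw SD or to a coefficient of variation used as SD1.
#'
#' @param sd1 measured SD (or CoV%) at reconstruction length `rl1_s`.
#' @param rl1_s source reconstruction length (s).
#' @param rl2_s target reconstruction length (s).
#' @return the extrapolated SD (or CoV%) at `rl2_s`.
#' @export
extrapolate_cov <- function(sd1, rl1_s, rl2_s) {
  if (any(sd1 <= 0) || any(rl1_s <= 0) || any(rl2_s <= 0))
    stop("sd1, rl1_s and rl2_s must all be positive")
  sd1 * sqrt(rl1_s / rl2_s)
}

#' Per-subset coefficient of variation table
#'
#' Summarizes a long metric table into one row per
#' (metric, sphere, reconstruction length): number of frames, mean, SD and
#' CoV%.
#'
#' @param records data.frame from [compute_all_metrics()].
#' @return data.frame with columns `metric`, `sphere_id`, `rl_s`,
#'   `n_frames`, `mean_value`, `sd_value`, `cov_percent`. Cells with a
#'   single frame carry `NA` SD and CoV (a standard deviation needs two
#'   values); downstream estimation rejects such cells by name.
#' @export
cov_by_subset <- function(records) {
  key <- interaction(records$metric, records$sphere_id, records$rl_s,
                     drop = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    cv <- if (nrow(p) >= 2L) coefficient_of_variation(p$value_kbq_ml)
          else list(mean = mean(p$value_kbq_ml), sd = NA_real_,
                    cov_percent = NA_real_)
    data.frame(metric = p$metric[1], sphere_id = p$sphere_id[1],
               rl_s = p$rl_s[1], n_frames = nrow(p),
               mean_value = cv$mean, sd_value = cv$sd,
               cov_percent = cv$cov_percent, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$metric, out$sphere_id, out$rl_s), ]
  rownames(out) <- NULL
  out
}

# Verify that a CoV table has every (metric, sphere, RL) cell with n >= 2.
check_cov_complete <- function(cov_tab, rls) {
  metrics <- unique(cov_tab$metric)
  spheres <- unique(cov_tab$sphere_id)
  for (m in metrics) for (s in spheres) for (rl in rls) {
    row <- cov_tab[cov_tab$metric == m & cov_tab$sphere_id == s &
                     cov_tab$rl_s == rl, ]
    if (nrow(row) == 0L)
      stop(sprintf("missing records for metric %s, sphere %s, RL=%g s",
                   m, s, rl))
    if (row$n_frames < 2L)
      stop(sprintf("subset RL=%g s has fewer than 2 frames for %s/%s",
                   rl, m, s))
  }
  invisible(TRUE)
}

#' Estimate the coefficient of variation at the full reconstruction length
#'
#' For each (metric, sphere), the CoV measured within each subset is
#' extrapolated to the target reconstruction length (default 150 s) by the
#' square-root law, yielding one estimate per source subset (14 for the
#' default schedules). The mean and SD of these estimates quantify the
#' expected technical variation at full length and the spread of the
#' estimation itself.
#'
#' @param records data.frame from [compute_all_metrics()].
#' @param schedules list of [make_schedule()] results that produced the
#'   records (defines the expected source RLs); if `NULL`, the RLs present
#'   in the records are used.
#' @param rl2_s target reconstruction length (s, default 150).
#' @return list with `estimates` (one row per metric, sphere and source RL)
#'   and `summary` (one row per metric and sphere with `n_estimates`,
#'   `mean_estimate`, `sd_of_estimates`).
#' @export
estimate_at_full_length <- function(records, schedules = NULL, rl2_s = 150) {
  cov_tab <- cov_by_subset(records)
  rls <- if (is.null(schedules)) sort(unique(cov_tab$rl_s))
         else sort(vapply(schedules, function(s) s$rl_s, 0))
  check_cov_complete(cov_tab, rls)
  est <- cov_tab[cov_tab$rl_s %in% rls, ]
  est$rl2_s <- rl2_s
  est$sd2_percent <- extrapolate_cov(est$cov_percent, est$rl_s, rl2_s)
  est <- est[, c("metric", "sphere_id", "rl_s", "n_frames", "cov_percent",
                 "rl2_s", "sd2_percent")]
  key <- interaction(est$metric, est$sphere_id, drop = TRUE)
  summ <- do.call(rbind, lapply(split(est, key), function(p) {
    data.frame(metric = p$metric[1], sphere_id = p$sphere_id[1],
               rl2_s = rl2_s, n_estimates = nrow(p),
               mean_estimate = mean(p$sd2_percent),
               sd_of_estimates = stats::sd(p$sd2_percent),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$metric, summ$sphere_id), ]
  rownames(summ) <- NULL
  rownames(est) <- NULL
  list(estimates = est, summary = summ)
}

#' Cross-estimate each subset's CoV from all the others
#'
#' For each target reconstruction length among the schedules, the CoV is
#' estimated from each of the other source subsets by the square-root law
#' (13 estimates per target for the default 14 schedules), alongside the
#' directly measured CoV at the target.
#'
#' @inheritParams estimate_at_full_length
#' @return list with `estimates` (metric, sphere, target RL, source RL,
#'   estimate) and `summary` (per metric, sphere, target RL: number of
#'   estimates, mean, SD, and the measured CoV at the target).
#' @export
cross_estimate_matrix <- function(records, schedules = NULL) {
  cov_tab <- cov_by_subset(records)
  rls <- if (is.null(schedules)) sort(unique(cov_tab$rl_s))
         else sort(vapply(schedules, function(s) s$rl_s, 0))
  if (length(rls) < 2L)
    stop("cross-estimation requires at least two schedules")
  check_cov_complete(cov_tab, rls)
  est_rows <- list(); sum_rows <- list()
  key <- interaction(cov_tab$metric, cov_tab$sphere_id, drop = TRUE)
  for (p in split(cov_tab[cov_tab$rl_s %in% rls, ], key, drop = TRUE)) {
    for (target in rls) {
      src <- p[p$rl_s != target, ]
      est <- extrapolate_cov(src$cov_percent, src$rl_s, target)
      est_rows[[length(est_rows) + 1]] <- data.frame(
        metric = p$metric[1], sphere_id = p$sphere_id[1],
        target_rl_s = target, source_rl_s = src$rl_s,
        estimate_percent = est, stringsAsFactors = FALSE)
      sum_rows[[length(sum_rows) + 1]] <- data.frame(
        metric = p$metric[1], sphere_id = p$sphere_id[1],
        target_rl_s = target, n_estimates = nrow(src),
        mean_estimate = mean(est), sd_of_estimates = stats::sd(est),
        measured_cov_percent = p$cov_percent[p$rl_s == target],
        stringsAsFactors = FALSE)
    }
  }
  list(estimates = do.call(rbind, est_rows),
       summary = do.call(rbind, sum_rows))
}
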