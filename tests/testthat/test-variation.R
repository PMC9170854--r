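test_that("coefficient of variation uses the sample SD and percent scale", {
  expect_equal(coefficient_of_variation(c(5, 5, 5))$cov_percent, 0)
  cv <- coefficient_of_variation(c(1, 2, 3))
  expect_equal(cv$mean, 2)
  expect_equal(cv$sd, 1)          # n - 1 denominator
  expect_equal(cv$cov_percent, 50)
  # scale invariance
  expect_equal(coefficient_of_variation(c(1, 2, 3) * 17.3)$cov_percent, 50)
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("square-root extrapolation obeys its algebraic identities", {
  expect_equal(extrapolate_cov(12.5, 20, 20), 12.5)       # identity
  expect_equal(extrapolate_cov(10, 10, 40), 5)            # 4x time halves SD
  expect_equal(extrapolate_cov(30, 4, 150), 30 * sqrt(4 / 150))
  expect_equal(extrapolate_cov(30, 4, 150), 4.8990, tolerance = 1e-4)
  # round trip is exact to floating point
  sd1 <- 7.234567
  back <- extrapolate_cov(extrapolate_cov(sd1, 4, 150), 150, 4)
  expect_equal(back, sd1, tolerance = 1e-12)
  expect_error(extrapolate_cov(-1, 4, 150), "positive")
  expect_error(extrapolate_cov(10, 0, 150), "positive")
})

# build a long metric table whose subset CoVs follow cov_fun(RL) exactly or
# stochastically (normal draws around a common mean)
synthetic_records <- function(cov_fun, schedules = default_schedules(),
                              metrics = "Max3D", spheres = "10mm",
                              mean_value = 1000, seed = NULL, exact = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sch in schedules) {
    n <- nrow(sch$intervals)
    target_sd <- mean_value * cov_fun(sch$rl_s) / 100
    for (m in metrics) for (s in spheres) {
      v <- if (exact) {
        # n values with exactly the requested mean and SD
        base <- scale(seq_len(n))[, 1]
        mean_value + base * target_sd
      } else {
        stats::rnorm(n, mean_value, target_sd)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sphere_id = s, metric = m, frame_index = seq_len(n),
        rl_s = sch$rl_s, value_kbq_ml = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("records that satisfy the law exactly give coincident estimates", {
  rec <- synthetic_records(function(rl) 30 * sqrt(4 / rl), exact = TRUE)
  agg <- estimate_at_full_length(rec, rl2_s = 150)
  expect_equal(agg$summary$n_estimates, 14)
  expect_equal(agg$summary$mean_estimate, 30 * sqrt(4 / 150),
               tolerance = 1e-10)
  expect_equal(agg$summary$sd_of_estimates, 0, tolerance = 1e-8)
})

test_that("stochastic records recover the full-length CoV near 4.9%", {
  rec <- synthetic_records(function(rl) 30 * sqrt(4 / rl), seed = 8)
  agg <- estimate_at_full_length(rec, rl2_s = 150)
  expect_equal(agg$summary$mean_estimate, 4.899,
               tolerance = 3 * agg$summary$sd_of_estimates / sqrt(14) / 4.899)
})

test_that("missing subsets are reported by name", {
  rec <- synthetic_records(function(rl) 10, seed = 1)
  gap <- rec[rec$rl_s != 17, ]
  expect_error(estimate_at_full_length(gap, default_schedules()), "RL=17")
  single <- rec[rec$rl_s != 4 | rec$frame_index == 1, ]
  expect_error(estimate_at_full_length(single, default_schedules()),
               "RL=4")
})

test_that("cross-estimation yields 13 estimates per target and the law's identity", {
  rec <- synthetic_records(function(rl) 20 * sqrt(10 / rl), seed = 3)
  cr <- cross_estimate_matrix(rec, default_schedules())
  expect_equal(unique(cr$summary$n_estimates), 13)
  expect_equal(nrow(cr$summary), 14)
  # SD2(a -> b) * SD2(b -> a) = SD1(a) * SD1(b)
  cov_tab <- cov_by_subset(rec)
  est <- cr$estimates
  ab <- est[est$source_rl_s == 4 & est$target_rl_s == 30, "estimate_percent"]
  ba <- est[est$source_rl_s == 30 & est$target_rl_s == 4, "estimate_percent"]
  sd1a <- cov_tab$cov_percent[cov_tab$rl_s == 4]
  sd1b <- cov_tab$cov_percent[cov_tab$rl_s == 30]
  expect_equal(ab * ba, sd1a * sd1b, tolerance = 1e-12)
  # two schedules: one estimate per target
  two <- rec[rec$rl_s %in% c(4, 30), ]
  cr2 <- cross_estimate_matrix(two, list(make_schedule(150, 4),
                                         make_schedule(150, 30)))
  expect_equal(unique(cr2$summary$n_estimates), 1)
})
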