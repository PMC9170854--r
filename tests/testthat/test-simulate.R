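test_that("decay correction factor matches numerical quadrature and limits", {
  t_half <- 109.7 * 60
  # near-zero frame length: no decay elapsed
  expect_equal(decay_correction_factor(0, 1e-6, t_half), 1, tolerance = 1e-9)
  # a frame starting one half-life in: half the activity remains
  expect_equal(decay_correction_factor(t_half, 1e-6, t_half), 2,
               tolerance = 1e-9)
  # 150 s frame from t = 0 against quadrature of the decay integral
  quad <- stats::integrate(function(t) 2^(-t / t_half), 0, 150)$value / 150
  expect_equal(decay_correction_factor(0, 150, t_half), 1 / quad,
               tolerance = 1e-6)
  expect_equal(decay_correction_factor(0, 150, t_half), 1.0079,
               tolerance = 1e-3)
  expect_error(decay_correction_factor(0, 150, -1), "half_life")
  expect_error(decay_correction_factor(0, 0, t_half), "rl_s")
})

test_that("simulated voxel noise follows Poisson counting statistics", {
  truth <- uniform_volume(1, n = 22L)  # 1 kBq/ml, 0.064 ml voxels
  # sensitivity chosen so mu = 100 at RL = 1 s
  nm <- noise_model(100 / 0.064, psf_fwhm_mm = 0)
  fr <- simulate_frame(truth, 0, 1, nm, seed = 42)
  vox <- as.numeric(fr$values)
  expect_equal(sd(vox) / mean(vox), 0.10, tolerance = 0.05)
  expect_equal(mean(vox), 1, tolerance = 0.01)
})

test_that("relative noise vanishes in the high-count limit", {
  truth <- uniform_volume(5, n = 12L)
  nm <- noise_model(1e6 / (5 * 0.064), psf_fwhm_mm = 0)  # mu = 1e6 at RL 1 s
  fr <- simulate_frame(truth, 0, 1, nm, seed = 1)
  expect_true(all(abs(fr$values - 5) / 5 < 0.005))
})

test_that("quadrupling the reconstruction length halves the voxel CoV", {
  truth <- uniform_volume(1, n = 16L)
  nm <- noise_model(25 / 0.064, psf_fwhm_mm = 0)  # mu = 25 * RL
  covs <- vapply(c(1, 4), function(rl) {
    v <- vapply(1:120, function(i)
      simulate_frame(truth, 0, rl, nm, seed = 1000 * rl + i)$values[8, 8, 8],
      0)
    sd(v) / mean(v)
  }, 0)
  expect_equal(covs[1] / covs[2], 2, tolerance = 0.35)
})

test_that("voxel SD scales as RL^(-1/2) under the default correlated noise", {
  truth <- uniform_volume(10, n = 20L)
  nm <- noise_model(50 / (10 * 0.064))  # mu = 50 * RL, default post-noise PSF
  rls <- c(4, 10, 30, 150)
  sds <- vapply(rls, function(rl) {
    v <- vapply(1:100, function(i)
      simulate_frame(truth, 0, rl, nm, seed = 7000 + 200 * rl + i)$values[10, 10, 10],
      0)
    sd(v)
  }, 0)
  slope <- coef(lm(log(sds) ~ log(rls)))[2]
  expect_gt(slope, -0.55)
  expect_lt(slope, -0.45)
})

test_that("the mean simulated frame converges to the truth", {
  truth <- uniform_volume(2, n = 16L)
  nm <- noise_model(1000 / (2 * 0.064))  # mu ~ 1e3, default post-PSF
  acc <- array(0, dim(truth$values))
  for (i in 1:200)
    acc <- acc + simulate_frame(truth, 0, 1, nm, seed = 3000 + i)$values
  expect_equal(mean(acc / 200), 2, tolerance = 0.01)
})

test_that("decay correction removes the frame-start dependence of the mean", {
  truth <- uniform_volume(1, n = 16L)
  nm <- noise_model(200 / 0.064, psf_fwhm_mm = 0)
  m0 <- mean(vapply(1:100, function(i)
    mean(simulate_frame(truth, 0, 10, nm, seed = 4000 + i)$values), 0))
  m3000 <- mean(vapply(1:100, function(i)
    mean(simulate_frame(truth, 3000, 10, nm, seed = 4500 + i)$values), 0))
  expect_equal(m3000 / m0, 1, tolerance = 0.005)
})

test_that("simulation is reproducible and subsets carry their metadata", {
  truth <- uniform_volume(5, n = 12L)
  nm <- noise_model(0.5)
  sch <- list(make_schedule(20, 5), make_schedule(20, 10))
  a <- simulate_subsets(truth, sch, nm, seed = 9)
  b <- simulate_subsets(truth, sch, nm, seed = 9)
  expect_identical(a, b)
  expect_named(a, c("5", "10"))
  expect_length(a[["5"]], 4)
  expect_length(a[["10"]], 2)
  expect_equal(a[["5"]][[3]]$frame_start_s, 10)
  expect_equal(a[["5"]][[3]]$frame_duration_s, 5)
  # frames are statistically distinct (independent substreams)
  expect_false(identical(a[["5"]][[1]]$values, a[["5"]][[2]]$values))
  expect_error(simulate_subsets(truth, list(), nm, 1), "non-empty")
})

test_that("fill texture is fixed, mean-preserving and amplitude-controlled", {
  truth <- uniform_volume(10, n = 20L)
  t1 <- apply_fill_texture(truth, 3, 8, seed = 5)
  t2 <- apply_fill_texture(truth, 3, 8, seed = 5)
  expect_identical(t1$values, t2$values)
  expect_equal(mean(t1$values), 10, tolerance = 0.02)
  expect_equal(sd(t1$values) / mean(t1$values), 0.03, tolerance = 0.3)
  expect_identical(apply_fill_texture(truth, 0)$values, truth$values)
})
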