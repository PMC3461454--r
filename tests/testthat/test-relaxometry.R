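test_that("pixel fit recovers noiseless decays and the two-point closed form", {
  s <- decay_signal(100, 91.7, TSL_SCHEDULE)
  fit <- fit_monoexp_pixel(s, TSL_SCHEDULE)
  expect_true(fit$valid)
  expect_equal(fit$t1rho, 91.7, tolerance = 1e-6)
  expect_equal(fit$s0, 100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)

  # two arbitrary points: t1rho = (t2 - t1) / log(S1 / S2) exactly
  s2 <- c(80, 30)
  fit2 <- fit_monoexp_pixel(s2, c(6, 48))
  expect_equal(fit2$t1rho, (48 - 6) / log(80 / 30), tolerance = 1e-9)
})

test_that("degenerate inputs are rejected or flagged with a reason", {
  expect_error(fit_monoexp_pixel(c(1, 2, 3), c(6, 18)), "same length")
  expect_error(fit_monoexp_pixel(5, 6), "2 distinct")

  flat <- fit_monoexp_pixel(rep(100, 5), TSL_SCHEDULE)
  expect_false(flat$valid)
  expect_identical(flat$reason, "no decay")
  expect_true(is.na(flat$t1rho))

  neg <- fit_monoexp_pixel(rep(-1, 5), TSL_SCHEDULE)
  expect_false(neg$valid)
  expect_identical(neg$reason, "nonpositive")

  grow <- fit_monoexp_pixel(decay_signal(10, -50, TSL_SCHEDULE), TSL_SCHEDULE)
  expect_false(grow$valid)
  expect_identical(grow$reason, "no decay")

  # decays faster than the 1 ms lower bound are rejected, not clamped
  fast <- fit_monoexp_pixel(decay_signal(100, 0.5, TSL_SCHEDULE), TSL_SCHEDULE)
  expect_false(fast$valid)
  expect_identical(fast$reason, "bounds")
})

test_that("log-linear and nonlinear routes agree on noiseless decays", {
  for (t1 in c(10, 47.2, 91.7, 400)) {
    s <- decay_signal(50, t1, TSL_SCHEDULE)
    # independent closed-form oracle: OLS of log(signal) on TSL
    slope <- unname(coef(lm(log(s) ~ TSL_SCHEDULE))[2])
    oracle <- -1 / slope
    fit <- fit_monoexp_pixel(s, TSL_SCHEDULE)
    expect_equal(fit$t1rho, oracle, tolerance = 1e-6)
  }
})

test_that("nonlinear fit matches an independent optimizer on noisy pixels", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  for (i in 1:5) {
    s <- decay_signal(100, 60, TSL_SCHEDULE) + rnorm(5, sd = 2)
    fit <- fit_monoexp_pixel(s, TSL_SCHEDULE)
    ref <- minpack.lm::nlsLM(y ~ A * exp(-t / T1),
                             data = data.frame(y = s, t = TSL_SCHEDULE),
                             start = list(A = 100, T1 = 60))
    expect_equal(fit$t1rho, unname(coef(ref)["T1"]), tolerance = 1e-5)
    expect_equal(fit$s0, unname(coef(ref)["A"]), tolerance = 1e-5)
  }
})

test_that("fit is scale-equivariant", {
  s <- decay_signal(100, 70, TSL_SCHEDULE) + c(0.5, -0.3, 0.2, -0.1, 0.05)
  f1 <- fit_monoexp_pixel(s, TSL_SCHEDULE)
  f2 <- fit_monoexp_pixel(s * 37.5, TSL_SCHEDULE)
  expect_equal(f2$t1rho, f1$t1rho, tolerance = 1e-8)
  expect_equal(f2$s0, 37.5 * f1$s0, tolerance = 1e-8)
})

test_that("map fitting recovers tissue constants pixelwise on a noiseless phantom", {
  tr <- generate_phantom(small_phantom(noise_sigma = 0))
  s <- simulate_tsl_series(tr, tsl_ms = TSL_SCHEDULE)
  mask <- wall_mask(tr)
  map <- fit_map(s, mask)
  expect_true(all(map$valid[mask]))
  expect_true(all(!map$valid[!mask]))
  expect_true(all(is.na(map$t1rho[!mask])))
  myo <- pure_tissue_mask(tr, "myocardium")
  inf <- pure_tissue_mask(tr, "infarct")
  expect_lt(max(abs(map$t1rho[myo] - 47.2)), 0.1)
  expect_lt(max(abs(map$t1rho[inf] - 91.7)), 0.1)

  expect_error(fit_map(s, array(FALSE, dim = dim(mask))), "no voxels")
})

test_that("region mean is recovered within 3% under 2% Rician noise", {
  tr <- generate_phantom(small_phantom(noise_sigma = 0))
  s <- simulate_tsl_series(tr, tsl_ms = TSL_SCHEDULE)
  noisy <- add_noise(s, sigma = 2, seed = 17)   # 2% of s0 = 100
  inf <- pure_tissue_mask(tr, "infarct")
  expect_gte(sum(inf), 500)
  map <- fit_map(noisy, wall_mask(tr))
  st <- region_t1rho(map, inf, "infarct")
  expect_lt(abs(st$mean - 91.7) / 91.7, 0.03)
})

test_that("mean fitted T1rho is nearly unbiased at SNR 50", {
  tr <- generate_phantom(small_phantom(noise_sigma = 0))
  s <- simulate_tsl_series(tr, tsl_ms = TSL_SCHEDULE)
  myo <- pure_tissue_mask(tr, "myocardium")
  means <- vapply(1:4, function(seed) {
    noisy <- add_noise(s, sigma = 2, seed = seed)
    region_t1rho(fit_map(noisy, myo), myo)$mean
  }, numeric(1))
  expect_lt(abs(mean(means) - 47.2) / 47.2, 0.01)
})

test_that("region statistics summarize valid pixels only", {
  tr <- generate_phantom(small_phantom(noise_sigma = 0))
  s <- simulate_tsl_series(tr, tsl_ms = TSL_SCHEDULE)
  mask <- wall_mask(tr)
  map <- fit_map(s, mask)

  myo <- pure_tissue_mask(tr, "myocardium")
  st <- region_t1rho(map, myo, "remote")
  expect_equal(st$mean, 47.2, tolerance = 1e-6)
  expect_equal(st$sd, 0, tolerance = 1e-6)
  expect_equal(st$n_pixels, sum(myo))

  # hand-built two-pixel map: mean 50, sample sd sqrt(200)
  two <- map
  two$t1rho[] <- NA_real_; two$valid[] <- FALSE
  two$t1rho[1:2] <- c(40, 60); two$valid[1:2] <- TRUE
  sel <- array(FALSE, dim = dim(two$t1rho)); sel[1:4] <- TRUE
  st2 <- region_t1rho(two, sel)
  expect_equal(st2$mean, 50)
  expect_equal(st2$sd, sqrt(200), tolerance = 1e-12)
  expect_equal(st2$n_pixels, 2L)
  expect_equal(st2$n_excluded, 2L)

  expect_error(region_t1rho(map, array(FALSE, dim = dim(mask))),
               "no valid pixels")
})
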