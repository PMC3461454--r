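test_that("configuration invariants are enforced with informative errors", {
  expect_error(small_phantom(endo_radius = 15, epi_radius = 14),
               "endo_radius")
  expect_error(small_phantom(epi_radius = 30), "epi_radius")
  expect_error(small_phantom(infarct_angular_extent = 400), "\\[0, 360\\]")
  expect_error(small_phantom(infarct_transmural_profile = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(small_phantom(apical_extent = c(0, 4)), "apical_extent")
  expect_error(small_phantom(blood_radius = 5), "blood_radius")
})

test_that("analytic ground truth matches closed-form geometry", {
  # fully transmural 90 degree sector covers a quarter of the endocardium
  tr <- generate_phantom(small_phantom(infarct_angular_extent = 90))
  expect_equal(tr$true_infarct_perimeter_fraction, 0.25)
  expect_equal(tr$true_nontransmural_infarct_fraction, 0)

  # no infarct: empty label, zero volume
  tr0 <- generate_phantom(small_phantom(infarct_angular_extent = 0))
  expect_false(any(tr0$label_volume == 4L))
  expect_equal(tr0$true_infarct_volume, 0)
  expect_equal(tr0$true_infarct_perimeter_fraction, 0)

  # annulus 30/20 mm, 10 slices of 2.6 mm: V = pi (30^2 - 20^2) * 26 mm^3
  cfg <- phantom_config(n_slices = 10L, supersample_factor = 8L)
  tr2 <- generate_phantom(cfg)
  expect_equal(tr2$true_lv_myocardial_volume,
               pi * (30^2 - 20^2) * 26 / 1000, tolerance = 1e-12)
  vox_ml <- sum(tr2$label_volume >= 3L) * voxel_volume_mm3(cfg) / 1000
  expect_lt(abs(vox_ml - tr2$true_lv_myocardial_volume) /
              tr2$true_lv_myocardial_volume, 0.01)
})

test_that("partial-volume fractions sum to 1 and converge to analytic volumes", {
  tr <- generate_phantom(small_phantom())
  pv <- tr$partial_volume_maps
  sums <- pv[, , , 1] + pv[, , , 2] + pv[, , , 3] + pv[, , , 4]
  expect_lt(max(abs(sums - 1)), 1e-9)

  # voxel-count volume error shrinks as the supersampling factor grows
  err <- vapply(c(1L, 4L, 8L), function(f) {
    cfg <- small_phantom(supersample_factor = f)
    tr <- generate_phantom(cfg)
    pvsum <- sum(tr$partial_volume_maps[, , , 4]) * voxel_volume_mm3(cfg) / 1000
    abs(pvsum - tr$true_infarct_volume) / tr$true_infarct_volume
  }, numeric(1))
  expect_true(err[3] <= err[1])
  expect_lt(err[3], 0.01)
})

test_that("signal model reproduces pure-tissue decay and mixes partial volumes", {
  cfg <- small_phantom()
  tr <- generate_phantom(cfg)
  s <- simulate_tsl_series(tr, tsl_ms = c(0, 47.2))
  pure_myo <- pure_tissue_mask(tr, "myocardium")
  i <- which(pure_myo)[1]
  flat <- matrix(s$data, ncol = 2)
  expect_equal(flat[i, 1], 100, tolerance = 1e-6)
  expect_equal(flat[i, 2], 100 / exp(1), tolerance = 1e-6)

  # 50/50 myocardium-infarct voxel at TSL 48 ms: oracle is scalar arithmetic
  mix <- tr
  mix$partial_volume_maps <- array(0, dim = c(1, 1, 1, 4))
  mix$partial_volume_maps[1, 1, 1, 3] <- 0.5
  mix$partial_volume_maps[1, 1, 1, 4] <- 0.5
  sm <- simulate_tsl_series(mix, config = cfg, tsl_ms = c(6, 48))
  expected <- 0.5 * 100 * exp(-48 / 47.2) + 0.5 * 100 * exp(-48 / 91.7)
  expect_equal(sm$data[1, 1, 1, 2], expected, tolerance = 1e-12)

  # noiseless signal is strictly decreasing in TSL wherever tissue is present
  s5 <- simulate_tsl_series(tr, tsl_ms = TSL_SCHEDULE)
  flat5 <- matrix(s5$data, ncol = 5)
  body <- which(tr$partial_volume_maps[, , , 1] < 1)  # any non-background
  diffs <- flat5[body, -1] - flat5[body, -5]
  expect_true(all(diffs < 0))

  # log-ratio identity on a pure voxel
  expect_equal(log(flat5[i, 1]) - log(flat5[i, 5]),
               (TSL_SCHEDULE[5] - TSL_SCHEDULE[1]) / 47.2, tolerance = 1e-9)
})

test_that("phantom generation is deterministic and noise is seed-reproducible", {
  cfg <- small_phantom()
  tr1 <- generate_phantom(cfg)
  tr2 <- generate_phantom(cfg)
  expect_identical(tr1$partial_volume_maps, tr2$partial_volume_maps)
  expect_identical(tr1$label_volume, tr2$label_volume)

  s <- simulate_tsl_series(tr1, tsl_ms = TSL_SCHEDULE)
  n1 <- add_noise(s, sigma = 2, seed = 42)
  n2 <- add_noise(s, sigma = 2, seed = 42)
  expect_identical(n1$data, n2$data)
  n3 <- add_noise(s, sigma = 2, seed = 43)
  expect_false(identical(n1$data, n3$data))
})

test_that("noise model honours its contracts", {
  cfg <- small_phantom()
  tr <- generate_phantom(cfg)
  s <- simulate_tsl_series(tr, tsl_ms = TSL_SCHEDULE)
  expect_identical(add_noise(s, sigma = 0, seed = 1), s)
  expect_error(add_noise(s, sigma = -1, seed = 1), "non-negative")

  # Rician magnitude of a zero signal is Rayleigh with mean sigma sqrt(pi/2)
  zero <- array(0, dim = c(500, 400, 1))
  noisy <- add_noise(zero, sigma = 3, seed = 7, model = "rician")
  expect_equal(mean(noisy), 3 * sqrt(pi / 2), tolerance = 0.01)

  # gaussian model clips at zero
  g <- add_noise(zero, sigma = 3, seed = 8, model = "gaussian")
  expect_true(min(g) >= 0)
})

test_that("reference modality orders tissues and is reproducible", {
  cfg <- small_phantom(noise_sigma = 2)
  tr <- generate_phantom(cfg)
  img0 <- simulate_reference_modality(tr, sigma = 0)
  m_inf <- mean(img0[pure_tissue_mask(tr, "infarct")])
  m_bld <- mean(img0[pure_tissue_mask(tr, "blood")])
  m_myo <- mean(img0[pure_tissue_mask(tr, "myocardium")])
  expect_true(m_inf > m_bld && m_bld > m_myo)

  img1 <- simulate_reference_modality(tr, seed = 5)
  img2 <- simulate_reference_modality(tr, seed = 5)
  expect_identical(img1, img2)

  # without an infarct no myocardial voxel is hyperenhanced
  tr0 <- generate_phantom(small_phantom(infarct_angular_extent = 0))
  img <- simulate_reference_modality(tr0, seed = 9)
  myo <- img[pure_tissue_mask(tr0, "myocardium")]
  expect_true(max(myo) <= mean(myo) + 5 * sd(myo) + 1e-9 ||
                sum(myo > mean(myo) + 5 * sd(myo)) / length(myo) < 1e-3)
})
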