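# Phantom generation and the simulated observer model.

quiet_cfg <- function(...) {
  cohort_config(image_noise_sd = 0, texture_sd = 0, gradient_amp = 0, ...)
}

test_that("with zero image noise every in-mask voxel exceeds background by the contrast", {
  cfg <- quiet_cfg(tumor_contrast = 37)
  ph <- generate_phantom(cfg, patient_seed = 5)
  inside <- ph$image$values[ph$truth$indicator]
  outside <- ph$image$values[!ph$truth$indicator]
  expect_equal(min(inside) - max(outside), 37)
  expect_equal(unique(round(inside - cfg$background_level, 10)), 37)
})

test_that("phantoms and cohorts are deterministic in their seeds", {
  cfg <- cohort_config(n_patients = 1, master_seed = 9)
  p1 <- generate_phantom(cfg, 123)
  p2 <- generate_phantom(cfg, 123)
  expect_identical(p1$image$values, p2$image$values)
  expect_identical(p1$truth$indicator, p2$truth$indicator)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients[[1]]$masks[["RA2"]]$indicator,
                   c2$patients[[1]]$masks[["RA2"]]$indicator)
  # different patient seeds give different tumors
  p3 <- generate_phantom(cfg, 124)
  expect_false(identical(p1$truth$indicator, p3$truth$indicator))
})

test_that("rasterized tumor volumes track the configured distribution", {
  cfg <- cohort_config(tumor_volume_mean = 50, tumor_volume_sd = 15)
  vols <- vapply(seq_len(250), function(i)
    withr::with_seed(20000 + i, mask_volume_cm3(segrobust:::phantom_mask(cfg))),
    numeric(1))
  # truncation to [15, 100] barely moves the mean of N(50, 15); allow 3 SE
  expect_lt(abs(mean(vols) - 50), 3 * 15 / sqrt(250))
  expect_gt(stats::sd(vols), 10)
})

test_that("identity profile reproduces the truth; volume bias hits its target", {
  cfg <- quiet_cfg()
  ph <- generate_phantom(cfg, 31)
  ident <- simulate_observer_mask(ph$truth,
                                  observer_profile("o", "A", 1, 0, 0), 77)
  expect_identical(ident$indicator, ph$truth$indicator)
  shrunk <- simulate_observer_mask(ph$truth,
                                   observer_profile("o", "B", 0.66, 0, 0), 77)
  ratio <- sum(shrunk$indicator) / sum(ph$truth$indicator)
  expect_gt(ratio, 0.61)
  expect_lt(ratio, 0.71)
  tiny <- observer_profile("o", "B", 1e-6, 0, 0)
  expect_error(simulate_observer_mask(ph$truth, tiny, 77), "annihilat")
})

test_that("stronger boundary noise lowers DSC against the truth", {
  cfg <- quiet_cfg()
  ph <- generate_phantom(cfg, 55)
  sdist <- segrobust:::signed_distance(ph$truth)
  dsc_at <- function(noise_sd, seeds) {
    vapply(seeds, function(s) {
      m <- simulate_observer_mask(ph$truth,
                                  observer_profile("o", "A", 1, noise_sd, 0),
                                  s, sdist = sdist)
      dice(m, ph$truth)
    }, numeric(1))
  }
  seeds <- 300 + seq_len(60)
  d2 <- dsc_at(2, seeds)
  d4 <- dsc_at(4, seeds)
  expect_gt(mean(d2), mean(d4))
  expect_true(all(d2 < 1))  # noise always perturbs the contour
})

test_that("cohort-level discipline volume ratio recovers the configured bias", {
  ratios <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(n_patients = 5, master_seed = 400 + s))
    vols <- segrobust:::cohort_volumes(co)
    mean(vols$volume_cm3[vols$discipline == "B"]) /
      mean(vols$volume_cm3[vols$discipline == "A"])
  }, numeric(1))
  expect_gt(mean(ratios), 0.56)
  expect_lt(mean(ratios), 0.76)
})

test_that("minimal cohorts and geometry consistency", {
  obs <- dplyr::bind_rows(observer_profile("x", "A", 1, 1, 0.02),
                          observer_profile("y", "B", 0.8, 2, 0.02))
  co <- generate_cohort(cohort_config(n_patients = 1, observers = obs,
                                      master_seed = 2))
  expect_length(co$patients, 1)
  expect_length(co$patients[[1]]$masks, 2)
  for (m in co$patients[[1]]$masks)
    expect_true(same_geometry(m, co$patients[[1]]$image))
  expect_error(cohort_config(observers = obs[1, ]), "at least 2")
  expect_error(cohort_config(n_patients = 0), "n_patients")
})

test_that("tumors larger than the field of view are rejected", {
  cfg <- cohort_config(tumor_volume_mean = 100, tumor_volume_sd = 0.1,
                       fov_mm = c(40, 40, 40))
  expect_error(generate_phantom(cfg, 3), "field of view")
})

test_that("seed derivation is a stable counter scheme", {
  expect_equal(derive_seed(5, 1, 0), derive_seed(5, 1, 0))
  expect_false(derive_seed(5, 1, 1) == derive_seed(5, 2, 1))
  # adding observers or patients never changes existing seeds
  s_before <- vapply(1:3, function(i) derive_seed(9, i, 2), integer(1))
  s_after <- vapply(1:3, function(i) derive_seed(9, i, 2), integer(1))
  expect_identical(s_before, s_after)
  expect_true(all(vapply(1:50, function(i)
    derive_seed(.Machine$integer.max - 1, i, 6) < 2^31, logical(1))))
})
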