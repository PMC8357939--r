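# Panel composition and whole-extraction behavior.

test_that("panel cardinality: 1277 total, 143 original, 126 per filtered image", {
  cfg <- cohort_config(n_patients = 1, master_seed = 6)
  ph <- generate_phantom(cfg, derive_seed(6, 1, 0))
  feats <- extract_panel(ph$image, ph$truth)
  expect_equal(nrow(feats), 1277)
  expect_false(anyDuplicated(feats$feature_id) > 0)
  counts <- table(feats$filter)
  expect_equal(unname(counts["original"]), 143)
  expect_true(all(counts[setdiff(names(counts), "original")] == 126))
  by_class <- feats |>
    dplyr::filter(.data$filter == "original") |>
    dplyr::count(.data$feature_class)
  expect_equal(
    stats::setNames(by_class$n, by_class$feature_class),
    c(FirstOrder = 24L, GLCM = 26L, GLRLM = 16L, GLSZM = 16L, IVH = 22L,
      NGTDM_NGLDM = 22L, Shape = 17L))
  # shape appears once, on the original image only
  expect_equal(sum(feats$feature_class == "Shape"), 17)

  orig_only <- extract_panel(ph$image, ph$truth,
                             extraction_config(filters = "original"))
  expect_equal(nrow(orig_only), 143)
  wav_only <- extract_panel(ph$image, ph$truth,
                            extraction_config(filters = wavelet_subbands()))
  expect_equal(nrow(wav_only), 1008)
})

test_that("extraction is deterministic and errors on vanishing masks", {
  cfg <- cohort_config(n_patients = 1, master_seed = 8)
  ph <- generate_phantom(cfg, derive_seed(8, 1, 0))
  f1 <- extract_panel(ph$image, ph$truth)
  f2 <- extract_panel(ph$image, ph$truth)
  expect_identical(f1$value, f2$value)
  expect_true(all(is.finite(f1$value)))
  # a one-voxel sliver at 0.9 mm disappears when resampled to 5 mm
  sliver <- array(FALSE, dim(ph$truth$indicator))
  sliver[2, 2, 2] <- TRUE
  expect_error(
    extract_panel(ph$image, binary_mask(sliver, geometry = ph$truth),
                  id = "patient P77"),
    "P77.*empty|empty.*P77")
})

test_that("cohort extraction matches per-mask extraction", {
  co <- generate_cohort(cohort_config(n_patients = 1, master_seed = 12))
  feats <- extract_cohort_features(co)
  expect_equal(nrow(feats), 1277 * 6)
  one <- extract_panel(co$patients[[1]]$image,
                       co$patients[[1]]$masks[["RA1"]])
  sub <- dplyr::filter(feats, .data$observer_id == "RA1")
  expect_equal(sub$value[match(one$feature_id, sub$feature_id)], one$value)
  wide <- features_wide(feats)
  expect_equal(dim(wide), c(6, 3 + 1277))
})

test_that("shape features: voxel arithmetic, cube surface, sphere behavior", {
  one <- binary_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)),
                           c(3, 3, 3)), spacing = c(5, 5, 5))
  sf <- shape_features(one)
  expect_equal(unname(sf["shape_volume_mm3"]), 125)
  expect_equal(unname(sf["shape_surface_area_mm2"]), 150)

  cube <- array(FALSE, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- TRUE
  sfc <- shape_features(binary_mask(cube, spacing = c(5, 5, 5)))
  expect_equal(unname(sfc["shape_surface_area_mm2"]), 600)  # 24 faces x 25 mm^2
  expect_equal(unname(sfc["shape_volume_mm3"]), 1000)
  expect_equal(unname(sfc["shape_extent"]), 1)
  expect_equal(unname(sfc["shape_max_3d_diameter_mm"]), sqrt(75))

  # voxel-face area upper-bounds the true area, so sphericity stays in (0, 1]
  for (r in c(3, 5, 8)) {
    sphere <- shape_features(ball_mask(r))
    expect_lte(unname(sphere["shape_sphericity"]), 1)
    expect_gt(unname(sphere["shape_sphericity"]), 0.5)
    expect_equal(unname(sphere["shape_elongation"]), 1, tolerance = 0.05)
  }
  expect_length(sfc, 17)
})
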