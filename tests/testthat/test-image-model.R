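# Volumetric types, NIfTI round-trips, and isotropic resampling.

test_that("volume and mask constructors enforce their invariants", {
  expect_error(image_volume(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(c(1, NA), c(2, 1, 1)), c(1, 1, 1)),
               "non-finite")
  expect_error(image_volume(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(binary_mask(array(2, c(2, 2, 2)), c(1, 1, 1)), "0 and 1")
  m <- binary_mask(array(c(1, 0, 0, 1, 1, 0, 0, 0), c(2, 2, 2)),
                   spacing = c(5, 5, 5))
  expect_equal(mask_volume_cm3(m), 3 * 125 / 1000)
})

test_that("NIfTI round-trip is exact for float volumes and 0/1 masks", {
  dir <- withr::local_tempdir()
  v <- image_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                    spacing = c(0.7, 0.7, 5), origin = c(-10, 3.5, 7))
  f <- file.path(dir, "v.nii")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$values, v$values)           # float64 on disk
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)

  m <- binary_mask(array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6)),
                   spacing = c(0.7, 0.7, 5))
  fm <- file.path(dir, "m.nii")
  write_mask(m, fm)
  rm <- read_mask(fm)
  expect_identical(rm$indicator, m$indicator)    # bit-exact for 0/1 uint8

  # filtered (signed, floating) volume round-trips within 1e-6
  lg <- log_filter(image_volume(array(rnorm(6^3), c(6, 6, 6)),
                                spacing = c(5, 5, 5)), sigma = 5)
  fl <- file.path(dir, "log.nii")
  write_volume(lg, fl)
  expect_lt(max(abs(read_volume(fl)$values - lg$values)), 1e-6)
})

test_that("read_volume rejects missing, non-3D and unwritable cases", {
  dir <- withr::local_tempdir()
  expect_error(read_volume(file.path(dir, "absent.nii")), "not found")
  img2d <- RNifti::asNifti(matrix(1, 4, 4))
  f2 <- file.path(dir, "flat.nii")
  RNifti::writeNifti(img2d, f2)
  expect_error(read_volume(f2), "3D")
  v <- image_volume(array(1, c(2, 2, 2)), c(1, 1, 1))
  expect_error(write_volume(v, file.path(dir, "no_such_dir", "x.nii")),
               "cannot write")
})

test_that("resampling preserves constants exactly and is identity at target", {
  vi <- image_volume(array(rnorm(9 * 9 * 9), c(9, 9, 9)), spacing = c(5, 5, 5))
  expect_lt(max(abs(resample_isotropic(vi, 5)$values - vi$values)), 1e-6)
  vc <- image_volume(array(3.25, c(20, 20, 8)), spacing = c(1.3, 1.3, 4))
  rc <- resample_isotropic(vc, 5)
  expect_lt(max(abs(rc$values - 3.25)), 1e-9)
  expect_equal(rc$spacing, c(5, 5, 5))
})

test_that("mask resampling is strictly binary and volume-preserving", {
  ind <- array(FALSE, c(100, 100, 100))
  ind[11:90, 11:90, 11:90] <- TRUE            # 80 mm cube at 1 mm voxels
  mk <- binary_mask(ind, spacing = c(1, 1, 1))
  r <- resample_isotropic(mk, 5)
  expect_true(all(r$indicator %in% c(TRUE, FALSE)))
  expect_lt(abs(mask_volume_cm3(r) - mask_volume_cm3(mk)) / mask_volume_cm3(mk),
            0.05)
  # physical extent preserved within one voxel
  expect_lt(abs(prod(dim(r$indicator)) * 125 - prod(dim(ind))), 125 * 8)
})

test_that("resampling degenerate single-voxel axes to finer spacing errors", {
  v <- image_volume(array(1, c(8, 8, 1)), spacing = c(1, 1, 5))
  expect_error(resample_isotropic(v, 2), "single-voxel")
})
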