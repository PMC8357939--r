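# Texture matrices vs exhaustive enumeration, degenerate conventions, and
# symmetry invariance.

test_that("texture matrices equal brute-force enumeration on small ROIs", {
  set.seed(11)
  for (rep in 1:6) {
    q <- random_quantized(c(4, 4, 4), ng = 3)     # <= 64 voxels
    d <- dim(q$levels)
    lv <- q$levels
    ng <- q$n_levels
    expect_equal(segrobust:::cpp_glcm(as.integer(lv), d[1], d[2], d[3], ng, 1L),
                 bf_glcm(lv, ng))
    expect_equal(segrobust:::cpp_glrlm(as.integer(lv), d[1], d[2], d[3], ng)[, 1:4],
                 bf_glrlm(lv, ng)[, 1:4])
    zo <- segrobust:::cpp_glszm_zones(as.integer(lv), d[1], d[2], d[3])
    bz <- bf_glszm(lv)
    expect_equal(sort(zo[, 2] * 100 + zo[, 1]), sort(bz[, 2] * 100 + bz[, 1]))
    nt <- segrobust:::cpp_ngtdm(as.integer(lv), d[1], d[2], d[3], ng)
    bo <- bf_ngtdm(lv, ng)
    expect_equal(nt$s, bo$s, tolerance = 1e-12)
    expect_equal(nt$n, bo$n)
    expect_equal(segrobust:::cpp_ngldm(as.integer(lv), d[1], d[2], d[3], ng, 0L),
                 bf_ngldm(lv, ng))
  }
})

test_that("hand-enumerated 1x1x4 ROI with levels (1,2,1,2)", {
  lv <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  q <- quantized_fixture(lv)
  # co-occurrences along x at offset 1: pairs (1,2),(2,1),(1,2) counted both
  # ways -> 6 off-diagonal entries, none diagonal
  g <- glcm_features(q)
  expect_equal(unname(g["glcm_energy"]), (3 / 6)^2 + (3 / 6)^2)
  expect_equal(unname(g["glcm_contrast"]), 1)         # |1-2|^2 everywhere
  expect_equal(unname(g["glcm_joint_max"]), 0.5)
  # runs: 13 directions; along x: four runs of length 1; the other 12
  # directions see each voxel as its own run
  r <- glrlm_features(q)
  expect_equal(unname(r["glrlm_long_run_emphasis"]), 1)   # all runs length 1
  expect_equal(unname(r["glrlm_run_percentage"]), 52 / 52)
  # zones: 26-connectivity joins diagonals; here voxels 1,3 (level 1) are not
  # adjacent (gap at voxel 2), so 4 zones of size 1
  z <- glszm_features(q)
  expect_equal(unname(z["glszm_long_zone_emphasis"]), 1)
  expect_equal(unname(z["glszm_zone_percentage"]), 1)
})

test_that("constant ROI degenerate conventions", {
  lv <- array(1L, c(3, 3, 3))
  q <- quantized_fixture(lv)
  g <- glcm_features(q)
  expect_equal(unname(g["glcm_energy"]), 1)
  expect_equal(unname(g["glcm_joint_entropy"]), 0)
  z <- glszm_features(q)
  expect_equal(sum(segrobust:::cpp_glszm_zones(as.integer(lv), 3, 3, 3)[, 1] > 0), 1)
  expect_equal(unname(z["glszm_zone_entropy"]), 0)
  # single voxel: no pairs -> documented all-zero convention
  q1 <- quantized_fixture(array(1L, c(1, 1, 1)))
  expect_true(all(glcm_features(q1) == 0))
  expect_true(all(ngtdm_features(q1) == 0))
})

test_that("merged-direction features are invariant under grid symmetries", {
  set.seed(21)
  q <- random_quantized(c(5, 4, 3), ng = 4)
  base <- c(glcm_features(q), glrlm_features(q), glszm_features(q),
            ngtdm_features(q), ngldm_features(q))
  for (axis in c("x", "y", "z")) {
    qr <- quantized_fixture(rot90_levels(q$levels, axis))
    rot <- c(glcm_features(qr), glrlm_features(qr), glszm_features(qr),
             ngtdm_features(qr), ngldm_features(qr))
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("feature family sizes match the panel definition", {
  set.seed(3)
  q <- random_quantized(c(4, 4, 4), ng = 3)
  expect_length(glcm_features(q), 26)
  expect_length(glrlm_features(q), 16)
  expect_length(glszm_features(q), 16)
  expect_length(c(ngtdm_features(q), ngldm_features(q)), 22)
  expect_length(texture_features(q, "NGTDM_NGLDM"), 22)
})
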