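# STAPLE consensus, Dice, agreement grading, and discipline comparisons.

mk <- function(ind, sp = c(1, 1, 1)) binary_mask(ind, spacing = sp)

test_that("dice: identity, disjoint, counted overlap, symmetry, conventions", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1:2, 1] <- TRUE   # |A|=|B|=4, |A^B|=2
  expect_equal(dice(mk(a), mk(a)), 1)
  expect_equal(dice(mk(a), mk(b)), 0.5)
  expect_equal(dice(mk(a), mk(b)), dice(mk(b), mk(a)))
  d <- array(FALSE, c(4, 4, 4)); d[4, 4, 4] <- TRUE
  expect_equal(dice(mk(a), mk(d)), 0)
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(mk(e), mk(e)), 1)  # empty-vs-empty convention
  expect_error(dice(mk(a), binary_mask(a, spacing = c(2, 1, 1))), "geometry")
})

test_that("agreement grades use the printed boundaries", {
  expect_equal(as.character(grade_agreement(c(0.85, 0.84999, 0.70, 0.699,
                                              0.5, 0.49, 1, 0))),
               c("High", "Medium", "Medium", "Low", "Low", "VeryLow",
                 "High", "VeryLow"))
  # the scale partitions [0,1]: every value gets exactly one grade
  xs <- seq(0, 1, by = 0.001)
  expect_false(anyNA(grade_agreement(xs)))
  expect_error(grade_agreement(1.2), "0, 1")
})

test_that("unanimous STAPLE reproduces the input with p, q near 1", {
  ind <- array(FALSE, c(6, 6, 6)); ind[2:5, 2:4, 3:4] <- TRUE
  fit <- staple(list(mk(ind), mk(ind), mk(ind)))
  expect_identical(fit$consensus$indicator, ind)
  expect_true(all(fit$sensitivity > 1 - 1e-4))
  expect_true(all(fit$specificity > 1 - 1e-4))
  expect_true(fit$converged)
})

test_that("STAPLE matches an independently coded per-voxel EM", {
  set.seed(5)
  for (J in c(3, 4)) {
    nvox <- 180
    truth <- runif(nvox) < 0.35
    D <- vapply(seq_len(J), function(j) xor(truth, runif(nvox) < 0.12),
                logical(nvox))
    masks <- lapply(seq_len(J), function(j)
      mk(array(D[, j], c(nvox, 1, 1))))
    fit <- staple(masks, tol = 1e-8, max_iter = 200)
    ref <- bf_staple_em(D, tol = 1e-8, max_iter = 200)
    expect_lt(max(abs(c(fit$probability_map) - ref$W)), 1e-8)
    expect_lt(max(abs(unname(fit$sensitivity) - ref$p)), 1e-8)
    expect_lt(max(abs(unname(fit$specificity) - ref$q)), 1e-8)
  }
})

test_that("with symmetric observers STAPLE behaves like a majority vote", {
  # 6 equal-profile observers; one voxel marked by 5/6, another by 1/6
  set.seed(7)
  nvox <- 100
  base <- rep(c(TRUE, FALSE), each = nvox / 2)
  D <- matrix(base, nvox, 6)
  D[1, ] <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)   # 5 of 6 mark it
  D[60, ] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)  # 1 of 6
  flip <- matrix(runif(nvox * 6) < 0.05, nvox, 6)
  D <- xor(D, flip)
  D[1, ] <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  D[60, ] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  masks <- lapply(1:6, function(j) mk(array(D[, j], c(nvox, 1, 1))))
  fit <- staple(masks)
  expect_true(fit$consensus$indicator[1, 1, 1])
  expect_false(fit$consensus$indicator[60, 1, 1])
})

test_that("complementary equal-size masks leave the posterior at the prior", {
  a <- c(rep(TRUE, 5), rep(FALSE, 5))
  masks <- list(mk(array(a, c(10, 1, 1))), mk(array(!a, c(10, 1, 1))))
  fit <- staple(masks, max_iter = 200)
  ref <- bf_staple_em(cbind(a, !a), max_iter = 200)
  expect_lt(max(abs(c(fit$probability_map) - ref$W)), 1e-8)
  # no consensus signal: posterior equals the prior everywhere
  expect_lt(max(abs(c(fit$probability_map) - fit$prior)), 0.02)
})

test_that("STAPLE is invariant to observer order and errors on bad input", {
  set.seed(8)
  inds <- lapply(1:3, function(j) array(runif(64) < 0.4, c(4, 4, 4)))
  masks <- lapply(inds, mk)
  f1 <- staple(masks)
  f2 <- staple(masks[c(3, 1, 2)])
  expect_identical(f1$consensus$indicator, f2$consensus$indicator)
  expect_equal(unname(f1$sensitivity), unname(f2$sensitivity[c(2, 3, 1)]))
  expect_error(staple(masks[1]), "at least 2")
  empty <- mk(array(FALSE, c(4, 4, 4)))
  expect_error(staple(list(empty, empty)), "empty")
})

test_that("per-patient agreement is consistent with dice() and staple()", {
  co <- generate_cohort(cohort_config(n_patients = 2, master_seed = 7))
  rec <- per_patient_agreement(co)
  expect_equal(nrow(rec), 12)
  fits <- attr(rec, "staple")
  p1 <- co$patients[[1]]
  d_direct <- dice(p1$masks[["RO2"]], fits[["P01"]]$consensus)
  expect_equal(rec$dsc[rec$patient_id == "P01" & rec$observer_id == "RO2"],
               d_direct)
  expect_equal(as.character(rec$grade), as.character(grade_agreement(rec$dsc)))
})

test_that("identical observers give DSC 1 everywhere and degenerate tests", {
  ind <- array(FALSE, c(8, 8, 4)); ind[3:6, 3:6, 2:3] <- TRUE
  truth <- mk(ind, sp = c(2, 2, 5))
  obs <- dplyr::bind_rows(
    observer_profile("a1", "A"), observer_profile("a2", "A"),
    observer_profile("b1", "B"), observer_profile("b2", "B"))
  patients <- list(list(patient_id = "P01", image = NULL, truth = truth,
                        masks = stats::setNames(replicate(4, truth,
                                                          simplify = FALSE),
                                                obs$observer_id)),
                   list(patient_id = "P02", image = NULL, truth = truth,
                        masks = stats::setNames(replicate(4, truth,
                                                          simplify = FALSE),
                                                obs$observer_id)))
  co <- structure(list(patients = patients, observers = obs, config = NULL),
                  class = "study_cohort")
  rec <- per_patient_agreement(co)
  expect_true(all(rec$dsc == 1))
  tt <- compare_disciplines_dsc(rec)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_true(tt$degenerate)
})

test_that("paired t on discipline DSC means matches the closed form", {
  rec <- tibble::tibble(
    patient_id = rep(c("P1", "P2", "P3"), each = 2),
    observer_id = rep(c("a", "b"), 3),
    discipline = rep(c("A", "B"), 3),
    volume_cm3 = 1,
    dsc = c(0.8, 0.6, 0.9, 0.7, 0.85, 0.65))
  tt <- compare_disciplines_dsc(rec)
  d <- c(0.2, 0.2, 0.2)
  # zero-variance differences -> degenerate limit p -> 0
  expect_true(tt$degenerate)
  expect_equal(tt$p_value, 0)
  rec$dsc <- c(0.8, 0.6, 0.9, 0.75, 0.85, 0.68)
  tt2 <- compare_disciplines_dsc(rec)
  d2 <- c(0.2, 0.15, 0.17)
  tstat <- mean(d2) / (sd(d2) / sqrt(3))
  expect_equal(tt2$statistic, tstat, tolerance = 1e-12)
  expect_equal(tt2$p_value, 2 * pt(-abs(tstat), df = 2), tolerance = 1e-12)
})

test_that("volumes are voxel count times voxel volume, in cm^3", {
  ind <- array(FALSE, c(12, 12, 12)); ind[1:10, 1:10, 1:10] <- TRUE
  m <- mk(ind, sp = c(5, 5, 5))
  expect_equal(mask_volume_cm3(m), 125)
})
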