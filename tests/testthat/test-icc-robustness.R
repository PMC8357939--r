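# ICC(2,1) against brute-force ANOVA, robustness summaries, Wilcoxon and
# rank agreement.

test_that("icc21 closed-form cases", {
  # identical raters with between-subject variance -> ICC = 1
  m <- cbind(c(1, 3, 5, 9), c(1, 3, 5, 9), c(1, 3, 5, 9))
  expect_equal(icc21(m)$icc, 1)
  # hand computation for the 3x2 ladder matrix
  m2 <- rbind(c(1, 2), c(3, 4), c(5, 6))
  ms <- bf_anova_ms(m2)
  expect_equal(icc21(m2)$ms_subject, ms$msr)
  expect_equal(icc21(m2)$ms_rater, ms$msc)
  expect_equal(icc21(m2)$ms_error, ms$mse)
  expect_equal(icc21(m2)$icc, bf_icc21(m2))
  # constant subjects, raters offset -> rater variance dominates, ICC <= 0
  m3 <- cbind(rep(2, 5), rep(5, 5), rep(11, 5))
  expect_lte(icc21(m3)$icc, 0)
  expect_equal(icc21(m3)$icc, bf_icc21(m3))
  expect_error(icc21(cbind(c(1, NA), c(2, 3))), "non-finite")
  expect_error(icc21(matrix(1, 1, 3)), ">= 2")
})

test_that("icc21 matches brute-force ANOVA to 1e-10 on random matrices", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    k <- sample(2:10, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 5)) +
                  rep(rnorm(n, sd = 2), k), n, k)
    expect_equal(icc21(m)$icc, bf_icc21(m), tolerance = 1e-10)
  }
})

test_that("icc21 is invariant to constant shifts and subject relabeling", {
  set.seed(14)
  m <- matrix(rnorm(30), 10, 3) + rep(rnorm(10), 3)
  expect_equal(icc21(m + 42)$icc, icc21(m)$icc, tolerance = 1e-10)
  perm <- sample(10)
  expect_equal(icc21(m[perm, ])$icc, icc21(m)$icc, tolerance = 1e-10)
})

fake_features <- function(value_fun, n_pat = 6, features = NULL) {
  if (is.null(features))
    features <- tibble::tibble(
      feature_id = paste0("original.f", 1:4),
      filter = "original",
      feature_class = c("FirstOrder", "FirstOrder", "GLCM", "GLCM"),
      name = paste0("f", 1:4))
  obs <- tibble::tibble(observer_id = c("a1", "a2", "b1", "b2"),
                        discipline = c("A", "A", "B", "B"))
  tidyr::expand_grid(patient_id = sprintf("P%02d", 1:n_pat),
                     obs, features) |>
    dplyr::mutate(value = value_fun(dplyr::row_number(), .data$patient_id,
                                    .data$observer_id, .data$feature_id))
}

test_that("feature_icc_table: identical observers give ICC 1, all robust", {
  ft <- fake_features(function(i, pat, obs, fid)
    as.integer(factor(pat)) * 2 + as.integer(factor(fid)))
  recs <- feature_icc_table(ft)
  expect_equal(nrow(recs), 4 * 3)   # 4 features x {all, A, B}
  expect_true(all(recs$icc == 1))
  expect_true(all(recs$robust))
})

test_that("robustness threshold is strict at 0.75", {
  recs <- tibble::tibble(feature_id = c("x", "y"), filter = "original",
                         feature_class = "GLCM", name = c("x", "y"),
                         group = "all", icc = c(0.76, 0.74))
  recs$robust <- !is.na(recs$icc) & recs$icc > 0.75
  expect_equal(recs$robust, c(TRUE, FALSE))
  # monotone nonincreasing robust counts in the threshold
  set.seed(15)
  iccs <- runif(200, -0.2, 1)
  counts <- vapply(c(0.5, 0.7, 0.75, 0.8, 0.9), function(th)
    sum(iccs > th), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("robust_summary partitions counts and intersection is set overlap", {
  ft <- fake_features(function(i, pat, obs, fid) {
    base <- as.integer(factor(pat)) * 2
    noise <- ifelse(obs %in% c("b1", "b2") & fid %in% c("original.f3",
                                                        "original.f4"),
                    (i %% 7) * 3, 0)   # wreck f3/f4 for discipline B only
    base + noise
  })
  recs <- feature_icc_table(ft)
  summ <- robust_summary(recs)
  expect_true(all(summ$robust <= summ$total))
  tot <- summ |> dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$total))
  expect_true(all(tot$n == 4))
  setA <- recs$feature_id[recs$group == "A" & recs$robust]
  setB <- recs$feature_id[recs$group == "B" & recs$robust]
  expect_equal(robust_intersection(recs), length(intersect(setA, setB)))
})

test_that("top_features ranks by ICC with name tie-break", {
  recs <- tibble::tibble(
    feature_id = c("original.a", "original.b", "original.c", "LLL.z"),
    filter = c("original", "original", "original", "LLL"),
    feature_class = "GLCM", name = c("a", "b", "c", "z"),
    group = "all", icc = c(0.9, 0.9, 0.95, 0.999),
    robust = TRUE)
  top <- top_features(recs, "all", 2)
  expect_equal(top$feature_id[top$filter == "original"],
               c("original.c", "original.a"))
  expect_equal(top$feature_id[top$filter == "LLL"], "LLL.z")
})

test_that("wilcoxon on discipline ICCs: exact sign case and degeneracy", {
  mkrec <- function(a, b) {
    nf <- length(a)
    tibble::tibble(
      feature_id = rep(paste0("original.f", 1:nf), 2),
      filter = "original", feature_class = "GLCM",
      name = rep(paste0("f", 1:nf), 2),
      group = rep(c("A", "B"), each = nf),
      icc = c(a, b), robust = FALSE)
  }
  # 6 pairs, all differences positive -> exact two-sided p = 2/2^6
  a <- c(0.9, 0.8, 0.85, 0.7, 0.75, 0.95)
  w <- discipline_icc_wilcoxon(mkrec(a, a - runif(6, 0.01, 0.1)))
  expect_equal(w$p_value, 2 * (1 / 2^6), tolerance = 1e-12)
  expect_equal(w$n_pairs, 6)
  # all-zero differences -> flagged degenerate
  w0 <- discipline_icc_wilcoxon(mkrec(a, a))
  expect_true(w0$degenerate)
  expect_true(is.na(w0$p_value))
})

test_that("rank agreement: identity, reversal, and small-class error", {
  mkrec <- function(a, b, cls = "GLCM") {
    nf <- length(a)
    tibble::tibble(
      feature_id = rep(paste0("original.f", 1:nf), 2),
      filter = "original", feature_class = cls,
      name = rep(paste0("f", 1:nf), 2),
      group = rep(c("A", "B"), each = nf),
      icc = c(a, b), robust = FALSE)
  }
  a <- c(0.1, 0.35, 0.5, 0.62, 0.8, 0.9)
  ra <- rank_agreement(mkrec(a, a))
  expect_equal(ra$slope, 1)
  expect_equal(ra$r_squared, 1)
  rr <- rank_agreement(mkrec(a, rev(a) * 0.9))
  expect_equal(rr$slope, -1)
  expect_equal(rr$r_squared, 1)
  expect_error(rank_agreement(mkrec(a[1:2], a[1:2])), "fewer than 3")
})

test_that("shuffled ranks give near-null mean R^2 of 1/(n-1)", {
  set.seed(16)
  n <- 12
  r2 <- replicate(400, {
    ra <- sample(n); rb <- sample(n)
    summary(stats::lm(rb ~ ra))$r.squared
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * stats::sd(r2) / sqrt(400))
})
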