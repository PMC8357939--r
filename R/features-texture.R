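# Texture features from gray-level matrices built on the quantized ROI.
# GLCM and GLRLM are accumulated over the 13 symmetric 3D directions and
# merged into a single matrix before features are computed; GLSZM zones and
# NGLDM dependencies use 26-connectivity; NGTDM uses the 26-voxel
# neighborhood. Degenerate conventions (documented): on an ROI with no valid
# voxel pairs (e.g. a single voxel) all features of the affected family are
# 0; entropy-like features of a single-level ROI are 0; variance-normalized
# quantities with zero variance are 0.

#' Texture features of a quantized ROI
#'
#' Dispatches to the per-family feature sets:
#' GLCM (26), GLRLM (16), GLSZM (16), and the combined NGTDM/NGLDM class
#' (5 + 17 = 22 features).
#'
#' @param q A `quantized_roi` from [discretize()].
#' @param family One of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"NGTDM_NGLDM"`.
#' @param offset Voxel offset for GLCM co-occurrences (default 1).
#' @return Named numeric vector.
#' @export
texture_features <- function(q, family = c("GLCM", "GLRLM", "GLSZM", "NGTDM_NGLDM"),
                             offset = 1L) {
  stopifnot(inherits(q, "quantized_roi"))
  family <- match.arg(family)
  switch(family,
         GLCM = glcm_features(q, offset),
         GLRLM = glrlm_features(q),
         GLSZM = glszm_features(q),
         NGTDM_NGLDM = c(ngtdm_features(q), ngldm_features(q)))
}

roi_dims <- function(q) dim(q$levels)

#' @rdname texture_features
#' @export
glcm_features <- function(q, offset = 1L) {
  d <- roi_dims(q)
  ng <- q$n_levels
  counts <- cpp_glcm(as.integer(q$levels), d[1], d[2], d[3], ng, as.integer(offset))
  nm <- c("joint_max", "joint_average", "joint_variance", "joint_entropy",
          "difference_average", "difference_variance", "difference_entropy",
          "sum_average", "sum_variance", "sum_entropy", "energy", "contrast",
          "dissimilarity", "inverse_difference", "inverse_difference_norm",
          "inverse_difference_moment", "inverse_difference_moment_norm",
          "inverse_variance", "correlation", "autocorrelation",
          "cluster_tendency", "cluster_shade", "cluster_prominence",
          "information_correlation1", "information_correlation2",
          "max_correlation_coeff")
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(numeric(26), paste0("glcm_", nm)))
  P <- counts / tot
  i <- row(P); j <- col(P)
  px <- rowSums(P)  # symmetric: px == py
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  k_diff <- abs(i - j)
  pd <- tapply(P, k_diff, sum)           # p_{x-y}, indexed 0..ng-1
  kd <- as.numeric(names(pd))
  ps <- tapply(P, i + j, sum)            # p_{x+y}, indexed 2..2ng
  ks <- as.numeric(names(ps))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  da <- sum(kd * pd)
  sa <- sum(ks * ps)
  hx <- ent(px)
  hxy <- ent(P)
  pij <- outer(px, px)
  hxy1 <- -sum(P[pij > 0] * log2(pij[pij > 0]))
  hxy2 <- ent(pij)
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  dif <- (i - j)[i != j]
  inv_var <- sum(P[i != j] / dif^2)
  # maximal correlation coefficient: sqrt of the second eigenvalue of
  # Q_{ij} = sum_k p(i,k) p(j,k) / (p_x(i) p_x(k)), restricted to occupied
  # levels; 0 on a single-level ROI by convention
  act <- which(px > 0)
  mcc <- if (length(act) > 1) {
    Pa <- P[act, act, drop = FALSE]
    Q <- (Pa / px[act]) %*% t(Pa / rep(px[act], each = length(act)))
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(evq[2], 1)))
  } else 0
  out <- c(max(P), mu, sig2, hxy,
           da, sum((kd - da)^2 * pd), ent(pd),
           sa, sum((ks - sa)^2 * ps), ent(ps),
           sum(P^2), sum((i - j)^2 * P),
           sum(abs(i - j) * P), sum(P / (1 + abs(i - j))),
           sum(P / (1 + abs(i - j) / ng)), sum(P / (1 + (i - j)^2)),
           sum(P / (1 + (i - j)^2 / ng^2)),
           inv_var,
           corr, sum(i * j * P),
           sum((i + j - 2 * mu)^2 * P), sum((i + j - 2 * mu)^3 * P),
           sum((i + j - 2 * mu)^4 * P), ic1, ic2, mcc)
  stats::setNames(out, paste0("glcm_", nm))
}

# Shared formulas for run-length-style matrices: rows are gray levels, cols
# are run lengths / zone sizes / dependence counts.
rl_family_features <- function(M, np, prefix, size_name) {
  nm <- paste0(prefix, "_",
               c(paste0("short_", size_name, "_emphasis"),
                 paste0("long_", size_name, "_emphasis"),
                 "gray_level_nonuniformity", "gray_level_nonuniformity_norm",
                 paste0(size_name, "_nonuniformity"),
                 paste0(size_name, "_nonuniformity_norm"),
                 paste0(size_name, "_percentage"),
                 "low_gray_emphasis", "high_gray_emphasis",
                 paste0("short_", size_name, "_low_gray_emphasis"),
                 paste0("short_", size_name, "_high_gray_emphasis"),
                 paste0("long_", size_name, "_low_gray_emphasis"),
                 paste0("long_", size_name, "_high_gray_emphasis"),
                 "gray_level_variance",
                 paste0(size_name, "_variance"),
                 paste0(size_name, "_entropy")))
  ns <- sum(M)
  if (ns == 0) return(stats::setNames(numeric(16), nm))
  p <- M / ns
  i <- row(p); l <- col(p)
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  pe <- p[p > 0]
  out <- c(sum(p / l^2), sum(p * l^2),
           sum(rowSums(M)^2) / ns, sum(rowSums(M)^2) / ns^2,
           sum(colSums(M)^2) / ns, sum(colSums(M)^2) / ns^2,
           ns / np,
           sum(p / i^2), sum(p * i^2),
           sum(p / (i^2 * l^2)), sum(p * i^2 / l^2),
           sum(p * l^2 / i^2), sum(p * i^2 * l^2),
           sum(p * (i - mu_i)^2), sum(p * (l - mu_l)^2),
           -sum(pe * log2(pe)))
  stats::setNames(out, nm)
}

#' @rdname texture_features
#' @export
glrlm_features <- function(q) {
  d <- roi_dims(q)
  M <- cpp_glrlm(as.integer(q$levels), d[1], d[2], d[3], q$n_levels)
  rl_family_features(M, np = 13 * length(q$values), prefix = "glrlm",
                     size_name = "run")
}

#' @rdname texture_features
#' @export
glszm_features <- function(q) {
  d <- roi_dims(q)
  zones <- cpp_glszm_zones(as.integer(q$levels), d[1], d[2], d[3])
  maxs <- max(zones[, 2])
  M <- matrix(0, q$n_levels, maxs)
  for (r in seq_len(nrow(zones))) {
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  }
  rl_family_features(M, np = length(q$values), prefix = "glszm",
                     size_name = "zone")
}

#' @rdname texture_features
#' @export
ngtdm_features <- function(q) {
  d <- roi_dims(q)
  acc <- cpp_ngtdm(as.integer(q$levels), d[1], d[2], d[3], q$n_levels)
  s <- acc$s
  n <- acc$n
  nm <- paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                           "strength"))
  nvc <- sum(n)
  if (nvc == 0) return(stats::setNames(numeric(5), nm))
  p <- n / nvc
  act <- which(p > 0)
  ngp <- length(act)
  lv <- seq_along(p)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(lv[act], lv[act], `-`)^2) /
       (ngp * (ngp - 1))) * (sum(s) / nvc)
  } else 0
  ip <- lv[act] * p[act]
  bus_den <- sum(abs(outer(ip, ip, `-`)))
  busyness <- if (bus_den > 0) coarse_den / bus_den else 0
  ps <- p[act] * s[act]
  pij <- outer(p[act], p[act], `+`)
  dij <- abs(outer(lv[act], lv[act], `-`))
  complexity <- sum(dij * outer(ps, ps, `+`) / pij) / nvc
  strength <- if (sum(s) > 0) sum(pij * outer(lv[act], lv[act], `-`)^2) / sum(s) else 0
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}

#' @rdname texture_features
#' @param alpha Gray-level tolerance for counting a neighbor as dependent
#'   (default 0: equal levels only).
#' @export
ngldm_features <- function(q, alpha = 0L) {
  d <- roi_dims(q)
  M <- cpp_ngldm(as.integer(q$levels), d[1], d[2], d[3], q$n_levels,
                 as.integer(alpha))
  nm <- paste0("ngldm_", c("low_dependence_emphasis", "high_dependence_emphasis",
                           "low_gray_emphasis", "high_gray_emphasis",
                           "low_dependence_low_gray_emphasis",
                           "low_dependence_high_gray_emphasis",
                           "high_dependence_low_gray_emphasis",
                           "high_dependence_high_gray_emphasis",
                           "gray_level_nonuniformity",
                           "gray_level_nonuniformity_norm",
                           "dependence_count_nonuniformity",
                           "dependence_count_nonuniformity_norm",
                           "dependence_count_percentage",
                           "gray_level_variance", "dependence_count_variance",
                           "dependence_count_entropy", "dependence_count_energy"))
  ns <- sum(M)
  if (ns == 0) return(stats::setNames(numeric(17), nm))
  p <- M / ns
  i <- row(p)
  jd <- col(p)  # dependence count + 1
  mu_i <- sum(i * p)
  mu_j <- sum(jd * p)
  pe <- p[p > 0]
  out <- c(sum(p / jd^2), sum(p * jd^2),
           sum(p / i^2), sum(p * i^2),
           sum(p / (i^2 * jd^2)), sum(p * i^2 / jd^2),
           sum(p * jd^2 / i^2), sum(p * i^2 * jd^2),
           sum(rowSums(M)^2) / ns, sum(rowSums(M)^2) / ns^2,
           sum(colSums(M)^2) / ns, sum(colSums(M)^2) / ns^2,
           ns / length(q$values),
           sum(p * (i - mu_i)^2), sum(p * (jd - mu_j)^2),
           -sum(pe * log2(pe)), sum(p^2))
  stats::setNames(out, nm)
}
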