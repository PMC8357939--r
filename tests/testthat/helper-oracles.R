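# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

dirs26 <- rbind(dirs13, -dirs13)

inb <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric merged GLCM counts
bf_glcm <- function(lv, ng, offset = 1) {
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    for (k in 1:nrow(dirs26)) {
      p <- c(x, y, z) + dirs26[k, ] * offset
      if (!inb(p, d)) next
      b <- lv[p[1], p[2], p[3]]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1
    }
  }
  M
}

# merged run-length counts over 13 directions
bf_glrlm <- function(lv, ng) {
  d <- dim(lv)
  M <- matrix(0, ng, max(d))
  for (k in 1:13) {
    dd <- dirs13[k, ]
    done <- array(FALSE, d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (done[x, y, z] || lv[x, y, z] == 0) next
      # walk back to the run start
      p <- c(x, y, z)
      while (inb(p - dd, d) && lv[(p - dd)[1], (p - dd)[2], (p - dd)[3]] == lv[x, y, z])
        p <- p - dd
      # walk forward, marking
      len <- 0
      q <- p
      while (inb(q, d) && lv[q[1], q[2], q[3]] == lv[x, y, z]) {
        done[q[1], q[2], q[3]] <- TRUE
        len <- len + 1
        q <- q + dd
      }
      M[lv[x, y, z], len] <- M[lv[x, y, z], len] + 1
    }
  }
  M
}

# zone (level, size) table under 26-connectivity via repeated flood fill
bf_glszm <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || lv[x, y, z] == 0) next
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in 1:nrow(dirs26)) {
        q <- p + dirs26[k, ]
        if (inb(q, d) && !seen[q[1], q[2], q[3]] &&
            lv[q[1], q[2], q[3]] == lv[x, y, z]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones <- rbind(zones, c(lv[x, y, z], size))
  }
  zones
}

bf_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  s <- numeric(ng); n <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    nb <- c()
    for (k in 1:nrow(dirs26)) {
      q <- c(x, y, z) + dirs26[k, ]
      if (inb(q, d) && lv[q[1], q[2], q[3]] > 0)
        nb <- c(nb, lv[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1
  }
  list(s = s, n = n)
}

bf_ngldm <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  M <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    dep <- 0
    for (k in 1:nrow(dirs26)) {
      q <- c(x, y, z) + dirs26[k, ]
      if (inb(q, d) && lv[q[1], q[2], q[3]] > 0 &&
          abs(lv[q[1], q[2], q[3]] - a) <= alpha)
        dep <- dep + 1
    }
    M[a, dep + 1] <- M[a, dep + 1] + 1
  }
  M
}

# naive per-voxel STAPLE EM (no pattern grouping), global scalar prior
bf_staple_em <- function(D, tol = 1e-6, max_iter = 100, prior = mean(D)) {
  J <- ncol(D)
  p <- rep(0.99999, J); q <- rep(0.99999, J)
  eps <- 1e-7
  for (it in 1:max_iter) {
    W <- numeric(nrow(D))
    for (i in 1:nrow(D)) {
      a <- prior
      b <- 1 - prior
      for (j in 1:J) {
        a <- a * (if (D[i, j]) p[j] else 1 - p[j])
        b <- b * (if (D[i, j]) 1 - q[j] else q[j])
      }
      W[i] <- a / (a + b)
    }
    pn <- qn <- numeric(J)
    for (j in 1:J) {
      pn[j] <- min(1 - eps, max(eps, sum(W * D[, j]) / sum(W)))
      qn[j] <- min(1 - eps, max(eps, sum((1 - W) * (1 - D[, j])) / sum(1 - W)))
    }
    delta <- max(abs(pn - p), abs(qn - q))
    p <- pn; q <- qn
    if (delta < tol) break
  }
  W <- numeric(nrow(D))
  for (i in 1:nrow(D)) {
    a <- prior; b <- 1 - prior
    for (j in 1:J) {
      a <- a * (if (D[i, j]) p[j] else 1 - p[j])
      b <- b * (if (D[i, j]) 1 - q[j] else q[j])
    }
    W[i] <- a / (a + b)
  }
  list(W = W, p = p, q = q)
}

# explicit two-way ANOVA sums of squares by summation loops
bf_anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - g)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + g)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

bf_icc21 <- function(m) {
  ms <- bf_anova_ms(m)
  n <- nrow(m); k <- ncol(m)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# small fixtures ------------------------------------------------------------

ball_mask <- function(radius_vox, spacing = c(1, 1, 1), n = 2 * radius_vox + 3) {
  ctr <- (n + 1) / 2
  g <- seq_len(n)
  X <- array(g, c(n, n, n))
  Y <- array(rep(g, each = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  binary_mask((X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2 <= radius_vox^2,
              spacing = spacing)
}

quantized_fixture <- function(lv, spacing = c(1, 1, 1)) {
  # wrap an integer level array as the quantized_roi the feature code expects
  structure(list(levels = lv, n_levels = max(lv), bin_width = 1,
                 roi_min = 0, values = as.numeric(lv[lv > 0]),
                 spacing = spacing),
            class = "quantized_roi")
}

random_quantized <- function(dim3, ng, fg_prob = 0.8) {
  lv <- array(0L, dim3)
  fg <- array(stats::runif(prod(dim3)) < fg_prob, dim3)
  lv[fg] <- sample.int(ng, sum(fg), replace = TRUE)
  quantized_fixture(lv)
}

rot90_levels <- function(lv, axis) {
  # 90-degree rotation of a 3D integer array about one axis
  d <- dim(lv)
  out <- switch(axis,
                x = aperm(lv, c(1, 3, 2))[, rev(seq_len(d[3])), , drop = FALSE],
                y = aperm(lv, c(3, 2, 1))[, , rev(seq_len(d[1])), drop = FALSE],
                z = aperm(lv, c(2, 1, 3))[rev(seq_len(d[2])), , , drop = FALSE])
  out
}
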