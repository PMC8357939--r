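#' STAPLE consensus segmentation
#'
#' Simultaneous Truth And Performance Level Estimation: an
#' expectation-maximization estimate of a latent consensus segmentation
#' together with a per-observer sensitivity `p_j` and specificity `q_j`.
#' The E-step computes the per-voxel posterior probability of foreground
#' given the current `(p_j, q_j)` and a global scalar prior (the mean
#' foreground fraction across observers); the M-step re-estimates each
#' observer's `(p_j, q_j)` from the posteriors. Iteration stops when the
#' largest change in any `p_j`/`q_j` falls below `tol` or after `max_iter`
#' iterations. The consensus mask is the posterior thresholded at 0.5 with
#' ties counted as foreground.
#'
#' Voxels are grouped by their observer-label pattern (at most
#' `2^n_observers` patterns), which makes the EM exact but independent of
#' grid size.
#'
#' @param masks List of >= 2 `binary_mask`s sharing one grid; at least one
#'   must be non-empty.
#' @param tol Convergence tolerance on the rater parameters.
#' @param max_iter Maximum EM iterations.
#' @param prior Optional global foreground prior in (0, 1); default is the
#'   mean foreground fraction across observers.
#' @return A `staple_result`: `probability_map` (3D array), `consensus`
#'   (`binary_mask`), `sensitivity` and `specificity` (named per observer),
#'   `iterations`, `converged`, `prior`.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
#' masks <- replicate(3, binary_mask(m, spacing = c(1, 1, 1)), simplify = FALSE)
#' res <- staple(masks)
#' res$sensitivity
#' @export
staple <- function(masks, tol = 1e-6, max_iter = 100L, prior = NULL) {
  if (!is.list(masks) || length(masks) < 2)
    stop("need at least 2 masks", call. = FALSE)
  stopifnot(all(vapply(masks, inherits, logical(1), "binary_mask")))
  for (m in masks[-1]) stopifnot_same_geometry(masks[[1]], m, "masks")
  J <- length(masks)
  D <- vapply(masks, function(m) c(m$indicator), logical(prod(grid_dim(masks[[1]]))))
  if (!any(D)) stop("all masks are empty", call. = FALSE)
  g <- if (is.null(prior)) mean(D) else prior
  if (g <= 0 || g >= 1) stop("`prior` must be in (0, 1)", call. = FALSE)

  # group voxels by observer-label pattern
  code <- as.vector(D %*% 2^(seq_len(J) - 1)) + 1
  tab <- tabulate(code, nbits <- 2^J)
  pat <- which(tab > 0)
  wts <- tab[pat]
  Dp <- t(vapply(pat, function(cd) ((cd - 1) %/% 2^(seq_len(J) - 1)) %% 2,
                 numeric(J)))  # patterns x observers

  eps <- 1e-7
  p <- rep(0.99999, J)
  q <- rep(0.99999, J)
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    la <- log(g) + Dp %*% log(p) + (1 - Dp) %*% log(1 - p)
    lb <- log(1 - g) + (1 - Dp) %*% log(q) + Dp %*% log(1 - q)
    W <- as.numeric(1 / (1 + exp(lb - la)))
    sw <- sum(wts * W)
    swc <- sum(wts * (1 - W))
    p_new <- pmin(1 - eps, pmax(eps, colSums(wts * W * Dp) / sw))
    q_new <- pmin(1 - eps, pmax(eps, colSums(wts * (1 - W) * (1 - Dp)) / swc))
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  la <- log(g) + Dp %*% log(p) + (1 - Dp) %*% log(1 - p)
  lb <- log(1 - g) + (1 - Dp) %*% log(q) + Dp %*% log(1 - q)
  Wp <- as.numeric(1 / (1 + exp(lb - la)))
  lookup <- numeric(nbits)
  lookup[pat] <- Wp
  prob <- array(lookup[code], grid_dim(masks[[1]]))
  obs_names <- names(masks)
  if (is.null(obs_names)) obs_names <- paste0("obs", seq_len(J))
  structure(list(
    probability_map = prob,
    consensus = binary_mask(prob >= 0.5, geometry = masks[[1]]),
    sensitivity = stats::setNames(as.numeric(p), obs_names),
    specificity = stats::setNames(as.numeric(q), obs_names),
    iterations = it, converged = converged, prior = g),
    class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result> %d observers, %d EM iterations (%s), consensus %.2f cm^3\n",
              length(x$sensitivity), x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              mask_volume_cm3(x$consensus)))
  invisible(x)
}

#' Tidy a STAPLE fit into one row per observer
#' @param x A `staple_result`.
#' @param ... Unused.
#' @return Tibble with `observer_id`, `sensitivity`, `specificity`.
#' @export
tidy.staple_result <- function(x, ...) {
  tibble::tibble(observer_id = names(x$sensitivity),
                 sensitivity = unname(x$sensitivity),
                 specificity = unname(x$specificity))
}

#' One-row summary of a STAPLE fit
#' @param x A `staple_result`.
#' @param ... Unused.
#' @return Tibble with iteration count, convergence flag, prior, consensus
#'   volume.
#' @export
glance.staple_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 prior = x$prior,
                 consensus_volume_cm3 = mask_volume_cm3(x$consensus))
}
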