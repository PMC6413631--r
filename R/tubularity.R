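# Orientation-score tubularity: multiplies opposite oriented-edge responses
# (the positive-clipped imaginary part of the score) in the plane
# perpendicular to a candidate tube orientation and takes a smoothed
# minimum over the in-plane direction, so that only structures with a
# closed ring of edges (tubes, not plates or half-tubes) respond.

# Deterministic in-plane gauge: e1 proportional to n x e_z (or e_x when n
# is along e_z), e2 = n x e1.
tubularity_gauge <- function(n) {
  e1 <- c(n[2], -n[1], 0)
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Barycentric interpolation weights of direction d over the spherical
# triangulation: indices of the containing triangle's vertices and convex
# weights.  Planar barycentric coordinates (solve d = w1 v1 + w2 v2 + w3
# v3), selected by the triangle with the least-negative minimum weight.
orient_interp_weights <- function(grid, d) {
  d <- d / sqrt(sum(d^2))
  best <- NULL; bestmin <- -Inf
  for (t in seq_len(nrow(grid$triangles))) {
    idx <- grid$triangles[t, ]
    V <- t(grid$vectors[idx, ])
    w <- tryCatch(solve(V, d), error = function(e) NULL)
    if (is.null(w)) next
    if (any(!is.finite(w))) next
    s <- sum(w)
    if (s <= 1e-12) next   # triangle on the opposite hemisphere
    w <- w / s
    mn <- min(w)
    if (mn > bestmin) { bestmin <- mn; best <- list(idx = idx, w = w) }
    if (mn >= -1e-9) break
  }
  if (is.null(best)) stop("direction could not be located in the triangulation")
  best$w <- pmax(best$w, 0)
  best$w <- best$w / sum(best$w)
  best
}

# Wrapped-Gaussian smoothing matrix over the pi-periodic in-plane angle
# theta (trapezoid discretization at n_theta nodes); rows normalized so a
# constant edge profile is preserved.
theta_kernel <- function(n_theta, sigma_o) {
  th <- pi * (0:(n_theta - 1)) / n_theta
  K <- matrix(0, n_theta, n_theta)
  for (i in seq_len(n_theta)) {
    d <- abs(th - th[i])
    d <- pmin(d, pi - d)   # the edge product is pi-periodic in theta
    K[i, ] <- exp(-d^2 / (2 * sigma_o^2))
  }
  K / rowSums(K)
}

# Interpolated score value U(x, d): trilinear in space (zero outside),
# barycentric in orientation.  x is 1-based voxel coordinates.
score_interp <- function(score, x, d) {
  ow <- orient_interp_weights(score$grid, d)
  dims <- dim(score$data)[1:3]
  val <- 0i
  for (k in 1:3) {
    ch <- score$data[, , , ow$idx[k]]
    re <- cpp_sample_volume(Re(ch), dims, matrix(x - 1, 1))
    im <- cpp_sample_volume(Im(ch), dims, matrix(x - 1, 1))
    val <- val + ow$w[k] * complex(real = re, imaginary = im)
  }
  val
}

#' Product of opposite edge responses
#'
#' \eqn{E_{prod}(x, n, r, \theta) = \mathrm{Im}^+[U(x + r n^\perp(\theta),
#' n^\perp(\theta))] \cdot \mathrm{Im}^+[U(x - r n^\perp(\theta),
#' -n^\perp(\theta))]} with \eqn{\mathrm{Im}^+(z) = \max(0, \mathrm{Im}\,
#' z)}; the score is interpolated trilinearly in space (zero outside the
#' volume) and barycentrically over the orientation triangulation.
#'
#' @param score an `orientation_score` on a triangulated grid.
#' @param x position (1-based voxel coordinates).
#' @param n candidate tube orientation (unit vector).
#' @param r radius (voxels, > 0).
#' @param theta in-plane angle (radians).
#' @return nonnegative scalar.
#' @export
edge_product <- function(score, x, n, r, theta) {
  stopifnot(r > 0)
  g <- tubularity_gauge(n)
  np <- cos(theta) * g$e1 + sin(theta) * g$e2
  ep <- max(0, Im(score_interp(score, x + r * np, np)))
  em <- max(0, Im(score_interp(score, x - r * np, -np)))
  ep * em
}

#' Tubularity profile at one position and orientation
#'
#' \eqn{V(x, n, r) = \min_\theta \sum_{\theta'} K^{or}_{\sigma_o}(\theta -
#' \theta') E_{prod}(x, n, r, \theta')}: the smoothed minimum over the
#' in-plane direction of the opposite-edge products, per radius.
#'
#' @inheritParams edge_product
#' @param radii vector of radii to evaluate.
#' @param n_theta number of in-plane angles (>= 4).
#' @param sigma_o angular smoothing width (radians).
#' @param theta0 offset of the theta sampling grid (equivalently a
#'   rotation of the in-plane gauge about n); the measure is
#'   approximately invariant to it.
#' @return numeric vector of V values, one per radius.
#' @export
tubularity_profile <- function(score, x, n, radii, n_theta = 8,
                               sigma_o = pi / 8, theta0 = 0) {
  stopifnot(n_theta >= 4, sigma_o > 0)
  K <- theta_kernel(n_theta, sigma_o)
  th <- theta0 + pi * (0:(n_theta - 1)) / n_theta
  vapply(radii, function(r) {
    E <- vapply(th, function(t) edge_product(score, x, n, r, t), numeric(1))
    min(as.vector(K %*% E))
  }, numeric(1))
}

#' Tubularity features over a volume
#'
#' Evaluates the tubularity measure at every voxel (or a mask) for all
#' grid orientations and the given radii, and extracts the confidence
#' \eqn{s^t(x) = \max_{n,r} V}, the optimal orientation \eqn{n^*(x)} and
#' the optimal radius \eqn{r^*(x)} (deterministic tie-breaking: lowest
#' orientation index, then smallest radius).
#'
#' @param score an `orientation_score` built on a triangulated
#'   (icosahedral) grid.
#' @param radii radii swept (voxels); default 10 log-spaced values in
#'   `[1, 6]`.
#' @param n_theta in-plane angular samples.
#' @param sigma_o angular smoothing width (radians).
#' @param mask optional logical 3D array restricting evaluation.
#' @return an object of class `tubularity_result`: `s_t` (3D), `n_star`
#'   (unit-vector field, 4D with last dim 3), `r_star` (3D),
#'   `radii_tested`, `n_theta`, `sigma_o`, and `n_outside` (count of
#'   samples beyond the volume, treated as 0).
#' @export
tubularity_features <- function(score, radii = NULL, n_theta = 8,
                                sigma_o = pi / 8, mask = NULL) {
  if (is.null(score$grid$triangles)) {
    stop("tubularity requires a triangulated orientation grid")
  }
  radii <- radii %||% exp(seq(log(1), log(6), length.out = 10))
  stopifnot(all(diff(radii) > 0), all(radii > 0), n_theta >= 4)
  grid <- score$grid
  nv <- nrow(grid$vectors)
  th <- pi * (0:(n_theta - 1)) / n_theta
  ndir <- nv * n_theta
  dirs <- matrix(0, ndir, 3)
  idxP <- matrix(0L, ndir, 3); wP <- matrix(0, ndir, 3)
  idxN <- matrix(0L, ndir, 3); wN <- matrix(0, ndir, 3)
  for (i in seq_len(nv)) {
    g <- tubularity_gauge(grid$vectors[i, ])
    for (j in seq_len(n_theta)) {
      d <- cos(th[j]) * g$e1 + sin(th[j]) * g$e2
      row <- (i - 1) * n_theta + j
      dirs[row, ] <- d
      op <- orient_interp_weights(grid, d)
      on <- orient_interp_weights(grid, -d)
      idxP[row, ] <- op$idx - 1L; wP[row, ] <- op$w
      idxN[row, ] <- on$idx - 1L; wN[row, ] <- on$w
    }
  }
  ImW <- Im(score$data)
  K <- theta_kernel(n_theta, sigma_o)
  mk <- if (is.null(mask)) as.logical(NA) else as.logical(mask)
  res <- cpp_tubularity(ImW, dim(score$data), dirs, idxP, wP, idxN, wN,
                        radii, K, mk)
  n_star <- array(0, c(dim(res$s_t), 3))
  for (k in 1:3) {
    n_star[, , , k] <- array(grid$vectors[res$n_index, k], dim(res$s_t))
  }
  structure(list(s_t = res$s_t, n_star = n_star, r_star = res$r_star,
                 n_index = res$n_index,
                 radii_tested = radii, n_theta = n_theta, sigma_o = sigma_o,
                 n_outside = res$n_outside, grid = grid),
            class = "tubularity_result")
}

#' @export
print.tubularity_result <- function(x, ...) {
  cat(sprintf("tubularity_result: %s, radii %.2g..%.2g (%d), n_theta = %d\n",
              paste(dim(x$s_t), collapse = "x"),
              min(x$radii_tested), max(x$radii_tested),
              length(x$radii_tested), x$n_theta))
  cat(sprintf("  confidence range [%.4g, %.4g]; %d boundary samples\n",
              min(x$s_t), max(x$s_t), x$n_outside))
  invisible(x)
}

#' Ball-union segmentation from tubularity features
#'
#' Selects the positions in the top `centers_quantile` fraction of the
#' tubularity confidence and returns the indicator of the 0-sublevel set
#' of the distance map \eqn{d(x) = \min_i (\|x - c_i\| - r^*(c_i))}: the
#' union of balls centered at the selected positions with their optimal
#' radii.
#'
#' @param result a `tubularity_result`.
#' @param centers_quantile fraction in (0, 1) of highest-confidence
#'   voxels used as ball centers.
#' @return logical 3D array (the segmentation); attribute `n_centers`
#'   records the number of balls.
#' @export
ball_union_segmentation <- function(result, centers_quantile = 0.01) {
  stopifnot(centers_quantile > 0, centers_quantile < 1)
  thr <- stats::quantile(result$s_t, 1 - centers_quantile, names = FALSE)
  sel <- which(result$s_t >= thr & result$s_t > 0)
  if (length(sel) == 0) {
    warning("no voxels above the confidence quantile: empty segmentation")
    out <- array(FALSE, dim(result$s_t))
    attr(out, "n_centers") <- 0L
    return(out)
  }
  dims <- dim(result$s_t)
  idx <- arrayInd(sel, dims)
  dmap <- cpp_ball_union_dist(dims, idx - 1, result$r_star[sel])
  out <- dmap <= 0
  attr(out, "n_centers") <- length(sel)
  out
}
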