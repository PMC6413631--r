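# Crossing-preserving coherence-enhancing diffusion of orientation scores
# (CEDOS).  The score U(x, n) is treated as a function on R^3 x S^2
# embedded in SE(3); derivatives are taken in the left-invariant frame
# {A_1..A_6} (A_3 along the orientation, A_1/A_2 spatially perpendicular,
# A_4/A_5 angular; A_6 acts trivially on the zonal embedding) or in a
# locally adapted gauge frame {B_1..B_6} whose B_3 follows the structure
# tangent fitted from a first-order structure tensor.

# Rotation taking e_z to the grid orientation i: R = R_z(gamma) R_y(beta).
orientation_frames <- function(grid) {
  beta <- grid$euler[, "beta"]; gamma <- grid$euler[, "gamma"]
  cb <- cos(beta); sb <- sin(beta); cg <- cos(gamma); sg <- sin(gamma)
  list(
    a1 = cbind(cb * cg, cb * sg, -sb),     # R e_x
    a2 = cbind(-sg, cg, 0),                # R e_y
    a3 = grid$vectors                      # R e_z = n
  )
}

# Cotangent Laplace-Beltrami matrix on the triangulated orientation grid,
# normalized by the grid's quadrature areas:
# (L W)_i = (1/Delta_i) sum_j w_ij (W_j - W_i).
ang_laplacian <- function(grid) {
  if (is.null(grid$triangles)) {
    stop("orientation grid has no mesh connectivity; angular operators ",
         "require an icosahedral (triangulated) grid")
  }
  v <- grid$vectors
  tri <- grid$triangles
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- v[b, ] - v[a, ]; w <- v[c, ] - v[a, ]
    cr <- sqrt(sum(c(u[2] * w[3] - u[3] * w[2],
                     u[3] * w[1] - u[1] * w[3],
                     u[1] * w[2] - u[2] * w[1])^2))
    sum(u * w) / max(cr, 1e-14)
  }
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
    for (e in list(c(a, b, c), c(b, c, a), c(c, a, b))) {
      # edge (e1, e2), opposite vertex e3
      ct <- cot_at(e[3], e[1], e[2])
      ii <- c(ii, e[1], e[2]); jj <- c(jj, e[2], e[1]); ww <- c(ww, ct / 2, ct / 2)
    }
  }
  n <- nrow(v)
  Wm <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  d <- Matrix::rowSums(Wm)
  L <- (Wm - Matrix::Diagonal(n, d)) / grid$weights
  methods::as(L, "CsparseMatrix")
}

# Per-node tangential derivative matrices (A_4, A_5): least-squares fit of
# the tangential gradient from mesh-neighbor differences, expressed in the
# local basis (t1 = d/d beta, t2 = azimuthal; deterministic fallback near
# the poles).  Returns sparse matrices D4, D5 with (D4 U)_i the derivative
# along t1 at node i.
ang_gradients <- function(grid) {
  if (is.null(grid$triangles)) {
    stop("orientation grid has no mesh connectivity; angular operators ",
         "require an icosahedral (triangulated) grid")
  }
  v <- grid$vectors
  n <- nrow(v)
  nbrs <- vector("list", n)
  for (t in seq_len(nrow(grid$triangles))) {
    tr <- grid$triangles[t, ]
    for (k in 1:3) {
      nbrs[[tr[k]]] <- union(nbrs[[tr[k]]], tr[-k])
    }
  }
  ii4 <- integer(0); jj4 <- integer(0); xx4 <- numeric(0)
  ii5 <- integer(0); jj5 <- integer(0); xx5 <- numeric(0)
  for (i in seq_len(n)) {
    ni <- v[i, ]
    beta <- acos(pmin(1, pmax(-1, ni[3])))
    if (sin(beta) > 1e-8) {
      gam <- atan2(ni[2], ni[1])
      t1 <- c(cos(beta) * cos(gam), cos(beta) * sin(gam), -sin(beta))
      t2 <- c(-sin(gam), cos(gam), 0)
    } else {
      t1 <- c(1, 0, 0)
      t2 <- c(0, if (ni[3] >= 0) 1 else -1, 0)
    }
    js <- nbrs[[i]]
    A <- matrix(0, length(js), 2)
    for (k in seq_along(js)) {
      d <- v[js[k], ] - ni
      d <- d - ni * sum(d * ni)   # project to the tangent plane
      A[k, ] <- c(sum(d * t1), sum(d * t2))
    }
    P <- solve(crossprod(A), t(A))  # 2 x nj pseudo-inverse
    ii4 <- c(ii4, rep(i, length(js) + 1)); jj4 <- c(jj4, js, i)
    xx4 <- c(xx4, P[1, ], -sum(P[1, ]))
    ii5 <- c(ii5, rep(i, length(js) + 1)); jj5 <- c(jj5, js, i)
    xx5 <- c(xx5, P[2, ], -sum(P[2, ]))
  }
  list(D4 = Matrix::sparseMatrix(i = ii4, j = jj4, x = xx4, dims = c(n, n)),
       D5 = Matrix::sparseMatrix(i = ii5, j = jj5, x = xx5, dims = c(n, n)))
}

# Apply an N_o x N_o operator across the orientation axis of a 4D array.
apply_ang <- function(W, Op) {
  d <- dim(W)
  m <- matrix(W, prod(d[1:3]), d[4])
  array(as.matrix(m %*% Matrix::t(Op)), d)
}

#' Left-invariant derivatives of an orientation score
#'
#' First-order (`order = 1`) returns the spatial derivatives `A1`, `A2`,
#' `A3` of every orientation channel along its rotated frame (A3 along the
#' orientation, central differences with trilinear sampling along the
#' rotated axes, periodic boundary) and the angular derivatives `A4`, `A5`
#' (least-squares tangential gradients on the triangulated grid).
#' Second-order (`order = 2`) returns the iterated symmetric second
#' differences `A11`, `A22`, `A33` and the spherical Laplacian `Aang`
#' (cotangent discretisation, equal to \eqn{A_4^2 + A_5^2 + A_6^2} on the
#' zonal embedding).
#'
#' @param score an `orientation_score` (its real part is used) or a
#'   numeric 4D array plus `grid`.
#' @param order 1 or 2.
#' @param grid orientation grid (defaults to `score$grid`).
#' @param h spatial step of the stencil (voxels).
#' @return named list of 4D arrays.
#' @export
left_invariant_derivatives <- function(score, order = 1, grid = NULL, h = 1) {
  if (inherits(score, "orientation_score")) {
    grid <- grid %||% score$grid
    W <- score_real(score)
  } else {
    if (is.null(grid)) stop("grid required for bare arrays")
    W <- if (is.complex(score)) Re(score) else score
  }
  fr <- orientation_frames(grid)
  d4 <- dim(W)
  if (order == 1) {
    ag <- ang_gradients(grid)
    list(A1 = cpp_dirderiv_const(W, d4, fr$a1, h, 1L),
         A2 = cpp_dirderiv_const(W, d4, fr$a2, h, 1L),
         A3 = cpp_dirderiv_const(W, d4, fr$a3, h, 1L),
         A4 = apply_ang(W, ag$D4),
         A5 = apply_ang(W, ag$D5))
  } else if (order == 2) {
    L <- ang_laplacian(grid)
    list(A11 = cpp_dirderiv_const(W, d4, fr$a1, h, 2L),
         A22 = cpp_dirderiv_const(W, d4, fr$a2, h, 2L),
         A33 = cpp_dirderiv_const(W, d4, fr$a3, h, 2L),
         Aang = apply_ang(W, L))
  } else stop("order must be 1 or 2")
}

# Fourier-domain Gaussian smoothing of each orientation channel.
smooth_channels <- function(W, sigma) {
  if (sigma <= 0) return(W)
  d <- dim(W)
  G <- exp(-0.5 * sigma^2 * omega_norm_grid(d[1:3])^2)
  out <- W
  nv <- prod(d[1:3])
  for (i in seq_len(d[4])) {
    out[, , , i] <- Re(stats::fft(G * stats::fft(W[, , , i]), inverse = TRUE)) / nv
  }
  out
}

shift3 <- function(a, ax, by) {
  idx <- lapply(dim(a), seq_len)
  n <- dim(a)[ax]
  idx[[ax]] <- ((seq_len(n) - 1 + by) %% n) + 1
  do.call(`[`, c(list(a), idx))
}

#' Fit the locally adaptive gauge frame
#'
#' Estimates, per position and orientation, the structure tangent `B3` as
#' the eigenvector with smallest eigenvalue of the spatially and angularly
#' regularised structure tensor of the (real part of the) score; `B1`,
#' `B2` complete the spatially perpendicular plane (deterministic gauge)
#' and the angular directions are kept from the left-invariant frame.
#' This first-order fit approximates an exponential-curve fit: the tangent
#' of the locally best-aligned curve.  Where the tensor is degenerate
#' (relative eigenvalue gap below `degeneracy_tol`) the frame falls back
#' to the left-invariant frame (`B3 = n_i`).
#'
#' @param score an `orientation_score` or numeric 4D array (with `grid`).
#' @param spatial_scale Gaussian scale (voxels) of tensor smoothing.
#' @param angular_scale mixing weight in `[0, 1]` of one neighbor-averaging
#'   step of the tensor across the orientation mesh.
#' @param grad_scale Gaussian pre-smoothing scale of the score before
#'   differentiation.
#' @param degeneracy_tol relative eigenvalue-gap threshold of the fallback.
#' @param grid orientation grid (defaults to `score$grid`).
#' @return an object of class `gauge_frame`: fields `vx`, `vy`, `vz`
#'   (components of B3), logical `fallback`, numeric `gap`.
#' @export
fit_gauge_frame <- function(score, spatial_scale = 1.5, angular_scale = 0.3,
                            grad_scale = 1, degeneracy_tol = 0.8, grid = NULL) {
  if (inherits(score, "orientation_score")) {
    grid <- grid %||% score$grid
    W <- score_real(score)
  } else {
    if (is.null(grid)) stop("grid required for bare arrays")
    W <- if (is.complex(score)) Re(score) else score
  }
  stopifnot(spatial_scale >= 0, angular_scale >= 0)
  d <- dim(W)
  Ws <- smooth_channels(W, grad_scale)
  gx <- (shift3(Ws, 1, 1) - shift3(Ws, 1, -1)) / 2
  gy <- (shift3(Ws, 2, 1) - shift3(Ws, 2, -1)) / 2
  gz <- (shift3(Ws, 3, 1) - shift3(Ws, 3, -1)) / 2
  J <- list(xx = gx * gx, xy = gx * gy, xz = gx * gz,
            yy = gy * gy, yz = gy * gz, zz = gz * gz)
  J <- lapply(J, smooth_channels, sigma = spatial_scale)
  if (angular_scale > 0 && !is.null(grid$triangles)) {
    ag <- ang_adjacency_mean(grid)
    lam <- min(1, angular_scale)
    J <- lapply(J, function(a) (1 - lam) * a + lam * apply_ang(a, ag))
  }
  eig <- cpp_smallest_eigvec(J$xx, J$xy, J$xz, J$yy, J$yz, J$zz,
                             d, grid$vectors)
  fb <- eig$gap < degeneracy_tol
  if (any(fb)) {
    nvox <- prod(d[1:3])
    for (i in seq_len(d[4])) {
      sel <- which(fb[, , , i])
      if (length(sel)) {
        off <- (i - 1) * nvox
        eig$vx[off + sel] <- grid$vectors[i, 1]
        eig$vy[off + sel] <- grid$vectors[i, 2]
        eig$vz[off + sel] <- grid$vectors[i, 3]
      }
    }
  }
  structure(list(vx = eig$vx, vy = eig$vy, vz = eig$vz,
                 fallback = fb, gap = eig$gap, grid = grid,
                 spatial_scale = spatial_scale, angular_scale = angular_scale),
            class = "gauge_frame")
}

ang_adjacency_mean <- function(grid) {
  n <- nrow(grid$vectors)
  ii <- integer(0); jj <- integer(0)
  for (t in seq_len(nrow(grid$triangles))) {
    tr <- grid$triangles[t, ]
    ii <- c(ii, tr, tr[c(2, 3, 1)]); jj <- c(jj, tr[c(2, 3, 1)], tr)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                            dims = c(n, n))
  A@x <- rep(1, length(A@x))  # dedupe
  Matrix::Diagonal(n, 1 / Matrix::rowSums(A)) %*% A
}

#' @export
print.gauge_frame <- function(x, ...) {
  cat(sprintf("gauge_frame: %s nodes, fallback at %.1f%% of (x, n)\n",
              paste(dim(x$vx), collapse = "x"), 100 * mean(x$fallback)))
  invisible(x)
}

#' Data-adaptive diffusivities
#'
#' Orientation confidence \eqn{s(U) = -\sum_{i\in\{1,2,4,5,6\}} B_i^2 U}
#' (minus the Laplacian in the directions orthogonal to the structure
#' tangent) steers the perpendicular diffusivity
#' \eqn{D_{11} = 1 - e^{-(c_1/s)^2}} (1 where \eqn{s \le 0}), with
#' \eqn{c_1} the `quantile` of s over the score.  The tangential
#' diffusivity \eqn{D_{33} = 1 - e^{-(c_2/(B_3 U))^2}} (1 where
#' \eqn{B_3 U = 0}) stops diffusion at structure endpoints, with
#' \eqn{c_2} the same quantile of \eqn{|B_3 U|}.
#'
#' @param score an `orientation_score` or numeric 4D array.
#' @param frame a `gauge_frame` fitted on the same score.
#' @param quantile adaptivity quantile (default 0.5).
#' @param d11_floor lower bound applied to D11 in `"floor"` mode, or its
#'   constant value in `"constant"` mode.
#' @param d11_mode `"floor"` keeps the adaptive D11 bounded below by
#'   `d11_floor`; `"constant"` fixes D11 to `d11_floor` everywhere (the
#'   configuration used for edge-location experiments; see vignette).
#' @param D44 angular diffusivity constant.
#' @return an object of class `diffusivity_field`: `D11`, `D33` in
#'   `[0, 1]`, scalar `D44`, quantile values `c1`, `c2`.
#' @export
adaptive_diffusivities <- function(score, frame, quantile = 0.5,
                                   d11_floor = 0.001, D44 = 0.01,
                                   d11_mode = c("floor", "constant")) {
  d11_mode <- match.arg(d11_mode)
  W <- if (inherits(score, "orientation_score")) score_real(score) else
    if (is.complex(score)) Re(score) else score
  d <- dim(W)
  gd <- cpp_gauge_derivs(W, d, frame$vx, frame$vy, frame$vz)
  L <- ang_laplacian(frame$grid)
  s <- -(gd$d2perp + apply_ang(W, L))
  # quantile of the magnitude: the signed median degenerates to ~0 on
  # noise-dominated scores where s is sign-symmetric (see vignette)
  c1 <- stats::quantile(abs(s), quantile, names = FALSE)
  D11 <- ifelse(s <= 0, 1, 1 - exp(-(c1 / s)^2))
  D11 <- if (d11_mode == "constant") array(d11_floor, d) else
    pmin(pmax(D11, d11_floor), 1)
  b3u <- gd$db3
  c2 <- stats::quantile(abs(b3u), quantile, names = FALSE)
  D33 <- ifelse(b3u == 0, 1, 1 - exp(-(c2 / b3u)^2))
  dim(D11) <- d; dim(D33) <- d
  structure(list(D11 = D11, D33 = D33, D44 = D44, c1 = c1, c2 = c2),
            class = "diffusivity_field")
}

#' @export
print.diffusivity_field <- function(x, ...) {
  cat(sprintf("diffusivity_field: D11 in [%.3g, %.3g], D33 in [%.3g, %.3g], D44 = %.3g\n",
              min(x$D11), max(x$D11), min(x$D33), max(x$D33), x$D44))
  cat(sprintf("  quantiles c1 = %.4g, c2 = %.4g\n", x$c1, x$c2))
  invisible(x)
}

# Explicit-scheme step bound: 1 / (2 (2 max D11 + max D33)/h^2 +
# D44 * max_i sum_j |L_ij|) -- diagonal dominance of the full stencil.
evolve_dt_bound <- function(diff, L, h = 1) {
  gersh <- max(Matrix::rowSums(abs(L)))
  1 / (2 * (2 * max(diff$D11) + max(diff$D33)) / h^2 + diff$D44 * gersh)
}

#' Evolve an orientation score by adaptive diffusion
#'
#' Explicit Euler time stepping of
#' \eqn{\partial_t W = D_{11}(B_1^2 + B_2^2)W + D_{33}B_3^2 W +
#' D_{44}(B_4^2+B_5^2+B_6^2)W} on the real part of the score, with frozen
#' coefficients.  The step size must respect the documented stability
#' bound (computed from the stencil); the default uses 80% of it.
#'
#' @param score an `orientation_score` (real part is evolved).
#' @param frame a `gauge_frame`.
#' @param diff a `diffusivity_field`.
#' @param t_end diffusion end time (>= 0; 0 returns the input).
#' @param dt explicit step; `NULL` selects `0.8 *` the stability bound.
#' @return the evolved `orientation_score` (numeric data).
#' @export
evolve <- function(score, frame, diff, t_end, dt = NULL) {
  stopifnot(t_end >= 0)
  W <- score_real(score)
  out <- score
  if (t_end == 0) {
    out$data <- W
    return(out)
  }
  L <- ang_laplacian(frame$grid)
  bound <- evolve_dt_bound(diff, L)
  if (is.null(dt)) dt <- 0.8 * bound
  if (dt > bound + 1e-12) {
    stop(sprintf("dt = %.4g exceeds the explicit stability bound %.4g", dt, bound))
  }
  nfull <- floor(t_end / dt)
  rem <- t_end - nfull * dt
  dts <- c(rep(dt, nfull), if (rem > 1e-12) rem)
  Lc <- methods::as(L, "CsparseMatrix")
  Wn <- cpp_evolve(W, dim(W), frame$vx, frame$vy, frame$vz,
                   diff$D11, diff$D33, diff$D44,
                   Lc@p, Lc@i, Lc@x, dts)
  if (max(Wn) > max(W) + 1e-6) {
    warning(sprintf("maximum principle violated: max grew by %.3g",
                    max(Wn) - max(W)))
  }
  out$data <- Wn
  out
}

#' Coherence-enhancing diffusion via orientation scores, end to end
#'
#' Pipeline: forward transform, gauge-frame fit, adaptive diffusivities,
#' explicit diffusion, reconstruction by summation (which includes the
#' inherent projection back onto the range of the transform).
#'
#' @param vol a `volume3d` or 3D array.
#' @param stack a `wavelet_stack`.
#' @param t_end diffusion end time.
#' @param D44 angular diffusivity.
#' @param quantile adaptivity quantile.
#' @param d11_floor floor on D11 (or its constant value).
#' @param d11_mode `"floor"` or `"constant"`, see
#'   [adaptive_diffusivities()].
#' @param dt explicit step (`NULL`: from the stability bound).
#' @param spatial_scale,angular_scale,grad_scale gauge-frame fit scales.
#' @return the enhanced `volume3d`; attributes `c1`, `c2`, `dt_bound`
#'   record the adaptive quantiles and the stability bound.
#' @export
cedos_pipeline <- function(vol, stack, t_end = 2, D44 = 0.01, quantile = 0.5,
                           d11_floor = 0.001, d11_mode = "floor", dt = NULL,
                           spatial_scale = 1.5, angular_scale = 0.3,
                           grad_scale = 1) {
  sc <- forward(vol, stack)
  fr <- fit_gauge_frame(sc, spatial_scale, angular_scale, grad_scale)
  df <- adaptive_diffusivities(sc, fr, quantile, d11_floor, D44, d11_mode)
  ev <- evolve(sc, fr, df, t_end, dt)
  out <- reconstruct_sum(ev)
  attr(out, "c1") <- df$c1
  attr(out, "c2") <- df$c2
  attr(out, "dt_bound") <- evolve_dt_bound(df, ang_laplacian(stack$grid))
  out
}
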