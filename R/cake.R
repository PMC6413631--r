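# DFT cake wavelets: Fourier-domain design of an orientation-selective
# filter bank that tiles the Fourier ball, with splitting into low and high
# frequency channels and spherical-harmonic steering of rotated filters.

#' Wavelet design parameters
#'
#' Bundles the parameters of the orientation-score filter bank with their
#' customary defaults: 42 orientations, inflection fraction
#' `gamma = 0.85` of the Nyquist frequency, radial decay width
#' `sigma_erf = (rho_N - varrho)/3`, Fourier-Gaussian low-pass scale
#' `s_rho = (1/2) 16^2`, spherical diffusion time `s_o = (1/2) 0.45^2`, and
#' filters sampled on an 11x11x11 grid.  The Nyquist frequency is
#' \eqn{\rho_N = \pi} radians/voxel.
#'
#' @param n_orient number of orientations.
#' @param gamma inflection fraction in (0,1); the ball-limit is
#'   `varrho = gamma * rho_N`.
#' @param sigma_erf radial decay width (radians/voxel); default
#'   `(rho_N - varrho)/3`.
#' @param s_rho low-pass Fourier-Gaussian scale (the low-pass is
#'   `exp(-s_rho |omega|^2)`).
#' @param s_o angular diffusion time of the orientation distribution.
#' @param L angular truncation degree; `NULL` selects the smallest degree
#'   with heat-kernel coefficient ratio below `1e-3`.
#' @param grid_size odd filter size per axis.
#' @param rho_N Nyquist frequency in radians/voxel.
#' @return an object of class `wavelet_params`.
#' @export
wavelet_params <- function(n_orient = 42L, gamma = 0.85, sigma_erf = NULL,
                           s_rho = 0.5 * 16^2, s_o = 0.5 * 0.45^2,
                           L = NULL, grid_size = 11L, rho_N = pi) {
  stopifnot(gamma > 0, gamma < 1, s_rho > 0, s_o > 0, rho_N > 0)
  if (grid_size %% 2 == 0) stop("grid_size must be odd (centered filters)")
  varrho <- gamma * rho_N
  if (is.null(sigma_erf)) sigma_erf <- (rho_N - varrho) / 3
  stopifnot(sigma_erf > 0)
  if (!is.null(L) && L > MAX_DEGREE) stop("L exceeds the cap of ", MAX_DEGREE)
  structure(list(n_orient = as.integer(n_orient), gamma = gamma,
                 sigma_erf = sigma_erf, s_rho = s_rho, s_o = s_o, L = L,
                 grid_size = as.integer(grid_size), rho_N = rho_N,
                 varrho = varrho),
            class = "wavelet_params")
}

#' @export
print.wavelet_params <- function(x, ...) {
  cat(sprintf(paste0("wavelet_params: N_o = %d, gamma = %.3g ",
                     "(varrho = %.4g rad/vox), sigma_erf = %.4g,\n",
                     "  s_rho = %.4g, s_o = %.4g, grid %dx%dx%d, rho_N = %.4g\n"),
              x$n_orient, x$gamma, x$varrho, x$sigma_erf, x$s_rho, x$s_o,
              x$grid_size, x$grid_size, x$grid_size, x$rho_N))
  invisible(x)
}

#' Radial frequency profile of the cake wavelet
#'
#' \eqn{g(\rho) = \frac12 (1 - \mathrm{erf}((\rho - \varrho)/\sigma_{erf}))}:
#' approximately 1 over most of the ball and decaying smoothly to 0 towards
#' the Nyquist frequency, with inflection point at
#' \eqn{\varrho = \gamma \rho_N}.
#'
#' @param rho frequency magnitude(s), radians/voxel.
#' @param params a `wavelet_params` object.
#' @return numeric vector of profile values.
#' @export
radial_profile <- function(rho, params) {
  0.5 * (1 - erf((rho - params$varrho) / params$sigma_erf))
}

#' Split a radial profile into low and high frequency parts
#'
#' Multiplies by the Fourier-Gaussian window
#' \eqn{\hat G_{s_\rho}(\omega) = e^{-s_\rho \|\omega\|^2}} and its
#' complement, so that `low + high` reproduces the input exactly.
#'
#' @param g_hat profile values (any shape).
#' @param omega_norm matching \eqn{\|\omega\|} values.
#' @param s_rho splitting scale.
#' @return list with components `low` and `high`.
#' @export
split_lowpass <- function(g_hat, omega_norm, s_rho) {
  G <- exp(-s_rho * omega_norm^2)
  list(low = G * g_hat, high = (1 - G) * g_hat)
}

# Angular coefficients of the cake wavelet (line/edge detector):
# c_l = (P_l(0) + (1-(-1)^l)/2) * a_l, with a_l the heat-kernel spectrum.
cake_angular_coeffs <- function(params, plate = FALSE) {
  sp <- heat_kernel_spectrum(params$s_o, tol = 1e-3)
  L <- if (is.null(params$L)) attr(sp, "L") else params$L
  if (L > MAX_DEGREE) stop("angular truncation exceeds the cap of ", MAX_DEGREE)
  a <- sqrt((2 * (0:L) + 1) / (4 * pi)) * exp(-(0:L) * ((0:L) + 1) * params$s_o)
  l <- 0:L
  fac <- if (plate) 1 else legendre_at_zero(l) + (1 - (-1)^l) / 2
  list(a = a, c = fac * a, L = L)
}

# Zonal evaluation of the steered angular part: for unit directions `u`
# (n x 3) and orientation `n0`, h(u) = sum_l c_l sqrt((2l+1)/4pi) P_l(n0.u).
zonal_eval_dot <- function(c_l, dots) {
  L <- length(c_l) - 1L
  P <- legendre_poly_table(L, dots)
  as.vector(P %*% (c_l * sqrt((2 * (0:L) + 1) / (4 * pi))))
}

#' Build the DFT cake-wavelet stack
#'
#' Samples, for every orientation in `grid`, the Fourier-domain filter
#' \eqn{\hat\psi_{n_i}(\omega) = g(\rho)\, h_{n_i}(\omega/\rho)} on the
#' centered DFT grid of size `grid_size`^3, where the angular part is the
#' steered combination of Funk-transformed and anti-symmetrized heat-kernel
#' coefficients.  Each filter is split into a high-frequency part
#' \eqn{\hat\psi_1 = (1-\hat G_{s_\rho})\hat\psi} (stored, used for the
#' transform) and the complementary low-frequency part; spatial filters are
#' obtained by a centered inverse DFT.  The low-pass channel is the spatial
#' Gaussian \eqn{G_{s_\rho}(x) = (4\pi s_\rho)^{-3/2} e^{-\|x\|^2/(4 s_\rho)}}
#' with Fourier transform \eqn{e^{-s_\rho\|\omega\|^2}}.
#'
#' @param params a `wavelet_params` object.
#' @param grid an `orientation_grid` with `n_orient` orientations.
#' @return an object of class `wavelet_stack` with components
#'   `fourier_filters` (high-frequency, centered layout, complex
#'   `grid_size^3 x N_o`), `fourier_unsplit`, `spatial_filters`,
#'   `lowpass_spatial`, `ang_coeffs`, `radial_table`, `params`, `grid`,
#'   `design = "cake_dft"`.
#' @export
build_cake_stack <- function(params, grid) {
  build_dft_stack(params, grid, plate = FALSE)
}

#' Plate-detector variant of the cake wavelet stack
#'
#' Uses the orientation distribution directly as angular part (no Funk
#' transform), so the real part of the spatial filter responds to plates
#' perpendicular to the orientation instead of lines along it.  The
#' imaginary (edge) part is identical to the cake wavelet's.
#'
#' @inheritParams build_cake_stack
#' @return a `wavelet_stack` with `design = "plate_dft"`.
#' @export
assemble_plate_wavelet <- function(params, grid) {
  build_dft_stack(params, grid, plate = TRUE)
}

build_dft_stack <- function(params, grid, plate = FALSE) {
  if (params$grid_size %% 2 == 0) stop("grid_size must be odd")
  if (nrow(grid$vectors) != params$n_orient) {
    stop("grid has ", nrow(grid$vectors), " orientations but params expect ",
         params$n_orient)
  }
  n <- params$grid_size
  cf <- cake_angular_coeffs(params, plate = plate)
  ax <- 2 * pi * centered_axis(n) / n   # centered frequency axis
  wx <- rep(ax, times = n * n)
  wy <- rep(rep(ax, each = n), times = n)
  wz <- rep(ax, each = n * n)
  rho <- sqrt(wx^2 + wy^2 + wz^2)
  g <- radial_profile(rho, params)
  Ghat <- exp(-params$s_rho * rho^2)
  u <- cbind(wx, wy, wz) / ifelse(rho > 0, rho, 1)
  dc <- which(rho == 0)
  nv <- nrow(grid$vectors)
  four_hi <- matrix(0i, n^3, nv)
  four_full <- matrix(0i, n^3, nv)
  spat <- matrix(0i, n^3, nv)
  h0 <- cf$c[1] / sqrt(4 * pi)   # l = 0 term only at the origin
  for (i in seq_len(nv)) {
    dots <- as.vector(u %*% grid$vectors[i, ])
    h <- zonal_eval_dot(cf$c, dots)
    h[dc] <- h0
    psi <- g * h
    four_full[, i] <- psi
    four_hi[, i] <- (1 - Ghat) * psi
    arr <- array(four_hi[, i], c(n, n, n))
    sp <- stats::fft(ifftshift3(arr), inverse = TRUE) / n^3
    spat[, i] <- as.vector(fftshift3(sp))
  }
  xs <- centered_axis(n)
  r2 <- outer(outer(xs^2, xs^2, `+`), xs^2, `+`)
  lowpass <- (4 * pi * params$s_rho)^(-3 / 2) * exp(-r2 / (4 * params$s_rho))
  rad_rho <- seq(0, sqrt(3) * params$rho_N, length.out = 2048)
  structure(list(
    fourier_filters = four_hi,
    fourier_unsplit = four_full,
    spatial_filters = spat,
    lowpass_spatial = lowpass,
    ang_coeffs = cf$c,
    heat_coeffs = cf$a,
    radial_table = cbind(rho = rad_rho, g = radial_profile(rad_rho, params)),
    params = params, grid = grid,
    design = if (plate) "plate_dft" else "cake_dft"
  ), class = "wavelet_stack")
}

#' @export
print.wavelet_stack <- function(x, ...) {
  n <- x$params$grid_size
  cat(sprintf("wavelet_stack (%s): %d orientations, %dx%dx%d filters, L = %d\n",
              x$design, nrow(x$grid$vectors), n, n, n,
              length(x$ang_coeffs) - 1))
  cat(sprintf("  s_o = %.4g, s_rho = %.4g, gamma = %.3g\n",
              x$params$s_o, x$params$s_rho, x$params$gamma))
  invisible(x)
}

# Retrieve one filter as a 3D array (centered layout).
stack_filter <- function(stack, i, which = c("spatial", "fourier", "fourier_unsplit")) {
  which <- match.arg(which)
  n <- stack$params$grid_size
  m <- switch(which, spatial = stack$spatial_filters,
              fourier = stack$fourier_filters,
              fourier_unsplit = stack$fourier_unsplit)
  array(m[, i], c(n, n, n))
}
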