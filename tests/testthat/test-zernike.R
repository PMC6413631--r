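test_that("Zernike radial functions: closed forms and boundary behaviour", {
  rho <- seq(0, 1, 0.05)
  for (a in c(1, 3, 6)) {
    expect_equal(zernike_radial(0, 0, a, rho), (1 - rho^2)^a)
    expect_equal(zernike_radial(4, 2, a, 1), 0)
  }
  expect_error(zernike_radial(3, 0, 1, 0.5), "even")
  expect_error(zernike_radial(1, 3, 1, 0.5), "even|nonneg")
  expect_equal(zernike_norm(0, 0, 0), 1 / 3)
})

test_that("orthogonality under the weighted ball measure (quadrature oracle)", {
  gl <- pracma::gaussLegendre(200, 0, 1)
  for (a in c(1, 3, 6)) {
    for (l in 0:3) for (p1 in 0:3) for (p2 in p1:3) {
      n1 <- l + 2 * p1; n2 <- l + 2 * p2
      if (n1 > 6 || n2 > 6) next
      I <- sum(gl$w * zernike_radial(n1, l, a, gl$x) *
                 zernike_radial(n2, l, a, gl$x) * gl$x^2 / (1 - gl$x^2)^a)
      ref <- if (p1 == p2) zernike_norm(n1, l, a) else 0
      expect_lt(abs(I - ref) / zernike_norm(n1, l, a), 1e-6)
    }
  }
})

test_that("analytic radial inverse Fourier transform: values, quadrature, continuity", {
  expect_equal(analytic_ift_radial(0, 0, 0, 0), 1 / 3)
  expect_equal(analytic_ift_radial(2, 0, 3, 0), 0)    # delta_{n,0}
  expect_equal(analytic_ift_radial(4, 2, 1, 0), 0)
  # against direct quadrature of the defining integral
  gl <- pracma::gaussLegendre(300, 0, 1)
  jl <- function(l, x) ifelse(x == 0, as.numeric(l == 0),
                              sqrt(pi / (2 * x)) * besselJ(x, l + 0.5))
  for (cs in list(c(2, 0, 3), c(5, 1, 3), c(6, 2, 6), c(2, 0, 3))) {
    for (q in c(0.5, 5, 12)) {
      I <- sum(gl$w * zernike_radial(cs[1], cs[2], cs[3], gl$x) *
                 jl(cs[2], q * gl$x) * gl$x^2)
      expect_lt(abs(I - analytic_ift_radial(cs[1], cs[2], cs[3], q)), 1e-8)
    }
    # continuity at q -> 0
    expect_lt(abs(analytic_ift_radial(cs[1], cs[2], cs[3], 1e-7) -
                    analytic_ift_radial(cs[1], cs[2], cs[3], 0)), 1e-8)
  }
})

test_that("flattened radial profile: expansion matches the closed form", {
  rho <- seq(0, 1, 0.005)
  for (a in c(3, 6)) {
    for (l in c(0, 2)) {
      bt <- flat_radial_coeffs(a, l, 40)
      rec <- numeric(length(rho))
      for (p in 0:40) rec <- rec + bt[p + 1] * zernike_radial(l + 2 * p, l, a, rho)
      direct <- oscore3d:::flat_profile(a, rho)
      ok <- if (l == 0) rep(TRUE, length(rho)) else rho > 1e-8
      expect_lt(max(abs(rec[ok] - direct[ok])), 0.01)
    }
  }
  # maximum of the raw bump sits at rho_max^2 = 1/(alpha+1) (1/7 for alpha 6)
  b62 <- function(r) (1 - r^2)^6 * r^2
  expect_equal(optimize(b62, c(0, 1), maximum = TRUE, tol = 1e-10)$maximum^2,
               1 / 7, tolerance = 1e-6)
  # the flattening polynomial is the 2nd-order Taylor series of 1/B around
  # rho_max: match its rho^4 coefficient (343/12 for alpha 6) numerically
  u0 <- 1 / 7; h <- 1e-3
  recip <- function(u) 1 / ((1 - u)^6 * u) # as a function of u = rho^2
  d2 <- (recip(u0 + h) - 2 * recip(u0) + recip(u0 - h)) / h^2
  c2_num <- 0.5 * d2 * b62(sqrt(u0))
  expect_equal(c2_num, 343 / 12, tolerance = 1e-4)
})

test_that("Zernike stack: parity, center value, separability, DFT agreement", {
  g <- grid42()
  p <- wavelet_params(s_rho = 0.5 * 1.9^2, s_o = 0.5 * 0.4^2, grid_size = 15L)
  st <- build_zernike_stack(p, g, alpha = 3)
  n <- 15
  rev3 <- function(a) a[n:1, n:1, n:1]
  for (i in c(2, 33)) {
    f <- array(st$spatial_filters[, i], c(n, n, n))
    expect_lt(max(abs(Re(f) - Re(rev3(f)))), 1e-8)
    expect_lt(max(abs(Im(f) + Im(rev3(f)))), 1e-8)
    # value at the center (r = 0) is real: only l = 0 survives
    ctr <- (n + 1) / 2
    expect_lt(abs(Im(f[ctr, ctr, ctr])), 1e-12)
  }
  # separability: the sampled Fourier filter factorizes into the radial
  # profile times the steered angular part
  ax <- 2 * pi * oscore3d:::centered_axis(n) / n
  wx <- rep(ax, times = n * n)
  wy <- rep(rep(ax, each = n), times = n)
  wz <- rep(ax, each = n * n)
  rho <- sqrt(wx^2 + wy^2 + wz^2)
  i <- 5
  dots <- (wx * g$vectors[i, 1] + wy * g$vectors[i, 2] + wz * g$vectors[i, 3]) /
    ifelse(rho > 0, rho, 1)
  B <- oscore3d:::flat_profile(3, rho / p$rho_N)
  sel <- rho > 0 & rho <= p$rho_N
  # where the per-degree radial expansion terminates (degrees l <= 2, for
  # which rho^(2-l) * polynomial(rho^2) is itself polynomial) the expansion
  # equals the radial profile to near machine precision; the remaining
  # degrees converge slowly, so the sampled filter matches the exact
  # product form A * B only to the truncation level
  rg <- seq(0, 1, 0.01)
  for (l in c(0, 2)) {
    bt <- flat_radial_coeffs(3, l, 40)
    rec <- numeric(length(rg))
    for (pp in 0:40) rec <- rec + bt[pp + 1] * zernike_radial(l + 2 * pp, l, 3, rg)
    expect_lt(max(abs(rec - oscore3d:::flat_profile(3, rg))[rg > 1e-8 | l == 0]),
              1e-6)
  }
  h <- oscore3d:::zonal_eval_dot(st$ang_coeffs, dots)
  expect_lt(max(Mod(st$fourier_filters[sel, i] - (B * h)[sel])), 2e-3)
  # DFT of the Fourier-sampled filter approaches the analytic spatial filter
  p31 <- wavelet_params(s_rho = 0.5 * 1.9^2, s_o = 0.5 * 0.4^2, grid_size = 31L)
  st31 <- build_zernike_stack(p31, g, alpha = 3)
  err <- 0; den <- 0
  for (i in c(1, 20)) {
    fr <- array(st31$fourier_filters[, i], c(31, 31, 31))
    sp <- oscore3d:::fftshift3(stats::fft(oscore3d:::ifftshift3(fr),
                                          inverse = TRUE) / 31^3)
    sa <- array(st31$spatial_filters[, i], c(31, 31, 31))
    err <- err + sum(Mod(sp - sa)^2); den <- den + sum(Mod(sa)^2)
  }
  expect_lt(sqrt(err / den), 0.05)
})

test_that("an under-truncated radial expansion warns with diagnostics", {
  g <- grid42()
  p <- wavelet_params(s_o = 0.5 * 0.4^2, grid_size = 9L)
  expect_warning(build_zernike_stack(p, g, alpha = 3, p_max = 1,
                                     radial_tol = 1e-6), "not converged")
})
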