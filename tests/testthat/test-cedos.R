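test_that("left-invariant derivatives reproduce analytic fields", {
  g <- grid42()
  dims <- c(16, 16, 16)
  nv <- 42
  # constant score: all derivatives vanish
  Wc <- array(2, c(dims, nv))
  ld <- left_invariant_derivatives(Wc, 1, grid = g)
  for (nm in names(ld)) expect_lt(max(abs(ld[[nm]])), 1e-12)
  # U(x, n) = x . n has A3 U = 1 (exact for the trilinear stencil away
  # from the periodic seam)
  xs <- 1:16
  W <- array(0, c(dims, nv))
  for (i in 1:nv) {
    n <- g$vectors[i, ]
    W[, , , i] <- outer(outer(xs * n[1], xs * n[2], `+`), xs * n[3], `+`)
  }
  ld <- left_invariant_derivatives(W, 1, grid = g)
  int <- 5:12
  expect_equal(range(ld$A3[int, int, int, ]), c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(ld$A1[int, int, int, ])), 1e-10)
  expect_lt(max(abs(ld$A2[int, int, int, ])), 1e-10)
})

test_that("the mesh Laplacian has spherical-harmonic eigenvalues", {
  g <- grid42()
  L <- oscore3d:::ang_laplacian(g)
  y1 <- Re(sph_harm(1, 0, acos(g$vectors[, 3]),
                    atan2(g$vectors[, 2], g$vectors[, 1])))
  err <- sqrt(sum((as.vector(L %*% y1) + 2 * y1)^2) / sum((2 * y1)^2))
  expect_lt(err, 0.10)
  # second-order angular operator in the module surface
  dims <- c(8, 8, 8)
  W <- array(rep(y1, each = prod(dims)), c(dims, 42))
  ld <- left_invariant_derivatives(W, 2, grid = g)
  expect_lt(rel_l2(ld$Aang, -2 * W), 0.10)
  # a grid without mesh connectivity is rejected
  gr <- sample_sphere(20, "repulsion")
  expect_error(left_invariant_derivatives(W[, , , 1:20], 1, grid = gr),
               "mesh connectivity")
})

test_that("gauge frame: tube tangent recovery and isotropic fallback", {
  g <- grid42()
  st <- stack_default()
  ph <- make_tube(32, "straight", sigma = 2)
  sc <- forward(ph$volume, st)
  fr <- fit_gauge_frame(sc)
  iz <- which.max(g$vectors[, 3])
  tube <- ph$dist_gt <= 2
  ang <- acos(pmin(1, abs(fr$vz[, , , iz][tube]))) * 180 / pi
  expect_lt(stats::quantile(ang, 0.9), 5)
  # unit tangents
  nrm <- sqrt(fr$vx^2 + fr$vy^2 + fr$vz^2)
  expect_lt(max(abs(nrm - 1)), 1e-8)
  # isotropic random score falls back to the left-invariant frame
  set.seed(5)
  Wr <- array(rnorm(32^3 * 42), c(32, 32, 32, 42))
  frr <- fit_gauge_frame(bare_score(Wr, g))
  expect_gt(mean(frr$fallback), 0.90)
})

test_that("adaptive diffusivities: ranges, limits, degenerate cases", {
  g <- grid42()
  st <- stack_default()
  ph <- make_tube(24, "straight", sigma = 2)
  sc <- forward(add_noise(ph$volume, 0.3, seed = 1), st)
  fr <- fit_gauge_frame(sc)
  df <- adaptive_diffusivities(sc, fr)
  expect_true(all(df$D11 >= 0.001 & df$D11 <= 1))
  expect_true(all(df$D33 >= 0 & df$D33 <= 1))
  expect_gt(df$c1, 0); expect_gt(df$c2, 0)
  # formula landmarks: s = c1 -> D11 = 1 - e^{-1}; s <= 0 -> 1; s -> Inf -> 0
  d11 <- function(s, c1) ifelse(s <= 0, 1, 1 - exp(-(c1 / s)^2))
  expect_equal(d11(0.3, 0.3), 1 - exp(-1))
  expect_equal(d11(-1, 0.3), 1)
  expect_lt(d11(1e6, 0.3), 1e-10)
  # constant score: B3 U = 0 everywhere -> D33 = 1
  Wc <- array(1, c(16, 16, 16, 42))
  frc <- const_frame(c(16, 16, 16), g)
  dfc <- adaptive_diffusivities(bare_score(Wc, g), frc)
  expect_equal(max(abs(dfc$D33 - 1)), 0)
  # constant mode pins D11
  dfk <- adaptive_diffusivities(sc, fr, d11_mode = "constant")
  expect_equal(range(dfk$D11), c(0.001, 0.001))
})

test_that("evolve: identity at t = 0, step-bound validation, max principle", {
  g <- grid42()
  dims <- c(12, 12, 12)
  set.seed(1)
  W <- oscore3d:::smooth_channels(array(rnorm(prod(dims) * 42), c(dims, 42)), 1)
  sc <- bare_score(W, g)
  fr <- const_frame(dims, g)
  df <- const_diffusivities(dims, g, 0.5, 1, 0.02)
  e0 <- evolve(sc, fr, df, 0)
  expect_identical(e0$data, W)
  expect_error(evolve(sc, fr, df, 1, dt = 10), "stability bound")
  ev <- evolve(sc, fr, df, 1)
  expect_lte(max(ev$data), max(W) + 1e-6)
  # orientation-weighted mass is conserved for constant coefficients
  m0 <- sum(sweep(matrix(W, ncol = 42), 2, g$weights, `*`))
  m1 <- sum(sweep(matrix(ev$data, ncol = 42), 2, g$weights, `*`))
  expect_lt(abs(m1 - m0) / abs(m0), 0.005)
})

test_that("constant-coefficient isotropic diffusion matches a Gaussian blur", {
  g <- grid42()
  dims <- c(24, 24, 24)
  set.seed(3)
  W <- oscore3d:::smooth_channels(array(rnorm(prod(dims) * 42), c(dims, 42)), 2.5)
  sc <- bare_score(W, g)
  ev <- evolve(sc, const_frame(dims, g),
               const_diffusivities(dims, g, 1, 1, 0), t_end = 1, dt = 0.02)
  Wg <- oscore3d:::smooth_channels(W, sqrt(2))
  expect_lt(rel_l2(ev$data, Wg), 0.01)
})

test_that("the pipeline reduces background variance monotonically in t", {
  st <- stack_default()
  ph <- make_tube(32, "straight", sigma = 2)
  nv <- add_noise(ph$volume, 0.5, seed = 4)
  bg <- ph$dist_gt > 8
  vars <- vapply(c(0, 1, 2), function(t)
    stats::var(cedos_pipeline(nv, st, t_end = t)$data[bg]), numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("diffusion commutes with a 90-degree volume rotation (2% tolerance)", {
  st <- stack_default()
  ph <- make_tube(32, "straight", sigma = 2)
  va <- rot_y90(ph$volume$data)
  outA <- cedos_pipeline(volume3d(va), st, t_end = 1)
  outB <- cedos_pipeline(ph$volume, st, t_end = 1)
  expect_lt(rel_l2(outA$data, rot_y90(outB$data)), 0.02)
})
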