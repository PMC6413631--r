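test_that("forward transform: linearity, zero input, impulse identity", {
  st <- stack_default()
  dims <- c(12, 12, 12)
  z <- forward(volume3d(array(0, dims) + 0, spacing = c(1, 1, 1)), st)
  # zero input -> zero score (volume3d forbids <8 voxels, fine at 12)
  expect_equal(max(Mod(z$data)), 0)
  expect_equal(max(abs(z$lowfreq)), 0)
  # impulse at the center, spatial-kernel mode: each channel equals the
  # reversed conjugate filter
  n <- st$params$grid_size
  imp <- array(0, c(n, n, n)); ctr <- (n + 1) / 2
  imp[ctr, ctr, ctr] <- 1
  sc <- forward(volume3d(imp), st, filters = "spatial")
  for (i in c(4, 40)) {
    filt <- oscore3d:::stack_filter(st, i, "spatial")
    ref <- Conj(filt[n:1, n:1, n:1])
    expect_lt(max(Mod(sc$data[, , , i] - ref)), 1e-10)
  }
})

test_that("real input gives an odd imaginary part across antipodal channels", {
  st <- stack_default()
  g <- grid42()
  ph <- make_tube(16, "straight", sigma = 2)
  sc <- forward(ph$volume, st)
  # icosahedral grids are antipodally symmetric: locate -n for each n
  anti <- apply(-g$vectors, 1, function(v)
    which.max(g$vectors %*% v))
  for (i in c(2, 9, 20)) {
    expect_lt(max(abs(Im(sc$data[, , , i]) + Im(sc$data[, , , anti[i]]))), 1e-8)
    expect_lt(max(abs(Re(sc$data[, , , i]) - Re(sc$data[, , , anti[i]]))), 1e-8)
  }
})

test_that("summation reconstruction: constant volumes, weight linearity, accuracy", {
  st <- stack_default()
  dims <- c(32, 32, 32)
  vc <- volume3d(array(3.7, dims))
  rc <- reconstruct_sum(forward(vc, st))
  expect_lt(max(abs(rc$data - 3.7)), 1e-6)
  # random ball-limited volume
  f <- ball_limited_volume(dims)
  sc <- forward(volume3d(f), st)
  r <- reconstruct_sum(sc)
  expect_lt(rel_l2(r$data, f), 0.05)
  expect_lt(attr(r, "imag_energy"), 1e-10)
  # doubling the quadrature weights doubles the high-frequency term
  sc2 <- sc
  sc2$grid$weights <- 2 * sc$grid$weights
  r2 <- reconstruct_sum(sc2)
  hi1 <- r$data - sc$lowfreq
  hi2 <- r2$data - sc$lowfreq
  expect_equal(hi2, 2 * hi1, tolerance = 1e-12)
  # missing low-frequency channel is an instructive error
  sc$lowfreq <- NULL
  expect_error(reconstruct_sum(sc), "low-frequency")
})

test_that("exact reconstruction inverts ball-limited volumes", {
  st <- stack_default()
  dims <- c(32, 32, 32)
  f <- ball_limited_volume(dims, seed = 9)
  sc <- forward(volume3d(f), st)
  r <- reconstruct_exact(sc, st)
  expect_lt(rel_l2(r$data, f), 1e-2)
  # a single Fourier mode inside the ball is recovered at full amplitude
  ii <- 0:(dims[1] - 1)
  k <- c(4, 2, 5)
  arr <- array(0, dims)
  for (z in ii) {
    arr[, , z + 1] <- cos(2 * pi * (outer(ii * k[1], ii * k[2], function(a, b)
      a / dims[1] + b / dims[2]) + z * k[3] / dims[3]))
  }
  rm_ <- reconstruct_exact(forward(volume3d(arr), st), st)
  expect_lt(max(abs(rm_$data - arr)), 1e-3)
})

test_that("transform is translation-equivariant under periodic boundaries", {
  st <- stack_default()
  f <- ball_limited_volume(c(16, 16, 16), seed = 2)
  sc <- forward(volume3d(f), st)
  fs <- f[c(4:16, 1:3), , ]                 # shift by 3 voxels along x
  scs <- forward(volume3d(fs), st)
  expect_equal(scs$data[, , , 7], sc$data[c(4:16, 1:3), , , 7],
               tolerance = 1e-12)
})

test_that("norm relation holds for a stack rescaled to M = 1", {
  st <- stack_default()
  dims <- c(24, 24, 24)
  f <- ball_limited_volume(dims, seed = 5)
  fhat <- stats::fft(f)
  w <- st$grid$weights
  Ghat <- exp(-st$params$s_rho * oscore3d:::omega_norm_grid(dims)^2)
  M <- Ghat^2
  U2 <- 0
  Fis <- vector("list", 42)
  for (i in 1:42) {
    Fis[[i]] <- oscore3d:::synth_fourier_filter(st, dims, i)
    M <- M + Mod(Fis[[i]])^2 * w[i]
  }
  scale <- sqrt(pmax(M, 1e-12))
  for (i in 1:42) {
    U2 <- U2 + sum(Mod(Fis[[i]] / scale * fhat)^2) * w[i]
  }
  U2 <- U2 + sum(Mod(Ghat / scale * fhat)^2)
  expect_equal(U2 / sum(Mod(fhat)^2), 1, tolerance = 1e-3)
})

test_that("stability diagnostics: splitting identity and condition numbers", {
  rep <- os_diagnostics(stack_default())
  expect_lt(rep$lemma_residual, 1e-10)
  expect_gte(rep$cond_A, 1)
  expect_gt(rep$M_min, 0)
  expect_gte(rep$M_max, rep$M_min)
  # M of the split pair stays above half the unsplit floor (Lemma bound)
  st <- stack_default()
  w <- st$grid$weights
  M_full <- as.vector(Mod(st$fourier_unsplit)^2 %*% w)
  n <- st$params$grid_size
  ax <- 2 * pi * oscore3d:::centered_axis(n) / n
  rho <- as.vector(sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`)))
  G <- exp(-st$params$s_rho * rho^2)
  M_split <- as.vector(Mod(G * st$fourier_unsplit)^2 %*% w) +
    as.vector(Mod((1 - G) * st$fourier_unsplit)^2 %*% w)
  inball <- rho > 0 & rho <= 0.75 * st$params$varrho
  delta <- min(M_full[inball])
  expect_gte(min(M_split[inball]), delta / 2 - 1e-12)
})

test_that("a single-orientation stack reproduces M = 4 pi |psi|^2", {
  g1 <- oscore3d:::grid_from_vectors(matrix(c(0, 0, 1), 1))
  g1$weights <- 4 * pi
  p <- wavelet_params(n_orient = 1L, grid_size = 9L)
  st1 <- build_cake_stack(p, g1)
  M <- as.vector(Mod(st1$fourier_unsplit)^2 %*% (4 * pi))
  expect_equal(M, 4 * pi * Mod(st1$fourier_unsplit[, 1])^2, tolerance = 1e-14)
})

test_that("volume containers validate their inputs", {
  expect_error(volume3d(array(1, c(4, 4, 4))), "8 voxels")
  expect_error(volume3d(array(c(1, NA), c(8, 8, 8))), "finite")
  expect_error(volume3d(matrix(1, 8, 8)), "3D")
})
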