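test_that("spherical harmonics match closed forms and are orthonormal", {
  th <- c(0.3, 1.2, 2.8); ph <- c(0.1, 2.0, 5.5)
  expect_equal(sph_harm(0, 0, th, ph), rep(1 / sqrt(4 * pi) + 0i, 3))
  expect_equal(sph_harm(1, 0, th, ph), sqrt(3 / (4 * pi)) * cos(th) + 0i)
  # conjugation symmetry of the convention
  expect_equal(sph_harm(2, -1, th, ph), (-1)^1 * Conj(sph_harm(2, 1, th, ph)))
  # |Y_3^2| integrates to 1 (numerical quadrature oracle)
  q <- sphere_quadrature()
  I <- sum(Mod(sph_harm(3, 2, q$theta, q$phi))^2 * q$w)
  expect_equal(I, 1, tolerance = 1e-6)
  # cross-orthogonality
  I2 <- sum(sph_harm(3, 2, q$theta, q$phi) *
              Conj(sph_harm(4, 2, q$theta, q$phi)) * q$w)
  expect_lt(Mod(I2), 1e-6)
  expect_error(sph_harm(2, 3, 0.1, 0.1), "m")
})

test_that("heat-kernel spectrum follows the stated ratio and truncation rule", {
  for (s_o in c(0.5 * 0.25^2, 0.06, 0.5 * 0.45^2)) {
    sp <- heat_kernel_spectrum(s_o, tol = 1e-3)
    a <- oscore3d:::zonal_part(sp)
    expect_equal(a[1], sqrt(1 / (4 * pi)))
    L <- attr(sp, "L")
    ratio <- function(l) sqrt(2 * l + 1) * exp(-l * (l + 1) * s_o)
    expect_equal(a / a[1], vapply(0:L, ratio, numeric(1)))
    # L is the smallest degree below the tolerance
    expect_lt(ratio(L), 1e-3)
    expect_gte(ratio(L - 1), 1e-3)
  }
})

test_that("reconstructed heat kernel is nonnegative at practical truncation", {
  beta <- seq(0, pi, by = pi / 180)
  for (s_o in c(0.005, 0.02, 0.1)) {
    sp <- heat_kernel_spectrum(s_o, tol = 1e-3)
    vals <- Re(spec_eval(sp, beta, rep(0, length(beta))))
    # positive up to the O(tol) ringing of the truncated expansion
    expect_gte(min(vals), -1e-3 * max(vals))
  }
})

test_that("Funk transform is diagonal with eigenvalue P_l(0)", {
  sp <- heat_kernel_spectrum(0.05)
  ft <- funk_transform(sp)
  a <- oscore3d:::zonal_part(sp); b <- oscore3d:::zonal_part(ft)
  expect_equal(b[1], a[1])                      # l = 0 unchanged
  expect_equal(b[2], 0)                         # l = 1 annihilated
  expect_equal(b[3], -0.5 * a[3])               # l = 2 scaled by -1/2
  # against brute-force great-circle quadrature on random spectra
  set.seed(1)
  for (rep in 1:3) {
    L <- 10
    coeffs <- lapply(0:L, function(l) {
      v <- complex(real = rnorm(2 * l + 1), imaginary = rnorm(2 * l + 1))
      # make the function real: a_{l,-m} = (-1)^m conj(a_{l,m})
      if (l > 0) for (m in 1:l)
        v[l + 1 - m] <- (-1)^m * Conj(v[l + 1 + m])
      v[l + 1] <- complex(real = Re(v[l + 1]))
      v * 0.3
    })
    sp <- angular_spectrum(coeffs)
    ft <- funk_transform(sp)
    dirs <- oscore3d:::fibonacci_sphere(24)
    num <- oscore3d:::funk_numeric(function(t, p) Re(spec_eval(sp, t, p)), dirs)
    ana <- Re(spec_eval(ft, acos(dirs[, 3]), atan2(dirs[, 2], dirs[, 1])))
    expect_lt(max(abs(num - ana)), 1e-6)
  }
})

test_that("anti-symmetrization keeps odd degrees and enforces h(-n) = -h(n)", {
  sp <- heat_kernel_spectrum(0.05)
  as_ <- antisymmetrize(sp)
  a <- oscore3d:::zonal_part(sp); b <- oscore3d:::zonal_part(as_)
  l <- 0:(length(a) - 1)
  expect_equal(b[l %% 2 == 0], rep(0, sum(l %% 2 == 0)))
  expect_equal(b[l %% 2 == 1], a[l %% 2 == 1])
  dirs <- oscore3d:::fibonacci_sphere(50)
  h1 <- spec_eval(as_, acos(dirs[, 3]), atan2(dirs[, 2], dirs[, 1]))
  h2 <- spec_eval(as_, acos(-dirs[, 3]), atan2(-dirs[, 2], -dirs[, 1]))
  expect_lt(max(Mod(h1 + h2)), 1e-10)
})

test_that("Wigner rotation: identity, pointwise oracle, unitarity, inverse", {
  sp <- heat_kernel_spectrum(0.08)
  id <- wigner_rotate(sp, 0, 0)
  expect_equal(id$coeffs, sp$coeffs, tolerance = 1e-14)
  # rotated zonal function evaluated at the new pole equals the old pole value
  for (bg in list(c(0.7, 1.3), c(2.1, -0.4), c(1.5707, 3.0))) {
    rot <- wigner_rotate(sp, bg[1], bg[2])
    v_new <- spec_eval(rot, bg[1], bg[2])
    v_pole <- spec_eval(sp, 0, 0)
    expect_equal(Re(v_new), Re(v_pole), tolerance = 1e-10)
    expect_lt(abs(Im(v_new)), 1e-10)
    # norm preservation
    n2 <- function(s) sum(vapply(s$coeffs, function(v) sum(Mod(v)^2), numeric(1)))
    expect_equal(n2(rot), n2(sp), tolerance = 1e-12)
    # inverse rotation restores the spectrum
    back <- wigner_rotate(rot, -bg[1], 0, alpha = -bg[2])
    err <- max(vapply(0:sp$max_degree, function(l)
      max(Mod(back$coeffs[[l + 1]] - sp$coeffs[[l + 1]])), numeric(1)))
    expect_lt(err, 1e-10)
  }
})

test_that("wigner_d matches the explicit l = 1 matrix", {
  b <- 0.7
  d1 <- wigner_d(1, b)
  # rows/cols ordered m = -1, 0, 1
  ref <- matrix(c((1 + cos(b)) / 2, sin(b) / sqrt(2), (1 - cos(b)) / 2,
                  -sin(b) / sqrt(2), cos(b), sin(b) / sqrt(2),
                  (1 - cos(b)) / 2, -sin(b) / sqrt(2), (1 + cos(b)) / 2),
                3, 3, byrow = TRUE)
  expect_equal(d1, ref, tolerance = 1e-14)
})
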