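test_that("tube phantoms have Gaussian cross-sections and exact ground truth", {
  ph <- make_tube(25, "straight", sigma = 2, amplitude = 1.5)
  ctr <- 13
  # intensity at distance sigma from the axis is amplitude * exp(-1/2)
  expect_equal(ph$volume$data[ctr + 2, ctr, 5], 1.5 * exp(-1 / 2),
               tolerance = 1e-6)
  expect_true(all(ph$radius_gt == 2))
  expect_error(make_tube(24, "straight", sigma = 0.5), "at least 1")
  # random tubes are reproducible bit for bit and respect the margin
  a <- make_tube(40, "random", seed = 5)
  b <- make_tube(40, "random", seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_true(all(a$radius_gt >= 1.5 & a$radius_gt <= 3))
  lim <- 3 * 3
  expect_true(all(a$centerline[, 1] >= 1 + lim & a$centerline[, 1] <= 40 - lim))
})

test_that("crossing phantoms superpose two tubes with known axes", {
  cr <- make_crossing(25, angle = 90, sigmas = c(2, 2), amplitudes = c(1, 1))
  ctr <- 13
  expect_equal(cr$volume$data[ctr, ctr, ctr], max(cr$volume$data),
               tolerance = 0.05)
  expect_equal(cr$volume$data[ctr, ctr, ctr], 1, tolerance = 1e-6)
  crs <- make_crossing(25, angle = 90, mode = "sum")
  expect_equal(crs$volume$data[ctr, ctr, ctr], 2, tolerance = 1e-6)
  expect_warning(make_crossing(25, angle = 10), "near-parallel")
  expect_equal(nrow(cr$axes), 2)
})

test_that("a crossing lifts to two distinct orientation maxima", {
  st <- stack_default()
  cr <- make_crossing(32, angle = 90)
  sc <- forward(cr$volume, st)
  ctr <- round((32 + 1) / 2)
  prof <- Re(sc$data[ctr, ctr, ctr, ])
  lm <- orientation_local_maxima(prof, grid42())
  # modulo the antipodal pairing there are two distinct tube orientations
  dirs <- grid42()$vectors[lm, , drop = FALSE]
  dz <- abs(dirs[, 3]) > 0.9
  expect_gte(sum(dz), 1)
  expect_gte(sum(abs(dirs[, 1]) > 0.9), 1)
})

test_that("additive noise is seeded, unbiased, and correctly scaled", {
  ph <- make_tube(24, "straight", sigma = 2)
  expect_identical(add_noise(ph$volume, 0)$data, ph$volume$data)
  big <- volume3d(array(0, c(64, 64, 64)))
  nz <- add_noise(big, 0.37, seed = 8)
  expect_lt(abs(sd(nz$data - big$data) - 0.37) / 0.37, 0.02)
  expect_identical(add_noise(big, 0.37, seed = 8)$data, nz$data)
})

test_that("CNR: closed-form value, invariances, degenerate background", {
  dims <- c(16, 16, 16)
  set.seed(2)
  vol <- array(1 + rnorm(prod(dims), 0, 0.5), dims)
  omega_s <- array(FALSE, dims); omega_s[1:4, , ] <- TRUE
  vol[omega_s] <- 2
  omega_b <- array(FALSE, dims); omega_b[9:16, , ] <- TRUE
  regions <- list(omega_s = omega_s, omega_b = omega_b)
  v <- cnr(volume3d(vol), regions)
  expect_equal(v, (2 - mean(vol[omega_b])) / sd(vol[omega_b]))
  expect_equal(v, 2, tolerance = 0.1)
  # shift and scale invariance
  expect_equal(cnr(volume3d(vol + 5), regions), v, tolerance = 1e-12)
  expect_equal(cnr(volume3d(3 * vol), regions), v, tolerance = 1e-12)
  # pure noise: |CNR| small
  noise <- add_noise(volume3d(array(0, c(64, 64, 64))), 1, seed = 3)
  omega_s2 <- array(FALSE, c(64, 64, 64)); omega_s2[1:16, , ] <- TRUE
  omega_b2 <- array(FALSE, c(64, 64, 64)); omega_b2[33:64, , ] <- TRUE
  expect_lt(abs(cnr(noise, list(omega_s = omega_s2, omega_b = omega_b2))), 0.2)
  # constant background flags infinity
  volc <- array(1, dims); volc[omega_s] <- 2
  expect_warning(vi <- cnr(volume3d(volc), regions), "constant background")
  expect_equal(vi, Inf)
})

test_that("edge radius finds the inflection point of a Gaussian tube", {
  ph <- make_tube(32, "straight", sigma = 2)
  ctr <- c(16.5, 16.5, 16.5)
  r <- edge_radius(ph$volume, ctr, sigma_deriv = 0.5)
  expect_equal(as.numeric(r), 2, tolerance = 0.06)
  # stability across the derivative scale (within 5%)
  rs <- vapply(c(0.5, 1, 1.5), function(sd_)
    as.numeric(edge_radius(ph$volume, ctr, sigma_deriv = sd_)), numeric(1))
  expect_lt((max(rs) - min(rs)) / min(rs), 0.05)
  # and across the azimuthal sampling count (within 2%)
  ra <- vapply(c(8, 12, 16), function(na)
    as.numeric(edge_radius(ph$volume, ctr, n_azimuth = na)), numeric(1))
  expect_lt((max(ra) - min(ra)) / min(ra), 0.02)
  # no interior minimum on a flat volume -> flagged missing value
  flat <- volume3d(array(1, c(16, 16, 16)))
  rf <- edge_radius(flat, c(8.5, 8.5, 8.5))
  expect_true(is.na(rf))
  expect_equal(attr(rf, "n_valid"), 0L)
})

test_that("the random-tube suite is reproducible with radii in range", {
  suite <- paper_c_suite(n = 3, shape = 40, seed = 100L)
  expect_length(suite, 3)
  for (ph in suite) {
    expect_s3_class(ph, "phantom")
    expect_true(all(ph$radius_gt >= 1.5 & ph$radius_gt <= 3))
  }
  suite2 <- paper_c_suite(n = 3, shape = 40, seed = 100L)
  expect_identical(suite[[2]]$volume$data, suite2[[2]]$volume$data)
})
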