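# Shared fixtures, built once per test run.  Everything is generated in
# code; nothing is read from disk.

fix <- new.env()

grid42 <- function() {
  if (is.null(fix$grid42)) fix$grid42 <- sample_sphere(42, "icosahedral")
  fix$grid42
}

# Default cake stack (Table-style defaults, 11^3 filters).
stack_default <- function() {
  if (is.null(fix$stack_default)) {
    fix$stack_default <- build_cake_stack(wavelet_params(), grid42())
  }
  fix$stack_default
}

# Random real volume whose spectrum is supported in |omega| <= frac * varrho.
ball_limited_volume <- function(dims, frac = 0.8, seed = 7,
                                varrho = 0.85 * pi) {
  set.seed(seed)
  rho <- oscore3d:::omega_norm_grid(dims)
  fh <- array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
              dims) * (rho <= frac * varrho)
  f <- Re(stats::fft(fh, inverse = TRUE)) / prod(dims)
  f / sd(f)
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# Dense quadrature on the sphere (product trapezoid rule), returns nodes
# and weights for integration against sin(theta) d theta d phi.
sphere_quadrature <- function(n_theta = 200, n_phi = 400) {
  th <- seq(0, pi, length.out = n_theta + 1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(theta = th, phi = ph)
  w <- sin(g$theta) * (pi / n_theta) * (2 * pi / n_phi)
  list(theta = g$theta, phi = g$phi, w = w)
}

# Local maxima of a per-orientation profile over the grid's mesh graph.
orientation_local_maxima <- function(p, grid) {
  n <- nrow(grid$vectors)
  nbrs <- vector("list", n)
  for (t in seq_len(nrow(grid$triangles))) {
    tr <- grid$triangles[t, ]
    for (k in 1:3) nbrs[[tr[k]]] <- union(nbrs[[tr[k]]], tr[-k])
  }
  which(vapply(seq_len(n), function(i) all(p[i] >= p[nbrs[[i]]]), logical(1)))
}

# 90-degree rotation of a volume about the y axis: (x, y, z) -> (z, y, -x).
rot_y90 <- function(a) {
  d <- dim(a)
  aperm(a, c(3, 2, 1))[, , d[1]:1]
}

# Constant-coefficient frame/diffusivity pair (B = A) for evolve tests.
const_frame <- function(dims, grid) {
  nv <- nrow(grid$vectors)
  structure(list(
    vx = array(rep(grid$vectors[, 1], each = prod(dims)), c(dims, nv)),
    vy = array(rep(grid$vectors[, 2], each = prod(dims)), c(dims, nv)),
    vz = array(rep(grid$vectors[, 3], each = prod(dims)), c(dims, nv)),
    fallback = array(FALSE, c(dims, nv)), grid = grid), class = "gauge_frame")
}

const_diffusivities <- function(dims, grid, d11, d33, d44) {
  nv <- nrow(grid$vectors)
  structure(list(D11 = array(d11, c(dims, nv)), D33 = array(d33, c(dims, nv)),
                 D44 = d44, c1 = NA_real_, c2 = NA_real_),
            class = "diffusivity_field")
}

bare_score <- function(W, grid) {
  structure(list(data = W, grid = grid, lowfreq = array(0, dim(W)[1:3]),
                 spacing = c(1, 1, 1), origin = c(0, 0, 0)),
            class = "orientation_score")
}
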