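# Internal numerical helpers shared across modules.

# Centered DFT frequency axis (radians/voxel) for an n-point grid.
freq_axis <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * k / n
}

# Index permutation moving the centered layout (DC at (n+1)/2 for odd n,
# n/2+1 for even n) to DFT layout (DC at 1), and back.
fftshift_idx <- function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2))
ifftshift_idx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))

fftshift3 <- function(a) {
  d <- dim(a)
  a[fftshift_idx(d[1]), fftshift_idx(d[2]), fftshift_idx(d[3]), drop = FALSE]
}

ifftshift3 <- function(a) {
  d <- dim(a)
  a[ifftshift_idx(d[1]), ifftshift_idx(d[2]), ifftshift_idx(d[3]), drop = FALSE]
}

# |omega| on the DFT-layout grid (DC at [1,1,1]).
omega_norm_grid <- function(dims) {
  wx <- freq_axis(dims[1]); wy <- freq_axis(dims[2]); wz <- freq_axis(dims[3])
  sqrt(outer(outer(wx^2, wy^2, `+`), wz^2, `+`))
}

# Centered integer spatial coordinates for an odd-sized filter grid.
centered_axis <- function(n) seq_len(n) - (n + 1) / 2

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

relative_l2 <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

# Legendre polynomials P_0..P_lmax evaluated at t (vector); returns
# length(t) x (lmax+1) matrix. Three-term recurrence.
legendre_poly_table <- function(lmax, t) {
  out <- matrix(0, length(t), lmax + 1)
  out[, 1] <- 1
  if (lmax >= 1) out[, 2] <- t
  if (lmax >= 2) {
    for (l in 2:lmax) {
      out[, l + 1] <- ((2 * l - 1) * t * out[, l] - (l - 1) * out[, l - 1]) / l
    }
  }
  out
}

# P_l(0) in closed form: 0 for odd l, (-1)^(l/2) (l-1)!!/l!! for even l.
legendre_at_zero <- function(l) {
  ifelse(l %% 2 == 1, 0,
         (-1)^(l / 2) * exp(lgamma(l + 1) - 2 * (l / 2) * log(2) - 2 * lgamma(l / 2 + 1)))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
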