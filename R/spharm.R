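# Spherical harmonics, Funk transform, anti-symmetrization and Wigner-D
# steering on coefficient vectors.
#
# Convention: Y_l^m(theta, phi) = eps * sqrt((2l+1)/(4 pi)) *
#   sqrt((l-|m|)!/(l+|m|)!) * exp(i m phi) * P_l^{|m|}(cos theta),
# with eps = (-1)^m for m < 0 and eps = 1 for m >= 0, and P_l^m the
# associated Legendre function including the Condon-Shortley phase.  This is
# the standard physics convention; Y_l^{-m} = (-1)^m conj(Y_l^m).

MAX_DEGREE <- 64L

#' Angular spectrum (spherical-harmonic coefficient table)
#'
#' Creates a coefficient container for functions on the sphere expanded as
#' \eqn{\sum_{l=0}^{L}\sum_{m=-l}^{l} a_l^m Y_l^m}.  Coefficients are stored
#' densely per degree: `coeffs[[l+1]]` is a complex vector of length
#' `2l + 1` ordered `m = -l, ..., l`.
#'
#' @param coeffs list of complex vectors (one per degree), or `NULL` for a
#'   zero spectrum up to `max_degree`.
#' @param max_degree maximal degree L (capped at 64).
#' @return an object of class `angular_spectrum`.
#' @export
angular_spectrum <- function(coeffs = NULL, max_degree = NULL) {
  if (is.null(coeffs)) {
    stopifnot(!is.null(max_degree))
    coeffs <- lapply(0:max_degree, function(l) complex(2 * l + 1))
  }
  L <- length(coeffs) - 1L
  if (L > MAX_DEGREE) stop("max degree capped at ", MAX_DEGREE)
  for (l in 0:L) {
    if (length(coeffs[[l + 1]]) != 2 * l + 1) {
      stop("coefficient vector for degree ", l, " must have length ", 2 * l + 1)
    }
  }
  structure(list(coeffs = lapply(coeffs, as.complex), max_degree = L),
            class = "angular_spectrum")
}

# Convenience: zonal spectrum from a numeric vector a_l^0 (l = 0..L).
zonal_spectrum <- function(a_l0) {
  L <- length(a_l0) - 1L
  coeffs <- lapply(0:L, function(l) {
    v <- complex(2 * l + 1)
    v[l + 1] <- a_l0[l + 1]
    v
  })
  angular_spectrum(coeffs)
}

zonal_part <- function(spec) {
  vapply(0:spec$max_degree, function(l) Re(spec$coeffs[[l + 1]][l + 1]),
         numeric(1))
}

#' Spherical harmonic \eqn{Y_l^m}
#'
#' @param l degree (0 <= l).
#' @param m order (|m| <= l).
#' @param theta polar angle(s) in radians.
#' @param phi azimuthal angle(s) in radians.
#' @return complex vector of values.
#' @export
sph_harm <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("|m| must not exceed l")
  am <- abs(m)
  ct <- cos(theta)
  # pracma::legendre returns P_l^m (Condon-Shortley included), rows m = 0..l
  P <- pracma::legendre(l, ct)
  if (is.null(dim(P))) P <- matrix(P, ncol = length(ct))
  plm <- P[am + 1, ]
  eps <- if (m < 0) (-1)^m else 1
  norm <- sqrt((2 * l + 1) / (4 * pi)) *
    exp(0.5 * (lgamma(l - am + 1) - lgamma(l + am + 1)))
  eps * norm * plm * exp(1i * m * phi)
}

#' Evaluate an angular spectrum on the sphere
#'
#' @param spec an `angular_spectrum`.
#' @param theta,phi polar and azimuthal angles (vectors of equal length).
#' @return complex vector of function values.
#' @export
spec_eval <- function(spec, theta, phi) {
  out <- complex(length(theta))
  for (l in 0:spec$max_degree) {
    cl <- spec$coeffs[[l + 1]]
    nz <- which(Mod(cl) > 0)
    for (k in nz) {
      m <- k - l - 1L
      out <- out + cl[k] * sph_harm(l, m, theta, phi)
    }
  }
  out
}

#' Spectrum of the heat kernel on the sphere
#'
#' The diffusion kernel on \eqn{S^2} at time `s_o` is zonal with
#' \eqn{a_l^0 = \sqrt{(2l+1)/4\pi}\, e^{-l(l+1)s_o}}.  The expansion is
#' truncated at the smallest degree L for which the coefficient ratio
#' \eqn{a_L^0/a_0^0 = \sqrt{2L+1}\, e^{-L(L+1)s_o}} drops below `tol`.
#'
#' @param s_o diffusion time on the sphere (dimensionless), > 0.
#' @param tol truncation ratio in (0, 1).
#' @return a zonal `angular_spectrum`; the chosen degree is both
#'   `$max_degree` and attribute `L`.
#' @export
heat_kernel_spectrum <- function(s_o, tol = 1e-3) {
  stopifnot(s_o > 0, tol > 0, tol < 1)
  l <- 0
  repeat {
    l <- l + 1
    ratio <- sqrt(2 * l + 1) * exp(-l * (l + 1) * s_o)
    if (ratio < tol || l >= MAX_DEGREE) break
  }
  L <- l
  a <- sqrt((2 * (0:L) + 1) / (4 * pi)) * exp(-(0:L) * ((0:L) + 1) * s_o)
  sp <- zonal_spectrum(a)
  attr(sp, "L") <- L
  sp
}

#' Funk transform of an angular spectrum
#'
#' The Funk (great-circle) transform is diagonal on spherical harmonics with
#' eigenvalue \eqn{P_l(0)}: zero for odd degrees,
#' \eqn{(-1)^{l/2}(l-1)!!/l!!} for even degrees.
#'
#' @param spec an `angular_spectrum`.
#' @return the transformed spectrum.
#' @export
funk_transform <- function(spec) {
  out <- spec
  for (l in 0:spec$max_degree) {
    out$coeffs[[l + 1]] <- spec$coeffs[[l + 1]] * legendre_at_zero(l)
  }
  out
}

#' Anti-symmetrize an angular spectrum
#'
#' Keeps odd degrees and zeroes even degrees
#' (\eqn{a_l^m \to \frac{1-(-1)^l}{2} a_l^m}), so the reconstructed function
#' h satisfies \eqn{h(-n) = -h(n)}.
#'
#' @param spec an `angular_spectrum`.
#' @return the anti-symmetrized spectrum.
#' @export
antisymmetrize <- function(spec) {
  out <- spec
  for (l in 0:spec$max_degree) {
    out$coeffs[[l + 1]] <- spec$coeffs[[l + 1]] * ((1 - (-1)^l) / 2)
  }
  out
}

#' Wigner small-d matrix
#'
#' Returns the (2l+1) x (2l+1) matrix \eqn{d^l_{m',m}(\beta)} (rows m', cols
#' m, both ordered -l..l) computed by the explicit sum formula with
#' log-gamma factorials.
#'
#' @param l degree.
#' @param beta rotation angle about the y axis, radians.
#' @return numeric matrix.
#' @export
wigner_d <- function(l, beta) {
  ms <- -l:l
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  d <- matrix(0, 2 * l + 1, 2 * l + 1)
  for (ip in seq_along(ms)) {
    mp <- ms[ip]
    for (im in seq_along(ms)) {
      m <- ms[im]
      kmin <- max(0, m - mp)
      kmax <- min(l + m, l - mp)
      if (kmin > kmax) next
      acc <- 0
      for (k in kmin:kmax) {
        lognum <- 0.5 * (lgamma(l + mp + 1) + lgamma(l - mp + 1) +
                           lgamma(l + m + 1) + lgamma(l - m + 1))
        logden <- lgamma(l + m - k + 1) + lgamma(k + 1) +
          lgamma(l - k - mp + 1) + lgamma(k + mp - m + 1)
        pc <- 2 * l + m - mp - 2 * k
        ps <- mp - m + 2 * k
        acc <- acc + (-1)^(mp - m + k) * exp(lognum - logden) *
          (if (pc == 0) 1 else cb^pc) * (if (ps == 0) 1 else sb^ps)
      }
      d[ip, im] <- acc
    }
  }
  d
}

#' Rotate an angular spectrum
#'
#' Applies the rotation \eqn{R = R_z(\gamma) R_y(\beta) R_z(\alpha)} (ZYZ,
#' counterclockwise angles) to the function represented by `spec`.  For a
#' zonal input with `alpha = 0` this moves the pole to the direction with
#' polar angle `beta` and azimuth `gamma`; the output degree-l coefficients
#' are \eqn{c_l^0 d^l_{m',0}(\beta) e^{-i m' \gamma}}, which by the addition
#' theorem equals \eqn{c_l^0 \sqrt{4\pi/(2l+1)}\, \overline{Y_l^{m'}(\beta,
#' \gamma)}}.
#'
#' @param spec an `angular_spectrum`.
#' @param beta,gamma,alpha ZYZ Euler angles (radians).
#' @return the rotated spectrum (degree preserved; coefficient norm
#'   preserved by unitarity).
#' @export
wigner_rotate <- function(spec, beta, gamma, alpha = 0) {
  out <- spec
  for (l in 0:spec$max_degree) {
    cl <- spec$coeffs[[l + 1]]
    if (all(Mod(cl) == 0)) next
    d <- wigner_d(l, beta)
    ms <- -l:l
    D <- exp(-1i * ms * gamma) * d * rep(exp(-1i * ms * alpha), each = 2 * l + 1)
    out$coeffs[[l + 1]] <- as.complex(D %*% cl)
  }
  out
}

# Steered coefficients of a zonal function whose pole is moved to
# (beta, gamma): matrix with columns per (beta, gamma) is overkill here;
# returns the complex coefficient vector for one degree l.
steer_zonal_degree <- function(c_l0, l, beta, gamma) {
  ms <- -l:l
  y <- vapply(ms, function(m) sph_harm(l, m, beta, gamma), complex(1))
  c_l0 * sqrt(4 * pi / (2 * l + 1)) * Conj(y)
}

#' @export
print.angular_spectrum <- function(x, ...) {
  nz <- sum(vapply(x$coeffs, function(v) sum(Mod(v) > 0), numeric(1)))
  cat(sprintf("angular_spectrum: L = %d, %d nonzero coefficients\n",
              x$max_degree, nz))
  invisible(x)
}

# Numerical Funk transform by great-circle quadrature (oracle used in tests
# and diagnostics): averages `fun` over the great circle perpendicular to
# each direction.
funk_numeric <- function(fun, directions, n_quad = 512) {
  ts <- seq(0, 2 * pi, length.out = n_quad + 1)[-(n_quad + 1)]
  apply(directions, 1, function(n) {
    # orthonormal basis of the plane perpendicular to n
    e1 <- if (abs(n[3]) < 0.9) c(-n[2], n[1], 0) else c(0, -n[3], n[2])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    p <- outer(cos(ts), e1) + outer(sin(ts), e2)
    th <- acos(pmin(1, pmax(-1, p[, 3])))
    ph <- atan2(p[, 2], p[, 1])
    mean(fun(th, ph))
  })
}
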