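# Near-uniform samplings of the sphere S^2 with quadrature weights.

#' Sample orientations on the sphere
#'
#' Generates a near-uniform set of `n_orient` unit vectors on the sphere,
#' either as an icosahedral tessellation (vertices of the icosahedron and its
#' successive edge-midpoint subdivisions, admissible counts 12, 42, 162, 642,
#' ...) or by minimising an electrostatic repulsion energy
#' \eqn{\sum_{i<j} 1/\|n_i - n_j\|} for arbitrary counts.
#'
#' The icosahedral grids are pole-aligned (both poles are vertices), carry
#' their spherical triangulation, and are fully deterministic.  The repulsion
#' grids start from a seeded random configuration and run a fixed projected
#' gradient descent (at most 2000 iterations, or until the maximal tangential
#' gradient norm drops below 1e-8), so they are deterministic given the seed.
#'
#' @param n_orient number of orientations (>= 2).
#' @param method `"icosahedral"` or `"repulsion"`.
#' @param seed integer seed used by the repulsion initialisation.
#' @param weights quadrature weight mode passed to [area_weights()]:
#'   `"triangulated"` (default where a triangulation exists) or `"uniform"`.
#' @return An object of class `orientation_grid`: a list with `vectors`
#'   (`n_orient` x 3 matrix of unit vectors), `weights` (steradians, summing
#'   to \eqn{4\pi}), `euler` (matrix of polar/azimuthal angles `beta`,
#'   `gamma` with `n = (sin b cos g, sin b sin g, cos b)`), `triangles`
#'   (triangulation as an index matrix, or `NULL`), `method` and `seed`.
#' @export
sample_sphere <- function(n_orient, method = c("icosahedral", "repulsion"),
                          seed = 1L, weights = NULL) {
  method <- match.arg(method)
  if (n_orient < 2) stop("n_orient must be at least 2")
  if (method == "icosahedral") {
    counts <- icosahedral_counts()
    if (!n_orient %in% counts) {
      stop("icosahedral grids support n_orient in {",
           paste(counts, collapse = ", "), "}; got ", n_orient,
           ". Use method = \"repulsion\" for other counts.")
    }
    mesh <- icosphere(match(n_orient, counts) - 1L)
    g <- new_orientation_grid(mesh$vertices, mesh$triangles, "icosahedral", seed)
    g$weights <- area_weights(g, weights %||% "triangulated")
  } else {
    v <- repulsion_sphere(n_orient, seed)
    g <- new_orientation_grid(v, NULL, "repulsion", seed)
    g$weights <- area_weights(g, weights %||% "uniform")
  }
  g
}

icosahedral_counts <- function(max_level = 4L) {
  v <- 12; e <- 30; f <- 20
  out <- v
  for (k in seq_len(max_level)) {
    v <- v + e; e <- 2 * e + 3 * f; f <- 4 * f
    out <- c(out, v)
  }
  out
}

new_orientation_grid <- function(vectors, triangles, method, seed) {
  vectors <- vectors / sqrt(rowSums(vectors^2))
  beta <- acos(pmin(1, pmax(-1, vectors[, 3])))
  gamma <- atan2(vectors[, 2], vectors[, 1])
  gamma[abs(sin(beta)) < 1e-14] <- 0
  structure(list(
    vectors = vectors,
    weights = rep(4 * pi / nrow(vectors), nrow(vectors)),
    euler = cbind(beta = beta, gamma = gamma),
    triangles = triangles,
    method = method,
    seed = as.integer(seed)
  ), class = "orientation_grid")
}

# Pole-aligned icosahedron plus `level` edge-midpoint subdivisions.
icosphere <- function(level) {
  b <- acos(1 / sqrt(5))  # polar angle of the upper ring
  up <- t(vapply(0:4, function(k) {
    g <- 2 * pi * k / 5
    c(sin(b) * cos(g), sin(b) * sin(g), cos(b))
  }, numeric(3)))
  lo <- t(vapply(0:4, function(k) {
    g <- 2 * pi * (k + 0.5) / 5
    c(sin(b) * cos(g), sin(b) * sin(g), -cos(b))
  }, numeric(3)))
  v <- rbind(c(0, 0, 1), up, lo, c(0, 0, -1))
  nx <- function(k) (k %% 5) + 1
  tri <- matrix(0L, 20, 3)
  for (k in 0:4) {
    tri[k + 1, ] <- c(1L, 1L + k + 1L, 1L + nx(k + 1))              # top cap
    tri[6 + k, ] <- c(1L + k + 1L, 6L + k + 1L, 1L + nx(k + 1))      # upper band
    tri[11 + k, ] <- c(1L + nx(k + 1), 6L + k + 1L, 6L + nx(k + 1))  # lower band
    tri[16 + k, ] <- c(12L, 6L + nx(k + 1), 6L + k + 1L)             # bottom cap
  }
  for (s in seq_len(level)) {
    res <- subdivide_mesh(v, tri)
    v <- res$vertices; tri <- res$triangles
  }
  list(vertices = v, triangles = tri)
}

subdivide_mesh <- function(v, tri) {
  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  mid <- new.env(parent = emptyenv())
  verts <- v
  get_mid <- function(i, j) {
    k <- edge_key(i, j)
    if (!is.null(mid[[k]])) return(mid[[k]])
    m <- (verts[i, ] + verts[j, ])
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    mid[[k]] <- nrow(verts)
    nrow(verts)
  }
  out <- matrix(0L, 4 * nrow(tri), 3)
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    out[4 * t - 3, ] <- c(a, ab, ca)
    out[4 * t - 2, ] <- c(b, bc, ab)
    out[4 * t - 1, ] <- c(c, ca, bc)
    out[4 * t, ] <- c(ab, bc, ca)
  }
  list(vertices = verts, triangles = out)
}

repulsion_sphere <- function(n, seed, max_iter = 2000L, tol = 1e-8) {
  v <- with_seed(seed, {
    x <- matrix(stats::rnorm(3 * n), n, 3)
    x / sqrt(rowSums(x^2))
  })
  step <- 0.1 / n
  for (it in seq_len(max_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- sweep(v[-i, , drop = FALSE], 2, v[i, ], `-`)
      dist3 <- pmax(rowSums(d^2), 1e-12)^(3 / 2)
      force[i, ] <- -colSums(d / dist3)
    }
    # project onto the tangent plane
    force <- force - v * rowSums(force * v)
    gmax <- sqrt(max(rowSums(force^2)))
    if (gmax < tol) break
    v <- v + step * force / max(1, gmax)
    v <- v / sqrt(rowSums(v^2))
  }
  v
}

#' Quadrature weights for an orientation grid
#'
#' `uniform` mode assigns every orientation the same solid angle
#' \eqn{4\pi/N_o}.  `triangulated` mode computes per-vertex Voronoi areas
#' from the spherical triangulation: each triangle is split at its
#' circumcenter and edge midpoints (all projected to the sphere) and the
#' resulting spherical quadrilaterals are assigned to their vertices, so
#' the weights partition the sphere and sum to \eqn{4\pi} exactly.
#'
#' @param grid an `orientation_grid`.
#' @param mode `"uniform"` or `"triangulated"`.
#' @return numeric vector of weights (steradians).
#' @export
area_weights <- function(grid, mode = c("uniform", "triangulated")) {
  mode <- match.arg(mode)
  n <- nrow(grid$vectors)
  if (mode == "uniform") return(rep(4 * pi / n, n))
  if (is.null(grid$triangles)) {
    stop("triangulated weights require a grid with a spherical triangulation")
  }
  nrmz <- function(v) v / sqrt(sum(v^2))
  w <- numeric(n)
  for (t in seq_len(nrow(grid$triangles))) {
    idx <- grid$triangles[t, ]
    a <- grid$vectors[idx[1], ]; b <- grid$vectors[idx[2], ]
    c_ <- grid$vectors[idx[3], ]
    area <- spherical_triangle_area(a, b, c_)
    if (area <= 1e-14) stop("degenerate (zero-area) spherical triangle in grid")
    # spherical circumcenter: normal of the plane through the vertices,
    # oriented towards the triangle
    p <- pracma::cross(b - a, c_ - a)
    p <- nrmz(p)
    if (sum(p * (a + b + c_)) < 0) p <- -p
    mab <- nrmz(a + b); mbc <- nrmz(b + c_); mca <- nrmz(c_ + a)
    w[idx[1]] <- w[idx[1]] + spherical_triangle_area(a, mab, p) +
      spherical_triangle_area(a, p, mca)
    w[idx[2]] <- w[idx[2]] + spherical_triangle_area(b, mbc, p) +
      spherical_triangle_area(b, p, mab)
    w[idx[3]] <- w[idx[3]] + spherical_triangle_area(c_, mca, p) +
      spherical_triangle_area(c_, p, mbc)
  }
  w * (4 * pi / sum(w))
}

# Oriented spherical triangle area via the van Oosterom-Strackee formula.
spherical_triangle_area <- function(a, b, c) {
  num <- abs(det(rbind(a, b, c)))
  den <- 1 + sum(a * b) + sum(b * c) + sum(c * a)
  2 * atan2(num, den)
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat(sprintf("orientation_grid: %d orientations (%s)\n",
              nrow(x$vectors), x$method))
  cat(sprintf("  weights: sum %.8f (4*pi = %.8f), range [%.4g, %.4g]\n",
              sum(x$weights), 4 * pi, min(x$weights), max(x$weights)))
  cat(sprintf("  min pairwise angle: %.2f deg\n",
              min_pairwise_angle(x) * 180 / pi))
  if (!is.null(x$triangles)) {
    cat(sprintf("  triangulation: %d spherical triangles\n", nrow(x$triangles)))
  }
  invisible(x)
}

min_pairwise_angle <- function(grid) {
  g <- grid$vectors %*% t(grid$vectors)
  diag(g) <- -1
  acos(pmin(1, pmax(-1, max(g))))
}

#' Serialize an orientation grid to JSON
#'
#' Writes a plain JSON table with one record per orientation: index, the
#' Cartesian components, the Euler angles and the quadrature weight.
#'
#' @param grid an `orientation_grid`.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  df <- data.frame(
    index = seq_len(nrow(grid$vectors)),
    x = grid$vectors[, 1], y = grid$vectors[, 2], z = grid$vectors[, 3],
    beta = grid$euler[, "beta"], gamma = grid$euler[, "gamma"],
    delta = grid$weights
  )
  obj <- list(method = grid$method, seed = grid$seed, orientations = df)
  if (!is.null(grid$triangles)) obj$triangles <- unclass(grid$triangles)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an orientation grid written by [write_grid()]
#' @param path JSON file path.
#' @return an `orientation_grid`.
#' @export
read_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tri <- if (!is.null(obj$triangles)) matrix(as.integer(as.matrix(obj$triangles)),
                                             ncol = 3) else NULL
  g <- new_orientation_grid(as.matrix(obj$orientations[, c("x", "y", "z")]),
                            tri, obj$method, obj$seed)
  g$weights <- obj$orientations$delta
  g
}

# Build a grid from explicit vectors (mainly for tests and custom samplings).
grid_from_vectors <- function(vectors, triangles = NULL) {
  g <- new_orientation_grid(vectors, triangles, "custom", 0L)
  if (!is.null(triangles)) g$weights <- area_weights(g, "triangulated")
  g
}
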