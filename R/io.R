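# Volume I/O (NIfTI) and a versioned single-file container for orientation
# scores and wavelet stacks (JSON header + raw little-endian doubles).

#' Read a volume
#'
#' Reads a 3D scalar volume from NIfTI (`.nii` / `.nii.gz`).  4D images
#' are rejected: orientation scores use the score container
#' ([save_score()]), not NIfTI.
#'
#' @param path input file.
#' @return a `volume3d` (data, voxel spacing, origin; x fastest).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unknown volume format for ", path, "; expected .nii or .nii.gz")
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    stop("expected a 3D volume; got ", length(dim(img)), "D. ",
         "Orientation scores use save_score()/load_score().")
  }
  volume3d(as.array(img), spacing = RNifti::pixdim(img)[1:3],
           origin = RNifti::origin(img))
}

#' Write a volume to NIfTI
#'
#' @param vol a `volume3d` or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  img <- RNifti::asNifti(structure(vol$data, pixdim = vol$spacing),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

CONTAINER_VERSION <- 1L

write_container <- function(path, header, payload) {
  header$container_version <- CONTAINER_VERSION
  hj <- charToRaw(jsonlite::toJSON(header, digits = NA, auto_unbox = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("OSC3"), con)
  writeBin(length(hj), con, size = 4, endian = "little")
  writeBin(hj, con)
  writeBin(as.numeric(length(payload)), con, size = 8, endian = "little")
  writeBin(payload, con, size = 8, endian = "little")
  invisible(path)
}

read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "OSC3")) stop("not a score container: ", path)
  hl <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hl)),
                               simplifyVector = TRUE)
  np <- readBin(con, "double", 1, size = 8, endian = "little")
  payload <- readBin(con, "double", np, size = 8, endian = "little")
  if (length(payload) != np) stop("truncated container: ", path)
  list(header = header, payload = payload)
}

grid_header <- function(grid) {
  list(vectors = unclass(grid$vectors), weights = grid$weights,
       triangles = if (!is.null(grid$triangles)) unclass(grid$triangles),
       method = grid$method, seed = grid$seed)
}

grid_from_header <- function(h) {
  tri <- if (!is.null(h$triangles)) matrix(as.integer(as.matrix(h$triangles)),
                                           ncol = 3)
  g <- new_orientation_grid(as.matrix(h$vectors), tri, h$method, h$seed)
  g$weights <- as.numeric(h$weights)
  g
}

grid_hash <- function(grid) {
  v <- round(grid$vectors, 12)
  paste0(nrow(v), "-", format(sum(abs(v)) + sum(v[, 3] * seq_len(nrow(v))),
                              digits = 15))
}

#' Save an orientation score
#'
#' Writes the complex score, its orientation grid, low-frequency channel
#' and provenance to a single-file binary container (JSON header plus raw
#' doubles, versioned).
#'
#' @param score an `orientation_score`.
#' @param path output path.
#' @export
save_score <- function(score, path) {
  d <- dim(score$data)
  header <- list(kind = "orientation_score", dims = d,
                 design = score$design %||% "unknown",
                 params = unclass(score$params),
                 grid = grid_header(score$grid),
                 grid_hash = grid_hash(score$grid),
                 has_lowfreq = !is.null(score$lowfreq),
                 complex = is.complex(score$data))
  payload <- if (is.complex(score$data)) {
    c(as.numeric(Re(score$data)), as.numeric(Im(score$data)))
  } else as.numeric(score$data)
  if (!is.null(score$lowfreq)) payload <- c(payload, as.numeric(score$lowfreq))
  write_container(path, header, payload)
}

#' Load an orientation score saved by [save_score()]
#'
#' @param path container path.
#' @param stack optional `wavelet_stack`; when given, its orientation grid
#'   must match the stored one (grid-hash check).
#' @return an `orientation_score`.
#' @export
load_score <- function(path, stack = NULL) {
  ct <- read_container(path)
  h <- ct$header
  if (!identical(h$kind, "orientation_score")) stop("container is not a score")
  d <- as.integer(h$dims)
  grid <- grid_from_header(h$grid)
  if (!is.null(stack) && !identical(grid_hash(stack$grid), h$grid_hash)) {
    stop("orientation grid of the stack does not match the stored score")
  }
  nvox <- prod(d)
  if (isTRUE(h$complex)) {
    re <- ct$payload[seq_len(nvox)]
    im <- ct$payload[nvox + seq_len(nvox)]
    data <- array(complex(real = re, imaginary = im), d)
    off <- 2 * nvox
  } else {
    data <- array(ct$payload[seq_len(nvox)], d)
    off <- nvox
  }
  low <- if (isTRUE(h$has_lowfreq)) {
    array(ct$payload[off + seq_len(prod(d[1:3]))], d[1:3])
  }
  params <- h$params
  class(params) <- "wavelet_params"
  structure(list(data = data, grid = grid, lowfreq = low, params = params,
                 design = h$design, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
            class = "orientation_score")
}

#' Save a wavelet stack
#'
#' Serializes filters, low-pass, design parameters and the orientation
#' grid to the same container format used for scores; the design tag
#' (`cake_dft`, `plate_dft` or `zernike`) records provenance.
#'
#' @param stack a `wavelet_stack`.
#' @param path output path.
#' @export
save_stack <- function(stack, path) {
  header <- list(kind = "wavelet_stack", design = stack$design,
                 n = stack$params$grid_size,
                 n_orient = nrow(stack$grid$vectors),
                 params = unclass(stack$params),
                 alpha = stack$alpha %||% NULL, p_max = stack$p_max %||% NULL,
                 ang_coeffs = stack$ang_coeffs, heat_coeffs = stack$heat_coeffs,
                 grid = grid_header(stack$grid),
                 grid_hash = grid_hash(stack$grid))
  payload <- c(as.numeric(Re(stack$fourier_filters)),
               as.numeric(Im(stack$fourier_filters)),
               as.numeric(Re(stack$fourier_unsplit)),
               as.numeric(Im(stack$fourier_unsplit)),
               as.numeric(Re(stack$spatial_filters)),
               as.numeric(Im(stack$spatial_filters)),
               as.numeric(stack$lowpass_spatial),
               as.numeric(stack$radial_table))
  write_container(path, header, payload)
}

#' Load a wavelet stack saved by [save_stack()]
#' @param path container path.
#' @return a `wavelet_stack`.
#' @export
load_stack <- function(path) {
  ct <- read_container(path)
  h <- ct$header
  if (!identical(h$kind, "wavelet_stack")) stop("container is not a stack")
  n <- as.integer(h$n); nv <- as.integer(h$n_orient)
  params <- h$params
  class(params) <- "wavelet_params"
  grid <- grid_from_header(h$grid)
  m <- n^3 * nv
  p <- ct$payload
  take <- function(k) { out <- p[seq_len(k)]; p <<- p[-seq_len(k)]; out }
  cplx <- function(k) {
    re <- take(k); im <- take(k)
    matrix(complex(real = re, imaginary = im), n^3, nv)
  }
  four <- cplx(m); four_full <- cplx(m); spat <- cplx(m)
  lowpass <- array(take(n^3), c(n, n, n))
  rt <- matrix(take(length(p)), ncol = 2,
               dimnames = list(NULL, c("rho", "g")))
  structure(list(fourier_filters = four, fourier_unsplit = four_full,
                 spatial_filters = spat, lowpass_spatial = lowpass,
                 ang_coeffs = as.numeric(h$ang_coeffs),
                 heat_coeffs = as.numeric(h$heat_coeffs),
                 radial_table = rt, params = params, grid = grid,
                 alpha = h$alpha, p_max = h$p_max,
                 design = h$design), class = "wavelet_stack")
}
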