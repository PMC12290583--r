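#' Scalar volume on a brain grid
#'
#' A `volume_map` holds one scalar value per voxel of a [make_grid()] grid,
#' with a `kind` tag recording what the values are. Values outside the mask
#' are stored as 0 and are ignored by all statistics.
#'
#' @param grid A `brain_grid`.
#' @param values A numeric array matching the grid shape, a vector of in-mask
#'   values (in mask order), or a scalar.
#' @param kind One of `"MA"`, `"ALE"`, `"p"`, `"z"`, `"correlation"`,
#'   `"tstat"`, `"difference"`.
#' @return A `volume_map` object.
#' @export
volume_map <- function(grid, values = 0, kind = "ALE") {
  stopifnot(inherits(grid, "brain_grid"))
  kind <- match.arg(kind, c("MA", "ALE", "p", "z", "correlation", "tstat", "difference"))
  nmask <- sum(grid$mask)
  if (is.array(values)) {
    if (!identical(dim(values), as.integer(grid$shape))) {
      abort_metaclique("`values` array does not match the grid shape.")
    }
    data <- values
  } else if (length(values) == 1) {
    data <- array(as.numeric(values), dim = grid$shape)
  } else if (length(values) == nmask) {
    data <- array(0, dim = grid$shape)
    data[grid$mask] <- as.numeric(values)
  } else {
    abort_metaclique("`values` must be a full array, a scalar, or one value per in-mask voxel.")
  }
  data[!grid$mask] <- 0
  check_volume_values(data[grid$mask], kind)
  structure(list(grid = grid, data = data, kind = kind), class = "volume_map")
}

check_volume_values <- function(v, kind) {
  if (any(!is.finite(v))) abort_metaclique("Volume values must be finite.")
  if (kind %in% c("MA", "ALE") && (any(v < 0) || any(v > 1))) {
    abort_metaclique(sprintf("%s values must lie in [0, 1].", kind))
  }
  if (kind == "p" && (any(v <= 0) || any(v > 1))) {
    abort_metaclique("p values must lie in (0, 1].")
  }
  invisible(TRUE)
}

#' @export
print.volume_map <- function(x, ...) {
  v <- in_mask(x)
  cat("<volume_map:", x$kind, "> grid ", format(x$grid),
      sprintf("; in-mask range [%.4g, %.4g]\n", min(v), max(v)), sep = "")
  invisible(x)
}

#' Extract in-mask values of a volume map
#' @param map A `volume_map`.
#' @return Numeric vector, one value per in-mask voxel (mask order).
#' @export
in_mask <- function(map) {
  stopifnot(inherits(map, "volume_map"))
  map$data[map$grid$mask]
}

grid_affine <- function(grid) {
  rbind(cbind(diag(grid$voxel_mm), grid$origin_mm), c(0, 0, 0, 1))
}

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 with a diagonal sform built from the grid's
#' voxel size and origin. `read_volume()` checks the file geometry against
#' `grid` (error on mismatch) and returns a [volume_map()]; masking follows
#' the session grid.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param grid Session `brain_grid` the volume must live on.
#' @param kind Value kind for the returned map (see [volume_map()]).
#' @export
read_volume <- function(path, grid, kind = "ALE") {
  if (!file.exists(path)) abort_metaclique(sprintf("No such volume file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
    error = function(e) abort_metaclique(sprintf("Cannot read NIfTI '%s': %s", path, conditionMessage(e)),
                                         class = "metaclique_format_error"))
  arr <- as.array(img)
  aff <- RNifti::xform(img)
  check_geometry(aff, dim(arr)[1:3], grid)
  if (length(dim(arr)) > 3) abort_metaclique("Expected a 3D volume; got 4D. Use read_rest_run().")
  volume_map(grid, arr, kind = kind)
}

check_geometry <- function(aff, shape, grid, tol = 1e-4) {
  if (!identical(as.integer(shape), as.integer(grid$shape))) {
    abort_metaclique("Volume grid mismatch: voxel counts differ from the session grid.")
  }
  if (max(abs(diag(aff)[1:3] - grid$voxel_mm)) > tol) {
    abort_metaclique("Volume grid mismatch: voxel size differs from the session grid.")
  }
  if (max(abs(aff[1:3, 4] - grid$origin_mm)) > tol) {
    abort_metaclique("Volume grid mismatch: origin differs from the session grid.")
  }
  invisible(TRUE)
}

#' @rdname read_volume
#' @param map A `volume_map` to write.
#' @export
write_volume <- function(map, path) {
  stopifnot(inherits(map, "volume_map"))
  nifti_write_array(map$data, map$grid, path)
}

nifti_write_array <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_mm
  aff <- structure(grid_affine(grid), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- separable Gaussian smoothing on the grid ------------------------------

gaussian_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

shift_array <- function(arr, offset, axis) {
  # shift with zero fill; offset in voxels along `axis`
  if (offset == 0) return(arr)
  d <- dim(arr)
  out <- array(0, dim = d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (abs(offset) >= n) return(out)
  if (offset > 0) {
    idx_dst[[axis]] <- (offset + 1):n
    idx_src[[axis]] <- 1:(n - offset)
  } else {
    idx_dst[[axis]] <- 1:(n + offset)
    idx_src[[axis]] <- (1 - offset):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# banded convolution matrix for one axis (zero boundary)
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n - abs(o))
    if (o >= 0) K[cbind(idx + o, idx)] <- kernel[o + r + 1L]
    else K[cbind(idx, idx - o)] <- kernel[o + r + 1L]
  }
  K
}

# separable convolution along the first three axes of a 3D or 4D array,
# via banded-matrix multiplication (fast under BLAS)
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  nd <- length(d)
  perm <- seq_len(nd)
  if (axis != 1) { perm[c(1, axis)] <- c(axis, 1); arr <- aperm(arr, perm) }
  dp <- dim(arr)
  K <- conv_band_matrix(dp[1], kernel)
  arr <- array(K %*% matrix(arr, nrow = dp[1]), dim = dp)
  if (axis != 1) arr <- aperm(arr, perm)
  arr
}

# mask-renormalised isotropic Gaussian smoothing of a 3D array
smooth_volume_array <- function(arr, grid, fwhm_mm, mask_norm = NULL) {
  if (fwhm_mm <= 0) return(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  arr[!grid$mask] <- 0
  out <- arr
  for (ax in 1:3) {
    out <- convolve_axis(out, gaussian_1d(sigma_mm / grid$voxel_mm[ax]), ax)
  }
  if (is.null(mask_norm)) mask_norm <- smooth_mask_norm(grid, fwhm_mm)
  out <- out / mask_norm
  out[!grid$mask] <- 0
  out
}

smooth_mask_norm <- function(grid, fwhm_mm) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  m <- array(0, dim = grid$shape)
  m[grid$mask] <- 1
  for (ax in 1:3) {
    m <- convolve_axis(m, gaussian_1d(sigma_mm / grid$voxel_mm[ax]), ax)
  }
  m[m <= 0] <- 1
  m
}
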