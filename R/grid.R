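#' Construct a brain grid
#'
#' A `brain_grid` is a regular 3D voxel lattice with a millimetre affine
#' (diagonal scaling plus translation, right-handed axes) and an in-brain
#' mask playing the role of the gray-matter mask. Voxel indices are 0-based;
#' the world coordinate of voxel `(0,0,0)` is the (centred) origin.
#'
#' @param voxel_size_mm Voxel edge length(s) in mm; scalar or length 3.
#' @param extent_mm Grid extent in mm per axis; scalar or length 3. The number
#'   of voxels per axis is `round(extent / voxel_size)`.
#' @param mask Mask specification: `"full"` (all voxels in-mask), a list
#'   `list(type = "ellipsoid", semiaxes_mm =, center_mm =)`, or a logical
#'   array matching the grid shape.
#' @return A `brain_grid` object.
#' @examples
#' g <- make_grid(4, 80)           # 20 x 20 x 20, full mask
#' sum(g$mask)                     # 8000
#' @export
make_grid <- function(voxel_size_mm, extent_mm, mask = "full") {
  voxel <- rep_len(as.numeric(voxel_size_mm), 3)
  extent <- rep_len(as.numeric(extent_mm), 3)
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    abort_metaclique("`voxel_size_mm` must be positive and finite on all axes.")
  }
  if (any(extent < voxel)) {
    abort_metaclique("`extent_mm` must cover at least one voxel per axis.")
  }
  shape <- as.integer(round(extent / voxel))
  # centred origin: voxel centres symmetric about 0
  origin <- -(shape - 1) / 2 * voxel

  mask_arr <- resolve_mask(mask, shape, voxel, origin)
  if (!any(mask_arr)) {
    abort_metaclique("Mask is empty: no in-brain voxels.")
  }
  structure(
    list(shape = shape, voxel_mm = voxel, origin_mm = origin, mask = mask_arr),
    class = "brain_grid"
  )
}

resolve_mask <- function(mask, shape, voxel, origin) {
  if (is.character(mask) && identical(mask, "full")) {
    return(array(TRUE, dim = shape))
  }
  if (is.array(mask) && is.logical(mask)) {
    if (!identical(dim(mask), as.integer(shape))) {
      abort_metaclique("Supplied mask array does not match the grid shape.")
    }
    return(mask)
  }
  if (is.list(mask) && identical(mask$type, "ellipsoid")) {
    semi <- rep_len(as.numeric(mask$semiaxes_mm), 3)
    ctr <- rep_len(as.numeric(mask$center_mm %||% c(0, 0, 0)), 3)
    cents <- voxel_centers(shape, voxel, origin)
    inside <- ((cents[, 1] - ctr[1]) / semi[1])^2 +
      ((cents[, 2] - ctr[2]) / semi[2])^2 +
      ((cents[, 3] - ctr[3]) / semi[3])^2 <= 1
    return(array(inside, dim = shape))
  }
  abort_metaclique("Unknown mask specification.")
}

# all voxel centres as an N x 3 mm matrix (column-major voxel order)
voxel_centers <- function(shape, voxel, origin) {
  i <- seq_len(shape[1]) - 1
  j <- seq_len(shape[2]) - 1
  k <- seq_len(shape[3]) - 1
  cbind(
    rep(origin[1] + i * voxel[1], times = shape[2] * shape[3]),
    rep(rep(origin[2] + j * voxel[2], each = shape[1]), times = shape[3]),
    rep(origin[3] + k * voxel[3], each = shape[1] * shape[2])
  )
}

#' @export
print.brain_grid <- function(x, ...) {
  cat("<brain_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_mm, collapse = "x"), " mm; ",
      sum(x$mask), " in-mask\n", sep = "")
  invisible(x)
}

#' @export
format.brain_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(x$voxel_mm, collapse = "x"), "mm")
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_mm - b$voxel_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol &&
    identical(a$mask, b$mask)
}

#' Convert world (mm) coordinates to voxel indices
#'
#' Nearest-voxel-centre convention, 0-based indices. The inverse,
#' [voxel_to_world()], returns voxel centres in mm, so the round trip
#' world -> voxel -> world snaps to the nearest voxel centre while
#' voxel -> world -> voxel is the identity.
#'
#' @param coord_mm Numeric length-3 vector or N x 3 matrix of mm coordinates.
#' @param grid A [make_grid()] object.
#' @return Integer matrix (N x 3) of 0-based voxel indices.
#' @export
world_to_voxel <- function(coord_mm, grid) {
  m <- coerce_coords(coord_mm)
  idx <- round(sweep(sweep(m, 2, grid$origin_mm), 2, grid$voxel_mm, "/"))
  for (ax in 1:3) {
    bad <- idx[, ax] < 0 | idx[, ax] > grid$shape[ax] - 1
    if (any(bad)) {
      abort_metaclique(sprintf(
        "Coordinate out of grid extent on axis %s (row %d: %.1f mm).",
        c("x", "y", "z")[ax], which(bad)[1], m[which(bad)[1], ax]
      ))
    }
  }
  storage.mode(idx) <- "integer"
  idx
}

#' @rdname world_to_voxel
#' @param voxel_idx Integer length-3 vector or N x 3 matrix of 0-based indices.
#' @export
voxel_to_world <- function(voxel_idx, grid) {
  m <- coerce_coords(voxel_idx)
  sweep(sweep(m, 2, grid$voxel_mm, "*"), 2, grid$origin_mm, "+")
}

coerce_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  if (ncol(x) != 3) abort_metaclique("Coordinates must have 3 columns (x, y, z).")
  if (any(!is.finite(x))) abort_metaclique("Coordinates must be finite.")
  storage.mode(x) <- "double"
  x
}

# 0-based (i,j,k) matrix -> 1-based linear index into the array
voxel_linear <- function(idx, shape) {
  1L + idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3])
}

# 1-based linear -> 0-based (i,j,k)
linear_voxel <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i, j, k)
}

# mm coordinates of the centres of the in-mask voxels
mask_centers <- function(grid) {
  lin <- which(grid$mask)
  voxel_to_world(linear_voxel(lin, grid$shape), grid)
}
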