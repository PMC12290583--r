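#' Kernel width from sample size
#'
#' The full width at half maximum of the spatial-uncertainty kernel is
#' determined by the number of subjects in the experiment: a fixed
#' between-template uncertainty plus a between-subject uncertainty shrinking
#' as `1/sqrt(n)`, combined in quadrature. Strictly decreasing in `n`.
#'
#' @param n_subjects Number of subjects (>= 1); vectorised.
#' @param constants See [ale_uncertainty_constants()].
#' @return FWHM in mm.
#' @examples
#' kernel_fwhm_from_n(10) > kernel_fwhm_from_n(50)  # TRUE
#' @export
kernel_fwhm_from_n <- function(n_subjects, constants = ale_uncertainty_constants()) {
  if (any(!is.finite(n_subjects)) || any(n_subjects < 1)) {
    abort_metaclique("`n_subjects` must be >= 1.")
  }
  # mm standard-uncertainty -> FWHM conversion used throughout the ALE literature
  to_fwhm <- sqrt(8 * log(2)) / (2 * sqrt(2 / pi))
  ut <- constants$template_mm * to_fwhm
  us <- constants$subject_mm * to_fwhm / sqrt(n_subjects)
  sqrt(ut^2 + us^2)
}

#' Build a spherical Gaussian ALE kernel on a grid
#'
#' The kernel is an isotropic 3D Gaussian with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, sampled at voxel-centre distances and
#' scaled by the voxel volume so each value is the probability that the true
#' activation lies in that voxel; it is truncated where the value falls below
#' `trunc_rel` times the peak. The total probability mass is ~1.
#'
#' @param fwhm_mm Full width at half maximum in mm (> 0).
#' @param grid A [make_grid()] grid (supplies voxel size).
#' @param trunc_rel Relative truncation threshold (default 1e-8).
#' @return An `ale_kernel`: integer voxel `offsets` (K x 3), `values`,
#'   `dist_mm`, `peak`, `fwhm_mm`.
#' @export
ale_kernel <- function(fwhm_mm, grid, trunc_rel = 1e-8) {
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) abort_metaclique("`fwhm_mm` must be > 0.")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  voxvol <- prod(grid$voxel_mm)
  d_max <- sigma * sqrt(-2 * log(trunc_rel))
  r <- pmax(1L, floor(d_max / grid$voxel_mm))
  off <- as.matrix(expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3]))
  dist_mm <- sqrt((off[, 1] * grid$voxel_mm[1])^2 +
                  (off[, 2] * grid$voxel_mm[2])^2 +
                  (off[, 3] * grid$voxel_mm[3])^2)
  keep <- dist_mm <= d_max
  off <- off[keep, , drop = FALSE]
  dist_mm <- dist_mm[keep]
  values <- voxvol * (2 * pi * sigma^2)^(-3 / 2) * exp(-dist_mm^2 / (2 * sigma^2))
  peak <- max(values)
  if (peak >= 1) {
    abort_metaclique("Kernel peak >= 1: kernel too narrow for this voxel size.")
  }
  storage.mode(off) <- "integer"
  ord <- order(dist_mm)
  structure(
    list(fwhm_mm = fwhm_mm, sigma_mm = sigma,
         offsets = off[ord, , drop = FALSE],
         dist_mm = dist_mm[ord], values = values[ord], peak = peak),
    class = "ale_kernel"
  )
}

#' @export
print.ale_kernel <- function(x, ...) {
  cat(sprintf("<ale_kernel> fwhm %.2f mm, %d voxels, peak %.4g\n",
              x$fwhm_mm, nrow(x$offsets), x$peak))
  invisible(x)
}

# cache of kernels per unique fwhm (keyed by rounded fwhm) for one grid
kernel_cache <- function(grid, trunc_rel = 1e-8) {
  store <- new.env(parent = emptyenv())
  function(fwhm_mm) {
    key <- sprintf("%.6f", fwhm_mm)
    if (is.null(store[[key]])) store[[key]] <- ale_kernel(fwhm_mm, grid, trunc_rel)
    store[[key]]
  }
}
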