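# Vendored numerical constants. These are data, not contract: both sets are
# user-overridable through the functions that consume them.

# Lancaster icbm2tal affines (MNI/ICBM-152 -> Talairach-1988, mm). The
# Talairach -> MNI direction applies the matrix inverse. "pooled" is the
# software-independent average; "spm" and "fsl" are the tool-specific fits.
.icbm2tal_matrices <- list(
  pooled = rbind(
    c(0.9357,  0.0029, -0.0072, -1.0423),
    c(-0.0065, 0.9396, -0.0726, -1.3940),
    c(0.0103,  0.0752,  0.8967,  3.6475),
    c(0, 0, 0, 1)
  ),
  spm = rbind(
    c(0.9254,  0.0024, -0.0118, -1.0207),
    c(-0.0048, 0.9316, -0.0871, -1.7667),
    c(0.0152,  0.0883,  0.8924,  4.0926),
    c(0, 0, 0, 1)
  ),
  fsl = rbind(
    c(0.9464,  0.0034, -0.0026, -1.0680),
    c(-0.0083, 0.9479, -0.0580, -1.0239),
    c(0.0053,  0.0617,  0.9010,  3.1883),
    c(0, 0, 0, 1)
  )
)

#' Talairach/MNI affine constants
#'
#' Returns the vendored 4x4 affine used by [tal_to_mni()]. The stored
#' direction is MNI -> Talairach; the Talairach -> MNI transform is its
#' matrix inverse.
#'
#' @param variant One of `"pooled"` (default), `"spm"`, `"fsl"`.
#' @param inverse If `TRUE` (default) return the Talairach -> MNI matrix.
#' @return A 4x4 numeric matrix.
#' @export
tal2mni_affine <- function(variant = c("pooled", "spm", "fsl"), inverse = TRUE) {
  variant <- match.arg(variant)
  m <- .icbm2tal_matrices[[variant]]
  if (inverse) solve(m) else m
}

#' Empirical spatial-uncertainty constants for the ALE kernel
#'
#' The ALE kernel width combines, in quadrature, a between-template
#' uncertainty and a between-subject uncertainty that shrinks with the square
#' root of the sample size. The default millimetre constants are the ones in
#' standard use in the coordinate-based meta-analysis literature; both can be
#' overridden.
#'
#' @param template_mm Between-template spatial uncertainty (mm).
#' @param subject_mm Between-subject spatial uncertainty (mm), divided by
#'   `sqrt(n)` when applied.
#' @return A list with elements `template_mm` and `subject_mm`.
#' @export
ale_uncertainty_constants <- function(template_mm = 5.7, subject_mm = 11.6) {
  stopifnot(template_mm > 0, subject_mm > 0)
  list(template_mm = template_mm, subject_mm = subject_mm)
}
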