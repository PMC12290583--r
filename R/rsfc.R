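## Desk-scale seed-based resting-state functional connectivity: seed time
## course, global-signal nuisance regression, 6-mm smoothing, fixed-effects
## run combination, group map with sign-flip max-height thresholding.

#' Construct a resting-state run
#'
#' @param series T x V numeric matrix (time points x in-mask voxels, mask
#'   order) or a 4D array matching the grid shape plus time.
#' @param grid A [make_grid()] grid.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id,run_id Identifiers.
#' @return A `rest_run`.
#' @export
rest_run <- function(series, grid, tr_seconds = 1, subject_id = "sub01", run_id = "run01") {
  if (is.array(series) && length(dim(series)) == 4) {
    if (!identical(dim(series)[1:3], as.integer(grid$shape))) {
      abort_metaclique("4D series does not match the grid shape.")
    }
    tdim <- dim(series)[4]
    mat <- t(apply(series, 4, function(a) a[grid$mask]))
    if (tdim == 1) mat <- matrix(mat, nrow = 1)
    series <- mat
  }
  series <- as.matrix(series)
  if (nrow(series) < 20) abort_metaclique("A rest run needs >= 20 time points.")
  if (ncol(series) != sum(grid$mask)) {
    abort_metaclique("Series must have one column per in-mask voxel.")
  }
  if (any(!is.finite(series))) abort_metaclique("Rest series must be finite.")
  structure(list(series = series, grid = grid, tr_seconds = tr_seconds,
                 subject_id = subject_id, run_id = run_id),
            class = "rest_run")
}

#' @export
print.rest_run <- function(x, ...) {
  cat(sprintf("<rest_run %s/%s> %d time points (TR %gs), %d voxels\n",
              x$subject_id, x$run_id, nrow(x$series), x$tr_seconds, ncol(x$series)))
  invisible(x)
}

#' Read / write a 4D rest run as NIfTI
#' @param path File path.
#' @param grid Session grid.
#' @inheritParams rest_run
#' @export
read_rest_run <- function(path, grid, tr_seconds = 1, subject_id = "sub01", run_id = "run01") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) abort_metaclique("Expected a 4D rest run.")
  check_geometry(RNifti::xform(img), dim(arr)[1:3], grid)
  rest_run(arr, grid, tr_seconds, subject_id, run_id)
}

#' @rdname read_rest_run
#' @param run A `rest_run`.
#' @export
write_rest_run <- function(run, path) {
  grid <- run$grid
  arr <- array(0, dim = c(grid$shape, nrow(run$series)))
  mask_lin <- which(grid$mask)
  nvol <- prod(grid$shape)
  for (t in seq_len(nrow(run$series))) {
    arr[mask_lin + (t - 1) * nvol] <- run$series[t, ]
  }
  nifti_write_array(arr, grid, path)
}

# positions of ROI voxels among the in-mask columns
roi_columns <- function(roi, grid) {
  cols <- match(roi$voxels, which(grid$mask))
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0) abort_metaclique("ROI does not intersect the run's mask.")
  cols
}

#' Average seed time course of an ROI
#'
#' Unweighted mean over the ROI's in-mask voxels at each time point.
#'
#' @param run A [rest_run()].
#' @param roi A [sphere_roi()].
#' @return Numeric vector of length T.
#' @export
seed_timecourse <- function(run, roi) {
  cols <- roi_columns(roi, run$grid)
  rowMeans(run$series[, cols, drop = FALSE])
}

# smooth every time point of a run (one 4D slab pass); returns the T x V matrix
smooth_run_series <- function(run, fwhm_mm) {
  if (fwhm_mm <= 0) return(run$series)
  grid <- run$grid
  mask_lin <- which(grid$mask)
  norm <- smooth_mask_norm(grid, fwhm_mm)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  Tn <- nrow(run$series)
  nvol <- prod(grid$shape)
  arr <- array(0, dim = c(grid$shape, Tn))
  arr[rep(mask_lin, Tn) + rep((seq_len(Tn) - 1) * nvol, each = length(mask_lin))] <-
    as.vector(t(run$series))
  for (ax in 1:3) {
    arr <- convolve_axis(arr, gaussian_1d(sigma_mm / grid$voxel_mm[ax]), ax)
  }
  arr <- arr / as.vector(norm)  # norm recycles over the time axis
  out <- run$series
  for (t in seq_len(Tn)) out[t, ] <- arr[mask_lin + (t - 1) * nvol]
  out
}

#' Run-level seed connectivity map
#'
#' Per voxel, ordinary least squares of the (spatially smoothed) voxel
#' series on an intercept, the seed time course, and the global-signal time
#' course (regressor of no interest). The map value is the seed coefficient
#' standardised to a correlation-scale value,
#' `beta_seed * sd(seed) / sd(voxel)`. The seed and global-signal courses
#' are extracted from the unsmoothed run; smoothing (isotropic Gaussian,
#' default 6-mm FWHM) is applied to the voxel data per time point before
#' regression.
#'
#' @param run A [rest_run()].
#' @param roi A [sphere_roi()].
#' @param smoothing_fwhm Smoothing FWHM in mm (default 6; 0 disables).
#' @param smoothed Optional pre-smoothed T x V series (caching across ROIs).
#' @param standardize If `FALSE`, return the raw seed coefficient instead of
#'   the correlation-scale value.
#' @return A `volume_map` of kind `"correlation"` with attributes `level`
#'   (`"run"`), `subject_id`, `roi_id`.
#' @export
seed_connectivity <- function(run, roi, smoothing_fwhm = 6, smoothed = NULL,
                              standardize = TRUE) {
  s <- seed_timecourse(run, roi)
  if (sd(s) == 0) abort_metaclique("Seed time course is constant.")
  g <- rowMeans(run$series)
  if (sd(g) > 0 && abs(cor(s, g)) > 0.999) {
    abort_metaclique("Seed and global-signal regressors are collinear (|r| > 0.999).")
  }
  Y <- smoothed %||% smooth_run_series(run, smoothing_fwhm)
  # a constant global signal carries no information and would make the
  # design singular; drop it (the intercept absorbs it)
  X <- if (sd(g) > 0) cbind(intercept = 1, seed = s, global = g)
       else cbind(intercept = 1, seed = s)
  beta <- solve(crossprod(X), crossprod(X, Y))
  b_seed <- beta[2, ]
  b_seed[is.na(b_seed)] <- 0
  val <- if (standardize) {
    Tn <- nrow(Y)
    mu <- colMeans(Y)
    sdv <- sqrt(pmax(colSums(Y^2) / (Tn - 1) - mu^2 * Tn / (Tn - 1), 0))
    out <- ifelse(sdv > 0, b_seed * sd(s) / sdv, 0)
    pmin(pmax(out, -1), 1)
  } else {
    b_seed
  }
  m <- volume_map(run$grid, val, kind = "correlation")
  attr(m, "level") <- "run"
  attr(m, "subject_id") <- run$subject_id
  attr(m, "roi_id") <- roi$roi_id
  m
}

#' Fixed-effects combination of run-level maps
#'
#' Voxel-wise unweighted mean across a subject's runs.
#'
#' @param run_maps List of run-level `volume_map`s on a common grid.
#' @return A subject-level `volume_map`.
#' @export
fixed_effects_combine <- function(run_maps) {
  if (length(run_maps) < 1) abort_metaclique("Need >= 1 run map.")
  grid <- run_maps[[1]]$grid
  for (m in run_maps) {
    if (!grids_equal(grid, m$grid)) abort_metaclique("Run maps are on different grids.")
  }
  avg <- Reduce(`+`, lapply(run_maps, function(m) m$data)) / length(run_maps)
  out <- volume_map(grid, avg, kind = "correlation")
  attr(out, "level") <- "subject"
  attr(out, "subject_id") <- attr(run_maps[[1]], "subject_id")
  attr(out, "roi_id") <- attr(run_maps[[1]], "roi_id")
  out
}

#' Group-level seed connectivity
#'
#' Voxel-wise mean and one-sample t across subject maps, with maximum-height
#' thresholding of the t map by sign-flip permutation (the nonparametric
#' analogue of random-field maximum-height control): per iteration each
#' subject map is multiplied by a random sign, the max |t| is recorded, and
#' the threshold is the `1 - voxel_p` percentile of the maxima. A parametric
#' t threshold is available as an alternative.
#'
#' @param subject_maps List of >= 3 subject-level `volume_map`s.
#' @param voxel_p Voxel-level FWE level (default 0.001).
#' @param n_iterations Sign-flip iterations (default 1000; `0` skips
#'   thresholding).
#' @param seed RNG seed.
#' @param method `"signflip"` (default) or `"parametric"` (Bonferroni-style
#'   t quantile across in-mask voxels).
#' @return A `group_connectivity`: `mean_map`, `t_map`, `thresholded`,
#'   `threshold_t`, `n_subjects`.
#' @export
group_connectivity <- function(subject_maps, voxel_p = 0.001, n_iterations = 1000,
                               seed = NULL, method = c("signflip", "parametric")) {
  method <- match.arg(method)
  n <- length(subject_maps)
  if (n < 3) abort_metaclique("Group analysis needs >= 3 subjects.")
  grid <- subject_maps[[1]]$grid
  M <- do.call(rbind, lapply(subject_maps, in_mask))  # n x V
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)

  thr <- NA_real_
  thresholded <- NULL
  if (method == "parametric") {
    thr <- stats::qt(1 - voxel_p / ncol(M), df = n - 1)
  } else if (n_iterations > 0) {
    if (is.null(seed)) abort_metaclique("`seed` is required for sign-flip thresholding.")
    set.seed(derive_seed(seed, "signflip"))
    mx <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      Ms <- M * signs
      mu_i <- colMeans(Ms)
      sd_i <- sqrt((colSums(Ms^2) - n * mu_i^2) / (n - 1))
      t_i <- ifelse(sd_i > 0, mu_i / (sd_i / sqrt(n)), 0)
      mx[it] <- max(abs(t_i))
    }
    thr <- sort(mx)[ceiling((1 - voxel_p) * n_iterations)]
  }
  if (is.finite(thr)) {
    tv <- ifelse(abs(tval) >= thr, tval, 0)
    thresholded <- volume_map(grid, tv, kind = "tstat")
  }
  mean_map <- volume_map(grid, mu, kind = "correlation")
  attr(mean_map, "level") <- "group"
  attr(mean_map, "roi_id") <- attr(subject_maps[[1]], "roi_id")
  structure(
    list(mean_map = mean_map,
         t_map = volume_map(grid, tval, kind = "tstat"),
         thresholded = thresholded, threshold_t = thr,
         method = method, voxel_p = voxel_p, n_subjects = n),
    class = "group_connectivity"
  )
}

#' @export
print.group_connectivity <- function(x, ...) {
  cat(sprintf("<group_connectivity> %d subjects; %s max-height threshold t = %.3g\n",
              x$n_subjects, x$method, x$threshold_t))
  invisible(x)
}

#' Seed-based rsFC for one ROI across subjects and runs
#'
#' Convenience wrapper: run-level [seed_connectivity()] per run,
#' [fixed_effects_combine()] per subject, then [group_connectivity()].
#'
#' @param runs List of [rest_run()]s (multiple subjects, >= 1 run each).
#' @param roi A [sphere_roi()].
#' @param smoothing_fwhm Smoothing FWHM in mm.
#' @param smoothed_cache Optional named list `run_id -> smoothed series`.
#' @inheritParams group_connectivity
#' @return A `group_connectivity`.
#' @export
rsfc_roi <- function(runs, roi, smoothing_fwhm = 6, voxel_p = 0.001,
                     n_iterations = 1000, seed = NULL, smoothed_cache = NULL) {
  subjects <- split(runs, vapply(runs, function(r) r$subject_id, ""))
  subject_maps <- lapply(subjects, function(subj_runs) {
    maps <- lapply(subj_runs, function(r) {
      sm <- smoothed_cache[[paste(r$subject_id, r$run_id)]]
      seed_connectivity(r, roi, smoothing_fwhm, smoothed = sm)
    })
    fixed_effects_combine(maps)
  })
  group_connectivity(subject_maps, voxel_p = voxel_p,
                     n_iterations = n_iterations, seed = seed)
}
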