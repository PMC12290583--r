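## ALE statistic: modeled activation maps, probabilistic union, analytic
## voxel-level null, Monte-Carlo cluster-extent FWE, conjunction, subtraction.

# ---- modeled activation ----------------------------------------------------

# place one kernel per focus, per-voxel maximum; foci as 0-based voxel indices
ma_array_from_idx <- function(idx0, kernel, shape) {
  ma <- array(0, dim = shape)
  off <- kernel$offsets
  val <- kernel$values
  for (f in seq_len(nrow(idx0))) {
    ti <- off[, 1] + idx0[f, 1]
    tj <- off[, 2] + idx0[f, 2]
    tk <- off[, 3] + idx0[f, 3]
    ok <- ti >= 0L & ti < shape[1] & tj >= 0L & tj < shape[2] & tk >= 0L & tk < shape[3]
    lin <- 1L + ti[ok] + shape[1] * (tj[ok] + shape[2] * tk[ok])
    ma[lin] <- pmax(ma[lin], val[ok])
  }
  ma
}

#' Modeled activation (MA) map of one experiment
#'
#' Each focus is blurred with a spherical Gaussian kernel whose width
#' reflects the experiment's sample size; each voxel's MA value is the
#' *maximum* over the experiment's focus kernels — the probability that the
#' experiment's true activation lies in that voxel.
#'
#' @param foci_mm N x 3 matrix (or length-3 vector) of focus coordinates, mm.
#' @param n_subjects Sample size, sets the kernel width via
#'   [kernel_fwhm_from_n()]. Ignored when `kernel` is given.
#' @param grid A [make_grid()] grid.
#' @param kernel Optional pre-built [ale_kernel()] (e.g. the fixed 15-mm
#'   coactivation kernel).
#' @return A `volume_map` of kind `"MA"` (zero outside the mask).
#' @export
modeled_activation <- function(foci_mm, n_subjects = NULL, grid, kernel = NULL) {
  foci_mm <- coerce_coords(foci_mm)
  if (nrow(foci_mm) == 0) abort_metaclique("Experiment has zero foci.")
  if (is.null(kernel)) {
    if (is.null(n_subjects)) abort_metaclique("Give either `n_subjects` or `kernel`.")
    kernel <- ale_kernel(kernel_fwhm_from_n(n_subjects), grid)
  }
  idx0 <- world_to_voxel(foci_mm, grid)
  volume_map(grid, ma_array_from_idx(idx0, kernel, grid$shape), kind = "MA")
}

# ---- union statistic -------------------------------------------------------

ale_from_arrays <- function(arrs) {
  acc <- 1 - arrs[[1]]
  for (i in seq_along(arrs)[-1]) acc <- acc * (1 - arrs[[i]])
  1 - acc
}

#' ALE union of modeled activation maps
#'
#' The ALE statistic is the voxel-wise probabilistic union of the
#' per-experiment MA maps: `ALE = 1 - prod_i (1 - MA_i)`. It quantifies
#' spatial convergence across experiments; it is bounded in \[0, 1\] and is
#' at least the largest individual MA value everywhere.
#'
#' @param ma_maps List of MA `volume_map`s on a common grid.
#' @return A `volume_map` of kind `"ALE"`.
#' @export
ale_union <- function(ma_maps) {
  if (length(ma_maps) < 1) abort_metaclique("Need at least one MA map.")
  grid <- ma_maps[[1]]$grid
  for (m in ma_maps) {
    if (!grids_equal(grid, m$grid)) abort_metaclique("MA maps are on different grids.")
  }
  volume_map(grid, ale_from_arrays(lapply(ma_maps, function(m) m$data)), kind = "ALE")
}

# ---- analytic voxel-level null --------------------------------------------

#' Null distribution of the ALE statistic (histogram convolution)
#'
#' Computes the distribution of the ALE union under independent random
#' placement of each experiment's MA values across in-mask voxels, by
#' discretising each experiment's in-mask MA-value histogram and sequentially
#' convolving the histograms under the union operation. The convolution is
#' carried out in the log-complement domain `y = -log(1 - MA)`, where the
#' union is additive (a product of FFTs), then rebinned onto ALE-value bins
#' of width `bin_width`.
#'
#' @param ma_maps List of MA `volume_map`s (or plain arrays with `grid`).
#' @param grid The grid (taken from the maps when omitted).
#' @param bin_width Discretisation step for ALE values (default 1e-5).
#' @return An `ale_null` object: `bin_width`, `pmf`, `ccdf` (right tail
#'   including the bin itself), plus empty Monte-Carlo record slots.
#' @export
ale_null <- function(ma_maps, grid = NULL, bin_width = 1e-5) {
  arrs <- lapply(ma_maps, function(m) if (inherits(m, "volume_map")) m$data else m)
  if (is.null(grid)) grid <- ma_maps[[1]]$grid
  if (!any(grid$mask)) abort_metaclique("Mask is empty.")
  mask <- grid$mask

  hists <- lapply(arrs, function(a) {
    y <- -log1p(-a[mask])
    b <- floor(y / bin_width + 1e-12)
    tabulate(b + 1L, nbins = max(b) + 1L) / length(y)
  })
  total_len <- sum(vapply(hists, length, 1L)) - length(hists) + 1L
  n_fft <- stats::nextn(total_len, 2)
  acc <- NULL
  for (h in hists) {
    hp <- c(h, numeric(n_fft - length(h)))
    fh <- fft(hp)
    acc <- if (is.null(acc)) fh else acc * fh
  }
  pmf_y <- Re(fft(acc, inverse = TRUE)) / n_fft
  pmf_y <- pmf_y[seq_len(total_len)]
  pmf_y[pmf_y < 0] <- 0
  pmf_y <- pmf_y / sum(pmf_y)

  # ALE-value-bin view of the pmf (lower-edge representatives; monotone map)
  y_low <- (seq_along(pmf_y) - 1) * bin_width
  a_low <- -expm1(-y_low)
  j <- floor(a_low / bin_width + 1e-12) + 1L
  B <- max(j)
  pmf <- numeric(B)
  acc2 <- rowsum(pmf_y, j)
  pmf[as.integer(rownames(acc2))] <- acc2[, 1]

  structure(
    list(bin_width = bin_width, pmf = pmf,
         y_ccdf = rev(cumsum(rev(pmf_y))),
         support_max = -expm1(-(total_len - 1) * bin_width),
         n_experiments = length(arrs),
         mc_max_cluster_sizes = NULL, mc_max_stats = NULL, n_iterations = 0L),
    class = "ale_null"
  )
}

#' @export
print.ale_null <- function(x, ...) {
  cat(sprintf("<ale_null> %d experiments, %d bins of %g; support max %.4g\n",
              x$n_experiments, length(x$pmf), x$bin_width, x$support_max))
  if (x$n_iterations > 0) {
    cat(sprintf("  Monte-Carlo records: %d iterations\n", x$n_iterations))
  }
  invisible(x)
}

# right-tail p for raw ALE values against the discretised null. The lookup
# happens in the same floor-binned log-complement domain the null was built
# in; the observed bin is lowered by (k - 1) bins so that every null atom
# whose true value is >= the observation stays inside the tail (the sum of k
# floors under-shoots the floor of the sum by at most k - 1): conservative
# lower-edge rounding.
null_pvalue <- function(values, null) {
  delta <- null$bin_width
  y <- -log1p(-pmin(values, 1 - 1e-15))
  b <- floor(y / delta + 1e-9) - (null$n_experiments - 1L)
  b[b < 0] <- 0L
  L <- length(null$y_ccdf)
  over <- b + 1L > L
  b[over] <- L - 1L
  p <- null$y_ccdf[b + 1L]
  p[values <= 0] <- 1
  floor_p <- max(min(null$y_ccdf[null$y_ccdf > 0]), .Machine$double.xmin)
  p[over] <- floor_p
  if (any(over)) {
    message(sprintf("%d voxel(s) above the null support; assigned smallest tail mass %.3g.",
                    sum(over), floor_p))
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Voxel-wise p and z maps from the ALE null
#'
#' `p = P(null ALE >= observed)` from the discretised null CDF, with the
#' observed value rounded down to its bin's lower edge (conservative);
#' `z` is the upper-tail standard-normal quantile of `p`.
#'
#' @param ale_map ALE `volume_map`.
#' @param null An [ale_null()] built from the same MA set.
#' @return List with `p` and `z` volume maps.
#' @export
ale_pvalues <- function(ale_map, null) {
  grid <- ale_map$grid
  p <- null_pvalue(in_mask(ale_map), null)
  z <- qnorm(p, lower.tail = FALSE)
  z[!is.finite(z)] <- 0
  list(p = volume_map(grid, p_full(p, grid), kind = "p"),
       z = volume_map(grid, z, kind = "z"))
}

# p maps need 1 (not 0) outside the representable range; fill full array
p_full <- function(p_mask_values, grid) {
  arr <- array(1, dim = grid$shape)
  arr[grid$mask] <- p_mask_values
  arr
}

#' Critical ALE value for a voxel-level threshold
#'
#' Smallest discretised ALE value whose right-tail null probability is below
#' `voxel_p`; a voxel is supra-threshold iff its ALE value is `>=` this.
#'
#' @param null An [ale_null()].
#' @param voxel_p Voxel-level threshold (default 0.001).
#' @return Critical ALE value (`Inf` when unattainable).
#' @export
ale_critical <- function(null, voxel_p = 0.001) {
  m <- which(null$y_ccdf < voxel_p)
  if (length(m) == 0) return(Inf)
  # invert the conservative lookup of null_pvalue: p(v) < voxel_p iff
  # floor(y/delta) - (k-1) >= m* iff v >= 1 - exp(-(m* + k - 1) delta)
  mstar <- m[1] - 1L
  -expm1(-(mstar + null$n_experiments - 1L) * null$bin_width)
}

# ---- connected components (26-connectivity) --------------------------------

neighbor_offsets_26 <- local({
  m <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m[rowSums(abs(m)) > 0, , drop = FALSE]
})

# logical array -> integer label array + sizes; frontier-expansion BFS
label_components <- function(mask_arr) {
  shape <- dim(mask_arr)
  lab <- array(0L, dim = shape)
  todo <- which(mask_arr)
  sizes <- integer(0)
  comp <- 0L
  off_lin <- neighbor_offsets_26
  for (seed_lin in todo) {
    if (lab[seed_lin] != 0L) next
    comp <- comp + 1L
    lab[seed_lin] <- comp
    frontier <- seed_lin
    csize <- 1L
    while (length(frontier) > 0) {
      co <- linear_voxel(frontier, shape)
      ni <- rep(co[, 1], each = 26) + rep(off_lin[, 1], times = nrow(co))
      nj <- rep(co[, 2], each = 26) + rep(off_lin[, 2], times = nrow(co))
      nk <- rep(co[, 3], each = 26) + rep(off_lin[, 3], times = nrow(co))
      ok <- ni >= 0L & ni < shape[1] & nj >= 0L & nj < shape[2] & nk >= 0L & nk < shape[3]
      lin <- unique(1L + ni[ok] + shape[1] * (nj[ok] + shape[2] * nk[ok]))
      lin <- lin[mask_arr[lin] & lab[lin] == 0L]
      lab[lin] <- comp
      csize <- csize + length(lin)
      frontier <- lin
    }
    sizes <- c(sizes, csize)
  }
  list(labels = lab, sizes = sizes)
}

#' Connected-component cluster table of a thresholded map
#'
#' Components are taken under 26-connectivity (corner-touching voxels are
#' connected). Per cluster: volume in mm^3 (voxel count x voxel volume),
#' peak value and its mm coordinate. Ordered by volume, descending.
#'
#' @param thresholded Logical array / `volume_map` marking supra-threshold
#'   voxels, or a `volume_map` whose positive voxels are supra-threshold.
#' @param ale_map `volume_map` with the statistic values (for peaks).
#' @return A tibble: `cluster`, `x`, `y`, `z`, `volume_mm3`, `ale_max`,
#'   `n_voxels`, plus a `voxels` list-column of linear indices.
#' @export
extract_clusters <- function(thresholded, ale_map) {
  grid <- ale_map$grid
  supra <- if (inherits(thresholded, "volume_map")) thresholded$data != 0 else thresholded
  supra <- supra & grid$mask
  if (!any(supra)) {
    return(tibble(cluster = integer(), x = numeric(), y = numeric(), z = numeric(),
                  volume_mm3 = numeric(), ale_max = numeric(), n_voxels = integer(),
                  voxels = list()))
  }
  cc <- label_components(supra)
  voxvol <- prod(grid$voxel_mm)
  rows <- lapply(seq_along(cc$sizes), function(ci) {
    lin <- which(cc$labels == ci)
    vals <- ale_map$data[lin]
    pk <- lin[which.max(vals)]
    mm <- voxel_to_world(linear_voxel(pk, grid$shape), grid)
    tibble(x = mm[1], y = mm[2], z = mm[3],
           volume_mm3 = length(lin) * voxvol, ale_max = max(vals),
           n_voxels = length(lin), voxels = list(lin))
  })
  out <- bind_rows(rows) %>%
    arrange(desc(.data$volume_mm3), desc(.data$ale_max)) %>%
    mutate(cluster = row_number()) %>%
    select("cluster", dplyr::everything())
  out
}

# ---- Monte-Carlo cluster-extent FWE ---------------------------------------

# uniform relocation of every experiment's foci onto in-mask voxel centres
random_idx0 <- function(n_foci, mask_lin, shape) {
  linear_voxel(sample(mask_lin, n_foci, replace = TRUE), shape)
}

#' Monte-Carlo cluster-extent threshold (FWE)
#'
#' For each iteration every focus is replaced by a uniformly drawn in-mask
#' voxel centre (preserving per-experiment focus counts and kernel widths),
#' the ALE map is recomputed and thresholded at `voxel_p` (using the analytic
#' null of the corpus composition), and the maximum supra-threshold cluster
#' size (26-connectivity) is recorded. The family-wise criterion keeps
#' observed clusters strictly larger than the null distribution's
#' `1 - fwe` percentile (ceiling order statistic), i.e.
#' `extent_threshold_voxels = percentile size + 1`.
#'
#' @param foci_tbl Validated foci table (the corpus).
#' @param grid A [make_grid()] grid.
#' @param voxel_p Cluster-forming voxel threshold (default 0.001).
#' @param n_iterations Number of Monte-Carlo iterations (>= 100; 10,000 in
#'   full-scale runs).
#' @param seed RNG seed (required for reproducibility).
#' @param fwe Family-wise error level (default 0.05).
#' @param constants Kernel constants, see [ale_uncertainty_constants()].
#' @param null Optional precomputed [ale_null()] for this corpus composition.
#' @return An `ale_extent_null`: `extent_threshold_voxels`, `max_sizes`,
#'   `crit_ale`, the analytic `null`, and the call parameters.
#' @export
cluster_extent_threshold <- function(foci_tbl, grid, voxel_p = 0.001,
                                     n_iterations = 10000, seed,
                                     fwe = 0.05,
                                     constants = ale_uncertainty_constants(),
                                     null = NULL) {
  if (missing(seed)) abort_metaclique("`seed` is required for reproducibility.")
  if (n_iterations < 100) abort_metaclique("`n_iterations` must be >= 100.")
  exps <- foci_experiments(foci_tbl)
  kc <- kernel_cache(grid)
  kernels <- lapply(exps, function(e) kc(kernel_fwhm_from_n(e$n_subjects, constants)))
  n_foci <- vapply(exps, function(e) nrow(e$foci_mm), 1L)

  if (is.null(null)) {
    ma <- lapply(seq_along(exps), function(i) {
      ma_array_from_idx(world_to_voxel(exps[[i]]$foci_mm, grid), kernels[[i]], grid$shape)
    })
    null <- ale_null(ma, grid)
  }
  crit <- ale_critical(null, voxel_p)
  mask_lin <- which(grid$mask)
  shape <- grid$shape

  set.seed(derive_seed(seed, "extent-mc"))
  max_sizes <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    arrs <- lapply(seq_along(exps), function(i) {
      ma_array_from_idx(random_idx0(n_foci[i], mask_lin, shape), kernels[[i]], shape)
    })
    ale <- ale_from_arrays(arrs)
    supra <- ale >= crit & grid$mask
    max_sizes[it] <- if (any(supra)) max(label_components(supra)$sizes) else 0L
  }
  pct <- sort(max_sizes)[ceiling((1 - fwe) * n_iterations)]
  structure(
    list(extent_threshold_voxels = pct + 1L, percentile_size = pct,
         max_sizes = max_sizes, crit_ale = crit, null = null,
         voxel_p = voxel_p, fwe = fwe, n_iterations = n_iterations, seed = seed),
    class = "ale_extent_null"
  )
}

# ---- full ALE analysis -----------------------------------------------------

#' Run a complete ALE meta-analysis
#'
#' Modeled activation maps -> ALE union -> analytic voxel null -> p/z maps ->
#' Monte-Carlo cluster-extent FWE correction -> cluster table.
#'
#' @inheritParams cluster_extent_threshold
#' @param extent_null Optional precomputed [cluster_extent_threshold()]
#'   result (reusable across corpora with the same composition).
#' @return An `ale_result` with `ale`, `p`, `z`, `thresholded` volume maps,
#'   a `clusters` tibble, the `null`, and the thresholds used.
#' @export
run_ale <- function(foci_tbl, grid, voxel_p = 0.001, fwe = 0.05,
                    n_iterations = 10000, seed,
                    constants = ale_uncertainty_constants(),
                    extent_null = NULL) {
  exps <- foci_experiments(foci_tbl)
  kc <- kernel_cache(grid)
  ma <- lapply(exps, function(e) {
    k <- kc(kernel_fwhm_from_n(e$n_subjects, constants))
    ma_array_from_idx(world_to_voxel(e$foci_mm, grid), k, grid$shape)
  })
  ale_arr <- ale_from_arrays(ma)
  ale_arr[!grid$mask] <- 0
  ale_map <- volume_map(grid, ale_arr, kind = "ALE")
  null <- if (!is.null(extent_null)) extent_null$null else ale_null(ma, grid)
  pz <- ale_pvalues(ale_map, null)
  if (is.null(extent_null)) {
    extent_null <- cluster_extent_threshold(foci_tbl, grid, voxel_p, n_iterations,
                                            seed, fwe, constants, null = null)
  }
  crit <- ale_critical(null, voxel_p)
  supra <- ale_map$data >= crit & grid$mask
  clusters <- extract_clusters(supra, ale_map)
  keep <- clusters$n_voxels >= extent_null$extent_threshold_voxels
  clusters <- clusters[keep, , drop = FALSE]
  if (nrow(clusters) > 0) clusters$cluster <- seq_len(nrow(clusters))
  thr_arr <- array(0, dim = grid$shape)
  for (lin in clusters$voxels) thr_arr[lin] <- ale_map$data[lin]
  null$mc_max_cluster_sizes <- extent_null$max_sizes
  null$n_iterations <- extent_null$n_iterations

  structure(
    list(ale = ale_map, p = pz$p, z = pz$z,
         thresholded = volume_map(grid, thr_arr, kind = "ALE"),
         clusters = clusters, null = null,
         voxel_threshold_p = voxel_p, fwe = fwe, crit_ale = crit,
         extent_threshold_voxels = extent_null$extent_threshold_voxels,
         n_experiments = length(exps), seed = seed),
    class = "ale_result"
  )
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf("<ale_result> %d experiments; voxel p < %g, extent >= %d voxels; %d cluster(s)\n",
              x$n_experiments, x$voxel_threshold_p, x$extent_threshold_voxels,
              nrow(x$clusters)))
  invisible(x)
}

#' @export
tidy.ale_result <- function(x, ...) {
  select(x$clusters, "cluster", "x", "y", "z", "volume_mm3", "ale_max", "n_voxels")
}

#' @export
glance.ale_result <- function(x, ...) {
  tibble(n_experiments = x$n_experiments, n_clusters = nrow(x$clusters),
         voxel_p = x$voxel_threshold_p, fwe = x$fwe,
         crit_ale = x$crit_ale,
         extent_threshold_voxels = x$extent_threshold_voxels,
         mc_iterations = x$null$n_iterations, seed = x$seed)
}

# ---- conjunction -----------------------------------------------------------

#' Minimum-statistic conjunction of two thresholded ALE maps
#'
#' A voxel is retained iff it is significant (non-zero) in *both*
#' thresholded inputs; its value is the minimum of the two ALE values —
#' the convergence common to both groups.
#'
#' @param thresholded_a,thresholded_b Thresholded `volume_map`s.
#' @param ale_a,ale_b The corresponding unthresholded ALE maps (default:
#'   the thresholded maps themselves carry ALE values).
#' @return A `volume_map` of kind `"ALE"`.
#' @export
ale_conjunction <- function(thresholded_a, thresholded_b,
                            ale_a = thresholded_a, ale_b = thresholded_b) {
  grid <- thresholded_a$grid
  if (!grids_equal(grid, thresholded_b$grid)) abort_metaclique("Grid mismatch in conjunction.")
  both <- thresholded_a$data != 0 & thresholded_b$data != 0
  out <- array(0, dim = grid$shape)
  out[both] <- pmin(ale_a$data[both], ale_b$data[both])
  volume_map(grid, out, kind = "ALE")
}

# ---- permutation subtraction ----------------------------------------------

#' Permutation subtraction of two ALE groups
#'
#' The observed statistic is the voxel-wise difference of the two groups'
#' unthresholded ALE maps. The null shuffles experiment labels between the
#' groups (group sizes preserved) and recomputes the pseudo-ALE difference
#' per iteration. Voxel p-values come from the permutation distribution of
#' `|difference|`; family-wise control uses the max-`|difference|`
#' distribution at level `fwe`; surviving voxels are additionally filtered by
#' an extent threshold (default 100 contiguous voxels, 26-connectivity).
#' Swapping the group arguments exactly negates the result.
#'
#' @param foci_a,foci_b Validated foci tables for the two groups.
#' @param grid A [make_grid()] grid.
#' @param n_iterations Number of permutations (>= 100; 10,000 at full scale).
#' @param seed RNG seed.
#' @param fwe Family-wise level for the max-statistic criterion (default 0.05).
#' @param extent_voxels Contiguity filter in voxels (default 100).
#' @param method `"fwe"` (max-statistic, default) or `"fdr"`
#'   (Benjamini-Hochberg on the voxel permutation p-values).
#' @param constants Kernel constants.
#' @return An `ale_subtraction` with `difference`, `p`, `z`, `thresholded`
#'   volume maps and per-sign cluster tables; `NULL` (with a warning) when a
#'   group has fewer than 2 experiments.
#' @export
ale_subtraction <- function(foci_a, foci_b, grid, n_iterations = 10000, seed,
                            fwe = 0.05, extent_voxels = 100,
                            method = c("fwe", "fdr"),
                            constants = ale_uncertainty_constants()) {
  method <- match.arg(method)
  if (missing(seed)) abort_metaclique("`seed` is required for reproducibility.")
  exps_a <- foci_experiments(foci_a)
  exps_b <- foci_experiments(foci_b)
  if (length(exps_a) < 2 || length(exps_b) < 2) {
    rlang::warn("Each group needs >= 2 experiments; permutation space degenerate. Returning NULL.")
    return(NULL)
  }
  # canonicalise the unordered pair so swapping the arguments only flips signs
  key <- function(ex) paste(sort(vapply(ex, function(e) as.character(e$experiment_id), "")),
                            collapse = "|")
  flipped <- key(exps_a) > key(exps_b)
  if (flipped) { tmp <- exps_a; exps_a <- exps_b; exps_b <- tmp }

  kc <- kernel_cache(grid)
  all_exps <- c(exps_a, exps_b)
  mask <- grid$mask
  # per-experiment log-complement MA vectors: union over a subset is additive
  logc <- lapply(all_exps, function(e) {
    k <- kc(kernel_fwhm_from_n(e$n_subjects, constants))
    ma <- ma_array_from_idx(world_to_voxel(e$foci_mm, grid), k, grid$shape)
    log1p(-ma[mask])
  })
  n_a <- length(exps_a)
  n_tot <- length(all_exps)
  total <- Reduce(`+`, logc)
  sum_subset <- function(sel) Reduce(`+`, logc[sel])
  diff_of <- function(sel_a) {
    sa <- sum_subset(sel_a)
    exp(total - sa) - exp(sa)  # ALE(a) - ALE(b) = (1-e^{sa}) - (1-e^{s_tot-sa})
  }
  obs <- diff_of(seq_len(n_a))

  set.seed(derive_seed(seed, "subtraction"))
  cnt <- numeric(length(obs))
  max_abs <- numeric(n_iterations)
  abs_obs <- abs(obs)
  for (it in seq_len(n_iterations)) {
    d <- diff_of(sample.int(n_tot, n_a))
    cnt <- cnt + (abs(d) >= abs_obs)
    max_abs[it] <- max(abs(d))
  }
  p <- (1 + cnt) / (n_iterations + 1)
  flo <- 1 / (n_iterations + 1)
  z <- sign(obs) * qnorm(pmin(pmax(p, flo), 1 - flo), lower.tail = FALSE)
  z[obs == 0] <- 0

  if (method == "fwe") {
    thr <- sort(max_abs)[ceiling((1 - fwe) * n_iterations)]
    surv <- abs_obs >= thr & abs_obs > 0
  } else {
    surv <- stats::p.adjust(p, method = "BH") < fwe & abs_obs > 0
  }

  if (flipped) { obs <- -obs; z <- -z }
  diff_arr <- z_arr <- array(0, dim = grid$shape)
  diff_arr[mask] <- obs
  z_arr[mask] <- z
  diff_map <- volume_map(grid, diff_arr, kind = "difference")

  surv_arr <- array(FALSE, dim = grid$shape)
  surv_arr[mask] <- surv
  thr_arr <- array(0, dim = grid$shape)
  keep_component <- function(sign_mask) {
    out <- list()
    if (any(sign_mask)) {
      cc <- label_components(sign_mask)
      for (ci in which(cc$sizes >= extent_voxels)) {
        lin <- which(cc$labels == ci)
        thr_arr[lin] <<- diff_arr[lin]
        out[[length(out) + 1]] <- lin
      }
    }
    out
  }
  pos_clusters <- keep_component(surv_arr & diff_arr > 0)
  neg_clusters <- keep_component(surv_arr & diff_arr < 0)

  cluster_tbl <- function(linsets, label) {
    if (length(linsets) == 0) return(tibble())
    bind_rows(lapply(linsets, function(lin) {
      pk <- lin[which.max(abs(diff_arr[lin]))]
      mm <- voxel_to_world(linear_voxel(pk, grid$shape), grid)
      tibble(direction = label, x = mm[1], y = mm[2], z = mm[3],
             n_voxels = length(lin),
             volume_mm3 = length(lin) * prod(grid$voxel_mm),
             peak_difference = diff_arr[pk])
    }))
  }
  clusters <- bind_rows(cluster_tbl(pos_clusters, "a_gt_b"),
                        cluster_tbl(neg_clusters, "b_gt_a"))

  structure(
    list(difference = diff_map,
         p = volume_map(grid, p_full(p, grid), kind = "p"),
         z = volume_map(grid, z_arr, kind = "z"),
         thresholded = volume_map(grid, thr_arr, kind = "difference"),
         clusters = clusters, method = method, fwe = fwe,
         extent_voxels = extent_voxels, n_iterations = n_iterations,
         seed = seed),
    class = "ale_subtraction"
  )
}

#' @export
print.ale_subtraction <- function(x, ...) {
  cat(sprintf("<ale_subtraction> %s at %g, extent >= %d voxels; %d surviving cluster(s)\n",
              toupper(x$method), x$fwe, x$extent_voxels, nrow(x$clusters)))
  invisible(x)
}

#' @export
tidy.ale_subtraction <- function(x, ...) x$clusters
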