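## Seed ROIs: local maxima of thresholded ALE clusters, 20-mm separation
## pruning, 6-mm spheres, configurable label lookup.

#' Local maxima of an ALE map within clusters
#'
#' A voxel is a local maximum iff its value is `>=` all 26 neighbours and it
#' lies in one of the supplied clusters. A flat plateau of equal, connected
#' candidate voxels yields a single maximum: the voxel with the smallest
#' linear index (deterministic tie rule).
#'
#' @param ale_map `volume_map` with the statistic.
#' @param clusters Cluster tibble from [extract_clusters()] (needs the
#'   `voxels` list-column and `cluster` ids).
#' @return A tibble of peaks: `cluster_id`, `x`, `y`, `z`, `value`, sorted
#'   within cluster by descending value.
#' @export
local_maxima <- function(ale_map, clusters) {
  grid <- ale_map$grid
  if (nrow(clusters) == 0) {
    return(tibble(cluster_id = integer(), x = numeric(), y = numeric(),
                  z = numeric(), value = numeric()))
  }
  arr <- ale_map$data
  shape <- grid$shape
  # candidate = value >= all 26 neighbours (out-of-bounds treated as -Inf)
  nb_max <- array(-Inf, dim = shape)
  for (r in seq_len(nrow(neighbor_offsets_26))) {
    o <- neighbor_offsets_26[r, ]
    sh <- shift_array(arr, o[1], 1)
    sh <- shift_array(sh, o[2], 2)
    sh <- shift_array(sh, o[3], 3)
    # zero-filled shifts are fine: statistic values are >= 0 and candidates > 0
    nb_max <- pmax(nb_max, sh)
  }
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    lin <- clusters$voxels[[i]]
    cand <- lin[arr[lin] >= nb_max[lin]]
    if (length(cand) == 0) cand <- lin[which.max(arr[lin])]
    cand <- resolve_plateaus(cand, arr, shape)
    mm <- voxel_to_world(linear_voxel(cand, shape), grid)
    tibble(cluster_id = clusters$cluster[i],
           x = mm[, 1], y = mm[, 2], z = mm[, 3], value = arr[cand]) %>%
      arrange(desc(.data$value))
  })
  bind_rows(rows)
}

# among candidate voxels, merge 26-connected equal-value plateaus and keep
# the smallest linear index of each
resolve_plateaus <- function(cand, arr, shape) {
  if (length(cand) <= 1) return(cand)
  cand <- sort(cand)
  sel <- array(FALSE, dim = shape)
  sel[cand] <- TRUE
  cc <- label_components(sel)
  keep <- integer(0)
  for (ci in seq_along(cc$sizes)) {
    lin <- sort(which(cc$labels == ci))
    vals <- arr[lin]
    # within a connected candidate set, equal-value runs collapse to one voxel
    for (v in unique(vals)) keep <- c(keep, min(lin[vals == v]))
  }
  sort(keep)
}

#' Prune peaks by a minimum separation rule
#'
#' Greedy selection in descending value order: a peak is accepted iff its
#' Euclidean distance to every already-accepted peak is at least
#' `min_separation_mm`. Deterministic; idempotent; the accepted set has all
#' pairwise distances `>=` the separation.
#'
#' @param peaks Tibble with `x`, `y`, `z`, `value` (e.g. [local_maxima()]).
#' @param min_separation_mm Minimum separation (default 20 mm).
#' @return The retained subset of `peaks`, in descending value order.
#' @export
prune_peaks <- function(peaks, min_separation_mm = 20) {
  if (nrow(peaks) == 0) return(peaks)
  ord <- order(-peaks$value)
  peaks <- peaks[ord, , drop = FALSE]
  xyz <- as.matrix(peaks[, c("x", "y", "z")])
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt(rowSums((xyz[keep, , drop = FALSE] -
                       matrix(xyz[i, ], sum(keep), 3, byrow = TRUE))^2))
    keep[i] <- all(d >= min_separation_mm)
  }
  peaks[keep, , drop = FALSE]
}

#' Spherical seed ROI around a peak
#'
#' The ROI voxel set is every in-mask voxel whose centre lies within
#' `radius_mm` of the centre (closed ball).
#'
#' @param center_mm Length-3 mm coordinate.
#' @param grid A [make_grid()] grid.
#' @param radius_mm Sphere radius (default 6 mm).
#' @param roi_id Optional identifier.
#' @param label Optional text label.
#' @return A `seed_roi`: `center_mm`, `radius_mm`, `voxels` (linear indices),
#'   `roi_id`, `label`.
#' @export
sphere_roi <- function(center_mm, grid, radius_mm = 6, roi_id = NULL, label = NA_character_) {
  center_mm <- as.numeric(coerce_coords(center_mm))
  mask_lin <- which(grid$mask)
  cents <- voxel_to_world(linear_voxel(mask_lin, grid$shape), grid)
  d2 <- (cents[, 1] - center_mm[1])^2 + (cents[, 2] - center_mm[2])^2 +
    (cents[, 3] - center_mm[3])^2
  lin <- mask_lin[d2 <= radius_mm^2]
  if (length(lin) == 0) {
    abort_metaclique(sprintf(
      "Sphere at (%.1f, %.1f, %.1f) mm contains no in-mask voxels.",
      center_mm[1], center_mm[2], center_mm[3]))
  }
  structure(list(center_mm = center_mm, radius_mm = radius_mm, voxels = lin,
                 roi_id = roi_id, label = label),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat(sprintf("<seed_roi%s> centre (%.1f, %.1f, %.1f) mm, r = %g mm, %d voxels\n",
              if (!is.null(x$roi_id)) paste0(" ", x$roi_id) else "",
              x$center_mm[1], x$center_mm[2], x$center_mm[3],
              x$radius_mm, length(x$voxels)))
  invisible(x)
}

#' Label a coordinate against a region table
#'
#' Configurable replacement for atlas lookup: `label_table` is a tibble of
#' axis-aligned mm boxes (`label`, `xmin`, `xmax`, `ymin`, `ymax`, `zmin`,
#' `zmax`). The label of the box containing the centre is returned;
#' containment ties go to the alphabetically first label (messaged); a
#' centre inside no box is `"unlabeled"`.
#'
#' @param center_mm Length-3 mm coordinate.
#' @param label_table Region box tibble (or `NULL` -> `"unlabeled"`).
#' @return A character label.
#' @export
label_roi <- function(center_mm, label_table = NULL) {
  if (is.null(label_table) || nrow(label_table) == 0) return("unlabeled")
  c3 <- as.numeric(coerce_coords(center_mm))
  inside <- label_table$xmin <= c3[1] & c3[1] <= label_table$xmax &
    label_table$ymin <= c3[2] & c3[2] <= label_table$ymax &
    label_table$zmin <= c3[3] & c3[3] <= label_table$zmax
  hits <- sort(label_table$label[inside])
  if (length(hits) == 0) return("unlabeled")
  if (length(hits) > 1) {
    message(sprintf("Label tie at (%g, %g, %g): %s; keeping '%s'.",
                    c3[1], c3[2], c3[3], paste(hits, collapse = ", "), hits[1]))
  }
  hits[1]
}

#' Build the seed-ROI set from an ALE result
#'
#' Local maxima of the thresholded clusters, pruned by the separation rule
#' (applied jointly across all clusters by default), then turned into
#' spherical seeds and labelled.
#'
#' @param ale_result An [run_ale()] result.
#' @param radius_mm Sphere radius (default 6 mm).
#' @param min_separation_mm Peak separation (default 20 mm).
#' @param per_cluster If `TRUE`, apply the separation rule within each
#'   cluster only, rather than jointly.
#' @param label_table Optional region boxes for [label_roi()].
#' @return A tibble: `roi_id`, `cluster_id`, `x`, `y`, `z`, `value`,
#'   `label`, `n_voxels`, plus a `roi` list-column of `seed_roi` objects.
#' @export
build_seed_rois <- function(ale_result, radius_mm = 6, min_separation_mm = 20,
                            per_cluster = FALSE, label_table = NULL) {
  peaks <- local_maxima(ale_result$ale, ale_result$clusters)
  pruned <- if (per_cluster) {
    peaks %>% group_by(.data$cluster_id) %>%
      dplyr::group_modify(~ prune_peaks(.x, min_separation_mm)) %>% ungroup()
  } else {
    prune_peaks(peaks, min_separation_mm)
  }
  if (nrow(pruned) == 0) return(tibble())
  grid <- ale_result$ale$grid
  rois <- lapply(seq_len(nrow(pruned)), function(i) {
    sphere_roi(c(pruned$x[i], pruned$y[i], pruned$z[i]), grid, radius_mm,
               roi_id = sprintf("roi%02d", i),
               label = label_roi(c(pruned$x[i], pruned$y[i], pruned$z[i]), label_table))
  })
  pruned %>%
    mutate(roi_id = vapply(rois, function(r) r$roi_id, ""),
           label = vapply(rois, function(r) r$label, ""),
           n_voxels = vapply(rois, function(r) length(r$voxels), 1L),
           roi = rois) %>%
    select("roi_id", "cluster_id", "x", "y", "z", "value", "label", "n_voxels", "roi")
}

#' Export a seed-ROI set
#'
#' Writes a TSV of the ROI table, one NIfTI mask per ROI, and a combined
#' indexed mask.
#'
#' @param roi_tbl Output of [build_seed_rois()].
#' @param grid The session grid.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_rois <- function(roi_tbl, grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(select(roi_tbl, "roi_id", "x", "y", "z", "value", "label", "n_voxels"),
                   file.path(dir, "rois.tsv"), progress = FALSE)
  combined <- array(0L, dim = grid$shape)
  for (i in seq_len(nrow(roi_tbl))) {
    r <- roi_tbl$roi[[i]]
    m <- array(0L, dim = grid$shape)
    m[r$voxels] <- 1L
    nifti_write_array(m, grid, file.path(dir, paste0(r$roi_id, "_mask.nii.gz")))
    combined[r$voxels] <- i
  }
  nifti_write_array(combined, grid, file.path(dir, "rois_indexed.nii.gz"))
  invisible(dir)
}
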