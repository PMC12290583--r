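## Meta-analytic connectivity modeling against a term-annotated coordinate
## database: study selection by seed ROI, fixed 15-mm-kernel coactivation
## ALE with voxel-level FWE, and term-association maps for decoding.

#' Construct a term-annotated coordinate database
#'
#' @param foci Tibble: `study_id`, `x`, `y`, `z` (mm) and optionally `n`.
#' @param annotations Tibble: `study_id`, `term` (binary annotations).
#' @return A `coordinate_db`.
#' @export
coordinate_db <- function(foci, annotations = NULL) {
  req <- c("study_id", "x", "y", "z")
  missing_cols <- setdiff(req, names(foci))
  if (length(missing_cols) > 0) {
    abort_metaclique(sprintf("Database foci table is missing: %s",
                             paste(missing_cols, collapse = ", ")),
                     class = "metaclique_schema_error")
  }
  foci <- as_tibble(foci)
  if (any(!is.finite(foci$x + foci$y + foci$z))) {
    abort_metaclique("Database foci must be finite.", class = "metaclique_validation_error")
  }
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    unknown <- setdiff(annotations$study_id, foci$study_id)
    if (length(unknown) > 0) {
      abort_metaclique(sprintf("Annotated study '%s' has no foci in the database.", unknown[1]),
                       class = "metaclique_validation_error")
    }
  } else {
    annotations <- tibble(study_id = character(), term = character())
  }
  structure(list(foci = foci, annotations = annotations), class = "coordinate_db")
}

#' @export
print.coordinate_db <- function(x, ...) {
  cat(sprintf("<coordinate_db> %d studies, %d foci, %d terms\n",
              length(unique(x$foci$study_id)), nrow(x$foci),
              length(unique(x$annotations$term))))
  invisible(x)
}

#' Read / write a coordinate database as two TSVs
#' @param foci_path TSV with `study_id`, `x`, `y`, `z`.
#' @param annotations_path TSV with `study_id`, `term` (optional).
#' @export
read_coordinate_db <- function(foci_path, annotations_path = NULL) {
  foci <- readr::read_tsv(foci_path, show_col_types = FALSE, progress = FALSE)
  ann <- if (!is.null(annotations_path)) {
    readr::read_tsv(annotations_path, show_col_types = FALSE, progress = FALSE)
  }
  coordinate_db(foci, ann)
}

#' @rdname read_coordinate_db
#' @param db A `coordinate_db`.
#' @param dir Output directory.
#' @export
write_coordinate_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(db$foci, file.path(dir, "db_foci.tsv"), progress = FALSE)
  readr::write_tsv(db$annotations, file.path(dir, "db_annotations.tsv"), progress = FALSE)
  invisible(dir)
}

#' Select database studies reporting a focus in a seed ROI
#'
#' Under the default `"sphere"` rule a study is selected iff at least one of
#' its foci lies within the closed ball of the ROI's radius around the ROI
#' centre. The `"voxel"` rule instead requires a focus whose nearest voxel
#' belongs to the ROI voxel set. Selection is monotone in the ROI radius.
#'
#' @param db A [coordinate_db()].
#' @param roi A [sphere_roi()].
#' @param rule `"sphere"` (default) or `"voxel"`.
#' @param grid Required for the `"voxel"` rule.
#' @return Character vector of selected study ids.
#' @export
select_studies <- function(db, roi, rule = c("sphere", "voxel"), grid = NULL) {
  rule <- match.arg(rule)
  if (nrow(db$foci) == 0) abort_metaclique("Coordinate database is empty.")
  if (rule == "sphere") {
    d2 <- (db$foci$x - roi$center_mm[1])^2 + (db$foci$y - roi$center_mm[2])^2 +
      (db$foci$z - roi$center_mm[3])^2
    hit <- d2 <= roi$radius_mm^2
  } else {
    stopifnot(!is.null(grid))
    idx <- world_to_voxel(as.matrix(db$foci[, c("x", "y", "z")]), grid)
    hit <- voxel_linear(idx, grid$shape) %in% roi$voxels
  }
  sort(unique(as.character(db$foci$study_id[hit])))
}

# union ALE over a set of studies with a fixed kernel
study_ale_array <- function(db, study_ids, grid, kernel) {
  arrs <- lapply(study_ids, function(s) {
    foci <- as.matrix(db$foci[db$foci$study_id == s, c("x", "y", "z")])
    ma_array_from_idx(world_to_voxel(foci, grid), kernel, grid$shape)
  })
  a <- ale_from_arrays(arrs)
  a[!grid$mask] <- 0
  a
}

#' Meta-analytic coactivation map of a seed ROI
#'
#' Selects database studies reporting a focus in the ROI, computes their
#' coactivation ALE with a fixed-width kernel (15-mm FWHM for all study
#' coordinates, not sample-size-dependent), and applies a voxel-level FWE
#' correction via a max-statistic Monte-Carlo null (uniform in-mask
#' relocation of all selected studies' foci; threshold at the
#' `1 - voxel_fwe_p` percentile of per-iteration maxima). Downstream
#' profile correlation uses the *unthresholded* map.
#'
#' @param db A [coordinate_db()].
#' @param roi A [sphere_roi()].
#' @param grid A [make_grid()] grid.
#' @param fwhm_mm Fixed kernel width (default 15 mm).
#' @param n_iterations Max-statistic null iterations (10,000 at full scale;
#'   `0` skips thresholding).
#' @param seed RNG seed (required when `n_iterations > 0`).
#' @param voxel_fwe_p Voxel-level FWE level (default 0.001).
#' @param rule Study selection rule, see [select_studies()].
#' @return A `macm_result`: `roi_id`, `selected_study_ids`, `unthresholded`
#'   and `thresholded` volume maps, `threshold_ale`, `degenerate` flag.
#' @export
macm_map <- function(db, roi, grid, fwhm_mm = 15, n_iterations = 10000,
                     seed = NULL, voxel_fwe_p = 0.001, rule = "sphere") {
  selected <- select_studies(db, roi, rule = rule, grid = grid)
  degenerate <- length(selected) < 2
  if (length(selected) == 0) {
    rlang::warn(sprintf("ROI %s selects no studies; degenerate MACM result.",
                        roi$roi_id %||% "?"))
    return(structure(list(roi_id = roi$roi_id, selected_study_ids = character(),
                          unthresholded = volume_map(grid, 0, "ALE"),
                          thresholded = NULL, threshold_ale = NA_real_,
                          degenerate = TRUE),
                     class = "macm_result"))
  }
  if (degenerate) {
    rlang::warn(sprintf("ROI %s selects only %d study; degenerate MACM result.",
                        roi$roi_id %||% "?", length(selected)))
  }
  kernel <- ale_kernel(fwhm_mm, grid)
  unthr <- study_ale_array(db, selected, grid, kernel)

  thresholded <- NULL
  thr <- NA_real_
  if (n_iterations > 0 && !degenerate) {
    if (is.null(seed)) abort_metaclique("`seed` is required for the Monte-Carlo null.")
    n_foci <- vapply(selected, function(s) sum(db$foci$study_id == s), 1L)
    mask_lin <- which(grid$mask)
    set.seed(derive_seed(seed, paste0("macm-", roi$roi_id %||% "roi")))
    mc_max <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      arrs <- lapply(n_foci, function(nf) {
        ma_array_from_idx(random_idx0(nf, mask_lin, grid$shape), kernel, grid$shape)
      })
      a <- ale_from_arrays(arrs)
      mc_max[it] <- max(a[grid$mask])
    }
    thr <- sort(mc_max)[ceiling((1 - voxel_fwe_p) * n_iterations)]
    thr_arr <- unthr
    thr_arr[thr_arr < thr] <- 0
    thresholded <- volume_map(grid, thr_arr, kind = "ALE")
  }
  structure(
    list(roi_id = roi$roi_id, selected_study_ids = selected,
         unthresholded = volume_map(grid, unthr, kind = "ALE"),
         thresholded = thresholded, threshold_ale = thr,
         fwhm_mm = fwhm_mm, voxel_fwe_p = voxel_fwe_p,
         n_iterations = n_iterations, degenerate = degenerate),
    class = "macm_result"
  )
}

#' @export
print.macm_result <- function(x, ...) {
  cat(sprintf("<macm_result%s> %d selected studies%s\n",
              if (!is.null(x$roi_id)) paste0(" ", x$roi_id) else "",
              length(x$selected_study_ids),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Term-association map from the coordinate database
#'
#' A transparent stand-in for database term maps: the difference of the
#' fixed-kernel ALE over studies annotated *with* the term and the ALE over
#' studies *without* it. When every study carries the term the complement is
#' taken as a zero map (messaged). Externally computed term maps can be
#' supplied to [decode_terms()] instead.
#'
#' @param db A [coordinate_db()].
#' @param term Term id present in the annotations.
#' @param grid A [make_grid()] grid.
#' @param fwhm_mm Fixed kernel width (default 15 mm).
#' @return A `volume_map` of kind `"difference"`.
#' @export
term_map <- function(db, term, grid, fwhm_mm = 15) {
  with_ids <- unique(db$annotations$study_id[db$annotations$term == term])
  if (length(with_ids) == 0) {
    abort_metaclique(sprintf("Term '%s' annotates no studies.", term))
  }
  all_ids <- unique(db$foci$study_id)
  without_ids <- setdiff(all_ids, with_ids)
  kernel <- ale_kernel(fwhm_mm, grid)
  a_with <- study_ale_array(db, with_ids, grid, kernel)
  a_without <- if (length(without_ids) == 0) {
    message(sprintf("Term '%s' annotates all studies; complement taken as zero map.", term))
    array(0, dim = grid$shape)
  } else {
    study_ale_array(db, without_ids, grid, kernel)
  }
  volume_map(grid, a_with - a_without, kind = "difference")
}
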