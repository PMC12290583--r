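#' Read a table of activation foci
#'
#' One row per reported activation peak. Required header columns:
#' `study_id`, `experiment_id`, `group`, `n`, `space`, `x`, `y`, `z`.
#' Tab- or comma-separated is detected from the header line. Row order is
#' preserved; rows in Talairach space keep `space == "Talairach"` as the
#' flag that [foci_to_mni()] will convert them.
#'
#' @param path Path to a TSV/CSV file.
#' @return A validated tibble of foci.
#' @seealso [validate_foci()], [foci_to_mni()]
#' @export
read_foci <- function(path) {
  if (!file.exists(path)) abort_metaclique(sprintf("No such foci file: %s", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  validate_foci(tbl)
}

#' Validate an in-memory foci table
#'
#' Checks the schema and the row-level invariants: finite coordinates,
#' positive integer subject counts, a single `n` per experiment, at least one
#' focus per experiment, known coordinate space, non-empty group label.
#'
#' @param tbl A data frame with the [read_foci()] columns.
#' @return The validated tibble (coordinates and `n` coerced to numeric).
#' @export
validate_foci <- function(tbl) {
  required <- c("study_id", "experiment_id", "group", "n", "space", "x", "y", "z")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort_metaclique(sprintf("Foci table is missing column(s): %s",
                             paste(missing_cols, collapse = ", ")),
                     class = "metaclique_schema_error")
  }
  tbl <- as_tibble(tbl)
  for (col in c("n", "x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort_metaclique(sprintf("Non-numeric or non-finite `%s` at row %d.", col, bad[1]),
                       class = "metaclique_validation_error")
    }
    tbl[[col]] <- v
  }
  bad_n <- which(tbl$n <= 0 | tbl$n != round(tbl$n))
  if (length(bad_n) > 0) {
    abort_metaclique(sprintf("`n` must be a positive integer; violated at row %d.", bad_n[1]),
                     class = "metaclique_validation_error")
  }
  bad_space <- which(!tbl$space %in% c("MNI", "Talairach"))
  if (length(bad_space) > 0) {
    abort_metaclique(sprintf("`space` must be MNI or Talairach; violated at row %d.", bad_space[1]),
                     class = "metaclique_validation_error")
  }
  bad_group <- which(is.na(tbl$group) | tbl$group == "")
  if (length(bad_group) > 0) {
    abort_metaclique(sprintf("`group` must be non-empty; violated at row %d.", bad_group[1]),
                     class = "metaclique_validation_error")
  }
  n_per_exp <- tapply(tbl$n, tbl$experiment_id, function(v) length(unique(v)))
  if (any(n_per_exp > 1)) {
    abort_metaclique(sprintf("Experiment '%s' has more than one subject count.",
                             names(n_per_exp)[which(n_per_exp > 1)[1]]),
                     class = "metaclique_validation_error")
  }
  tbl
}

#' Write a foci table as TSV
#' @param tbl A validated foci tibble.
#' @param path Output path.
#' @export
write_foci <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Convert Talairach coordinates to MNI space
#'
#' Applies the vendored Lancaster-style affine (see [tal2mni_affine()]);
#' deterministic matrix application, exactly invertible.
#'
#' @param coord_mm Length-3 vector or N x 3 matrix of Talairach mm coordinates.
#' @param variant Affine variant, `"pooled"` (default), `"spm"` or `"fsl"`.
#' @param affine Optional explicit 4x4 matrix overriding the vendored one.
#' @return Matrix (N x 3) of MNI mm coordinates.
#' @export
tal_to_mni <- function(coord_mm, variant = "pooled", affine = NULL) {
  m <- coerce_coords(coord_mm)
  a <- affine %||% tal2mni_affine(variant)
  stopifnot(identical(dim(a), c(4L, 4L)))
  out <- cbind(m, 1) %*% t(a)
  out[, 1:3, drop = FALSE]
}

#' Convert all Talairach rows of a foci table to MNI
#'
#' Rows flagged `space == "Talairach"` are transformed with [tal_to_mni()]
#' and re-flagged `MNI`; MNI rows pass through untouched. Order-preserving
#' and idempotent.
#'
#' @inheritParams tal_to_mni
#' @param tbl A validated foci tibble.
#' @return The tibble with all rows in MNI space.
#' @export
foci_to_mni <- function(tbl, variant = "pooled", affine = NULL) {
  tal <- tbl$space == "Talairach"
  if (any(tal)) {
    xyz <- tal_to_mni(as.matrix(tbl[tal, c("x", "y", "z")]), variant, affine)
    tbl$x[tal] <- xyz[, 1]
    tbl$y[tal] <- xyz[, 2]
    tbl$z[tal] <- xyz[, 3]
    tbl$space[tal] <- "MNI"
  }
  tbl
}

# split a foci table into per-experiment lists used by the ALE machinery
foci_experiments <- function(tbl) {
  tbl <- foci_to_mni(validate_foci(tbl))
  ids <- unique(tbl$experiment_id)
  lapply(ids, function(id) {
    rows <- tbl[tbl$experiment_id == id, ]
    list(
      experiment_id = id,
      group = rows$group[1],
      n_subjects = rows$n[1],
      foci_mm = as.matrix(rows[, c("x", "y", "z")])
    )
  })
}
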