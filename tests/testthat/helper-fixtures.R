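# Shared fixtures, all built in code. Heavy objects are computed lazily and
# cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small ellipsoid grid used throughout (3544 in-mask voxels)
tiny_grid <- function() {
  cached("tiny_grid",
         make_grid(4, 80, mask = list(type = "ellipsoid", semiaxes_mm = c(38, 38, 38))))
}

# 100-voxel full grid for exact/toy checks
toy_grid <- function() cached("toy_grid", make_grid(4, c(20, 20, 16)))

# a two-row valid foci table
two_row_foci <- function() {
  tibble::tibble(
    study_id = c("s1", "s2"), experiment_id = c("e1", "e2"),
    group = c("Grammatical", "Ungrammatical"), n = c(12, 20),
    space = "MNI", x = c(-18, 16), y = c(10, -14), z = c(8, 12)
  )
}

# a fully random ("null") corpus on the tiny grid; `n_vec` pins the
# per-experiment subject counts so replicate corpora share one composition
random_corpus <- function(seed, n_exp = 18, n_foci = 8, n_range = 10:30,
                          grid = tiny_grid(), n_vec = NULL) {
  set.seed(seed)
  mask_lin <- which(grid$mask)
  dplyr::bind_rows(lapply(seq_len(n_exp), function(e) {
    xyz <- voxel_to_world(
      metaclique:::linear_voxel(sample(mask_lin, n_foci, replace = TRUE), grid$shape),
      grid)
    tibble::tibble(study_id = sprintf("s%02d", e), experiment_id = sprintf("e%02d", e),
                   group = "Grammatical",
                   n = if (is.null(n_vec)) sample(n_range, 1) else n_vec[e],
                   space = "MNI",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
}

# the calibration fixture corpus and its per-experiment subject counts
calibration_fixture <- function() cached("calibration_fixture", random_corpus(seed = 1))

calibration_n_vec <- function() {
  fix <- calibration_fixture()
  dplyr::distinct(fix, experiment_id, n)$n
}

# uniform-foci database table (null coactivation structure)
uniform_db_foci <- function(grid, n_studies, foci_per_study, seed) {
  set.seed(seed)
  mask_lin <- which(grid$mask)
  dplyr::bind_rows(lapply(seq_len(n_studies), function(s) {
    xyz <- voxel_to_world(
      metaclique:::linear_voxel(sample(mask_lin, foci_per_study, TRUE), grid$shape), grid)
    tibble::tibble(study_id = sprintf("u%03d", s), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
}

# per-experiment MA arrays for a corpus (internal fast path)
corpus_ma_arrays <- function(foci_tbl, grid) {
  exps <- metaclique:::foci_experiments(foci_tbl)
  kc <- metaclique:::kernel_cache(grid)
  lapply(exps, function(e) {
    k <- kc(kernel_fwhm_from_n(e$n_subjects))
    metaclique:::ma_array_from_idx(world_to_voxel(e$foci_mm, grid), k, grid$shape)
  })
}

# Monte-Carlo extent null of the calibration fixture (shared by several tests)
calibration_extent <- function() {
  cached("calibration_extent", {
    cluster_extent_threshold(calibration_fixture(), tiny_grid(), voxel_p = 0.001,
                             n_iterations = 500, seed = 11)
  })
}

# planted-signal world corpus: 3 loci, 5-mm scatter, 5 noise foci, fixed n
planted_corpus <- function(seed) {
  w <- synth_world("tiny", seed = seed)
  gen_foci_corpus(w, n_experiments = 20, n_noise_foci = 5,
                  n_subjects_range = c(20, 20),
                  group_counts = c(Grammatical = 13, Ungrammatical = 7),
                  seed = seed)
}

# end-to-end paper-like pipeline run (clustering-focused stages), cached per seed
e2e_run <- function(seed, with_rsfc = TRUE) {
  cached(paste0("e2e_", seed, "_", with_rsfc), {
    cfg <- pipeline_config(
      out_dir = file.path(tempdir(), sprintf("metaclique_e2e_%d", seed)),
      seed = seed, simulate = "paper-like",
      iterations = list(ale = 100, subtraction = 100, macm = 0, rsfc = 0),
      simulate_args = list(
        db = list(n_studies = 200, n_null_terms = 1),
        runs = list(n_subjects = 4, n_runs = 2, n_timepoints = 100)
      ))
    suppressWarnings(run_pipeline(cfg, stages = if (with_rsfc) "rsfc" else character(0)))
  })
}

# ground-truth network of each recovered ROI: network of the nearest locus
roi_truth_networks <- function(run) {
  w <- run$world
  vapply(seq_len(nrow(run$rois)), function(i) {
    d <- sqrt((w$loci$x - run$rois$x[i])^2 + (w$loci$y - run$rois$y[i])^2 +
                (w$loci$z - run$rois$z[i])^2)
    w$loci$network[which.min(d)]
  }, integer(1))
}

# adjusted Rand index between two labelings (mclust when present)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  nij <- sum(choose(tab, 2)); ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2)); nn <- choose(sum(tab), 2)
  exp_idx <- ai * bj / nn
  (nij - exp_idx) / ((ai + bj) / 2 - exp_idx)
}
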