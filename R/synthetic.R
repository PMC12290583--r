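## Synthetic worlds with planted ground truth: convergent activation loci
## with Gaussian scatter plus uniform noise foci, term-specific focus
## distributions, and block-covariance rest series with a global component.

# pooled-ALE peak coordinates used by the "paper-like" preset (printed peak
# table of the source corpus; inputs, not re-derived results), partitioned
# into the three published cliques: 1 = language, 2 = salience, 3 =
# attention/cognitive control.
paperlike_loci <- function() {
  tibble::tribble(
    ~locus_id, ~x, ~y, ~z, ~network,
    "L_IFG_oper",   -44, 12, 20, 1L,
    "R_IFG_tri_a",   48, 26, 20, 1L,
    "R_IFG_tri_b",   50, 26,  4, 1L,
    "L_insula",     -34, 22, -2, 2L,
    "R_insula",      36, 22, -4, 2L,
    "R_mid_cing",     6, 26, 34, 2L,
    "L_SMA",          2, 22, 50, 2L,
    "R_precentral",  48,  4, 30, 3L,
    "R_mid_occ",     32, -66, 38, 3L,
    "R_IPL",         36, -50, 48, 3L
  )
}

#' Build a synthetic world with planted ground truth
#'
#' A world fixes the grid, the true convergent loci (with scatter sd), their
#' partition into ground-truth networks, the term plan (term -> generating
#' network), and the master seed. Presets:
#' \describe{
#'   \item{`tiny`}{3 loci / 3 networks on a small ellipsoid grid; fast
#'     end-to-end smoke runs.}
#'   \item{`paper-like`}{10 loci echoing the printed pooled peak table,
#'     partitioned into 3 networks; corpus defaults of 25 + 14 experiments
#'     in two groups.}
#' }
#'
#' @param preset `"tiny"` or `"paper-like"`.
#' @param seed Master RNG seed; every generator derives its stream from it.
#' @param scatter_sd_mm Gaussian scatter of locus foci (default 5 mm).
#' @return A `synth_world`.
#' @export
synth_world <- function(preset = c("tiny", "paper-like"), seed = 1,
                        scatter_sd_mm = 5) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    grid <- make_grid(4, 80, mask = list(type = "ellipsoid", semiaxes_mm = c(38, 38, 38)))
    loci <- tibble::tribble(
      ~locus_id, ~x, ~y, ~z, ~network,
      "A", -18, 10,  8, 1L,
      "B",  16, -14, 12, 2L,
      "C",   0, 18, -14, 3L
    )
    corpus_defaults <- list(n_experiments = 20L,
                            group_counts = c(Grammatical = 13L, Ungrammatical = 7L),
                            n_noise_foci = 5L, n_subjects_range = c(10L, 30L))
  } else {
    grid <- make_grid(4, c(144, 196, 156),
                      mask = list(type = "ellipsoid", semiaxes_mm = c(70, 95, 75),
                                  center_mm = c(0, -20, 10)))
    loci <- paperlike_loci()
    corpus_defaults <- list(n_experiments = 39L,
                            group_counts = c(Grammatical = 25L, Ungrammatical = 14L),
                            n_noise_foci = 5L, n_subjects_range = c(7L, 61L))
  }
  loci$scatter_sd <- scatter_sd_mm
  # loci must be in-mask
  lin <- voxel_linear(world_to_voxel(as.matrix(loci[, c("x", "y", "z")]), grid), grid$shape)
  if (!all(grid$mask[lin])) {
    abort_metaclique("A planted locus lies outside the mask.")
  }
  term_plan <- tibble(
    term = paste0("term_net", sort(unique(loci$network))),
    network = sort(unique(loci$network))
  )
  structure(
    list(preset = preset, grid = grid, loci = loci,
         networks = sort(unique(loci$network)), term_plan = term_plan,
         corpus_defaults = corpus_defaults, seed = seed),
    class = "synth_world"
  )
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world '%s'> %d loci in %d networks on %s; seed %s\n",
              x$preset, nrow(x$loci), length(x$networks), format(x$grid),
              format(x$seed)))
  invisible(x)
}

# truncated-Gaussian draw around a centre: rejection sampling to the mask
draw_near_locus <- function(center, sd_mm, grid, max_attempts = 1000) {
  for (a in seq_len(max_attempts)) {
    p <- center + rnorm(3, 0, sd_mm)
    idx <- tryCatch(world_to_voxel(p, grid), error = function(e) NULL)
    if (!is.null(idx) && grid$mask[voxel_linear(idx, grid$shape)]) return(p)
  }
  abort_metaclique("Could not place a focus inside the mask after 1000 attempts.")
}

uniform_mask_mm <- function(n, grid, mask_lin = which(grid$mask)) {
  voxel_to_world(linear_voxel(sample(mask_lin, n, replace = TRUE), grid$shape), grid)
}

#' Generate a foci corpus with planted convergence
#'
#' Per experiment: one focus per planted locus, drawn from an isotropic
#' Gaussian (the world's scatter sd) truncated to the mask, plus
#' `n_noise_foci` uniform in-mask foci. Subject counts are uniform over
#' `n_subjects_range`; group labels follow `group_counts`.
#'
#' @param world A [synth_world()].
#' @param n_experiments Number of experiments (default from the preset).
#' @param foci_per_locus Foci drawn per locus per experiment (default 1).
#' @param n_noise_foci Uniform noise foci per experiment.
#' @param n_subjects_range Length-2 integer range.
#' @param group_counts Named integer vector of experiments per group label;
#'   must sum to `n_experiments`.
#' @param seed RNG seed (default: derived from the world's seed).
#' @return A validated foci tibble ([read_foci()] schema, MNI space).
#' @export
gen_foci_corpus <- function(world, n_experiments = NULL, foci_per_locus = 1,
                            n_noise_foci = NULL, n_subjects_range = NULL,
                            group_counts = NULL, seed = NULL) {
  cd <- world$corpus_defaults
  n_experiments <- n_experiments %||% cd$n_experiments
  n_noise_foci <- n_noise_foci %||% cd$n_noise_foci
  n_subjects_range <- n_subjects_range %||% cd$n_subjects_range
  group_counts <- group_counts %||% cd$group_counts
  if (sum(group_counts) != n_experiments) {
    abort_metaclique("`group_counts` must sum to `n_experiments`.")
  }
  set.seed(derive_seed(seed %||% world$seed, "foci-corpus"))
  grid <- world$grid
  mask_lin <- which(grid$mask)
  groups <- rep(names(group_counts), group_counts)
  rows <- lapply(seq_len(n_experiments), function(e) {
    n_subj <- sample(seq(n_subjects_range[1], n_subjects_range[2]), 1)
    locus_foci <- do.call(rbind, lapply(seq_len(nrow(world$loci)), function(li) {
      ctr <- as.numeric(world$loci[li, c("x", "y", "z")])
      do.call(rbind, lapply(seq_len(foci_per_locus), function(j) {
        if (world$loci$scatter_sd[li] == 0) ctr
        else draw_near_locus(ctr, world$loci$scatter_sd[li], grid)
      }))
    }))
    noise <- if (n_noise_foci > 0) uniform_mask_mm(n_noise_foci, grid, mask_lin) else NULL
    xyz <- rbind(locus_foci, noise)
    tibble(study_id = sprintf("study%02d", e),
           experiment_id = sprintf("exp%02d", e),
           group = groups[e], n = n_subj, space = "MNI",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  validate_foci(bind_rows(rows))
}

#' Generate a term-annotated coordinate database
#'
#' Each annotated study carries one term; a fraction `term_signal_fraction`
#' of its foci is placed near the loci of that term's generating network
#' (Gaussian scatter), the rest uniform in-mask. Unannotated studies are
#' fully uniform.
#'
#' @param world A [synth_world()].
#' @param n_studies Total number of studies.
#' @param term_signal_fraction Scalar in \[0, 1\], or a named vector per
#'   term (names must match the world's term plan).
#' @param foci_per_study Foci per study (default 8).
#' @param annotated_fraction Fraction of studies that carry a term
#'   (default 0.75, split evenly over the terms).
#' @param n_null_terms Number of additional terms with no spatial signal
#'   (their studies' foci are fully uniform); named `term_null1`, ... and
#'   included in the annotation split.
#' @param seed RNG seed (default from the world).
#' @return A [coordinate_db()].
#' @export
gen_coordinate_db <- function(world, n_studies = 200, term_signal_fraction = 0.8,
                              foci_per_study = 8, annotated_fraction = 0.75,
                              n_null_terms = 0, seed = NULL) {
  set.seed(derive_seed(seed %||% world$seed, "coordinate-db"))
  terms <- world$term_plan$term
  if (length(term_signal_fraction) > 1 || !is.null(names(term_signal_fraction))) {
    unknown <- setdiff(names(term_signal_fraction), terms)
    if (length(unknown) > 0) {
      abort_metaclique(sprintf("Term '%s' has no generating network in the plan.", unknown[1]))
    }
    frac <- term_signal_fraction
  } else {
    frac <- setNames(rep(term_signal_fraction, length(terms)), terms)
  }
  if (n_null_terms > 0) {
    frac <- c(frac, setNames(rep(0, n_null_terms), paste0("term_null", seq_len(n_null_terms))))
  }
  n_annotated <- round(annotated_fraction * n_studies)
  per_term <- diff(round(seq(0, n_annotated, length.out = length(frac) + 1)))
  study_terms <- c(rep(names(frac), per_term),
                   rep(NA_character_, n_studies - n_annotated))
  grid <- world$grid
  mask_lin <- which(grid$mask)
  foci_rows <- list()
  ann_rows <- list()
  for (s in seq_len(n_studies)) {
    sid <- sprintf("db%04d", s)
    term <- study_terms[s]
    if (!is.na(term)) {
      n_signal <- round(frac[[term]] * foci_per_study)
      sig <- if (n_signal > 0) {
        net <- world$term_plan$network[world$term_plan$term == term]
        net_loci <- world$loci[world$loci$network == net, , drop = FALSE]
        do.call(rbind, lapply(seq_len(n_signal), function(j) {
          li <- ((j - 1) %% nrow(net_loci)) + 1
          ctr <- as.numeric(net_loci[li, c("x", "y", "z")])
          if (net_loci$scatter_sd[li] == 0) ctr
          else draw_near_locus(ctr, net_loci$scatter_sd[li], grid)
        }))
      } else NULL
      unif <- if (foci_per_study - n_signal > 0) {
        uniform_mask_mm(foci_per_study - n_signal, grid, mask_lin)
      } else NULL
      xyz <- rbind(sig, unif)
      ann_rows[[length(ann_rows) + 1]] <- tibble(study_id = sid, term = term)
    } else {
      xyz <- uniform_mask_mm(foci_per_study, grid, mask_lin)
    }
    foci_rows[[length(foci_rows) + 1]] <-
      tibble(study_id = sid, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  coordinate_db(bind_rows(foci_rows), bind_rows(ann_rows))
}

# assignment of in-mask voxels to networks: voxels within `radius_mm` of a
# locus belong to the nearest locus's network; 0 = unassigned background
voxel_networks <- function(world, radius_mm = 12) {
  grid <- world$grid
  cents <- mask_centers(grid)
  loci_xyz <- as.matrix(world$loci[, c("x", "y", "z")])
  d2 <- vapply(seq_len(nrow(loci_xyz)), function(li) {
    (cents[, 1] - loci_xyz[li, 1])^2 + (cents[, 2] - loci_xyz[li, 2])^2 +
      (cents[, 3] - loci_xyz[li, 3])^2
  }, numeric(nrow(cents)))
  nearest <- max.col(-d2)
  net <- world$loci$network[nearest]
  net[d2[cbind(seq_len(nrow(cents)), nearest)] > radius_mm^2] <- 0L
  as.integer(net)
}

#' Generate block-covariance resting-state runs
#'
#' Per time point, a voxel's value is
#' `global_amp * g(t) + sqrt(block_rho) * b_k(t) + noise_sd * e(t)`, where
#' `g` is a global latent shared by all voxels, `b_k` the unit-variance
#' latent of the voxel's network (voxels within `block_radius_mm` of a
#' planted locus), and `e` white noise. With the default
#' `noise_sd = sqrt(1 - block_rho)` the expected within-network correlation
#' (ignoring the global component) is `block_rho`. Background voxels carry
#' only global signal and noise.
#'
#' @param world A [synth_world()].
#' @param n_subjects,n_runs,n_timepoints Acquisition layout
#'   (`n_timepoints >= 50`).
#' @param block_rho Within-network correlation target in \[0, 1).
#' @param global_amp Amplitude of the global component.
#' @param noise_sd White-noise sd (default `sqrt(1 - block_rho)`).
#' @param block_radius_mm Network membership radius around loci (default 12).
#' @param tr_seconds Repetition time (default 1 s).
#' @param seed RNG seed (default from the world).
#' @return List of [rest_run()]s with a `voxel_networks` attribute.
#' @export
gen_rest_runs <- function(world, n_subjects = 5, n_runs = 2, n_timepoints = 150,
                          block_rho = 0.5, global_amp = 0.5,
                          noise_sd = sqrt(1 - block_rho), block_radius_mm = 12,
                          tr_seconds = 1, seed = NULL) {
  if (block_rho < 0 || block_rho >= 1) abort_metaclique("`block_rho` must be in [0, 1).")
  if (n_timepoints < 50) abort_metaclique("`n_timepoints` must be >= 50.")
  set.seed(derive_seed(seed %||% world$seed, "rest-runs"))
  grid <- world$grid
  nets <- voxel_networks(world, block_radius_mm)
  V <- length(nets)
  runs <- list()
  for (subj in seq_len(n_subjects)) {
    for (r in seq_len(n_runs)) {
      g <- rnorm(n_timepoints)
      B <- matrix(rnorm(n_timepoints * length(world$networks)), n_timepoints)
      E <- matrix(rnorm(n_timepoints * V, sd = max(noise_sd, 1e-12)), n_timepoints)
      S <- global_amp * matrix(g, n_timepoints, V) + E
      for (k in world$networks) {
        cols <- which(nets == k)
        if (length(cols) > 0) {
          S[, cols] <- S[, cols] + sqrt(block_rho) * B[, which(world$networks == k)]
        }
      }
      runs[[length(runs) + 1]] <- rest_run(
        S, grid, tr_seconds,
        subject_id = sprintf("sub%02d", subj), run_id = sprintf("run%02d", r))
    }
  }
  attr(runs, "voxel_networks") <- nets
  runs
}

#' Emit a world's inputs to disk
#'
#' Writes the exact file formats the pipeline consumes — foci TSV, database
#' TSVs, per-run 4D NIfTI with a manifest TSV — plus a ground-truth JSON
#' (loci, network assignments, term plan, seed). Deterministic per
#' (world, seed): identical calls produce byte-identical files.
#'
#' @param world A [synth_world()].
#' @param dir Output directory.
#' @param corpus,db,runs Optional pre-generated objects (generated from the
#'   world's defaults when omitted).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, corpus = NULL, db = NULL, runs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- corpus %||% gen_foci_corpus(world)
  db <- db %||% gen_coordinate_db(world)
  runs <- runs %||% gen_rest_runs(world)
  write_foci(corpus, file.path(dir, "foci.tsv"))
  write_coordinate_db(db, dir)
  manifest <- bind_rows(lapply(runs, function(r) {
    fn <- sprintf("%s_%s.nii.gz", r$subject_id, r$run_id)
    write_rest_run(r, file.path(dir, fn))
    tibble(subject_id = r$subject_id, run_id = r$run_id, file = fn,
           tr_seconds = r$tr_seconds)
  }))
  readr::write_tsv(manifest, file.path(dir, "rest_manifest.tsv"), progress = FALSE)
  truth <- list(preset = world$preset, seed = world$seed,
                loci = world$loci, term_plan = world$term_plan)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
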