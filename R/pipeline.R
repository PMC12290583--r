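## End-to-end orchestration: one config drives simulate/load -> ALE ->
## contrasts -> ROIs -> MACM + rsFC -> profile matrices -> cliques ->
## decoding, with logged thresholds, artifacts, and a manifest.

#' Pipeline configuration
#'
#' Collects every numeric threshold and path the pipeline uses. Defaults
#' mirror the full-scale analysis (voxel p < 0.001, cluster FWE 0.05,
#' 100-voxel subtraction extent, MACM voxel FWE p < 0.001, decoding
#' r > 0.29, 6-mm ROI spheres with 20-mm separation, 10,000 iterations);
#' desk-scale runs lower the iteration counts. The config round-trips
#' through YAML unchanged.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed for every stochastic stage.
#' @param simulate `NULL`, `"tiny"` or `"paper-like"`: generate inputs from
#'   a [synth_world()] instead of reading files.
#' @param paths Named list: `foci`, `db_foci`, `db_annotations`,
#'   `rest_manifest` (ignored when simulating).
#' @param grid Named list: `voxel_mm`, `extent_mm`, `mask` (ignored when
#'   simulating; the world supplies the grid).
#' @param thresholds Named list: `voxel_p`, `fwe`, `subtraction_extent`,
#'   `macm_fwe_p`, `rsfc_voxel_p`, `decode_r`.
#' @param iterations Named list: `ale`, `subtraction`, `macm`, `rsfc`.
#' @param roi Named list: `radius_mm`, `separation_mm`.
#' @param clustering Named list: `k_range`, `override_k`.
#' @param rsfc Named list: `smoothing_fwhm`.
#' @param simulate_args Extra arguments forwarded to the generators.
#' @return A `pipeline_config` (a named list).
#' @export
pipeline_config <- function(out_dir = tempfile("metaclique_run_"), seed = 1,
                            simulate = NULL, paths = list(), grid = list(),
                            thresholds = list(), iterations = list(),
                            roi = list(), clustering = list(), rsfc = list(),
                            simulate_args = list()) {
  cfg <- list(
    out_dir = out_dir, seed = seed, simulate = simulate, paths = paths,
    grid = modifyList(list(voxel_mm = 4, extent_mm = 80, mask = "full"), grid),
    thresholds = modifyList(list(voxel_p = 0.001, fwe = 0.05,
                                 subtraction_extent = 100, macm_fwe_p = 0.001,
                                 rsfc_voxel_p = 0.001, decode_r = 0.29),
                            thresholds),
    iterations = modifyList(list(ale = 10000, subtraction = 10000,
                                 macm = 10000, rsfc = 1000), iterations),
    roi = modifyList(list(radius_mm = 6, separation_mm = 20), roi),
    clustering = modifyList(list(k_range = NULL, override_k = NULL), clustering),
    rsfc = modifyList(list(smoothing_fwhm = 6), rsfc),
    simulate_args = simulate_args
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$voxel_p > 0, th$voxel_p < 1, th$fwe > 0, th$fwe < 1,
            th$subtraction_extent >= 0, th$macm_fwe_p > 0, th$macm_fwe_p < 1,
            th$decode_r >= -1, th$decode_r <= 1)
  it <- cfg$iterations
  stopifnot(it$ale >= 100, it$subtraction >= 100)
  invisible(cfg)
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(run_dir, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  cat(line, "\n", file = file.path(run_dir, "run_log.txt"), append = TRUE, sep = "")
  invisible(line)
}

#' Run the full pipeline
#'
#' Executes the stages in order: pooled and per-group ALE meta-analyses,
#' conjunction and permutation subtraction, seed-ROI extraction, per-ROI
#' MACM and rsFC, per-modality and multimodal profile matrices, clique
#' clustering, and functional decoding. Every intermediate artifact is
#' written under `config$out_dir` together with a checksum manifest and a
#' plain-text log; re-running with the same config and seed reproduces all
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param stages Which stages to run, as subcommand names; the default runs
#'   everything. `"contrast"` (conjunction + subtraction) and `"rsfc"` can be
#'   dropped for clustering-focused runs; the core chain
#'   ale -> rois -> macm -> profile -> cluster -> decode always runs.
#' @return A `pipeline_run` (all stage results plus `run_dir`), invisibly.
#' @export
run_pipeline <- function(config, stages = c("contrast", "rsfc")) {
  stopifnot(inherits(config, "pipeline_config"))
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(stage, err) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(err)),
               file.path(run_dir, "FAILED"))
    abort_metaclique(sprintf("Pipeline stage '%s' failed: %s", stage,
                             conditionMessage(err)))
  }
  stage <- function(name, expr) {
    log_line(run_dir, name, "start")
    tryCatch(expr, error = function(e) on_fail(name, e))
  }
  th <- config$thresholds
  it <- config$iterations
  seed <- config$seed

  # -- inputs ----------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      world <- do.call(synth_world, c(list(preset = config$simulate, seed = seed),
                                      config$simulate_args$world %||% list()))
      corpus <- do.call(gen_foci_corpus,
                        c(list(world = world), config$simulate_args$corpus %||% list()))
      db <- do.call(gen_coordinate_db,
                    c(list(world = world), config$simulate_args$db %||% list()))
      runs <- do.call(gen_rest_runs,
                      c(list(world = world), config$simulate_args$runs %||% list()))
      dir.create(file.path(run_dir, "inputs"), showWarnings = FALSE)
      write_foci(corpus, file.path(run_dir, "inputs", "foci.tsv"))
      write_coordinate_db(db, file.path(run_dir, "inputs"))
      list(world = world, grid = world$grid, corpus = corpus, db = db, runs = runs)
    } else {
      grid <- make_grid(config$grid$voxel_mm, config$grid$extent_mm, config$grid$mask)
      corpus <- read_foci(config$paths$foci)
      db <- read_coordinate_db(config$paths$db_foci, config$paths$db_annotations)
      runs <- NULL
      if (!is.null(config$paths$rest_manifest)) {
        man <- readr::read_tsv(config$paths$rest_manifest, show_col_types = FALSE)
        base <- dirname(config$paths$rest_manifest)
        runs <- lapply(seq_len(nrow(man)), function(i) {
          read_rest_run(file.path(base, man$file[i]), grid,
                        tr_seconds = man$tr_seconds[i] %||% 1,
                        subject_id = man$subject_id[i], run_id = man$run_id[i])
        })
      }
      list(world = NULL, grid = grid, corpus = corpus, db = db, runs = runs)
    }
  })
  grid <- inputs$grid
  corpus <- inputs$corpus

  # -- pooled + per-group ALE ------------------------------------------------
  log_line(run_dir, "ale", sprintf("voxel_p=%g fwe=%g iterations=%d",
                                   th$voxel_p, th$fwe, it$ale))
  ale_dir <- file.path(run_dir, "ale")
  dir.create(ale_dir, showWarnings = FALSE)
  pooled <- stage("ale", {
    res <- run_ale(corpus, grid, voxel_p = th$voxel_p, fwe = th$fwe,
                   n_iterations = it$ale, seed = derive_seed(seed, "ale-pooled"))
    write_volume(res$ale, file.path(ale_dir, "pooled_ale.nii.gz"))
    write_volume(res$z, file.path(ale_dir, "pooled_z.nii.gz"))
    write_volume(res$thresholded, file.path(ale_dir, "pooled_thresholded.nii.gz"))
    res
  })
  groups <- if ("contrast" %in% stages) unique(corpus$group) else character(0)
  group_results <- stage("ale_groups", {
    out <- list()
    for (g in groups) {
      sub <- corpus[corpus$group == g, ]
      if (length(unique(sub$experiment_id)) >= 2) {
        out[[g]] <- run_ale(sub, grid, voxel_p = th$voxel_p, fwe = th$fwe,
                            n_iterations = it$ale,
                            seed = derive_seed(seed, paste0("ale-", g)))
        write_volume(out[[g]]$thresholded,
                     file.path(ale_dir, sprintf("%s_thresholded.nii.gz", tolower(g))))
      }
    }
    out
  })

  # -- conjunction & subtraction --------------------------------------------
  contrast <- stage("contrast", {
    conj <- NULL
    subt <- NULL
    if ("contrast" %in% stages && length(group_results) >= 2) {
      ga <- group_results[[1]]; gb <- group_results[[2]]
      conj <- ale_conjunction(ga$thresholded, gb$thresholded, ga$ale, gb$ale)
      dir.create(file.path(run_dir, "contrast"), showWarnings = FALSE)
      write_volume(conj, file.path(run_dir, "contrast", "conjunction.nii.gz"))
      log_line(run_dir, "contrast", sprintf("subtraction extent=%d iterations=%d",
                                            th$subtraction_extent, it$subtraction))
      subt <- ale_subtraction(corpus[corpus$group == names(group_results)[1], ],
                              corpus[corpus$group == names(group_results)[2], ],
                              grid, n_iterations = it$subtraction,
                              seed = derive_seed(seed, "subtraction"),
                              fwe = th$fwe, extent_voxels = th$subtraction_extent)
      if (!is.null(subt)) {
        write_volume(subt$difference, file.path(run_dir, "contrast", "subtraction_diff.nii.gz"))
        write_volume(subt$thresholded, file.path(run_dir, "contrast", "subtraction_thresholded.nii.gz"))
      }
    }
    list(conjunction = conj, subtraction = subt)
  })

  # -- seed ROIs -------------------------------------------------------------
  rois <- stage("rois", {
    tbl <- build_seed_rois(pooled, radius_mm = config$roi$radius_mm,
                           min_separation_mm = config$roi$separation_mm)
    if (nrow(tbl) == 0) abort_metaclique("No seed ROIs survive thresholding/pruning.")
    write_rois(tbl, grid, file.path(run_dir, "rois"))
    tbl
  })

  # -- MACM ------------------------------------------------------------------
  log_line(run_dir, "macm", sprintf("fwe_p=%g iterations=%d", th$macm_fwe_p, it$macm))
  macm <- stage("macm", {
    dir.create(file.path(run_dir, "macm"), showWarnings = FALSE)
    out <- list()
    for (i in seq_len(nrow(rois))) {
      r <- rois$roi[[i]]
      res <- macm_map(inputs$db, r, grid, n_iterations = it$macm,
                      seed = derive_seed(seed, paste0("macm-", r$roi_id)),
                      voxel_fwe_p = th$macm_fwe_p)
      write_volume(res$unthresholded,
                   file.path(run_dir, "macm", sprintf("%s_unthresholded.nii.gz", r$roi_id)))
      readr::write_tsv(tibble(study_id = res$selected_study_ids),
                       file.path(run_dir, "macm", sprintf("%s_selected.tsv", r$roi_id)),
                       progress = FALSE)
      out[[r$roi_id]] <- res
    }
    out
  })

  # -- rsFC ------------------------------------------------------------------
  rsfc_maps <- NULL
  if ("rsfc" %in% stages && !is.null(inputs$runs)) {
    log_line(run_dir, "rsfc", sprintf("smoothing=%gmm voxel_p=%g iterations=%d",
                                      config$rsfc$smoothing_fwhm, th$rsfc_voxel_p, it$rsfc))
    rsfc_maps <- stage("rsfc", {
      dir.create(file.path(run_dir, "rsfc"), showWarnings = FALSE)
      cache <- list()
      for (r in inputs$runs) {
        cache[[paste(r$subject_id, r$run_id)]] <-
          smooth_run_series(r, config$rsfc$smoothing_fwhm)
      }
      out <- list()
      for (i in seq_len(nrow(rois))) {
        r <- rois$roi[[i]]
        gc_res <- rsfc_roi(inputs$runs, r,
                           smoothing_fwhm = config$rsfc$smoothing_fwhm,
                           voxel_p = th$rsfc_voxel_p, n_iterations = it$rsfc,
                           seed = derive_seed(seed, paste0("rsfc-", r$roi_id)),
                           smoothed_cache = cache)
        write_volume(gc_res$mean_map,
                     file.path(run_dir, "rsfc", sprintf("%s_group.nii.gz", r$roi_id)))
        out[[r$roi_id]] <- gc_res
      }
      out
    })
  }

  # -- profile matrices ------------------------------------------------------
  profiles <- stage("profiles", {
    dir.create(file.path(run_dir, "profiles"), showWarnings = FALSE)
    macm_unthr <- lapply(macm, function(m) m$unthresholded)
    pm_macm <- crosscorr_matrix(macm_unthr, modality = "macm")
    write_profile_matrix(pm_macm, file.path(run_dir, "profiles", "macm_matrix.tsv"))
    pm_rsfc <- NULL
    pm_multi <- pm_macm
    if (!is.null(rsfc_maps)) {
      pm_rsfc <- crosscorr_matrix(lapply(rsfc_maps, function(m) m$mean_map),
                                  modality = "rsfc")
      write_profile_matrix(pm_rsfc, file.path(run_dir, "profiles", "rsfc_matrix.tsv"))
      pm_multi <- multimodal_average(pm_rsfc, pm_macm)
    }
    write_profile_matrix(pm_multi, file.path(run_dir, "profiles", "multimodal_matrix.tsv"))
    list(macm = pm_macm, rsfc = pm_rsfc, multimodal = pm_multi)
  })

  # -- clustering ------------------------------------------------------------
  cliques <- stage("cluster", {
    tree <- cluster_profiles(profiles$multimodal)
    sol <- choose_k(tree, k_range = config$clustering$k_range,
                    override_k = config$clustering$override_k)
    dir.create(file.path(run_dir, "cliques"), showWarnings = FALSE)
    readr::write_tsv(sol$assignment, file.path(run_dir, "cliques", "assignment.tsv"),
                     progress = FALSE)
    readr::write_tsv(sol$metrics, file.path(run_dir, "cliques", "metrics.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(merge = unclass(tree$hclust$merge), height = tree$hclust$height,
           labels = tree$hclust$labels),
      file.path(run_dir, "cliques", "linkage.json"), auto_unbox = FALSE, digits = NA)
    if (requireNamespace("ape", quietly = TRUE)) {
      write_newick(tree, file.path(run_dir, "cliques", "dendrogram.nwk"))
    }
    sol
  })

  # -- decoding --------------------------------------------------------------
  decoding <- stage("decode", {
    terms <- unique(inputs$db$annotations$term)
    if (length(terms) == 0) return(tibble())
    term_maps <- lapply(setNames(terms, terms),
                        function(tm) term_map(inputs$db, tm, grid))
    cmaps <- clique_mean_map(cliques, lapply(macm, function(m) m$unthresholded))
    tbl <- decode_cliques(cmaps, term_maps, r_threshold = th$decode_r)
    dir.create(file.path(run_dir, "decode"), showWarnings = FALSE)
    readr::write_tsv(tbl, file.path(run_dir, "decode", "decoding.tsv"), progress = FALSE)
    tbl
  })

  run <- structure(
    list(config = config, run_dir = run_dir, grid = grid, world = inputs$world,
         corpus = corpus, db = inputs$db,
         pooled = pooled, groups = group_results,
         conjunction = contrast$conjunction, subtraction = contrast$subtraction,
         rois = rois, macm = macm, rsfc = rsfc_maps, profiles = profiles,
         cliques = cliques, decoding = decoding),
    class = "pipeline_run"
  )
  stage("report", write_report(run))
  stage("manifest", write_manifest(run))
  log_line(run_dir, "done", "all stages complete")
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$run_dir, "\n")
  cat(sprintf("  %d experiments -> %d pooled clusters -> %d ROIs -> k = %d cliques\n",
              x$pooled$n_experiments, nrow(x$pooled$clusters), nrow(x$rois),
              x$cliques$k))
  invisible(x)
}

write_profile_matrix <- function(pm, path) {
  readr::write_tsv(as_tibble(pm), path, progress = FALSE)
  invisible(path)
}

#' Write the human-readable report of a completed run
#'
#' Emits the pooled cluster table in the peak-table layout
#' (`cluster`, `x`, `y`, `z`, `volume_mm3`, `ale_max`, `label`), the ROI
#' table, the clique assignment with metrics, and the decoding table.
#'
#' @param run A `pipeline_run`.
#' @return The run directory, invisibly.
#' @export
write_report <- function(run) {
  missing_parts <- c("pooled", "rois", "cliques")[
    vapply(c("pooled", "rois", "cliques"), function(f) is.null(run[[f]]), TRUE)]
  if (length(missing_parts) > 0) {
    abort_metaclique(sprintf("Run is incomplete; missing: %s",
                             paste(missing_parts, collapse = ", ")))
  }
  dir <- file.path(run$run_dir, "report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctab <- tidy(run$pooled) %>%
    mutate(label = vapply(seq_len(dplyr::n()), function(i) {
      label_roi(c(.data$x[i], .data$y[i], .data$z[i]), NULL)
    }, "")) %>%
    select("cluster", "x", "y", "z", "volume_mm3", "ale_max", "label")
  readr::write_tsv(ctab, file.path(dir, "cluster_table.tsv"), progress = FALSE)
  readr::write_tsv(select(run$rois, -"roi"), file.path(dir, "roi_table.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$cliques$assignment, file.path(dir, "clique_assignment.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$cliques$metrics, file.path(dir, "clique_metrics.tsv"),
                   progress = FALSE)
  if (is.data.frame(run$decoding)) {
    readr::write_tsv(run$decoding, file.path(dir, "decoding_table.tsv"), progress = FALSE)
  }
  if (!is.null(run$subtraction)) {
    readr::write_tsv(run$subtraction$clusters,
                     file.path(dir, "subtraction_clusters.tsv"), progress = FALSE)
  }
  invisible(run$run_dir)
}

write_manifest <- function(run) {
  files <- list.files(run$run_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|run_log\\.txt$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    seed = run$config$seed,
    thresholds = run$config$thresholds,
    iterations = run$config$iterations,
    package_version = as.character(utils::packageVersion("metaclique")),
    files = tibble(file = sub(paste0("^", run$run_dir, "/?"), "", files),
                   md5 = unname(sums))
  )
  jsonlite::write_json(manifest, file.path(run$run_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
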