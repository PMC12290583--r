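test_that("degenerate scatter places locus foci exactly at the true centres", {
  w <- synth_world("tiny", seed = 40, scatter_sd_mm = 0)
  corpus <- gen_foci_corpus(w, n_experiments = 4, n_noise_foci = 0,
                            group_counts = c(Grammatical = 4))
  expect_equal(nrow(corpus), 4 * nrow(w$loci))
  per_exp <- split(corpus, corpus$experiment_id)
  for (e in per_exp) {
    expect_equal(unname(as.matrix(e[, c("x", "y", "z")]))[order(e$x), ],
                 unname(as.matrix(w$loci[order(w$loci$x), c("x", "y", "z")])))
  }
})

test_that("one locus, no noise gives exactly one focus per experiment", {
  w <- synth_world("tiny", seed = 41)
  w1 <- w
  w1$loci <- w$loci[1, ]
  corpus <- gen_foci_corpus(w1, n_experiments = 6, n_noise_foci = 0,
                            group_counts = c(Grammatical = 6))
  expect_equal(unname(table(corpus$experiment_id)), rep(1L, 6), ignore_attr = TRUE)
})

test_that("locus-focus scatter is unbiased: the mean approaches the true centre", {
  w <- synth_world("tiny", seed = 42)
  w1 <- w
  w1$loci <- w$loci[1, ]  # centre (-18, 10, 8), sd 5 mm
  corpus <- gen_foci_corpus(w1, n_experiments = 200, n_noise_foci = 0,
                            group_counts = c(Grammatical = 200))
  ctr <- colMeans(corpus[, c("x", "y", "z")])
  expect_lt(sqrt(sum((ctr - c(-18, 10, 8))^2)), 1.5)
})

test_that("generated corpora pass validation and are seed-reproducible", {
  w <- synth_world("paper-like", seed = 43)
  c1 <- gen_foci_corpus(w)
  c2 <- gen_foci_corpus(w)
  expect_identical(c1, c2)
  expect_silent(validate_foci(c1))
  # foci land in-mask
  lin <- metaclique:::voxel_linear(world_to_voxel(as.matrix(c1[, c("x", "y", "z")]), w$grid),
                                   w$grid$shape)
  expect_true(all(w$grid$mask[lin]))
})

test_that("database generation allocates terms and signal fractions as planned", {
  w <- synth_world("tiny", seed = 44)
  db <- gen_coordinate_db(w, n_studies = 40, annotated_fraction = 0.75, seed = 44)
  expect_equal(length(unique(db$foci$study_id)), 40)
  expect_equal(length(unique(db$annotations$study_id)), 30)  # 75% annotated
  counts <- table(db$annotations$term)
  expect_equal(unname(counts), rep(10L, 3), ignore_attr = TRUE)

  # fraction 1 with zero scatter puts all annotated foci at network loci
  w0 <- synth_world("tiny", seed = 45, scatter_sd_mm = 0)
  db0 <- gen_coordinate_db(w0, n_studies = 6, term_signal_fraction = 1,
                           annotated_fraction = 1, foci_per_study = 4, seed = 45)
  loci_xyz <- as.matrix(w0$loci[, c("x", "y", "z")])
  for (i in seq_len(nrow(db0$foci))) {
    d <- sqrt(rowSums(sweep(loci_xyz, 2, as.numeric(db0$foci[i, c("x", "y", "z")]))^2))
    expect_equal(min(d), 0)
  }

  # null terms generate annotated but spatially flat studies
  dbn <- gen_coordinate_db(w, n_studies = 40, n_null_terms = 1, seed = 46)
  expect_true("term_null1" %in% dbn$annotations$term)
  expect_error(gen_coordinate_db(w, term_signal_fraction = c(bogus_term = 1)),
               "no generating network")
})

test_that("rest runs realise the stated block-covariance model", {
  w <- synth_world("tiny", seed = 47)
  # noiseless, no global: two voxels of one block correlate at 1
  runs0 <- gen_rest_runs(w, n_subjects = 1, n_runs = 1, n_timepoints = 80,
                         block_rho = 0.5, global_amp = 0, noise_sd = 0)
  nets <- attr(runs0, "voxel_networks")
  b1 <- which(nets == 1)
  expect_equal(cor(runs0[[1]]$series[, b1[1]], runs0[[1]]$series[, b1[2]]), 1)

  # block_rho = 0: cross-voxel correlations are small at 200 time points
  runs_null <- gen_rest_runs(w, n_subjects = 1, n_runs = 1, n_timepoints = 200,
                             block_rho = 0, global_amp = 0)
  s <- runs_null[[1]]$series
  expect_lt(abs(cor(s[, b1[1]], s[, b1[2]])), 0.2)

  # empirical within-block correlation near the target at default noise
  runs <- gen_rest_runs(w, n_subjects = 1, n_runs = 1, n_timepoints = 200,
                        block_rho = 0.5, global_amp = 0)
  cors <- cor(runs[[1]]$series[, b1[seq_len(min(12, length(b1)))]])
  expect_equal(mean(cors[upper.tri(cors)]), 0.5, tolerance = 0.1)

  expect_error(gen_rest_runs(w, block_rho = 1.2), "block_rho")
  expect_error(gen_rest_runs(w, n_timepoints = 20), ">= 50")
})

test_that("worlds emit byte-identical files for identical (preset, seed)", {
  w <- synth_world("tiny", seed = 48)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  small <- list(corpus = gen_foci_corpus(w, n_experiments = 4,
                                         group_counts = c(Grammatical = 4)),
                db = gen_coordinate_db(w, n_studies = 10),
                runs = gen_rest_runs(w, n_subjects = 1, n_runs = 1, n_timepoints = 50))
  write_world(w, d1, corpus = small$corpus, db = small$db, runs = small$runs)
  write_world(w, d2, corpus = small$corpus, db = small$db, runs = small$runs)
  for (f in c("foci.tsv", "db_foci.tsv", "db_annotations.tsv", "ground_truth.json",
              "rest_manifest.tsv", "sub01_run01.nii.gz")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # unknown preset errors, listing the presets
  expect_error(synth_world("huge"), "tiny")
})
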