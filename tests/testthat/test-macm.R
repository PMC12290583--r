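test_that("study selection follows the closed-ball rule and a brute-force oracle", {
  w <- synth_world("tiny", seed = 6)
  grid <- w$grid
  db <- gen_coordinate_db(w, n_studies = 60, seed = 6)
  roi <- sphere_roi(c(-18, 10, 8), grid, radius_mm = 6, roi_id = "roiA")

  sel <- select_studies(db, roi)
  # oracle: all-pairs distance scan
  oracle <- sort(unique(db$foci$study_id[
    sqrt((db$foci$x - roi$center_mm[1])^2 + (db$foci$y - roi$center_mm[2])^2 +
         (db$foci$z - roi$center_mm[3])^2) <= 6]))
  expect_equal(sel, oracle)

  # focus exactly at the centre -> selected; nearest focus 7 mm away -> not
  db2 <- coordinate_db(tibble::tibble(
    study_id = c("hit", "miss"), x = c(-18, -18 + 7), y = c(10, 10), z = c(8, 8)))
  expect_equal(select_studies(db2, roi), "hit")

  # monotone in radius
  small <- select_studies(db, sphere_roi(c(-18, 10, 8), grid, 4))
  large <- select_studies(db, sphere_roi(c(-18, 10, 8), grid, 10))
  expect_true(all(small %in% sel))
  expect_true(all(sel %in% large))

  expect_error(select_studies(coordinate_db(tibble::tibble(
    study_id = character(), x = numeric(), y = numeric(), z = numeric())), roi),
    "empty")
})

test_that("coactivation of identical foci follows the closed-form union of kernels", {
  g <- toy_grid()
  S <- 4
  db <- coordinate_db(tibble::tibble(
    study_id = sprintf("s%d", 1:S), x = 0, y = 0, z = 0))
  roi <- sphere_roi(c(0, 0, 0), g, 6, roi_id = "r1")
  res <- macm_map(db, roi, g, fwhm_mm = 15, n_iterations = 0)
  k0 <- ale_kernel(15, g)$peak
  ctr <- metaclique:::voxel_linear(world_to_voxel(c(0, 0, 0), g), g$shape)
  expect_equal(res$unthresholded$data[ctr], 1 - (1 - k0)^S, tolerance = 1e-12)
  expect_equal(length(res$selected_study_ids), S)
})

test_that("the coactivation map is invariant to study order and seed-deterministic", {
  w <- synth_world("tiny", seed = 14)
  db <- gen_coordinate_db(w, n_studies = 40, seed = 14)
  roi <- sphere_roi(c(-18, 10, 8), w$grid, 6, roi_id = "r1")
  r1 <- macm_map(db, roi, w$grid, n_iterations = 100, seed = 7)
  r2 <- macm_map(db, roi, w$grid, n_iterations = 100, seed = 7)
  expect_equal(r1$threshold_ale, r2$threshold_ale)
  expect_equal(r1$thresholded$data, r2$thresholded$data)
  # reversed database rows -> same unthresholded map
  db_rev <- coordinate_db(db$foci[rev(seq_len(nrow(db$foci))), ], db$annotations)
  r3 <- macm_map(db_rev, roi, w$grid, n_iterations = 0)
  expect_equal(r3$unthresholded$data, r1$unthresholded$data)
  # an ROI selecting no studies warns and returns a degenerate result
  far <- sphere_roi(c(34, 2, 2), w$grid, 4, roi_id = "far")
  db_one <- coordinate_db(tibble::tibble(study_id = "s", x = -30, y = 0, z = 0))
  expect_warning(deg <- macm_map(db_one, far, w$grid, n_iterations = 0), "no studies")
  expect_true(deg$degenerate)
})

test_that("with a null database the thresholded coactivation map is almost always empty", {
  w <- synth_world("tiny", seed = 15)
  set.seed(15)
  mask_lin <- which(w$grid$mask)
  hits <- vapply(1:10, function(r) {
    xyz <- uniform_db_foci(w$grid, 30, 6, seed = 600 + r)
    db <- coordinate_db(xyz)
    roi <- sphere_roi(c(-18, 10, 8), w$grid, 10, roi_id = "r")
    res <- suppressWarnings(macm_map(db, roi, w$grid, n_iterations = 100, seed = 700 + r))
    if (is.null(res$thresholded)) return(FALSE)
    any(in_mask(res$thresholded) > 0)
  }, TRUE)
  expect_lte(mean(hits), 0.05 + 0.2)  # >= 95% empty, small-sample slack
})

test_that("term maps localise planted terms and oppose disjoint study sets", {
  w <- synth_world("tiny", seed = 16)
  grid <- w$grid
  db <- gen_coordinate_db(w, n_studies = 90, term_signal_fraction = 1,
                          annotated_fraction = 1, seed = 16)
  tm <- term_map(db, "term_net1", grid)
  loc <- as.numeric(w$loci[w$loci$network == 1, c("x", "y", "z")])
  pk <- which.max(tm$data)
  mm <- voxel_to_world(metaclique:::linear_voxel(pk, grid$shape), grid)
  expect_lt(sqrt(sum((mm - loc)^2)), 8)

  # disjoint term study sets produce negatively correlated maps
  t2 <- term_map(db, "term_net2", grid)
  expect_lt(cor(in_mask(tm), in_mask(t2)), 0)

  # a term annotating every study has a zero complement, messaged
  db_all <- coordinate_db(db$foci,
                          tibble::tibble(study_id = unique(db$foci$study_id),
                                         term = "everything"))
  expect_message(tall <- term_map(db_all, "everything", grid), "complement")
  with_ale <- macm_map(db_all, sphere_roi(c(0, 0, 0), grid, 500, roi_id = "all"),
                       grid, n_iterations = 0)
  expect_equal(tall$data, with_ale$unthresholded$data)

  expect_error(term_map(db, "nonexistent", grid), "no studies")
})
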