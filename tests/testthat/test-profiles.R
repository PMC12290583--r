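pm_grid <- function() cached("pm_grid", make_grid(4, c(24, 24, 24)))

random_maps <- function(n, seed, grid = pm_grid()) {
  set.seed(seed)
  maps <- lapply(seq_len(n), function(i) volume_map(grid, rnorm(sum(grid$mask)), "correlation"))
  names(maps) <- sprintf("roi%02d", seq_len(n))
  maps
}

test_that("cross-correlation matrices are exact Pearson with the stated invariants", {
  g <- pm_grid()
  maps <- random_maps(4, seed = 30)
  pm <- crosscorr_matrix(maps, "macm")
  # self-correlation 1, negation -1
  expect_equal(unname(diag(pm$matrix)), rep(1, 4))
  neg <- maps
  neg$roi02 <- volume_map(g, -in_mask(maps$roi01), "correlation")
  pmn <- crosscorr_matrix(neg, "macm")
  expect_equal(pmn$matrix["roi01", "roi02"], -1)

  # brute-force pairwise Pearson oracle within 1e-12
  X <- vapply(maps, in_mask, numeric(sum(g$mask)))
  oracle <- matrix(1, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_lt(max(abs(unname(pm$matrix) - oracle)), 1e-12)

  # symmetry / unit diagonal / bounded / PSD within tolerance
  expect_lt(max(abs(pm$matrix - t(pm$matrix))), 1e-9)
  expect_true(all(pm$matrix >= -1 & pm$matrix <= 1))
  expect_gte(min(eigen(pm$matrix, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  const <- maps
  const$roi03 <- volume_map(g, 0.7, "correlation")
  expect_error(crosscorr_matrix(const, "macm"), "roi03")
})

test_that("the multimodal matrix is the element-wise mean with no silent reordering", {
  maps <- random_maps(4, seed = 31)
  a <- crosscorr_matrix(maps, "rsfc")
  b <- crosscorr_matrix(lapply(maps, function(m) volume_map(m$grid, in_mask(m) + rnorm(length(in_mask(m)), 0, 0.4), "correlation")), "macm")
  avg <- multimodal_average(a, b)
  expect_equal(avg$matrix, (a$matrix + b$matrix) / 2)
  expect_equal(avg$modality, "multimodal")
  expect_equal(multimodal_average(a, a)$matrix, a$matrix)
  expect_lt(max(abs(avg$matrix - t(avg$matrix))), 1e-12)
  b2 <- b; b2$roi_ids <- rev(b2$roi_ids)
  expect_error(multimodal_average(a, b2), "order")
})

block_profile_matrix <- function(k_blocks, per_block, within = 0.85, between = 0.05,
                                 jitter = 0.02, seed = 1) {
  set.seed(seed)
  M <- k_blocks * per_block
  lab <- rep(seq_len(k_blocks), each = per_block)
  C <- matrix(between, M, M) + matrix(rnorm(M * M, 0, jitter), M, M)
  C <- (C + t(C)) / 2
  for (b in seq_len(k_blocks)) C[lab == b, lab == b] <- within
  diag(C) <- 1
  metaclique:::new_profile_matrix(sprintf("roi%02d", 1:M), C, "multimodal")
}

test_that("Ward clustering merges duplicates first and recovers planted blocks", {
  # within = 1 makes the rows of a block exactly identical (unit diagonal
  # included), so the first merge is a duplicate pair at height zero
  pm_dup <- block_profile_matrix(2, 3, within = 1, jitter = 0)
  tree_dup <- cluster_profiles(pm_dup)
  expect_equal(tree_dup$hclust$height[1], 0, tolerance = 1e-12)

  pm <- block_profile_matrix(2, 3, jitter = 0)
  tree <- cluster_profiles(pm)
  # merge heights are monotone non-decreasing
  expect_true(all(diff(tree$hclust$height) >= -1e-12))
  # cutting at k = 2 recovers the blocks exactly
  labels <- cutree(tree$hclust, 2)
  expect_equal(length(unique(labels[1:3])), 1)
  expect_equal(length(unique(labels[4:6])), 1)
  expect_true(labels[1] != labels[4])
  expect_error(cluster_profiles(block_profile_matrix(1, 2)), ">= 3")
})

test_that("clustering is invariant to ROI input order up to relabeling", {
  pm <- block_profile_matrix(3, 3, jitter = 0.03, seed = 5)
  sol <- choose_k(cluster_profiles(pm))
  set.seed(6)
  perm <- sample(length(pm$roi_ids))
  pm2 <- metaclique:::new_profile_matrix(pm$roi_ids[perm],
                                         pm$matrix[perm, perm], "multimodal")
  sol2 <- choose_k(cluster_profiles(pm2))
  j <- dplyr::left_join(sol$assignment, sol2$assignment, by = "roi_id",
                        suffix = c("", "2"))
  expect_equal(ari(j$clique, j$clique2), 1)
})

test_that("cluster-count selection maximises silhouette and honours overrides", {
  pm3 <- block_profile_matrix(3, 3, jitter = 0.02, seed = 7)
  sol <- choose_k(cluster_profiles(pm3))
  expect_equal(sol$k, 3L)
  expect_named(sol$metrics, c("k", "silhouette", "calinski_harabasz"))

  # two duplicate-row groups -> silhouette exactly 1 at k = 2
  pm2 <- block_profile_matrix(2, 3, within = 1, jitter = 0)
  sol2 <- choose_k(cluster_profiles(pm2), k_range = 2:4)
  expect_equal(sol2$metrics$silhouette[sol2$metrics$k == 2], 1, tolerance = 1e-9)

  # override wins regardless of metrics
  sol4 <- choose_k(cluster_profiles(pm3), override_k = 4)
  expect_equal(sol4$k, 4L)
  expect_equal(length(unique(sol4$assignment$clique)), 4)
  expect_true(sol4$overridden)
  expect_error(choose_k(cluster_profiles(pm3), k_range = 10:12), "k_range")

  expect_equal(glance(sol)$k, 3L)
  expect_equal(nrow(tidy(sol)), 9)
})

test_that("clique mean maps are arithmetic means of member coactivation maps", {
  g <- pm_grid()
  maps <- random_maps(3, seed = 33)
  assign1 <- tibble::tibble(roi_id = names(maps), clique = c(1L, 1L, 2L))
  out <- clique_mean_map(assign1, maps)
  oracle <- (in_mask(maps[[1]]) + in_mask(maps[[2]])) / 2
  expect_equal(in_mask(out[["1"]]), oracle)
  # singleton clique passes through unchanged
  expect_equal(out[["2"]]$data, maps[[3]]$data)
  # two identical members -> the same map
  assign2 <- tibble::tibble(roi_id = names(maps)[1:2], clique = 1L)
  same <- clique_mean_map(assign2, list(roi01 = maps[[1]], roi02 = maps[[1]]))
  expect_equal(same[["1"]]$data, maps[[1]]$data)
  expect_error(clique_mean_map(assign1, maps[1:2]), "Missing")
})

test_that("decoding ranks by spatial r, thresholds, and de-duplicates synonyms", {
  g <- pm_grid()
  set.seed(34)
  v <- rnorm(sum(g$mask))
  clique <- volume_map(g, v, "correlation")
  terms <- list(
    self = volume_map(g, v, "correlation"),
    noisy = volume_map(g, v + rnorm(length(v), 0, 1.2), "correlation"),
    ortho = volume_map(g, rnorm(length(v)), "correlation")
  )
  tab <- decode_terms(clique, terms, r_threshold = 0.29)
  expect_equal(tab$term[1], "self")
  expect_equal(tab$r[1], 1.0)
  expect_false("ortho" %in% tab$term)  # |r| < 0.29 at V >= 1000

  # synonym group: only the highest-r member is reported
  tab2 <- decode_terms(clique, terms, r_threshold = 0.1,
                       synonym_groups = list(c("self", "noisy")))
  expect_true("self" %in% tab2$term)
  expect_false("noisy" %in% tab2$term)
  expect_error(decode_terms(clique, list()), "term")
})
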