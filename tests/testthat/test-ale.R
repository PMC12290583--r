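test_that("modeled activation takes the per-voxel maximum over focus kernels", {
  g <- toy_grid()
  k <- ale_kernel(kernel_fwhm_from_n(20), g)
  # single focus at a voxel centre -> MA at that voxel equals the kernel peak
  ma <- modeled_activation(c(0, 0, 0), 20, g)
  ctr <- metaclique:::voxel_linear(world_to_voxel(c(0, 0, 0), g), g$shape)
  expect_equal(ma$data[ctr], k$peak)

  # coincident foci are idempotent under the max rule
  ma2 <- modeled_activation(rbind(c(0, 0, 0), c(0, 0, 0)), 20, g)
  expect_equal(ma2$data, ma$data)

  expect_error(modeled_activation(matrix(numeric(0), ncol = 3), 20, g), "zero foci")
})

test_that("well-separated foci match a brute-force per-voxel max oracle", {
  g <- make_grid(4, c(120, 40, 40))
  # 100 mm apart, snapped to the voxel-centre lattice (the placement convention)
  foci <- voxel_to_world(world_to_voxel(rbind(c(-50, 0, 0), c(50, 0, 0)), g), g)
  fwhm <- 10
  k <- ale_kernel(fwhm, g)
  ma <- modeled_activation(foci, grid = g, kernel = k)
  # peaks equal the single-focus peak; midpoint ~ 0
  for (f in 1:2) {
    lin <- metaclique:::voxel_linear(world_to_voxel(foci[f, ], g), g$shape)
    expect_equal(ma$data[lin], k$peak)
  }
  mid <- metaclique:::voxel_linear(world_to_voxel(c(0, 0, 0), g), g$shape)
  expect_lt(ma$data[mid], 1e-10)

  # brute force: for every voxel, max over Gaussian kernels at true distances
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cents <- metaclique:::voxel_centers(g$shape, g$voxel_mm, g$origin_mm)
  vals <- matrix(0, nrow(cents), 2)
  for (f in 1:2) {
    d2 <- rowSums(sweep(cents, 2, foci[f, ])^2)
    v <- prod(g$voxel_mm) * (2 * pi * sigma^2)^(-3 / 2) * exp(-d2 / (2 * sigma^2))
    v[v < 1e-8 * max(v)] <- 0  # kernel truncation
    vals[, f] <- v
  }
  oracle <- pmax(vals[, 1], vals[, 2])
  expect_lt(max(abs(as.vector(ma$data) - oracle)), 1e-12)
})

test_that("the ALE union is the probabilistic union with its invariants", {
  g <- toy_grid()
  # {0.2, 0.5} -> 0.6
  m1 <- volume_map(g, 0.2, "MA"); m2 <- volume_map(g, 0.5, "MA")
  u <- ale_union(list(m1, m2))
  expect_equal(in_mask(u), rep(0.6, sum(g$mask)))

  # all-zero maps give a zero union
  z <- volume_map(g, 0, "MA")
  expect_equal(max(in_mask(ale_union(list(z, z)))), 0)

  # random maps: per-voxel brute-force product loop within 1e-12,
  # ALE >= every individual MA, and a zero map changes nothing
  set.seed(4)
  maps <- lapply(1:5, function(i) volume_map(g, runif(sum(g$mask), 0, 0.6), "MA"))
  u5 <- ale_union(maps)
  vm <- vapply(maps, in_mask, numeric(sum(g$mask)))
  oracle <- apply(vm, 1, function(r) 1 - prod(1 - r))
  expect_lt(max(abs(in_mask(u5) - oracle)), 1e-12)
  expect_true(all(in_mask(u5) >= apply(vm, 1, max) - 1e-15))
  expect_true(all(in_mask(u5) >= 0 & in_mask(u5) <= 1))
  expect_equal(in_mask(ale_union(c(maps, list(z)))), in_mask(u5), tolerance = 1e-14)

  g2 <- make_grid(2, 20)
  expect_error(ale_union(list(m1, volume_map(g2, 0.1, "MA"))), "different grids")
})

test_that("the analytic null matches the single-experiment histogram and normalises", {
  g <- toy_grid()
  ma <- modeled_activation(c(0, 0, 0), 25, g)
  nl <- ale_null(list(ma), g)
  expect_equal(sum(nl$pmf), 1, tolerance = 1e-9)
  # single experiment: tail probabilities equal the empirical MA histogram tail
  v <- in_mask(ma)
  for (q in quantile(v[v > 0], c(0.3, 0.7, 0.95))) {
    expect_equal(metaclique:::null_pvalue(q, nl), mean(v >= q), tolerance = 2e-3)
  }
})

test_that("voxel p-values have the right degenerate and median behaviour", {
  g <- toy_grid()
  ma1 <- modeled_activation(c(0, 0, 0), 25, g)
  ma2 <- modeled_activation(c(4, 0, 0), 12, g)
  nl <- ale_null(list(ma1, ma2), g)
  # observed 0 -> p = 1
  expect_equal(metaclique:::null_pvalue(0, nl), 1)
  # observed at the null median -> p ~ 0.5
  v1 <- in_mask(ma1); v2 <- in_mask(ma2)
  set.seed(8)
  draws <- 1 - (1 - sample(v1, 5e4, TRUE)) * (1 - sample(v2, 5e4, TRUE))
  med <- median(draws)
  # ~0.5 up to the atom mass at the median of this discrete toy distribution
  expect_equal(metaclique:::null_pvalue(med, nl), mean(draws >= med), tolerance = 0.02)
  expect_gte(metaclique:::null_pvalue(med, nl), 0.45)
  # observed above the support gets the smallest positive tail mass, flagged
  expect_message(p_over <- metaclique:::null_pvalue(0.999, nl), "above the null support")
  expect_gt(p_over, 0)
  expect_lt(p_over, 1e-3)
  # z transform is the upper-tail quantile
  amap <- ale_union(list(ma1, ma2))
  pz <- ale_pvalues(amap, nl)
  msk <- in_mask(pz$p) < 1
  expect_equal(in_mask(pz$z)[msk], qnorm(in_mask(pz$p)[msk], lower.tail = FALSE))
})

test_that("the critical ALE value reproduces the p-value threshold exactly", {
  g <- toy_grid()
  ma1 <- modeled_activation(c(0, 0, 0), 25, g)
  ma2 <- modeled_activation(c(4, 0, 0), 12, g)
  nl <- ale_null(list(ma1, ma2), g)
  for (alpha in c(0.01, 0.001)) {
    crit <- ale_critical(nl, alpha)
    eps <- 1e-9
    expect_lt(metaclique:::null_pvalue(crit + eps, nl), alpha)
    expect_gte(metaclique:::null_pvalue(crit - 1e-5, nl), alpha)
  }
})

test_that("under random foci the voxel p-values are uniform", {
  # marginal uniformity: one sampled voxel per independent null corpus, so
  # the KS iid assumption holds; a fine bin width keeps the conservative
  # (k-1)-bin lookup offset below the test's resolution at k = 18
  grid <- tiny_grid()
  fix <- calibration_fixture()
  nv <- calibration_n_vec()
  null_fine <- ale_null(corpus_ma_arrays(fix, grid), grid, bin_width = 1e-6)
  set.seed(21)
  ps <- vapply(1:400, function(r) {
    ma <- corpus_ma_arrays(random_corpus(seed = 5000 + r, n_vec = nv), grid)
    ale <- metaclique:::ale_from_arrays(ma)
    sample(metaclique:::null_pvalue(ale[grid$mask], null_fine), 1)
  }, 1.0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the extent threshold is deterministic given the seed and keeps records", {
  g <- tiny_grid()
  corpus <- random_corpus(seed = 50, n_exp = 3, n_foci = 3)
  ext1 <- cluster_extent_threshold(corpus, g, n_iterations = 100, seed = 5)
  ext2 <- cluster_extent_threshold(corpus, g, n_iterations = 100, seed = 5)
  expect_equal(length(ext1$max_sizes), 100)
  expect_identical(ext1$extent_threshold_voxels, ext2$extent_threshold_voxels)
  expect_identical(ext1$max_sizes, ext2$max_sizes)
  expect_error(cluster_extent_threshold(corpus, g, n_iterations = 100), "seed")
  expect_error(cluster_extent_threshold(corpus, g, n_iterations = 10, seed = 1), ">= 100")
})

test_that("a full ALE run is deterministic and its clusters respect the thresholds", {
  corpus <- planted_corpus(seed = 77)
  grid <- tiny_grid()
  res <- run_ale(corpus, grid, n_iterations = 100, seed = 42)
  res2 <- run_ale(corpus, grid, n_iterations = 100, seed = 42)
  expect_equal(res$clusters$ale_max, res2$clusters$ale_max)
  expect_equal(res$extent_threshold_voxels, res2$extent_threshold_voxels)
  expect_true(all(res$clusters$n_voxels >= res$extent_threshold_voxels))
  expect_true(all(in_mask(res$ale) >= 0 & in_mask(res$ale) <= 1))
  # cluster voxel sets are disjoint
  all_vox <- unlist(res$clusters$voxels)
  expect_equal(length(all_vox), length(unique(all_vox)))
  # tidy/glance surfaces
  expect_named(tidy(res), c("cluster", "x", "y", "z", "volume_mm3", "ale_max", "n_voxels"))
  expect_equal(glance(res)$n_experiments, 20)
})
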