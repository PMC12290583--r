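# a small full-mask grid and handcrafted runs keep these checks exact
rsfc_grid <- function() cached("rsfc_grid", make_grid(4, c(24, 24, 16)))

test_that("seed time courses are unweighted voxel means", {
  g <- rsfc_grid()
  V <- sum(g$mask)
  set.seed(20)
  S <- matrix(rnorm(40 * V), 40)
  run <- rest_run(S, g)
  roi1 <- sphere_roi(voxel_to_world(c(0L, 0L, 0L), g), g, radius_mm = 1)
  expect_equal(length(roi1$voxels), 1)
  col <- match(roi1$voxels, which(g$mask))
  expect_equal(seed_timecourse(run, roi1), S[, col])

  # two voxels with series s and -s average to zero
  roi2 <- sphere_roi(voxel_to_world(c(0L, 0L, 0L), g), g, radius_mm = 4.1)
  cols <- match(roi2$voxels, which(g$mask))
  S2 <- S
  S2[, cols[2]] <- -S2[, cols[1]]
  S2[, cols[-(1:2)]] <- 0
  run2 <- rest_run(S2, g)
  expect_equal(seed_timecourse(run2, sphere_roi(voxel_to_world(c(0L, 0L, 0L), g), g, 4.1)),
               rowMeans(S2[, cols]))

  # brute-force mean oracle on a bigger ROI
  roi3 <- sphere_roi(c(0, 0, 0), g, radius_mm = 8)
  cols3 <- match(roi3$voxels, which(g$mask))
  expect_equal(seed_timecourse(run, roi3), apply(S[, cols3], 1, mean))
})

test_that("run-level connectivity: perfect coupling, nuisance absorption, noise bound", {
  g <- rsfc_grid()
  V <- sum(g$mask)
  set.seed(21)
  s <- rnorm(200)
  S <- matrix(0, 200, V)
  S[, 1] <- s          # the seed voxel
  S[, 2] <- s          # perfectly coupled voxel
  S[, 3] <- -2 * s     # keeps the global signal exactly zero...
  S[, 4] <- rnorm(200) # independent noise
  S[, 5] <- -S[, 4]
  roi <- sphere_roi(voxel_to_world(c(0L, 0L, 0L), g), g, radius_mm = 1)
  stopifnot(match(roi$voxels, which(g$mask)) == 1)
  run <- rest_run(S, g)
  expect_equal(max(abs(rowMeans(S))), 0)  # global signal is zero by construction
  m <- seed_connectivity(run, roi, smoothing_fwhm = 0)
  vals <- in_mask(m)
  expect_equal(vals[2], 1.0)
  expect_equal(vals[3], -1.0)
  expect_lt(abs(vals[4]), 0.2)  # sampling bound at 200 time points

  # a voxel equal to the global signal is absorbed by the nuisance regressor
  set.seed(22)
  gsig <- rnorm(200)
  S2 <- matrix(rep(gsig, V), 200, V)   # every voxel = global
  S2[, 1] <- s + gsig                  # seed rides on top
  S2[, 2] <- gsig                      # pure global voxel
  run2 <- rest_run(S2, g)
  m2 <- seed_connectivity(run2, roi, smoothing_fwhm = 0)
  # absorbed up to the seed's own 1/V leakage into the global mean
  expect_lt(abs(in_mask(m2)[2]), 0.05)

  # degenerate inputs error
  S3 <- S; S3[, 1] <- 1
  expect_error(seed_connectivity(rest_run(S3, g), roi, 0), "constant")
})

test_that("scale invariance: rescaling all series leaves correlation-scale maps unchanged", {
  g <- rsfc_grid()
  set.seed(23)
  S <- matrix(rnorm(60 * sum(g$mask)), 60)
  roi <- sphere_roi(c(0, 0, 0), g, 5)
  m1 <- seed_connectivity(rest_run(S, g), roi, smoothing_fwhm = 0)
  m2 <- seed_connectivity(rest_run(S * 37.5, g), roi, smoothing_fwhm = 0)
  expect_lt(max(abs(m1$data - m2$data)), 1e-9)
})

test_that("fixed-effects combination is the voxel-wise mean of runs", {
  g <- rsfc_grid()
  set.seed(24)
  mk <- function(v) volume_map(g, v, "correlation")
  a <- mk(runif(sum(g$mask), -1, 1))
  expect_equal(fixed_effects_combine(list(a))$data, a$data)
  b <- mk(-in_mask(a))
  expect_equal(max(abs(fixed_effects_combine(list(a, b))$data)), 0)
  maps <- lapply(1:4, function(i) mk(runif(sum(g$mask), -1, 1)))
  avg <- fixed_effects_combine(maps)
  oracle <- Reduce(`+`, lapply(maps, in_mask)) / 4
  expect_equal(in_mask(avg), oracle)
  g2 <- make_grid(4, 16)
  expect_error(fixed_effects_combine(list(a, mk <- volume_map(g2, 0, "correlation"))),
               "different grids")
})

test_that("group maps: mean identity, textbook t, sign-flip determinism", {
  g <- rsfc_grid()
  set.seed(25)
  base <- runif(sum(g$mask), -0.5, 0.5)
  same <- lapply(1:4, function(i) volume_map(g, base, "correlation"))
  grp <- group_connectivity(same, n_iterations = 0)
  expect_equal(in_mask(grp$mean_map), base)

  subj <- lapply(1:5, function(i) volume_map(g, rnorm(sum(g$mask), 0.2, 0.5), "correlation"))
  grp2 <- group_connectivity(subj, n_iterations = 100, seed = 3)
  M <- vapply(subj, in_mask, numeric(sum(g$mask)))
  v <- 10  # an arbitrary voxel against stats::t.test
  expect_equal(in_mask(grp2$t_map)[v], unname(t.test(M[v, ])$statistic))
  grp3 <- group_connectivity(subj, n_iterations = 100, seed = 3)
  expect_equal(grp2$threshold_t, grp3$threshold_t)
  expect_error(group_connectivity(subj[1:2]), ">= 3")
})

test_that("under null subjects the sign-flip threshold controls false positives", {
  g <- cached("rsfc_null_grid", make_grid(4, c(16, 16, 16)))
  V <- sum(g$mask)
  frac <- vapply(1:50, function(r) {
    set.seed(900 + r)
    subj <- lapply(1:6, function(i) volume_map(g, rnorm(V, 0, 0.3), "correlation"))
    grp <- group_connectivity(subj, voxel_p = 0.001, n_iterations = 200, seed = 900 + r)
    mean(in_mask(grp$thresholded) != 0)
  }, 1.0)
  expect_lte(mean(frac), 0.001)
})
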