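## Connectivity-profile matrices, multimodal averaging, Ward clustering into
## cliques, cluster-count selection, and term-based functional decoding.

#' ROI x ROI cross-correlation matrix of connectivity maps
#'
#' Vectorises the in-mask values of each unthresholded map (V x M) and
#' Pearson-correlates every pair of maps. Symmetric with a unit diagonal.
#'
#' @param maps Named list of `volume_map`s (names = ROI ids), or a V x M
#'   numeric matrix with column names.
#' @param modality One of `"rsfc"`, `"macm"`, `"multimodal"`.
#' @param grid Needed only when `maps` is a plain matrix with no grid.
#' @return A `profile_matrix`: `roi_ids`, `matrix`, `modality`.
#' @export
crosscorr_matrix <- function(maps, modality = c("rsfc", "macm", "multimodal"),
                             grid = NULL) {
  modality <- match.arg(modality)
  if (is.list(maps)) {
    if (length(maps) < 2) abort_metaclique("Need >= 2 maps.")
    grid <- maps[[1]]$grid
    for (m in maps) {
      if (!grids_equal(grid, m$grid)) abort_metaclique("Maps are on different grids.")
    }
    X <- vapply(maps, in_mask, numeric(sum(grid$mask)))
    colnames(X) <- names(maps) %||% paste0("roi", seq_along(maps))
  } else {
    X <- as.matrix(maps)
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort_metaclique(sprintf("Map '%s' is constant in-mask; cannot correlate.",
                             colnames(X)[which(sds == 0)[1]]))
  }
  C <- cor(X)
  diag(C) <- 1
  new_profile_matrix(colnames(X), C, modality)
}

new_profile_matrix <- function(roi_ids, C, modality) {
  dimnames(C) <- list(roi_ids, roi_ids)
  structure(list(roi_ids = roi_ids, matrix = C, modality = modality),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix: %s> %d ROIs\n", x$modality, length(x$roi_ids)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @export
as_tibble.profile_matrix <- function(x, ...) {
  as_tibble(x$matrix, rownames = "roi_id")
}

#' Element-wise average of the rsFC and MACM profile matrices
#'
#' @param matrix_rsfc,matrix_macm `profile_matrix` objects with identical
#'   ROI ids in identical order (no silent reordering).
#' @return A `profile_matrix` with modality `"multimodal"`.
#' @export
multimodal_average <- function(matrix_rsfc, matrix_macm) {
  if (!identical(matrix_rsfc$roi_ids, matrix_macm$roi_ids)) {
    abort_metaclique("ROI ids/order differ between the two matrices; refusing to reorder silently.")
  }
  new_profile_matrix(matrix_rsfc$roi_ids,
                     (matrix_rsfc$matrix + matrix_macm$matrix) / 2,
                     "multimodal")
}

# column-standardised feature matrix (rows = ROI profiles)
standardized_features <- function(pm) {
  F <- pm$matrix
  sds <- apply(F, 2, sd)
  drop <- sds == 0
  if (any(drop)) {
    rlang::warn(sprintf("Dropping %d zero-variance feature column(s): %s",
                        sum(drop), paste(colnames(F)[drop], collapse = ", ")))
    F <- F[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  sweep(F, 2, sds, "/")
}

#' Ward hierarchical clustering of connectivity profiles
#'
#' Each ROI's feature vector is its row of the profile matrix (the
#' multimodal averaged matrix for the final solution). Columns are
#' standardised to unit variance ("standardised Euclidean"), pairwise
#' Euclidean distances are formed, and Ward's minimum-variance linkage
#' agglomerates the ROIs. Merge heights are non-decreasing.
#'
#' @param profile_matrix A [crosscorr_matrix()] / [multimodal_average()]
#'   result with >= 3 ROIs.
#' @return A `clique_tree`: the `hclust` object, the standardised `features`,
#'   and the source `profile_matrix`.
#' @export
cluster_profiles <- function(profile_matrix) {
  M <- length(profile_matrix$roi_ids)
  if (M < 3) abort_metaclique("Clustering needs >= 3 ROIs.")
  F <- standardized_features(profile_matrix)
  d <- dist(F, method = "euclidean")
  hc <- hclust(d, method = "ward.D2")
  structure(list(hclust = hc, features = F, profile_matrix = profile_matrix),
            class = "clique_tree")
}

#' @export
print.clique_tree <- function(x, ...) {
  cat(sprintf("<clique_tree> Ward linkage over %d ROIs; merge heights %s\n",
              length(x$profile_matrix$roi_ids),
              paste(round(x$hclust$height, 3), collapse = ", ")))
  invisible(x)
}

# mean silhouette width of a partition given a dist object
mean_silhouette <- function(d, labels) {
  if (requireNamespace("cluster", quietly = TRUE)) {
    return(mean(cluster::silhouette(labels, d)[, "sil_width"]))
  }
  dm <- as.matrix(d)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(dm[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(dm[i, labels == k]), 1))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

calinski_harabasz <- function(F, labels) {
  n <- nrow(F)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(F)
  bss <- 0
  wss <- 0
  for (g in unique(labels)) {
    rows <- F[labels == g, , drop = FALSE]
    ctr <- colMeans(rows)
    bss <- bss + nrow(rows) * sum((ctr - grand)^2)
    wss <- wss + sum(sweep(rows, 2, ctr)^2)
  }
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}

#' Choose the number of cliques
#'
#' Cuts the Ward tree at each `k` in `k_range`, scores each partition by
#' mean silhouette width and the Calinski-Harabasz index on the
#' standardised features, and selects the `k` maximising the silhouette
#' (first on ties). The metric table and dendrogram are always retained so a
#' human can inspect and override (`override_k`).
#'
#' @param tree A [cluster_profiles()] result.
#' @param k_range Candidate cluster counts (default `2:(M-1)`).
#' @param override_k If given, this `k` is used regardless of the metrics.
#' @return A `clique_solution`: `tree`, `k`, `assignment` tibble
#'   (`roi_id`, `clique`), `metrics` tibble (`k`, `silhouette`,
#'   `calinski_harabasz`), `overridden` flag.
#' @export
choose_k <- function(tree, k_range = NULL, override_k = NULL) {
  M <- nrow(tree$features)
  k_range <- k_range %||% seq(2, max(2, M - 1))
  k_range <- k_range[k_range >= 2 & k_range <= M - 1]
  if (length(k_range) == 0) abort_metaclique("`k_range` must contain values in [2, M-1].")
  d <- dist(tree$features)
  metrics <- bind_rows(lapply(k_range, function(k) {
    labels <- cutree(tree$hclust, k = k)
    tibble(k = k, silhouette = mean_silhouette(d, labels),
           calinski_harabasz = calinski_harabasz(tree$features, labels))
  }))
  k <- override_k %||% metrics$k[which.max(metrics$silhouette)]
  labels <- cutree(tree$hclust, k = k)
  structure(
    list(tree = tree, k = as.integer(k),
         assignment = tibble(roi_id = names(labels) %||% tree$profile_matrix$roi_ids,
                             clique = as.integer(labels)),
         metrics = metrics, overridden = !is.null(override_k)),
    class = "clique_solution"
  )
}

#' @export
print.clique_solution <- function(x, ...) {
  cat(sprintf("<clique_solution> k = %d%s\n", x$k,
              if (x$overridden) " (override)" else " (max silhouette)"))
  print(x$assignment, n = Inf)
  invisible(x)
}

#' @export
tidy.clique_solution <- function(x, ...) x$assignment

#' @export
glance.clique_solution <- function(x, ...) {
  row <- x$metrics[x$metrics$k == x$k, ]
  tibble(k = x$k, silhouette = row$silhouette,
         calinski_harabasz = row$calinski_harabasz,
         n_rois = nrow(x$assignment), overridden = x$overridden)
}

#' Per-clique mean coactivation map
#'
#' Voxel-wise mean of the member ROIs' unthresholded MACM maps — the input
#' map for functional decoding.
#'
#' @param solution A [choose_k()] solution (or an assignment tibble).
#' @param macm_maps Named list `roi_id -> volume_map` (unthresholded).
#' @return Named list `clique id -> volume_map`.
#' @export
clique_mean_map <- function(solution, macm_maps) {
  assignment <- if (inherits(solution, "clique_solution")) solution$assignment else solution
  missing_maps <- setdiff(assignment$roi_id, names(macm_maps))
  if (length(missing_maps) > 0) {
    abort_metaclique(sprintf("Missing MACM map for ROI(s): %s",
                             paste(missing_maps, collapse = ", ")))
  }
  grid <- macm_maps[[1]]$grid
  out <- list()
  for (cl in sort(unique(assignment$clique))) {
    members <- assignment$roi_id[assignment$clique == cl]
    avg <- Reduce(`+`, lapply(macm_maps[members], function(m) m$data)) / length(members)
    out[[as.character(cl)]] <- volume_map(grid, avg, kind = macm_maps[[members[1]]]$kind)
  }
  out
}

#' Functional decoding of a clique map against term maps
#'
#' Pearson spatial correlation of the clique's mean coactivation map with
#' every term-association map over the in-mask voxels; terms are ranked by
#' descending correlation, kept at `r > r_threshold`, and de-duplicated
#' within user-supplied synonym groups (only the highest-r member of a group
#' is reported).
#'
#' @param clique_map `volume_map` (mean unthresholded MACM of the clique).
#' @param term_maps Named list `term -> volume_map`.
#' @param r_threshold Correlation threshold (default 0.29).
#' @param synonym_groups Optional list of character vectors of synonymous
#'   terms.
#' @return A tibble: `term`, `r`, descending; all rows satisfy
#'   `r > r_threshold`.
#' @export
decode_terms <- function(clique_map, term_maps, r_threshold = 0.29,
                         synonym_groups = NULL) {
  if (length(term_maps) == 0) abort_metaclique("No term maps supplied.")
  v <- in_mask(clique_map)
  rs <- vapply(term_maps, function(tm) {
    tv <- in_mask(tm)
    if (sd(tv) == 0 || sd(v) == 0) return(0)
    cor(v, tv)
  }, 1.0)
  out <- tibble(term = names(term_maps), r = unname(rs)) %>%
    arrange(desc(.data$r)) %>%
    filter(.data$r > r_threshold)
  if (!is.null(synonym_groups)) {
    for (grp in synonym_groups) {
      members <- which(out$term %in% grp)
      if (length(members) > 1) out <- out[-members[-1], , drop = FALSE]
    }
  }
  out
}

#' Rank all terms for every clique
#'
#' @param clique_maps Named list from [clique_mean_map()].
#' @inheritParams decode_terms
#' @return A tibble: `clique`, `term`, `r`.
#' @export
decode_cliques <- function(clique_maps, term_maps, r_threshold = 0.29,
                           synonym_groups = NULL) {
  bind_rows(lapply(names(clique_maps), function(cl) {
    decode_terms(clique_maps[[cl]], term_maps, r_threshold, synonym_groups) %>%
      mutate(clique = as.integer(cl)) %>%
      select("clique", "term", "r")
  }))
}

#' Export a linkage tree in Newick format
#'
#' @param tree A [cluster_profiles()] result.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort_metaclique("Newick export needs the 'ape' package.")
  }
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
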