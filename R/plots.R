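## ggplot2 views of the result types.

#' @importFrom ggplot2 aes geom_tile geom_segment geom_col geom_hline
#'   scale_fill_gradient2 scale_fill_viridis_c coord_fixed coord_flip labs
#'   theme_minimal facet_wrap ggplot
NULL

#' Heatmap of a profile matrix
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(-"roi_id", names_to = "roi2", values_to = "r") %>%
    mutate(roi_id = factor(.data$roi_id, levels = object$roi_ids),
           roi2 = factor(.data$roi2, levels = rev(object$roi_ids)))
  ggplot(df, aes(x = .data$roi_id, y = .data$roi2, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac", mid = "white",
                         high = "#b2182b") +
    coord_fixed() +
    labs(title = sprintf("%s connectivity-profile correlations", object$modality),
         x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# hclust -> segment table for a simple dendrogram rendering
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  xpos <- numeric(n + nrow(hc$merge))
  xpos[seq_len(n)] <- order(hc$order)
  node_x <- function(id) if (id < 0) xpos[-id] else cluster_x[id]
  node_h <- function(id) if (id < 0) 0 else hc$height[id]
  cluster_x <- numeric(nrow(hc$merge))
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    ha <- node_h(a); hb <- node_h(b)
    cluster_x[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(ha, hb, hc$height[i]), yend = c(hc$height[i], hc$height[i], hc$height[i])
    )
  }
  list(segments = bind_rows(segs),
       leaves = tibble(x = xpos[seq_len(n)], label = hc$labels %||% as.character(seq_len(n))))
}

#' Dendrogram of the clique tree
#' @param object A `clique_tree` or `clique_solution`.
#' @param ... Unused.
#' @export
autoplot.clique_tree <- function(object, ...) {
  hc <- object$hclust
  dd <- dendrogram_segments(hc)
  ggplot() +
    geom_segment(data = dd$segments,
                 aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = dd$leaves,
                       aes(x = .data$x, y = -0.02 * max(hc$height), label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    labs(y = "Ward merge height", x = NULL) +
    ggplot2::expand_limits(y = -0.4 * max(hc$height)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @rdname autoplot.clique_tree
#' @export
autoplot.clique_solution <- function(object, ...) {
  hc <- object$tree$hclust
  cut_height <- if (object$k < length(hc$height) + 1 && object$k >= 2) {
    mean(sort(hc$height, decreasing = TRUE)[c(object$k - 1, object$k)])
  } else NA_real_
  p <- autoplot(object$tree)
  if (is.finite(cut_height)) {
    p <- p + geom_hline(yintercept = cut_height, linetype = "dashed", colour = "grey40")
  }
  p + labs(title = sprintf("Clique solution, k = %d", object$k))
}

#' Bar chart of a decoding table
#' @param decoding Tibble from [decode_terms()] / [decode_cliques()].
#' @export
plot_decoding <- function(decoding) {
  if (!"clique" %in% names(decoding)) decoding$clique <- 1L
  ggplot(decoding,
         aes(x = stats::reorder(.data$term, .data$r), y = .data$r)) +
    geom_col(fill = "#4477aa") +
    coord_flip() +
    facet_wrap(~clique, scales = "free_y", labeller = ggplot2::label_both) +
    labs(x = NULL, y = "spatial correlation r") +
    theme_minimal()
}

#' Axial slice montage of a volume map
#' @param object A `volume_map`.
#' @param slices Axial (z) slice indices, 1-based (default: 6 evenly spaced).
#' @param ... Unused.
#' @export
autoplot.volume_map <- function(object, slices = NULL, ...) {
  shape <- object$grid$shape
  slices <- slices %||% unique(round(seq(1, shape[3], length.out = 6)))
  df <- bind_rows(lapply(slices, function(k) {
    sl <- object$data[, , k]
    tibble(i = rep(seq_len(shape[1]), shape[2]),
           j = rep(seq_len(shape[2]), each = shape[1]),
           value = as.vector(sl), slice = k)
  }))
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    coord_fixed() +
    facet_wrap(~slice, labeller = ggplot2::label_both) +
    labs(title = sprintf("%s map", object$kind), x = NULL, y = NULL) +
    theme_minimal()
}
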