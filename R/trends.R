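# Feature-activity trends along a trajectory: cells near the path are
# binned into consecutive segments, per-segment feature means are computed
# and normalised, trend profiles are clustered with k-means, and clusters
# are ordered (up-regulated first, by extremum position) for heatmap
# display.

#' Assign trajectory-neighborhood cells to segments
#'
#' Each cell within `radius` (Euclidean distance to its nearest trajectory
#' point) is assigned the segment
#' `floor(nearest_point_index * n_segments / n_points)` (0-based point
#' index), clipped to the last segment — an equal partition of the
#' trajectory's steps into `n_segments` consecutive stretches. Cells
#' farther than `radius` stay unassigned.
#'
#' @param trajectory a `trajectory` (or bare `m x 3` point matrix) with at
#'   least 2 points.
#' @param dataset a `cell_embedding`.
#' @param n_segments number of segments (>= 1).
#' @param radius neighborhood radius in embedding units (> 0).
#' @return a `segment_assignment`: list with `segment` (length `n_cells`
#'   integer vector in `1..n_segments`, `NA` = unassigned), `n_segments`,
#'   `radius`, `trajectory`.
#' @export
assign_segments <- function(trajectory, dataset, n_segments = 10L, radius) {
  stopifnot(inherits(dataset, "cell_embedding"))
  if (!inherits(trajectory, "trajectory")) {
    pts <- matrix(as.numeric(as.matrix(trajectory)), ncol = 3)
    trajectory <- new_trajectory(pts, pts[1, ], "loaded",
                                 integration_config(n_steps = max(1L, nrow(pts) - 1L)))
  }
  if (nrow(trajectory$points) < 2L) {
    cs_stop("trajectory needs at least 2 points for segment analysis",
            "cellstream_precondition_error")
  }
  if (!is_count(n_segments, 1L)) {
    cs_stop("n_segments must be a positive integer",
            "cellstream_parameter_error")
  }
  if (!is_scalar_num(radius) || radius <= 0) {
    cs_stop("radius must be a positive real", "cellstream_parameter_error")
  }
  d <- cross_dist(dataset$coords, trajectory$points)
  nearest <- max.col(-d, ties.method = "first")       # 1-based point index
  dist_min <- d[cbind(seq_len(nrow(d)), nearest)]
  n_points <- nrow(trajectory$points)
  seg0 <- pmin(floor((nearest - 1L) * n_segments / n_points),
               n_segments - 1L)
  segment <- ifelse(dist_min <= radius, seg0 + 1L, NA_integer_)
  structure(list(segment = as.integer(segment),
                 n_segments = as.integer(n_segments),
                 radius = radius, trajectory = trajectory),
            class = "segment_assignment")
}

#' @export
print.segment_assignment <- function(x, ...) {
  cat(sprintf("<segment_assignment> %d segments, %d/%d cells within radius %g\n",
              x$n_segments, sum(!is.na(x$segment)), length(x$segment),
              x$radius))
  invisible(x)
}

# linear fill of NA entries from flanking non-NA values; ends take the
# nearest non-NA value
fill_linear <- function(v) {
  na <- which(is.na(v))
  if (!length(na)) return(v)
  ok <- which(!is.na(v))
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
}

#' Per-segment mean feature activity along a trajectory
#'
#' `means[f, s]` is the mean activity of feature `f` over the cells
#' assigned to segment `s`. Empty segments are filled by linear
#' interpolation from the flanking non-empty segments (ends take the
#' nearest non-empty value). Row-wise normalisation: `"raw"` leaves means
#' untouched; `"zscore"` centers and scales each feature across segments
#' (constant rows become all zero); `"relative"` subtracts the first
#' segment's value from each feature.
#'
#' @param assignment a [assign_segments()] result.
#' @param modality feature matrix (`n_cells x n_features`, e.g. one entry
#'   of a dataset's `modalities`) aligned with the assignment's dataset.
#' @param normalization `"raw"`, `"zscore"` or `"relative"`.
#' @return a `trend_matrix`: list with `means` (`n_features x n_segments`),
#'   `feature_ids`, `normalization`, `segment_cell_counts`.
#' @export
segment_means <- function(assignment, modality,
                          normalization = c("raw", "zscore", "relative")) {
  stopifnot(inherits(assignment, "segment_assignment"))
  normalization <- match.arg(normalization)
  modality <- as.matrix(modality)
  seg <- assignment$segment
  if (nrow(modality) != length(seg)) {
    cs_stop("modality has %d rows but the assignment covers %d cells",
            "cellstream_alignment_error", nrow(modality), length(seg))
  }
  assigned <- !is.na(seg)
  if (!any(assigned)) {
    cs_stop("no cells within radius %g of the trajectory; increase the radius",
            "cellstream_empty_neighborhood_error", assignment$radius)
  }
  ns <- assignment$n_segments
  counts <- tabulate(seg[assigned], nbins = ns)

  sums <- rowsum(modality[assigned, , drop = FALSE], seg[assigned])
  means <- matrix(NA_real_, ns, ncol(modality))
  means[as.integer(rownames(sums)), ] <- sums / counts[as.integer(rownames(sums))]
  means <- apply(means, 2, fill_linear)
  if (is.null(dim(means))) means <- matrix(means, nrow = ns)
  means <- t(means)                                   # features x segments
  rownames(means) <- colnames(modality) %||%
    paste0("feature_", seq_len(nrow(means)) - 1L)

  if (normalization == "zscore") {
    mu <- rowMeans(means)
    sdv <- apply(means, 1, stats::sd)
    means <- (means - mu) / ifelse(sdv > 0, sdv, 1)
    means[sdv == 0, ] <- 0
  } else if (normalization == "relative") {
    means <- means - means[, 1]
  }

  structure(list(means = means,
                 feature_ids = rownames(means) %||%
                   paste0("feature_", seq_len(nrow(means)) - 1L),
                 normalization = normalization,
                 segment_cell_counts = counts),
            class = "trend_matrix")
}

#' @export
print.trend_matrix <- function(x, ...) {
  cat(sprintf("<trend_matrix> %d features x %d segments (%s)\n",
              nrow(x$means), ncol(x$means), x$normalization))
  cat(sprintf("  cells per segment: %s\n",
              paste(x$segment_cell_counts, collapse = ", ")))
  invisible(x)
}

#' Cluster feature trend profiles with k-means
#'
#' Features are optionally shortlisted to the `top_n` by a per-row spread
#' statistic (`variance` or `range` across segments), then clustered with
#' seeded, multi-restart k-means on the trend rows as stored in the
#' `trend_matrix` (i.e. in its normalisation).
#'
#' @param trends a [segment_means()] result.
#' @param k number of clusters, `1 <= k <=` retained features.
#' @param seed RNG seed; identical seeds give identical labels.
#' @param top_n retain only the `top_n` most variable features, or `NULL`
#'   to keep all. Default 200.
#' @param selection shortlist statistic, `"variance"` or `"range"`.
#' @param nstart number of k-means restarts (>= 10 recommended).
#' @return a `trend_clustering`: list with `labels` (1..k per retained
#'   feature, named by feature id), `centroids` (`k x n_segments`),
#'   `cluster_order` (identity until [order_clusters()]), `feature_ids`,
#'   `k`, `seed`.
#' @export
cluster_trends <- function(trends, k = 6L, seed = 1L, top_n = 200L,
                           selection = c("variance", "range"),
                           nstart = 10L) {
  stopifnot(inherits(trends, "trend_matrix"))
  selection <- match.arg(selection)
  rows <- trends$means
  if (!is.null(top_n) && nrow(rows) > top_n) {
    stat <- switch(selection,
                   variance = apply(rows, 1, stats::var),
                   range = apply(rows, 1, function(r) diff(range(r))))
    keep <- order(stat, decreasing = TRUE)[seq_len(top_n)]
    keep <- sort(keep)                 # preserve input feature order
    rows <- rows[keep, , drop = FALSE]
  }
  if (!is_count(k, 1L) || k > nrow(rows)) {
    cs_stop("k must be an integer in [1, %d] (retained features)",
            "cellstream_parameter_error", nrow(rows))
  }
  if (k == 1L) {
    labels <- rep(1L, nrow(rows))
    centroids <- matrix(colMeans(rows), 1)
  } else if (k == nrow(rows)) {
    # trivial partition; stats::kmeans cannot seed k == n by sampling
    labels <- seq_len(k)
    centroids <- unname(rows)
  } else {
    km <- local_seed(seed,
                     stats::kmeans(rows, centers = k, nstart = max(nstart, 10L),
                                   iter.max = 100L))
    labels <- km$cluster
    centroids <- km$centers
  }
  names(labels) <- rownames(rows)
  structure(list(k = as.integer(k), labels = labels, centroids = centroids,
                 cluster_order = seq_len(k), feature_ids = rownames(rows),
                 seed = as.integer(seed)),
            class = "trend_clustering")
}

# up-regulated if centroid's last value minus first value >= 0
centroid_classes <- function(centroids) {
  ifelse(centroids[, ncol(centroids)] - centroids[, 1] >= 0, "up", "down")
}

#' Order trend clusters for heatmap display
#'
#' Clusters are first split into up-regulated (centroid's last value minus
#' first value >= 0) and down-regulated profiles. Up-regulated clusters
#' come first, ordered by increasing segment position of the centroid
#' maximum; down-regulated follow, ordered by increasing position of the
#' centroid minimum; ties broken by cluster index. This yields a heatmap
#' whose bands progress with the trajectory.
#'
#' @param clustering a [cluster_trends()] result.
#' @return the clustering with `cluster_order` set to the display
#'   permutation.
#' @export
order_clusters <- function(clustering) {
  stopifnot(inherits(clustering, "trend_clustering"))
  cen <- clustering$centroids
  cls <- centroid_classes(cen)
  extremum <- ifelse(cls == "up",
                     apply(cen, 1, which.max),
                     apply(cen, 1, which.min))
  ord <- order(cls != "up", extremum, seq_len(nrow(cen)))
  clustering$cluster_order <- ord
  clustering
}

#' @export
print.trend_clustering <- function(x, ...) {
  cat(sprintf("<trend_clustering> k = %d over %d features, order: %s\n",
              x$k, length(x$labels),
              paste(x$cluster_order, collapse = " ")))
  invisible(x)
}

#' Heatmap-ready ordered trend table
#'
#' Rows are the retained features of the clustering, sorted by (position of
#' their cluster in `cluster_order`, within-cluster extremum position — the
#' row maximum for up-regulated clusters, the row minimum for
#' down-regulated ones — then feature id). Columns carry the feature id,
#' cluster id and one column per segment.
#'
#' @param trends a [segment_means()] result.
#' @param clustering a [cluster_trends()] / [order_clusters()] result on
#'   those trends.
#' @return a data.frame with columns `feature_id`, `cluster`,
#'   `segment_1..segment_S`.
#' @export
heatmap_table <- function(trends, clustering) {
  stopifnot(inherits(trends, "trend_matrix"),
            inherits(clustering, "trend_clustering"))
  feats <- clustering$feature_ids
  idx <- match(feats, trends$feature_ids)
  if (anyNA(idx)) {
    cs_stop("clustering features are not all present in the trend matrix",
            "cellstream_alignment_error")
  }
  rows <- trends$means[idx, , drop = FALSE]
  labels <- clustering$labels
  cls <- centroid_classes(clustering$centroids)[labels]
  extremum <- ifelse(cls == "up",
                     apply(rows, 1, which.max),
                     apply(rows, 1, which.min))
  pos_in_order <- match(labels, clustering$cluster_order)
  ord <- order(pos_in_order, extremum, feats)

  out <- data.frame(feature_id = feats[ord],
                    cluster = as.integer(labels[ord]),
                    rows[ord, , drop = FALSE],
                    check.names = FALSE, row.names = NULL)
  colnames(out)[-(1:2)] <- paste0("segment_", seq_len(ncol(rows)))
  out
}
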