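# Trend module: segment assignment geometry, group means with empty-segment
# fill, normalisations, k-means planted-partition recovery and canonical
# cluster ordering.

straight_path <- function(n_points = 10) {
  pts <- cbind(seq(0, 1, length.out = n_points), 0, 0)
  cellstream:::new_trajectory(pts, pts[1, ], "completed",
                              integration_config(n_steps = n_points - 1L))
}

test_that("segment index follows the nearest trajectory point", {
  tr <- straight_path(10)
  co <- rbind(c(0, 0.01, 0),        # nearest point 1 -> segment 1
              c(1, 0.01, 0),        # nearest point 10 -> clipped to segment 5
              c(0.47, 0, 0),        # nearest point 5 -> segment 3
              c(0, 5, 0))           # outside radius
  ds <- cell_embedding(co)
  a <- assign_segments(tr, ds, n_segments = 5, radius = 0.2)
  expect_equal(a$segment, c(1L, 5L, 3L, NA))
  expect_error(assign_segments(tr, ds, 5, radius = -1),
               class = "cellstream_parameter_error")
})

test_that("segment assignment matches the brute-force nearest-point oracle", {
  set.seed(50)
  tr <- straight_path(17)
  co <- cbind(runif(300), runif(300, -0.2, 0.2), runif(300, -0.2, 0.2))
  ds <- cell_embedding(co)
  a <- assign_segments(tr, ds, n_segments = 7, radius = 0.15)
  expect_equal(a$segment,
               oracle_assign_segments(tr$points, co, 7, 0.15))
  # count conservation
  expect_equal(sum(!is.na(a$segment)),
               sum(tabulate(a$segment, nbins = 7)))
})

test_that("raw segment means equal the groupby oracle; fill bridges gaps", {
  set.seed(51)
  tr <- straight_path(12)
  co <- cbind(runif(200), runif(200, -0.1, 0.1), runif(200, -0.1, 0.1))
  vals <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(NULL, paste0("g", 1:5)))
  ds <- cell_embedding(co, modalities = list(RNA = vals))
  a <- assign_segments(tr, ds, n_segments = 6, radius = 0.5)
  tm <- segment_means(a, ds$modalities$RNA, normalization = "raw")
  oracle <- oracle_segment_means(a$segment, vals, 6)
  expect_equal(unname(tm$means), oracle, tolerance = 1e-12)
  expect_equal(sum(tm$segment_cell_counts), sum(!is.na(a$segment)))

  # deliberately empty a middle segment: its mean must be the linear
  # midpoint of its non-empty flanks
  a2 <- a
  a2$segment[a2$segment == 3L] <- NA
  tm2 <- segment_means(a2, ds$modalities$RNA, normalization = "raw")
  expect_equal(tm2$means[, 3], (tm2$means[, 2] + tm2$means[, 4]) / 2,
               tolerance = 1e-12)
  expect_equal(tm2$segment_cell_counts[3], 0L)
})

test_that("one cell per segment yields that cell's raw values", {
  tr <- straight_path(4)
  co <- rbind(c(0, 0, 0), c(1 / 3, 0, 0), c(2 / 3, 0, 0), c(1, 0, 0))
  vals <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "g"))
  ds <- cell_embedding(co, modalities = list(RNA = vals))
  a <- assign_segments(tr, ds, n_segments = 4, radius = 0.1)
  tm <- segment_means(a, ds$modalities$RNA, "raw")
  expect_equal(unname(tm$means[1, ]), c(1, 2, 3, 4))
})

test_that("normalisations: zscore rows standardised, relative rows zeroed at start", {
  tr <- straight_path(10)
  set.seed(52)
  co <- cbind(runif(120), 0, 0)
  vals <- cbind(g_var = rnorm(120), g_const = rep(3, 120))
  ds <- cell_embedding(co, modalities = list(RNA = vals))
  a <- assign_segments(tr, ds, n_segments = 5, radius = 0.5)

  z <- segment_means(a, ds$modalities$RNA, "zscore")
  expect_lt(abs(mean(z$means["g_var", ])), 1e-9)
  expect_lt(abs(stats::var(z$means["g_var", ]) - 1), 1e-9)
  expect_equal(unname(z$means["g_const", ]), rep(0, 5))

  r <- segment_means(a, ds$modalities$RNA, "relative")
  expect_equal(unname(r$means[, 1]), c(0, 0))

  a_none <- a
  a_none$segment[] <- NA_integer_
  expect_error(segment_means(a_none, ds$modalities$RNA),
               class = "cellstream_empty_neighborhood_error")
})

planted_trend_matrix <- function(n_up = 6, n_down = 6, n_segments = 8,
                                 noise = 0) {
  s <- seq(0, 1, length.out = n_segments)
  rows <- rbind(
    t(replicate(n_up, s + rnorm(n_segments, 0, noise))),
    t(replicate(n_down, 1 - s + rnorm(n_segments, 0, noise)))
  )
  rownames(rows) <- c(paste0("up", seq_len(n_up)),
                      paste0("down", seq_len(n_down)))
  structure(list(means = rows, feature_ids = rownames(rows),
                 normalization = "raw",
                 segment_cell_counts = rep(1L, n_segments)),
            class = "trend_matrix")
}

test_that("k-means recovers planted monotone families and orders up first", {
  tm <- planted_trend_matrix()
  cl <- cluster_trends(tm, k = 2, seed = 11, top_n = NULL)
  lab_up <- unique(cl$labels[startsWith(names(cl$labels), "up")])
  lab_down <- unique(cl$labels[startsWith(names(cl$labels), "down")])
  expect_length(lab_up, 1)
  expect_length(lab_down, 1)
  expect_false(lab_up == lab_down)

  ordered <- order_clusters(cl)
  expect_equal(ordered$cluster_order[1], lab_up)
  expect_equal(ordered$cluster_order[2], lab_down)
})

test_that("clustering is deterministic under the seed; k=1 degenerates", {
  tm <- planted_trend_matrix(noise = 0.05)
  c1 <- cluster_trends(tm, k = 3, seed = 5)
  c2 <- cluster_trends(tm, k = 3, seed = 5)
  expect_identical(c1$labels, c2$labels)

  c3 <- cluster_trends(tm, k = 1)
  expect_true(all(c3$labels == 1L))
  expect_equal(unname(c3$centroids[1, ]), unname(colMeans(tm$means)))

  expect_error(cluster_trends(tm, k = 40),
               class = "cellstream_parameter_error")
})

test_that("top_n shortlisting keeps the most variable features", {
  tm <- planted_trend_matrix(n_up = 10, n_down = 10, noise = 0)
  flat <- matrix(0.5, 5, ncol(tm$means),
                 dimnames = list(paste0("flat", 1:5), NULL))
  tm$means <- rbind(tm$means, flat)
  tm$feature_ids <- rownames(tm$means)
  cl <- cluster_trends(tm, k = 2, top_n = 20)
  expect_length(cl$labels, 20)
  expect_false(any(startsWith(names(cl$labels), "flat")))
})

test_that("cluster ordering matches the tuple-sort oracle", {
  set.seed(53)
  for (rep in 1:5) {
    cen <- matrix(rnorm(6 * 7), 6, 7)
    cl <- structure(list(k = 6L, labels = setNames(1:6, paste0("f", 1:6)),
                         centroids = cen, cluster_order = 1:6,
                         feature_ids = paste0("f", 1:6), seed = 1L),
                    class = "trend_clustering")
    expect_equal(order_clusters(cl)$cluster_order,
                 oracle_cluster_order(cen))
  }
})

test_that("extremum ordering puts the earlier-peaking up-cluster first", {
  # both up-regulated (end above start), peaking at segments 2 and 6
  peak2 <- c(0, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  peak6 <- c(0, 0.1, 0.2, 0.3, 0.4, 1, 0.6, 0.6)
  cen <- rbind(peak6, peak2)
  cl <- structure(list(k = 2L, labels = setNames(c(1L, 2L), c("a", "b")),
                       centroids = cen, cluster_order = 1:2,
                       feature_ids = c("a", "b"), seed = 1L),
                  class = "trend_clustering")
  expect_equal(order_clusters(cl)$cluster_order, c(2L, 1L))
})

test_that("heatmap table rows are ordered, complete and round-trippable", {
  tm <- planted_trend_matrix(n_up = 4, n_down = 4, noise = 0.01)
  cl <- order_clusters(cluster_trends(tm, k = 2, seed = 3, top_n = NULL))
  tab <- heatmap_table(tm, cl)
  expect_equal(nrow(tab), 8L)
  # up-family rows come before down-family rows
  expect_true(all(startsWith(tab$feature_id[1:4], "up")))
  expect_true(all(startsWith(tab$feature_id[5:8], "down")))

  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  back <- read.csv(p, check.names = FALSE)
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # permuting feature rows permutes heatmap rows only, values unchanged
  perm <- sample(nrow(tm$means))
  tm2 <- tm
  tm2$means <- tm$means[perm, , drop = FALSE]
  tm2$feature_ids <- tm$feature_ids[perm]
  tab2 <- heatmap_table(tm2, cl)
  expect_equal(tab2[order(tab2$feature_id), -1],
               tab[order(tab$feature_id), -1], ignore_attr = TRUE)

  single <- heatmap_table(
    structure(list(means = tm$means[1, , drop = FALSE],
                   feature_ids = tm$feature_ids[1],
                   normalization = "raw",
                   segment_cell_counts = tm$segment_cell_counts),
              class = "trend_matrix"),
    structure(list(k = 1L, labels = setNames(1L, tm$feature_ids[1]),
                   centroids = tm$means[1, , drop = FALSE],
                   cluster_order = 1L, feature_ids = tm$feature_ids[1],
                   seed = 1L),
              class = "trend_clustering"))
  expect_equal(nrow(single), 1L)
})
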