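# Brute-force reference implementations and small dataset builders used as
# independent oracles. These deliberately use plain loops and direct
# formulas, not the package's vectorised code paths.

# random cells in the unit cube with random velocities
random_dataset <- function(n, seed = 1, with_features = 0) {
  set.seed(seed)
  coords <- matrix(runif(n * 3), n, 3)
  velocities <- matrix(rnorm(n * 3), n, 3)
  mods <- list()
  if (with_features > 0) {
    vals <- matrix(rnorm(n * with_features), n, with_features)
    colnames(vals) <- paste0("g", seq_len(with_features))
    mods$RNA <- vals
  }
  cell_embedding(coords, velocities = velocities, modalities = mods)
}

# all node positions of a grid, x-fastest, matching the package's ordering
oracle_node_positions <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + grid$spacing[a] * (seq_len(grid$shape[a]) - 1)
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# bin-mean averaging by explicit nearest-node search over all nodes
oracle_bin_mean <- function(coords, velocities, grid) {
  nodes <- oracle_node_positions(grid)
  n_nodes <- nrow(nodes)
  sums <- matrix(0, n_nodes, 3)
  counts <- integer(n_nodes)
  for (i in seq_len(nrow(coords))) {
    d2 <- rowSums((nodes - matrix(coords[i, ], n_nodes, 3, byrow = TRUE))^2)
    j <- which.min(d2)
    sums[j, ] <- sums[j, ] + velocities[i, ]
    counts[j] <- counts[j] + 1L
  }
  vectors <- sums
  occ <- counts > 0
  vectors[occ, ] <- sums[occ, , drop = FALSE] / counts[occ]
  list(vectors = vectors, occupancy = counts)
}

# a grid_vector_field whose node vectors are an analytic function of the
# node position
analytic_grid_field <- function(fun, lo = c(0, 0, 0), hi = c(1, 1, 1),
                                resolution = 11, scale = 1) {
  grid <- build_grid(rbind(lo, hi), resolution = resolution, padding = 0,
                     scale = scale)
  nodes <- oracle_node_positions(grid)
  vecs <- t(apply(nodes, 1, fun))
  grid_vector_field(grid, vecs, occupancy = rep(1L, nrow(nodes)))
}

# dense RBF solve with explicit loops: kernel matrix entry by entry,
# degree-1 polynomial tail [1, x, y, z], base solve()
oracle_rbf_predict <- function(coords, values, kernel, epsilon, smoothing,
                               query) {
  phi <- function(r) {
    # conditionally negative definite families enter the system negated,
    # matching the fitted model's documented convention
    switch(kernel,
           gaussian = exp(-(epsilon * r)^2),
           linear = -r,
           quadratic = if (r == 0) 0 else r^2 * log(r),
           multiquadric = -sqrt(1 + (epsilon * r)^2))
  }
  n <- nrow(coords)
  M <- matrix(0, n + 4, n + 4)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- phi(sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
    M[i, i] <- M[i, i] + smoothing
    p <- c(1, coords[i, ])
    M[i, n + (1:4)] <- p
    M[n + (1:4), i] <- p
  }
  sol <- solve(M, c(values, numeric(4)))
  out <- numeric(nrow(query))
  for (q in seq_len(nrow(query))) {
    acc <- sum(sol[n + (1:4)] * c(1, query[q, ]))
    for (i in seq_len(n)) {
      acc <- acc + sol[i] * phi(sqrt(sum((query[q, ] - coords[i, ])^2)))
    }
    out[q] <- acc
  }
  out
}

# nearest-trajectory-point segment assignment by explicit loops
oracle_assign_segments <- function(points, coords, n_segments, radius) {
  n_points <- nrow(points)
  out <- rep(NA_integer_, nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d <- sqrt(colSums((t(points) - coords[i, ])^2))
    j <- which.min(d)
    if (d[j] <= radius) {
      out[i] <- min(floor((j - 1) * n_segments / n_points), n_segments - 1) + 1L
    }
  }
  out
}

# group-by segment means with loops (no empty-segment fill)
oracle_segment_means <- function(segment, values, n_segments) {
  out <- matrix(NA_real_, ncol(values), n_segments)
  for (s in seq_len(n_segments)) {
    rows <- which(!is.na(segment) & segment == s)
    if (length(rows)) out[, s] <- colMeans(values[rows, , drop = FALSE])
  }
  out
}

# clone expansion by explicit set algebra over the label table
oracle_expand_clones <- function(clones, query) {
  labels <- setdiff(unique(clones[query]), NA)
  related <- integer(0)
  for (i in seq_along(clones)) {
    if (i %in% query) next
    if (!is.na(clones[i]) && clones[i] %in% labels) related <- c(related, i)
  }
  list(clone_ids = sort(labels), related = sort(related))
}

# canonical cluster order by sorting (class, extremum position, index)
# tuples
oracle_cluster_order <- function(centroids) {
  n <- nrow(centroids)
  keys <- lapply(seq_len(n), function(i) {
    cen <- centroids[i, ]
    up <- cen[length(cen)] - cen[1] >= 0
    ext <- if (up) which.max(cen) else which.min(cen)
    c(class = as.integer(!up), ext = ext, idx = i)
  })
  keys <- do.call(rbind, keys)
  order(keys[, "class"], keys[, "ext"], keys[, "idx"])
}
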