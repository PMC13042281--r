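# Regular 3D grid construction, velocity averaging onto grid nodes, and
# continuous (trilinear) field evaluation.
#
# Node storage: grids are indexed 0-based in exports, with node (i,j,k) at
# position origin + spacing * (i,j,k). In memory, node vectors live in an
# n_nodes x 3 matrix ordered x-fastest (the natural R array order for a
# dim = shape array).

#' Build a regular grid over a point cloud
#'
#' The longest axis of the (padded) bounding box gets `resolution` nodes;
#' the other axes get proportionally fewer — `ceil((resolution-1) * extent /
#' max_extent) + 1`, floored at 2 — which keeps voxels near-cubic. A
#' degenerate axis (zero extent) gets 2 nodes one unit apart, centred on the
#' data, with a notice.
#'
#' @param coords `n x 3` matrix of point positions.
#' @param resolution number of nodes along the longest axis (>= 2).
#' @param padding fraction of each axis extent added on both sides before
#'   gridding, in `[0, 1)`.
#' @param scale scalar multiplier applied to stored node vectors whenever
#'   the field is sampled or rendered; it scales integration displacement
#'   and glyph length, not node positions.
#' @return a `grid_spec`: list with `origin`, `spacing`, `shape`, `scale`.
#' @export
build_grid <- function(coords, resolution = 15L, padding = 0.05, scale = 1) {
  coords <- as.matrix(coords)
  if (!is_count(resolution, 2L)) {
    cs_stop("resolution must be an integer >= 2", "cellstream_parameter_error")
  }
  if (!is_scalar_num(padding) || padding < 0 || padding >= 1) {
    cs_stop("padding must lie in [0, 1)", "cellstream_parameter_error")
  }
  if (!is_scalar_num(scale) || scale <= 0) {
    cs_stop("scale must be a positive real", "cellstream_parameter_error")
  }
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  ext <- hi - lo
  lo <- lo - padding * ext
  hi <- hi + padding * ext
  ext <- hi - lo

  degen <- ext == 0
  if (any(degen)) {
    cs_notice("degenerate axis (%s): using 2 nodes with unit spacing",
              paste(c("x", "y", "z")[degen], collapse = ", "))
    lo[degen] <- lo[degen] - 0.5
    hi[degen] <- hi[degen] + 0.5
    ext <- hi - lo
  }

  # the resolution applies to the longest informative axis; degenerate axes
  # keep exactly 2 nodes (unit spacing) regardless
  emax <- if (all(degen)) 1 else max(ext[!degen])
  shape <- pmax(2L, as.integer(ceiling((resolution - 1L) * ext / emax)) + 1L)
  shape[degen] <- 2L
  spacing <- ext / (shape - 1L)

  structure(list(origin = unname(lo), spacing = unname(spacing),
                 shape = shape, scale = scale),
            class = "grid_spec")
}

grid_n_nodes <- function(grid) prod(grid$shape)

grid_upper <- function(grid) grid$origin + grid$spacing * (grid$shape - 1L)

# Axis node coordinates, a list of 3 numeric vectors.
grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + grid$spacing[a] * (seq_len(grid$shape[a]) - 1L))
}

# 0-based (i,j,k) per node, x-fastest ordering; rows align with the vector
# matrix of a grid_vector_field / values of a volume field.
grid_ijk <- function(grid) {
  s <- grid$shape
  idx <- seq_len(prod(s)) - 1L
  cbind(i = idx %% s[1],
        j = (idx %/% s[1]) %% s[2],
        k = idx %/% (s[1] * s[2]))
}

grid_node_positions <- function(grid) {
  ijk <- grid_ijk(grid)
  sweep(sweep(ijk, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# linear (1-based) node index from 0-based ijk columns
grid_linear_index <- function(grid, ijk) {
  s <- grid$shape
  1L + ijk[, 1] + s[1] * (ijk[, 2] + s[2] * ijk[, 3])
}

#' Construct a grid vector field from explicit node vectors
#'
#' Mostly used to set node vectors from an analytic field (e.g. to study
#' integrator accuracy) or to rebuild a field from an exported table.
#' Nodes with occupancy 0 must hold the zero vector.
#'
#' @param grid a `grid_spec`.
#' @param vectors `n_nodes x 3` matrix, x-fastest node order (the order of
#'   [as.data.frame.grid_vector_field()] rows).
#' @param occupancy integer vector of contributing-cell counts per node;
#'   defaults to 1 for every node with a non-zero vector.
#' @return a `grid_vector_field`.
#' @export
grid_vector_field <- function(grid, vectors, occupancy = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  vectors <- matrix(as.numeric(as.matrix(vectors)), ncol = 3)
  if (nrow(vectors) != grid_n_nodes(grid)) {
    cs_stop("vectors has %d rows but the grid has %d nodes",
            "cellstream_alignment_error", nrow(vectors), grid_n_nodes(grid))
  }
  if (any(!is.finite(vectors))) {
    cs_stop("node vectors contain non-finite values",
            "cellstream_parameter_error")
  }
  if (is.null(occupancy)) {
    occupancy <- as.integer(rowSums(vectors != 0) > 0)
  }
  occupancy <- as.integer(occupancy)
  if (length(occupancy) != nrow(vectors) || any(occupancy < 0)) {
    cs_stop("occupancy must be one non-negative count per node",
            "cellstream_parameter_error")
  }
  vectors[occupancy == 0L & rowSums(vectors != 0) > 0, ] <- 0
  structure(list(grid = grid, vectors = vectors, occupancy = occupancy,
                 method = "explicit"),
            class = "grid_vector_field")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> shape %s (%d nodes), scale %g\n",
              paste(x$shape, collapse = " x "), grid_n_nodes(x), x$scale))
  cat(sprintf("  origin : %s\n", paste(signif(x$origin, 5), collapse = ", ")))
  cat(sprintf("  spacing: %s\n", paste(signif(x$spacing, 5), collapse = ", ")))
  invisible(x)
}

#' Average per-cell velocities onto grid nodes
#'
#' `bin-mean` assigns each cell to its nearest grid node and stores the
#' arithmetic mean of the assigned cells' velocity vectors at each node.
#' `gaussian-kernel` stores at each node the kernel-weighted mean over all
#' cells, weight `exp(-d^2 / (2 sigma^2))`; its occupancy counts the cells
#' within `3 sigma` of the node. Nodes with no contributing cells hold the
#' zero vector.
#'
#' @param dataset a `cell_embedding` with velocities.
#' @param grid a `grid_spec` from [build_grid()].
#' @param method `"bin-mean"` (default) or `"gaussian-kernel"`.
#' @param bandwidth kernel sigma in embedding units, or `"auto"` (half the
#'   largest voxel edge). Ignored by `bin-mean`.
#' @return a `grid_vector_field`: list with `grid`, `vectors`
#'   (`n_nodes x 3`), `occupancy` (length `n_nodes`).
#' @export
average_velocities <- function(dataset, grid,
                               method = c("bin-mean", "gaussian-kernel"),
                               bandwidth = "auto") {
  stopifnot(inherits(dataset, "cell_embedding"), inherits(grid, "grid_spec"))
  method <- match.arg(method)
  if (is.null(dataset$velocities)) {
    cs_stop("dataset has no velocities; cannot build a vector field",
            "cellstream_precondition_error")
  }
  n_nodes <- grid_n_nodes(grid)
  vectors <- matrix(0, n_nodes, 3)
  occupancy <- integer(n_nodes)

  if (method == "bin-mean") {
    # nearest node along each axis = rounded fractional index, clamped
    tfrac <- sweep(sweep(dataset$coords, 2, grid$origin, `-`),
                   2, grid$spacing, `/`)
    ijk <- round(tfrac)
    ijk <- pmin(pmax(ijk, 0), matrix(grid$shape - 1L, nrow(ijk), 3, byrow = TRUE))
    lin <- grid_linear_index(grid, ijk)
    counts <- tabulate(lin, nbins = n_nodes)
    sums <- rowsum(dataset$velocities, lin)
    at <- as.integer(rownames(sums))
    vectors[at, ] <- sums / counts[at]
    occupancy <- counts
  } else {
    sigma <- if (identical(bandwidth, "auto")) max(grid$spacing) / 2
             else bandwidth
    if (!is_scalar_num(sigma) || sigma <= 0) {
      cs_stop("bandwidth must be a positive real or \"auto\"",
              "cellstream_parameter_error")
    }
    nodes <- grid_node_positions(grid)
    d2 <- cross_dist2(nodes, dataset$coords)
    d2[d2 < 0] <- 0
    w <- exp(-d2 / (2 * sigma^2))
    wsum <- rowSums(w)
    keep <- wsum > 0
    vectors[keep, ] <- (w %*% dataset$velocities)[keep, , drop = FALSE] / wsum[keep]
    occupancy <- as.integer(rowSums(d2 <= (3 * sigma)^2))
    vectors[occupancy == 0L, ] <- 0
  }

  structure(list(grid = grid, vectors = vectors, occupancy = occupancy,
                 method = method),
            class = "grid_vector_field")
}

#' @export
print.grid_vector_field <- function(x, ...) {
  cat(sprintf("<grid_vector_field> %s grid, %d/%d occupied nodes (%s)\n",
              paste(x$grid$shape, collapse = "x"),
              sum(x$occupancy > 0), grid_n_nodes(x$grid), x$method))
  invisible(x)
}

# Vectorised trilinear sampler. pts: m x 3. Returns list(vectors = m x 3
# scaled by grid$scale, out_of_domain = logical m). Points outside the grid
# bounding box get the zero vector and the flag.
sample_field_many <- function(field, pts) {
  grid <- field$grid
  pts <- matrix(as.numeric(pts), ncol = 3)
  m <- nrow(pts)
  s <- grid$shape
  tfrac <- sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`)
  eps <- 1e-12
  out <- rowSums(tfrac < -eps | tfrac > matrix(s - 1L + eps, m, 3, byrow = TRUE)) > 0

  tclamp <- pmin(pmax(tfrac, 0), matrix(s - 1L, m, 3, byrow = TRUE))
  i0 <- pmin(floor(tclamp), matrix(s - 2L, m, 3, byrow = TRUE))
  f <- tclamp - i0

  vec <- matrix(0, m, 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    lin <- grid_linear_index(grid, cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz))
    vec <- vec + w * field$vectors[lin, , drop = FALSE]
  }
  vec <- vec * grid$scale
  vec[out, ] <- 0
  list(vectors = vec, out_of_domain = out)
}

#' Sample the vector field at a point
#'
#' Trilinear interpolation of the 8 surrounding node vectors, multiplied by
#' the grid's `scale`. Points outside the grid bounding box return the zero
#' vector with attribute `out_of_domain = TRUE` instead of extrapolating,
#' so field lines terminate cleanly at the domain hull.
#'
#' @param field a `grid_vector_field`.
#' @param point numeric 3-vector.
#' @return length-3 numeric vector with logical attribute `out_of_domain`.
#' @export
sample_field <- function(field, point) {
  stopifnot(inherits(field, "grid_vector_field"))
  point <- as_point3(point)
  res <- sample_field_many(field, matrix(point, 1))
  structure(as.numeric(res$vectors), out_of_domain = res$out_of_domain[1])
}

#' Cone glyph anchors and directions
#'
#' One glyph per grid node whose occupancy reaches `min_occupancy` and whose
#' averaged vector is non-zero; direction is the node vector times the
#' grid scale.
#'
#' @param field a `grid_vector_field`.
#' @param min_occupancy minimum number of contributing cells per node.
#' @return data.frame with columns `x,y,z` (anchor), `u,v,w` (direction) and
#'   `occupancy`.
#' @export
cone_glyphs <- function(field, min_occupancy = 1L) {
  stopifnot(inherits(field, "grid_vector_field"))
  if (!is.numeric(min_occupancy) || min_occupancy < 0) {
    cs_stop("min_occupancy must be a non-negative integer",
            "cellstream_parameter_error")
  }
  nonzero <- rowSums(field$vectors != 0) > 0
  keep <- field$occupancy >= min_occupancy & nonzero
  pos <- grid_node_positions(field$grid)[keep, , drop = FALSE]
  dir <- field$vectors[keep, , drop = FALSE] * field$grid$scale
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             u = dir[, 1], v = dir[, 2], w = dir[, 3],
             occupancy = field$occupancy[keep])
}

#' @describeIn average_velocities Flat table of the field: 0-based node
#'   indices, node position, vector components and occupancy.
#' @param x a `grid_vector_field`.
#' @param row.names,optional,... ignored; present for method compatibility.
#' @export
as.data.frame.grid_vector_field <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  ijk <- grid_ijk(x$grid)
  pos <- grid_node_positions(x$grid)
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             vx = x$vectors[, 1], vy = x$vectors[, 2], vz = x$vectors[, 3],
             occupancy = x$occupancy)
}
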