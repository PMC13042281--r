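# Synthetic dataset generators with known ground truth: analytic vector
# fields for integration tests, planted monotone/transient feature trends
# along a reference path, and clone structure with a membership table.
# Every generator is deterministic under its seed.

analytic_field <- function(kind, params) {
  switch(kind,
    "uniform" = {
      v0 <- as_point3(params$v0 %||% c(1, 0, 0), "v0")
      function(p) matrix(v0, nrow(p), 3, byrow = TRUE)
    },
    "linear-sink" = {
      center <- as_point3(params$center %||% c(0.5, 0.5, 0.5), "center")
      function(p) sweep(-p, 2, center, `+`)           # v(x) = -(x - c)
    },
    "bifurcation" = {
      branch_x <- params$branch_x %||% 0.5
      z0 <- params$z0 %||% 0.5
      strength <- params$strength %||% 1
      function(p) {
        beyond <- p[, 1] > branch_x
        cbind(1, 0, strength * sign(p[, 3] - z0) * beyond)
      }
    },
    cs_stop("unknown field kind '%s'", "cellstream_parameter_error", kind)
  )
}

#' Synthetic dataset around an analytic vector field
#'
#' Samples cell coordinates uniformly in a box (the unit cube by default)
#' and sets each cell's velocity to an analytic field evaluated at its
#' position, plus isotropic Gaussian noise. Fields: `"uniform"` (constant
#' `v0`), `"linear-sink"` (`v(x) = -(x - c)`, flow converging on `c`) and
#' `"bifurcation"` (flow along +x that diverges in ±z beyond a branch
#' point) — the three regimes a velocity-field pipeline must handle:
#' translation, contraction and branching.
#'
#' @param n_cells number of cells.
#' @param field_kind `"uniform"`, `"linear-sink"` or `"bifurcation"`.
#' @param field_params list of field parameters (`v0`, `center`,
#'   `branch_x`, `z0`, `strength`, `box` as `2 x 3` min/max matrix).
#' @param noise_sd sd of the Gaussian noise added to each velocity
#'   component.
#' @param n_features if > 0, that many random smooth features (linear maps
#'   of the coordinates plus noise) are attached as modality `"RNA"`.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return a `cell_embedding` with a `celltype` annotation (thirds along
#'   the x axis).
#' @export
make_field_dataset <- function(n_cells = 500L,
                               field_kind = c("uniform", "linear-sink",
                                              "bifurcation"),
                               field_params = list(), noise_sd = 0,
                               n_features = 0L, seed = 1L) {
  field_kind <- match.arg(field_kind)
  if (!is_count(n_cells, 1L)) {
    cs_stop("n_cells must be a positive integer", "cellstream_parameter_error")
  }
  box <- field_params$box %||% rbind(c(0, 0, 0), c(1, 1, 1))
  f <- analytic_field(field_kind, field_params)
  local_seed(seed, {
    coords <- sapply(1:3, function(a) stats::runif(n_cells, box[1, a], box[2, a]))
    coords <- matrix(coords, n_cells, 3)
    velocities <- f(coords)
    if (noise_sd > 0) {
      velocities <- velocities + matrix(stats::rnorm(n_cells * 3, 0, noise_sd),
                                        n_cells, 3)
    }
    third <- cut(coords[, 1], breaks = 3, labels = c("early", "mid", "late"))
    modalities <- list()
    if (n_features > 0) {
      B <- matrix(stats::rnorm(3 * n_features), 3, n_features)
      vals <- coords %*% B + matrix(stats::rnorm(n_cells * n_features, 0, 0.1),
                                    n_cells, n_features)
      colnames(vals) <- paste0("gene_", seq_len(n_features) - 1L)
      modalities$RNA <- vals
    }
    cell_embedding(coords, velocities = velocities,
                   annotations = data.frame(celltype = third),
                   modalities = modalities)
  })
}

trend_profile <- function(shape) {
  switch(shape,
    "monotone-up" = function(s) s,
    "monotone-down" = function(s) 1 - s,
    "transient-peak" = function(s) 4 * s * (1 - s),
    cs_stop("unknown profile shape '%s'", "cellstream_parameter_error", shape)
  )
}

#' Plant feature trends along a reference path
#'
#' For each requested profile shape, adds one feature whose per-cell value
#' is the profile evaluated at the cell's progress along the path —
#' nearest path point index divided by the path length, so the cell nearest
#' the path start sits at progress 0 and the cell nearest the end at 1 —
#' plus Gaussian noise. Profiles: `"monotone-up"` (`s`), `"monotone-down"`
#' (`1 - s`), `"transient-peak"` (`4 s (1 - s)`, maximal at the midpoint).
#' Features are appended to (or create) modality `"RNA"`.
#'
#' @param dataset a `cell_embedding`.
#' @param reference_path a `trajectory` (or `m x 3` matrix) with >= 2
#'   points.
#' @param profiles character vector of profile shapes, one feature each;
#'   repeats allowed.
#' @param noise_sd Gaussian noise sd added per cell.
#' @param seed RNG seed.
#' @param feature_ids optional feature names; defaults to
#'   `<shape>_<index>`.
#' @return the dataset with the planted features added.
#' @export
make_trend_features <- function(dataset, reference_path,
                                profiles = c("monotone-up", "monotone-down",
                                             "transient-peak"),
                                noise_sd = 0, seed = 1L, feature_ids = NULL) {
  stopifnot(inherits(dataset, "cell_embedding"))
  pts <- if (inherits(reference_path, "trajectory")) reference_path$points
         else matrix(as.numeric(as.matrix(reference_path)), ncol = 3)
  if (nrow(pts) < 2L) {
    cs_stop("reference_path needs at least 2 points",
            "cellstream_precondition_error")
  }
  d <- cross_dist(dataset$coords, pts)
  nearest <- max.col(-d, ties.method = "first")
  s <- (nearest - 1) / (nrow(pts) - 1)

  if (is.null(feature_ids)) {
    feature_ids <- make.unique(paste0(gsub("-", "_", profiles), "_",
                                      seq_along(profiles) - 1L))
  }
  vals <- local_seed(seed, {
    v <- vapply(profiles, function(p) trend_profile(p)(s),
                numeric(length(s)))
    v <- matrix(v, ncol = length(profiles))
    if (noise_sd > 0) v <- v + matrix(stats::rnorm(length(v), 0, noise_sd),
                                      nrow(v))
    v
  })
  colnames(vals) <- feature_ids

  existing <- dataset$modalities[["RNA"]]
  combined <- if (is.null(existing)) vals else cbind(existing, vals)
  dataset$modalities[["RNA"]] <- modality_matrix(combined, "RNA",
                                                 n_cells(dataset))
  dataset
}

#' Synthetic clonal dataset with known membership
#'
#' Assigns clone labels so each clone occupies a contiguous region of the
#' embedding (cells near a clone-specific center) plus a dispersed minority
#' (a fraction of labelled cells reassigned to a random other clone),
#' mimicking barcoded lineage-tracing data where clones concentrate in a
#' fate compartment but scatter across states. A fraction of cells carries
#' the missing-label sentinel (`NA`).
#'
#' @param n_cells number of cells.
#' @param n_clones number of clones (>= 1).
#' @param sentinel_fraction fraction of cells left unlabelled.
#' @param dispersed_fraction fraction of labelled cells reassigned to a
#'   random different clone.
#' @param seed RNG seed.
#' @return list with `dataset` (a `cell_embedding` with clone labels) and
#'   `membership` (data.frame `cell_id`, `clone` — the ground truth,
#'   sentinel rows excluded).
#' @export
make_clonal_dataset <- function(n_cells = 500L, n_clones = 10L,
                                sentinel_fraction = 0.1,
                                dispersed_fraction = 0.15, seed = 1L) {
  if (!is_count(n_clones, 1L)) {
    cs_stop("n_clones must be >= 1", "cellstream_parameter_error")
  }
  local_seed(seed, {
    coords <- matrix(stats::runif(n_cells * 3), n_cells, 3)
    centers <- matrix(stats::runif(n_clones * 3), n_clones, 3)
    nearest <- max.col(-cross_dist2(coords, centers), ties.method = "first")
    clones <- paste0("clone_", nearest - 1L)

    labelled <- seq_len(n_cells)
    if (sentinel_fraction > 0) {
      drop <- sample(n_cells, floor(sentinel_fraction * n_cells))
      clones[drop] <- NA_character_
      labelled <- setdiff(labelled, drop)
    }
    if (dispersed_fraction > 0 && n_clones > 1L && length(labelled)) {
      move <- sample(labelled, floor(dispersed_fraction * length(labelled)))
      for (i in move) {
        others <- setdiff(paste0("clone_", seq_len(n_clones) - 1L), clones[i])
        clones[i] <- sample(others, 1)
      }
    }
    ds <- cell_embedding(coords, clones = clones)
    membership <- data.frame(cell_id = ds$cell_ids[!is.na(clones)],
                             clone = clones[!is.na(clones)],
                             stringsAsFactors = FALSE)
    list(dataset = ds, membership = membership)
  })
}

#' Write a fixture dataset in every supported format
#'
#' Writes `<name>.csv`, `<name>.h5ad` and, when the dataset has at least
#' two modalities, `<name>.h5mu`; a ground-truth membership table (if
#' supplied) goes to `<name>_membership.json`.
#'
#' @param dataset a `cell_embedding`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param membership optional ground-truth data.frame.
#' @return character vector of the files written.
#' @export
write_fixture <- function(dataset, dir, name = "fixture", membership = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_table(dataset, file.path(dir, paste0(name, ".csv"))),
    write_h5ad(dataset, file.path(dir, paste0(name, ".h5ad")))
  )
  if (length(dataset$modalities) >= 2L) {
    files <- c(files, write_h5mu(dataset, file.path(dir, paste0(name, ".h5mu"))))
  }
  if (!is.null(membership)) {
    p <- file.path(dir, paste0(name, "_membership.json"))
    jsonlite::write_json(membership, p, dataframe = "columns")
    files <- c(files, p)
  }
  files
}
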