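# Radial basis function interpolation of scattered per-cell feature values
# onto dense regular grids (isosurface-ready scalar volumes).
#
# The interpolant augments the kernel expansion with a degree-1 polynomial
# tail, solving
#     [ A + lambda I   P ] [w]   [y]
#     [ P^T            0 ] [c] = [0]
# with A_ij = phi(||x_i - x_j||) and P = [1 | x | y | z]. The polynomial
# tail makes every kernel reproduce constant and affine fields exactly and
# keeps the conditionally positive definite kernels (linear, thin-plate
# r^2 log r, multiquadric) well posed. `lambda` is the smoothing weight; at
# 0 the interpolant passes through the data.

rbf_kernels <- c("gaussian", "linear", "quadratic", "multiquadric")

# Kernel profiles as used in the linear system. The linear and multiquadric
# families are conditionally negative definite, so they enter the solve
# negated (-r, -sqrt(1 + (eps r)^2)) - the standard convention under which
# the smoothing term lambda*I acts as a true roughness penalty. At
# smoothing 0 the negation cancels and predictions are unchanged.
rbf_phi <- function(r, kernel, epsilon) {
  switch(kernel,
    gaussian = exp(-(epsilon * r)^2),
    linear = -r,
    # quadratic-order (thin-plate family) kernel r^2 log r, with phi(0) = 0
    quadratic = ifelse(r == 0, 0, r^2 * log(r)),
    multiquadric = -sqrt(1 + (epsilon * r)^2),
    cs_stop("unknown kernel '%s'; choose one of %s",
            "cellstream_parameter_error", kernel,
            paste(rbf_kernels, collapse = ", "))
  )
}

#' Fit a radial basis function interpolant to scattered 3D data
#'
#' Solves the dense RBF linear system for the chosen kernel: Gaussian
#' `exp(-(eps r)^2)`, linear `r`, quadratic (thin-plate family)
#' `r^2 log(r)` with `phi(0) = 0`, or multiquadric `sqrt(1 + (eps r)^2)`.
#' The conditionally negative definite families (linear, multiquadric)
#' enter the system negated so that smoothing acts as a proper penalty;
#' this leaves zero-smoothing predictions unchanged.
#' A degree-1 polynomial tail is appended so constant and affine fields are
#' reproduced exactly. `smoothing > 0` adds that weight to the system diagonal,
#' trading interpolation exactness for a smoother surface. Non-finite
#' values are dropped, duplicate coordinates are averaged (a singular
#' system otherwise), and datasets larger than `max_points` are reduced by
#' a seeded uniform subsample to keep the dense solve conditioned and fast.
#'
#' @param coords `n x 3` matrix of sample positions.
#' @param values length-`n` numeric vector of feature values.
#' @param kernel one of `"gaussian"`, `"linear"`, `"quadratic"`,
#'   `"multiquadric"`.
#' @param epsilon shape parameter for the kernels that use it; `NULL`
#'   (default) sets `1 / mean pairwise distance` of the fitted points.
#' @param smoothing non-negative regularisation weight; 0 interpolates.
#' @param max_points subsampling cap, default 2000.
#' @param value_range optional `c(lo, hi)` display clamp applied by
#'   [evaluate_volume()]; never applied to the fit itself.
#' @param seed RNG seed for the subsample.
#' @return an `rbf_interpolant`; use [predict()] or [evaluate_volume()].
#' @export
fit_rbf <- function(coords, values, kernel = c("gaussian", "linear",
                                               "quadratic", "multiquadric"),
                    epsilon = NULL, smoothing = 0, max_points = 2000L,
                    value_range = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 3)
  values <- as.numeric(values)
  if (nrow(coords) != length(values)) {
    cs_stop("coords has %d rows but values has length %d",
            "cellstream_alignment_error", nrow(coords), length(values))
  }
  if (!is_scalar_num(smoothing) || smoothing < 0) {
    cs_stop("smoothing must be >= 0", "cellstream_parameter_error")
  }
  ok <- is.finite(values) & rowSums(!is.finite(coords)) == 0
  coords <- coords[ok, , drop = FALSE]
  values <- values[ok]

  if (nrow(coords) > max_points) {
    take <- local_seed(seed, sort(sample(nrow(coords), max_points)))
    coords <- coords[take, , drop = FALSE]
    values <- values[take]
  }

  # average duplicate coordinates (singular kernel matrix at smoothing 0)
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "\r")
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    cs_notice("%d duplicate coordinates averaged before RBF fit",
              sum(duplicated(key)))
    coords <- rowsum(coords, grp) / as.vector(table(grp))
    values <- as.numeric(rowsum(values, grp) / as.vector(table(grp)))
  }
  n <- nrow(coords)
  if (n < 4L) {
    cs_stop("RBF fit needs at least 4 distinct finite points, got %d",
            "cellstream_precondition_error", n)
  }

  D <- cross_dist(coords, coords)
  if (is.null(epsilon)) epsilon <- 1 / mean(D[upper.tri(D)])
  if (!is_scalar_num(epsilon) || epsilon <= 0) {
    cs_stop("epsilon must be a positive real", "cellstream_parameter_error")
  }

  A <- rbf_phi(D, kernel, epsilon)
  P <- cbind(1, coords)                     # degree-1 polynomial tail
  M <- rbind(cbind(A + diag(smoothing, n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(values, numeric(4))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    # near-singular kernel block (e.g. wide Gaussian at zero smoothing):
    # retry with a minimal ridge on the kernel diagonal
    ridge <- 1e-10 * max(abs(A))
    cs_notice("RBF system is ill-conditioned; adding ridge %.3g", ridge)
    M[seq_len(n), seq_len(n)] <- A + diag(smoothing + ridge, n)
    solve(M, rhs)
  })

  structure(list(centers = coords, weights = sol[seq_len(n)],
                 poly = sol[n + (1:4)], kernel = kernel, epsilon = epsilon,
                 smoothing = smoothing, value_range = value_range),
            class = "rbf_interpolant")
}

#' Evaluate an RBF interpolant at new points
#'
#' @param object an `rbf_interpolant`.
#' @param newdata `m x 3` matrix (or length-3 vector) of query points.
#' @param ... unused.
#' @return numeric vector of `m` interpolated values (unclamped).
#' @export
predict.rbf_interpolant <- function(object, newdata, ...) {
  pts <- matrix(as.numeric(as.matrix(newdata)), ncol = 3)
  K <- rbf_phi(cross_dist(pts, object$centers), object$kernel, object$epsilon)
  as.numeric(K %*% object$weights + cbind(1, pts) %*% object$poly)
}

#' @export
print.rbf_interpolant <- function(x, ...) {
  cat(sprintf("<rbf_interpolant> %s kernel, %d centers, epsilon %.4g, smoothing %g\n",
              x$kernel, nrow(x$centers), x$epsilon, x$smoothing))
  invisible(x)
}

#' Evaluate an interpolant on every node of a grid
#'
#' Produces a dense scalar volume. When the interpolant carries a
#' `value_range`, node values are clamped to that range after evaluation
#' (display clamping only; the fit is untouched).
#'
#' @param interpolant an `rbf_interpolant` from [fit_rbf()].
#' @param grid a `grid_spec`; its resolution is independent of any
#'   vector-field grid.
#' @param feature_id,modality_name labels carried through to exports.
#' @return a `volume_scalar_field`: list with `grid`, `values` (one per
#'   node, x-fastest order), `feature_id`, `modality_name`, `config`.
#' @export
evaluate_volume <- function(interpolant, grid, feature_id = NA_character_,
                            modality_name = NA_character_) {
  stopifnot(inherits(interpolant, "rbf_interpolant"),
            inherits(grid, "grid_spec"))
  vals <- predict(interpolant, grid_node_positions(grid))
  rng <- interpolant$value_range
  if (!is.null(rng)) {
    vals <- pmin(pmax(vals, rng[1]), rng[2])
  }
  structure(list(grid = grid, values = vals, feature_id = feature_id,
                 modality_name = modality_name,
                 config = interpolant[c("kernel", "epsilon", "smoothing",
                                        "value_range")]),
            class = "volume_scalar_field")
}

#' Volume plot data for one feature of a dataset
#'
#' Convenience composition: builds a grid over the cells at its own
#' `resolution` (independent of any trajectory grid), fits an RBF
#' interpolant to the feature's per-cell values and evaluates it on every
#' node.
#'
#' @param dataset a `cell_embedding`.
#' @param modality modality name, e.g. `"RNA"`.
#' @param feature_id feature (column) id within the modality.
#' @param resolution volume grid resolution (longest axis), default 20.
#' @param padding grid padding fraction.
#' @param ... passed to [fit_rbf()] (`kernel`, `epsilon`, `smoothing`,
#'   `max_points`, `value_range`, `seed`).
#' @return a `volume_scalar_field`.
#' @export
volume_from_feature <- function(dataset, modality, feature_id,
                                resolution = 20L, padding = 0.05, ...) {
  stopifnot(inherits(dataset, "cell_embedding"))
  vals <- get_modality(dataset, modality)
  if (!feature_id %in% colnames(vals)) {
    near <- utils::head(agrep(feature_id, colnames(vals), value = TRUE,
                              ignore.case = TRUE, max.distance = 0.3), 5)
    cs_stop("feature '%s' not in modality '%s'%s",
            "cellstream_lookup_error", feature_id, modality,
            if (length(near)) paste0("; near matches: ",
                                     paste(near, collapse = ", ")) else "")
  }
  grid <- build_grid(dataset$coords, resolution = resolution,
                     padding = padding)
  interp <- fit_rbf(dataset$coords, vals[, feature_id], ...)
  evaluate_volume(interp, grid, feature_id = feature_id,
                  modality_name = modality)
}

#' @export
print.volume_scalar_field <- function(x, ...) {
  cat(sprintf("<volume_scalar_field> %s grid, feature %s (%s), %s kernel\n",
              paste(x$grid$shape, collapse = "x"), x$feature_id,
              x$modality_name, x$config$kernel))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.volume_scalar_field <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  ijk <- grid_ijk(x$grid)
  pos <- grid_node_positions(x$grid)
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             value = x$values)
}
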