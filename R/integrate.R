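# Field-line integration through a grid vector field: explicit Euler and
# classical fourth-order Runge-Kutta steppers, full trajectories with
# early-stopping rules, grid-seeded streamline bundles and truncated
# streamlets.

#' Integration settings
#'
#' @param method `"euler"` or `"rk4"`.
#' @param step_size step length `h` in pseudo-time units; may be negative to
#'   explore backward flow.
#' @param n_steps maximum number of steps (>= 1).
#' @param diff_threshold early stop: integration ends when a step displaces
#'   the point by less than this Euclidean distance (embedding units). A
#'   zero-displacement step always stops integration so trajectories never
#'   contain consecutive duplicate points.
#' @return an `integration_config` list.
#' @export
integration_config <- function(method = c("rk4", "euler"), step_size = 0.1,
                               n_steps = 100L, diff_threshold = 1e-6) {
  method <- match.arg(method)
  if (!is_scalar_num(step_size) || step_size == 0) {
    cs_stop("step_size must be a non-zero real", "cellstream_parameter_error")
  }
  if (!is_count(n_steps, 1L)) {
    cs_stop("n_steps must be a positive integer", "cellstream_parameter_error")
  }
  if (!is_scalar_num(diff_threshold) || diff_threshold < 0) {
    cs_stop("diff_threshold must be >= 0", "cellstream_parameter_error")
  }
  structure(list(method = method, step_size = step_size,
                 n_steps = as.integer(n_steps),
                 diff_threshold = diff_threshold),
            class = "integration_config")
}

#' One explicit Euler step
#'
#' Returns `point + h * v(point)` where `v` is [sample_field()].
#'
#' @param field a `grid_vector_field`.
#' @param point numeric 3-vector.
#' @param h step size.
#' @return the advanced 3-vector.
#' @export
euler_step <- function(field, point, h) {
  point <- as_point3(point)
  as.numeric(point + h * sample_field_many(field, matrix(point, 1))$vectors)
}

#' One classical fourth-order Runge-Kutta step
#'
#' `k1 = v(p)`, `k2 = v(p + h k1 / 2)`, `k3 = v(p + h k2 / 2)`,
#' `k4 = v(p + h k3)`; returns `p + (h/6)(k1 + 2 k2 + 2 k3 + k4)`.
#' Intermediate evaluations falling outside the grid use the sampler's
#' zero-vector convention rather than aborting the step.
#'
#' @inheritParams euler_step
#' @return the advanced 3-vector.
#' @export
rk4_step <- function(field, point, h) {
  point <- as_point3(point)
  v <- function(p) as.numeric(sample_field_many(field, matrix(p, 1))$vectors)
  k1 <- v(point)
  k2 <- v(point + h * k1 / 2)
  k3 <- v(point + h * k2 / 2)
  k4 <- v(point + h * k3)
  as.numeric(point + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4))
}

point_in_grid <- function(grid, p, eps = 1e-12) {
  up <- grid_upper(grid)
  all(p >= grid$origin - eps) && all(p <= up + eps)
}

#' Integrate a field line from a seed point
#'
#' Repeatedly applies the configured stepper. Integration stops when
#' `n_steps` steps are taken (`termination = "completed"`), when a step's
#' displacement drops below `diff_threshold` (`"below-threshold"`; the
#' sub-threshold point is not appended), or when the tentative next point
#' leaves the grid bounding box (`"out-of-domain"`; the last in-domain point
#' is kept). A seed outside the grid yields a length-1 trajectory flagged
#' out-of-domain.
#'
#' @param field a `grid_vector_field`.
#' @param seed numeric 3-vector starting point.
#' @param config an [integration_config()].
#' @return a `trajectory`: list with `points` (m x 3 matrix, `points[1, ]`
#'   is the seed), `seed`, `termination`, `config`.
#' @export
integrate_trajectory <- function(field, seed, config = integration_config()) {
  stopifnot(inherits(field, "grid_vector_field"),
            inherits(config, "integration_config"))
  seed <- as_point3(seed, "seed")
  step_fn <- if (config$method == "euler") euler_step else rk4_step

  pts <- matrix(NA_real_, config$n_steps + 1L, 3)
  pts[1, ] <- seed
  if (!point_in_grid(field$grid, seed)) {
    return(new_trajectory(pts[1, , drop = FALSE], seed, "out-of-domain", config))
  }
  cur <- seed
  n <- 1L
  termination <- "completed"
  for (i in seq_len(config$n_steps)) {
    nxt <- step_fn(field, cur, config$step_size)
    if (!point_in_grid(field$grid, nxt)) {
      termination <- "out-of-domain"
      break
    }
    disp <- sqrt(sum((nxt - cur)^2))
    if (disp < config$diff_threshold || disp == 0) {
      termination <- "below-threshold"
      break
    }
    n <- n + 1L
    pts[n, ] <- nxt
    cur <- nxt
  }
  new_trajectory(pts[seq_len(n), , drop = FALSE], seed, termination, config)
}

new_trajectory <- function(points, seed, termination, config) {
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, seed = seed, termination = termination,
                 config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points (%s, h = %g), termination: %s\n",
              nrow(x$points), x$config$method, x$config$step_size,
              x$termination))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(step = seq_len(nrow(x$points)) - 1L,
             x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
             termination = x$termination)
}

#' Seed coordinates of a named cell
#'
#' @param dataset a `cell_embedding`.
#' @param cell_id cell identifier.
#' @return that cell's coordinate row as a 3-vector.
#' @export
seed_from_cell <- function(dataset, cell_id) {
  stopifnot(inherits(dataset, "cell_embedding"))
  i <- match(cell_id, dataset$cell_ids)
  if (is.na(i)) {
    cs_stop("unknown cell id '%s'", "cellstream_lookup_error", cell_id)
  }
  as.numeric(dataset$coords[i, ])
}

#' Generate streamlines from grid-node seeds
#'
#' Candidate seeds are all grid nodes with occupancy at least
#' `min_occupancy`; a uniformly random fraction `density` of them
#' (`floor(density * n_eligible)` seeds, drawn without replacement,
#' deterministic under `seed`) is integrated forward. Trajectories shorter
#' than 2 points are dropped.
#'
#' @param field a `grid_vector_field`.
#' @param config an [integration_config()].
#' @param density fraction of eligible nodes to seed, in (0, 1].
#' @param min_occupancy minimum node occupancy for a seed.
#' @param seed RNG seed for the subsample.
#' @return a `streamline_set`: list with `trajectories`, `seeding`,
#'   `streamlet_steps` (NULL until [make_streamlets()]).
#' @export
generate_streamlines <- function(field, config = integration_config(),
                                 density = 1, min_occupancy = 1L, seed = 1L) {
  stopifnot(inherits(field, "grid_vector_field"))
  if (!is_scalar_num(density) || density <= 0 || density > 1) {
    cs_stop("density must lie in (0, 1]", "cellstream_parameter_error")
  }
  eligible <- which(field$occupancy >= min_occupancy)
  n_take <- floor(density * length(eligible))
  take <- if (n_take >= length(eligible)) eligible else
    local_seed(seed, sort(sample(eligible, n_take)))
  pos <- grid_node_positions(field$grid)
  trajs <- lapply(take, function(i) integrate_trajectory(field, pos[i, ], config))
  trajs <- trajs[vapply(trajs, function(tr) nrow(tr$points) >= 2L, TRUE)]
  structure(list(trajectories = trajs, seeding = "grid-nodes",
                 streamlet_steps = NULL),
            class = "streamline_set")
}

#' Truncate streamlines into streamlets
#'
#' Each trajectory is cut to its first `streamlet_steps + 1` points (a
#' forward-time prefix, preserving flow directionality); shorter
#' trajectories are left unchanged.
#'
#' @param lines a `streamline_set`.
#' @param streamlet_steps positive integer step budget per streamlet.
#' @return the truncated `streamline_set`, with `streamlet_steps` recorded.
#' @export
make_streamlets <- function(lines, streamlet_steps) {
  stopifnot(inherits(lines, "streamline_set"))
  if (!is_count(streamlet_steps, 1L)) {
    cs_stop("streamlet_steps must be a positive integer",
            "cellstream_parameter_error")
  }
  lines$trajectories <- lapply(lines$trajectories, function(tr) {
    keep <- min(nrow(tr$points), streamlet_steps + 1L)
    tr$points <- tr$points[seq_len(keep), , drop = FALSE]
    tr
  })
  lines$streamlet_steps <- as.integer(streamlet_steps)
  lines
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d trajectories (%s seeding)%s\n",
              length(x$trajectories), x$seeding,
              if (is.null(x$streamlet_steps)) "" else
                sprintf(", streamlets of %d steps", x$streamlet_steps)))
  invisible(x)
}

#' @export
as.data.frame.streamline_set <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  if (!length(x$trajectories)) {
    return(data.frame(trajectory_id = integer(0), step = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      termination = character(0)))
  }
  parts <- lapply(seq_along(x$trajectories), function(i) {
    df <- as.data.frame(x$trajectories[[i]])
    cbind(trajectory_id = i - 1L, df)
  })
  do.call(rbind, parts)
}
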