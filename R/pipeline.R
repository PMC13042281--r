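# End-to-end pipeline driver: load (or generate) a dataset, validate,
# build the grid vector field, run the requested analysis stages and write
# their canonical CSV/JSON outputs plus a checksummed run manifest. A
# serialised run_config plus the same input files reproduces a run's CSV
# outputs byte for byte.

#' Assemble a pipeline configuration
#'
#' All parameters have working defaults; `stages` picks which analyses
#' run. With `input = NULL` a synthetic linear-sink fixture is generated
#' (seeded from `seed`), which makes `run_pipeline(run_config())` a
#' self-contained smoke run.
#'
#' @param input path to a dataset file, or `NULL` for a synthetic fixture.
#' @param format `"auto"` (by extension), `"h5ad"`, `"h5mu"` or `"csv"`.
#' @param coords_key,velocity_key,clone_key,coords_modality loader options
#'   (see [load_h5ad()], [load_h5mu()]).
#' @param stages character subset of `c("field", "streamlines",
#'   "trajectory", "volume", "trends", "clones")`.
#' @param grid_resolution,grid_padding,grid_scale grid parameters
#'   ([build_grid()]).
#' @param field_method,field_bandwidth averaging parameters
#'   ([average_velocities()]).
#' @param method,step_size,n_steps,diff_threshold integration parameters
#'   ([integration_config()]).
#' @param density,min_occupancy,streamlet_steps streamline parameters
#'   ([generate_streamlines()]; `streamlet_steps = NULL` keeps full lines).
#' @param trajectory_cell cell id to seed the single trajectory; `NULL`
#'   uses the first cell.
#' @param trajectory_file optional CSV of a precomputed trajectory
#'   (columns `step,x,y,z`), used by the trends stage when no velocities
#'   are available.
#' @param volume_modality,volume_feature,volume_resolution,volume_kernel,volume_smoothing,volume_range
#'   volume parameters ([volume_from_feature()]); `volume_feature = NULL`
#'   picks the most variable feature.
#' @param trend_modality,n_segments,trend_radius,normalization,k,top_n
#'   trend parameters; `trend_radius = NULL` defaults to 2 voxel edges.
#' @param clone_center,clone_radius clonal query parameters; `clone_center
#'   = NULL` centres on the first clone-labelled cell, `clone_radius =
#'   NULL` defaults to one voxel edge.
#' @param out_dir output directory.
#' @param seed global seed feeding every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, format = "auto",
                       coords_key = "X_umap", velocity_key = "velocity_umap",
                       clone_key = NULL, coords_modality = "rna",
                       stages = c("field", "streamlines"),
                       grid_resolution = 15L, grid_padding = 0.05,
                       grid_scale = 1,
                       field_method = "bin-mean", field_bandwidth = "auto",
                       method = "rk4", step_size = 0.1, n_steps = 100L,
                       diff_threshold = 1e-6,
                       density = 1, min_occupancy = 1L,
                       streamlet_steps = NULL,
                       trajectory_cell = NULL, trajectory_file = NULL,
                       volume_modality = "RNA", volume_feature = NULL,
                       volume_resolution = 12L, volume_kernel = "gaussian",
                       volume_smoothing = 0, volume_range = NULL,
                       trend_modality = "RNA", n_segments = 10L,
                       trend_radius = NULL, normalization = "zscore",
                       k = 6L, top_n = 200L,
                       clone_center = NULL, clone_radius = NULL,
                       out_dir = tempfile("cellstream_run_"), seed = 1L) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$stages, c("field", "streamlines", "trajectory",
                               "volume", "trends", "clones"))
  if (length(bad)) {
    cs_stop("unknown stages: %s", "cellstream_parameter_error",
            paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    cs_stop("trajectory file needs columns x, y, z", "cellstream_io_error")
  }
  pts <- as.matrix(df[, need])
  new_trajectory(pts, pts[1, ], "loaded",
                 integration_config(n_steps = max(1L, nrow(pts) - 1L)))
}

load_any <- function(cfg) {
  fmt <- cfg$format
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(cfg$input)),
                  h5ad = "h5ad", h5mu = "h5mu", "csv")
  }
  switch(fmt,
    h5ad = load_h5ad(cfg$input, cfg$coords_key, cfg$velocity_key,
                     clone_key = cfg$clone_key),
    h5mu = load_h5mu(cfg$input, cfg$coords_key, cfg$velocity_key,
                     coords_modality = cfg$coords_modality,
                     clone_key = cfg$clone_key),
    csv = {
      ds <- load_table(cfg$input)
      if (!is.null(cfg$clone_key) && is.null(ds$clones) &&
          !is.null(ds$annotations) && cfg$clone_key %in% names(ds$annotations)) {
        ds$clones <- as.character(ds$annotations[[cfg$clone_key]])
        ds$annotations[[cfg$clone_key]] <- NULL
      }
      ds
    },
    cs_stop("unknown input format '%s'", "cellstream_parameter_error", fmt))
}

write_csv_artifact <- function(df, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

#' Run the configured pipeline
#'
#' Executes load → validate → grid/field → requested analyses → exports.
#' Stages whose preconditions fail gracefully (e.g. field stages without
#' velocities) are skipped with a notice and recorded in the manifest;
#' stage errors abort with a stage-named message. Every written artifact is
#' listed in the manifest with an md5 checksum; rerunning the same config
#' on the same input reproduces identical checksums for all CSV outputs.
#'
#' @param config a [run_config()].
#' @return the run manifest (list with `artifacts`, `skipped`, `config`),
#'   invisibly; also written to `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  skipped <- character(0)
  stage <- "load"
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      cs_stop("stage '%s' failed: %s", "cellstream_stage_error", stage,
              conditionMessage(e))
    })
  }

  dataset <- wrap({
    if (is.null(config$input)) {
      make_field_dataset(n_cells = 500L, field_kind = "linear-sink",
                         n_features = 10L, noise_sd = 0.05,
                         seed = config$seed)
    } else {
      load_any(config)
    }
  })

  stage <- "validate"
  report <- wrap(validate_for_field(dataset))
  jsonlite::write_json(
    list(n_cells = report$n_cells, has_velocities = report$has_velocities,
         n_nonfinite = report$n_nonfinite,
         bbox_min = unname(report$bbox["min", ]),
         bbox_max = unname(report$bbox["max", ]),
         usable_for_field = report$usable_for_field,
         usable_for_volume = report$usable_for_volume,
         flags = report$flags),
    file.path(config$out_dir, "validation.json"), auto_unbox = TRUE)
  artifacts <- c(artifacts, file.path(config$out_dir, "validation.json"))

  field <- NULL
  grid <- build_grid(dataset$coords, resolution = config$grid_resolution,
                     padding = config$grid_padding, scale = config$grid_scale)
  field_stages <- intersect(config$stages,
                            c("field", "streamlines", "trajectory"))
  if (length(field_stages)) {
    if (!report$usable_for_field) {
      cs_notice("no velocities: skipping stages %s",
                paste(field_stages, collapse = ", "))
      skipped <- c(skipped, field_stages)
    } else {
      stage <- "field"
      field <- wrap(average_velocities(dataset, grid,
                                       method = config$field_method,
                                       bandwidth = config$field_bandwidth))
      if ("field" %in% config$stages) {
        artifacts <- c(artifacts,
                       write_csv_artifact(as.data.frame(field),
                                          config$out_dir, "field.csv"))
      }
    }
  }

  icfg <- integration_config(method = config$method,
                             step_size = config$step_size,
                             n_steps = config$n_steps,
                             diff_threshold = config$diff_threshold)

  if ("streamlines" %in% config$stages && !is.null(field)) {
    stage <- "streamlines"
    lines <- wrap({
      sl <- generate_streamlines(field, icfg, density = config$density,
                                 min_occupancy = config$min_occupancy,
                                 seed = config$seed)
      if (!is.null(config$streamlet_steps)) {
        sl <- make_streamlets(sl, config$streamlet_steps)
      }
      sl
    })
    artifacts <- c(artifacts,
                   write_csv_artifact(as.data.frame(lines), config$out_dir,
                                      "streamlines.csv"))
  }

  trajectory <- NULL
  if ("trajectory" %in% config$stages && !is.null(field)) {
    stage <- "trajectory"
    trajectory <- wrap({
      seed_pt <- if (!is.null(config$trajectory_cell)) {
        seed_from_cell(dataset, config$trajectory_cell)
      } else {
        as.numeric(dataset$coords[1, ])
      }
      integrate_trajectory(field, seed_pt, icfg)
    })
    artifacts <- c(artifacts,
                   write_csv_artifact(as.data.frame(trajectory),
                                      config$out_dir, "trajectory.csv"))
  }

  if ("volume" %in% config$stages) {
    stage <- "volume"
    if (!report$usable_for_volume) {
      cs_notice("no modalities: skipping volume stage")
      skipped <- c(skipped, "volume")
    } else {
      vol <- wrap({
        feat <- config$volume_feature
        vals <- get_modality(dataset, config$volume_modality)
        if (is.null(feat)) {
          feat <- colnames(vals)[which.max(apply(vals, 2, stats::var))]
        }
        volume_from_feature(dataset, config$volume_modality, feat,
                            resolution = config$volume_resolution,
                            kernel = config$volume_kernel,
                            smoothing = config$volume_smoothing,
                            value_range = config$volume_range,
                            seed = config$seed)
      })
      artifacts <- c(artifacts,
                     write_csv_artifact(as.data.frame(vol), config$out_dir,
                                        "volume.csv"))
    }
  }

  if ("trends" %in% config$stages) {
    stage <- "trends"
    path_traj <- trajectory
    if (is.null(path_traj) && !is.null(config$trajectory_file)) {
      path_traj <- wrap(read_trajectory_csv(config$trajectory_file))
    }
    if (is.null(path_traj)) {
      cs_notice("no trajectory available: skipping trends stage")
      skipped <- c(skipped, "trends")
    } else {
      tab <- wrap({
        radius <- config$trend_radius %||% (2 * max(grid$spacing))
        assignment <- assign_segments(path_traj, dataset,
                                      n_segments = config$n_segments,
                                      radius = radius)
        trends <- segment_means(assignment,
                                get_modality(dataset, config$trend_modality),
                                normalization = config$normalization)
        k <- min(config$k, nrow(trends$means))
        clustering <- order_clusters(
          cluster_trends(trends, k = k, seed = config$seed,
                         top_n = config$top_n))
        heatmap_table(trends, clustering)
      })
      artifacts <- c(artifacts,
                     write_csv_artifact(tab, config$out_dir, "trends.csv"))
    }
  }

  if ("clones" %in% config$stages) {
    stage <- "clones"
    if (is.null(dataset$clones)) {
      cs_notice("no clone labels: skipping clones stage")
      skipped <- c(skipped, "clones")
    } else {
      tab <- wrap({
        radius <- config$clone_radius %||% max(grid$spacing)
        center <- config$clone_center %||%
          as.numeric(dataset$coords[which(!is.na(dataset$clones))[1], ])
        query <- select_sphere(dataset, center, radius)
        res <- expand_clones(dataset, query, center = center,
                             radius = radius)
        clone_class_table(dataset, res)
      })
      artifacts <- c(artifacts,
                     write_csv_artifact(tab, config$out_dir, "clones.csv"))
    }
  }

  stage <- "manifest"
  checksums <- tools::md5sum(artifacts)
  manifest <- list(
    artifacts = data.frame(name = basename(artifacts),
                           path = unname(artifacts),
                           md5 = unname(checksums),
                           stringsAsFactors = FALSE),
    skipped = skipped,
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(manifest)
}
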