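# Plotly-based 3D scene building and scene export. Figures are side
# effects; the CSV/JSON tables written elsewhere are the canonical,
# byte-checked outputs. plotly/htmlwidgets are soft dependencies: every
# entry point checks availability and fails with a clear message.

need_plotly <- function() {
  if (!requireNamespace("plotly", quietly = TRUE)) {
    cs_stop("package 'plotly' is required for figure output",
            "cellstream_missing_dependency_error")
  }
}

scene_trace <- function(fig, component, name, palette) {
  if (inherits(component, "cell_embedding")) {
    co <- component$coords
    color <- if (!is.null(component$annotations) &&
                 length(component$annotations)) {
      as.character(component$annotations[[1]])
    } else NULL
    fig <- plotly::add_markers(fig, x = co[, 1], y = co[, 2], z = co[, 3],
                               color = color, colors = palette,
                               marker = list(size = 2), name = name)
  } else if (inherits(component, "grid_vector_field")) {
    g <- cone_glyphs(component)
    fig <- plotly::add_trace(fig, type = "cone", x = g$x, y = g$y, z = g$z,
                             u = g$u, v = g$v, w = g$w, sizemode = "absolute",
                             showscale = FALSE, name = name)
  } else if (inherits(component, "trajectory")) {
    p <- component$points
    fig <- plotly::add_trace(fig, type = "scatter3d", mode = "lines",
                             x = p[, 1], y = p[, 2], z = p[, 3],
                             line = list(width = 6), name = name)
  } else if (inherits(component, "streamline_set")) {
    df <- as.data.frame(component)
    if (nrow(df)) {
      # NA rows break lines between trajectories in a single trace
      parts <- split(df, df$trajectory_id)
      df <- do.call(rbind, lapply(parts, function(p) rbind(p, NA)))
      fig <- plotly::add_trace(fig, type = "scatter3d", mode = "lines",
                               x = df$x, y = df$y, z = df$z,
                               line = list(width = 2), name = name)
    }
  } else if (inherits(component, "volume_scalar_field")) {
    pos <- grid_node_positions(component$grid)
    fig <- plotly::add_trace(fig, type = "volume",
                             x = pos[, 1], y = pos[, 2], z = pos[, 3],
                             value = component$values, opacity = 0.15,
                             surface = list(count = 12), name = name)
  } else {
    cs_stop("cannot render component '%s' of class %s",
            "cellstream_format_error", name, class(component)[1])
  }
  fig
}

component_table <- function(component) {
  if (inherits(component, "cell_embedding")) {
    df <- data.frame(cell_id = component$cell_ids, component$coords)
    if (!is.null(component$velocities)) {
      v <- component$velocities
      colnames(v) <- c("vx", "vy", "vz")
      df <- cbind(df, v)
    }
    df
  } else {
    as.data.frame(component)
  }
}

#' Export a combined 3D scene
#'
#' Layers the requested components — cell scatter, cone glyphs,
#' streamlines, a single trajectory, a scalar volume — into one output.
#' `"html"` writes an interactive plotly scene; `"csv-bundle"` writes each
#' component's underlying data table (`<stem>_<name>.csv`) next to `path`.
#' A `palette` choice only affects figure styling, never the data tables.
#'
#' @param components non-empty named list of renderable objects
#'   (`cell_embedding`, `grid_vector_field`, `trajectory`,
#'   `streamline_set`, `volume_scalar_field`).
#' @param path output file path (for `csv-bundle`, the stem).
#' @param format `"html"` or `"csv-bundle"`. Static raster/vector export is
#'   delegated to plotly's engines and not supported headless.
#' @param palette color palette name for categorical scatter coloring;
#'   `"viridis"` (default) is colorblind-safe.
#' @return the path(s) written, invisibly.
#' @export
export_scene <- function(components, path,
                         format = c("html", "csv-bundle"),
                         palette = "viridis") {
  format <- match.arg(format)
  if (!length(components)) {
    cs_stop("components must be a non-empty named list",
            "cellstream_parameter_error")
  }
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    names(components) <- paste0("component_", seq_along(components))
  }
  if (format == "csv-bundle") {
    stem <- sub("\\.csv$", "", path)
    out <- character(0)
    for (nm in names(components)) {
      p <- paste0(stem, "_", nm, ".csv")
      utils::write.csv(component_table(components[[nm]]), p,
                       row.names = FALSE, quote = FALSE)
      out <- c(out, p)
    }
    return(invisible(out))
  }
  need_plotly()
  if (!requireNamespace("htmlwidgets", quietly = TRUE)) {
    cs_stop("package 'htmlwidgets' is required for HTML scenes",
            "cellstream_missing_dependency_error")
  }
  fig <- plotly::plot_ly()
  for (nm in names(components)) {
    fig <- scene_trace(fig, components[[nm]], nm, palette)
  }
  fig <- plotly::layout(fig, scene = list(aspectmode = "data"))
  htmlwidgets::saveWidget(fig, path, selfcontained = FALSE,
                          libdir = paste0(sub("\\.html?$", "", path), "_files"))
  invisible(path)
}

#' @export
plot.cell_embedding <- function(x, ...) {
  need_plotly()
  scene_trace(plotly::plot_ly(), x, "cells", "viridis")
}

#' @export
plot.grid_vector_field <- function(x, ...) {
  need_plotly()
  scene_trace(plotly::plot_ly(), x, "cones", "viridis")
}

#' @export
plot.trajectory <- function(x, ...) {
  need_plotly()
  scene_trace(plotly::plot_ly(), x, "trajectory", "viridis")
}

#' @export
plot.streamline_set <- function(x, ...) {
  need_plotly()
  scene_trace(plotly::plot_ly(), x, "streamlines", "viridis")
}

#' @export
plot.volume_scalar_field <- function(x, ...) {
  need_plotly()
  scene_trace(plotly::plot_ly(), x, "volume", "viridis")
}

#' Interactive trend heatmap
#'
#' @param trends a [segment_means()] result.
#' @param clustering a matching [cluster_trends()] result (ordered with
#'   [order_clusters()] for the canonical band layout).
#' @return a plotly heatmap of the ordered trend table.
#' @export
plot_trend_heatmap <- function(trends, clustering) {
  need_plotly()
  tab <- heatmap_table(trends, clustering)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  plotly::plot_ly(x = colnames(m), y = rev(tab$feature_id),
                  z = m[rev(seq_len(nrow(m))), , drop = FALSE],
                  type = "heatmap")
}
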