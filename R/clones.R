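# Clonal lineage queries on barcoded datasets: spherical region selection,
# expansion to clonally related cells, and RBF clonal-enrichment volumes.

#' Select cells inside a sphere
#'
#' Models the GUI's "single click" region of interest as a sphere: all
#' cells whose Euclidean distance to `center` is at most `radius`.
#'
#' @param dataset a `cell_embedding`.
#' @param center numeric 3-vector (embedding units).
#' @param radius positive real.
#' @return integer vector of selected cell indices (1-based, sorted).
#' @export
select_sphere <- function(dataset, center, radius) {
  stopifnot(inherits(dataset, "cell_embedding"))
  center <- as_point3(center, "center")
  if (!is_scalar_num(radius) || radius <= 0) {
    cs_stop("radius must be a positive real", "cellstream_parameter_error")
  }
  d2 <- rowSums(sweep(dataset$coords, 2, center)^2)
  unname(which(d2 <= radius^2))
}

#' Expand a cell selection to clonally related cells
#'
#' Collects the clone labels carried by the query cells (ignoring the
#' missing-label sentinel) and returns every other cell sharing any of
#' those labels. Unlabelled cells can never be "related" through the
#' sentinel.
#'
#' @param dataset a `cell_embedding` with clone labels.
#' @param query integer vector of query cell indices.
#' @param center,radius optional provenance of the query (recorded in the
#'   result only).
#' @return a `clone_query_result`: list with `query_cells`,
#'   `related_cells` (disjoint from the query), `clone_ids`, `center`,
#'   `radius`.
#' @export
expand_clones <- function(dataset, query, center = NULL, radius = NULL) {
  stopifnot(inherits(dataset, "cell_embedding"))
  if (is.null(dataset$clones)) {
    cs_stop("dataset carries no clone labels", "cellstream_precondition_error")
  }
  query <- sort(unique(as.integer(query)))
  if (length(query) && (min(query) < 1L || max(query) > n_cells(dataset))) {
    cs_stop("query indices out of range 1..%d", "cellstream_parameter_error",
            n_cells(dataset))
  }
  clone_ids <- unique(dataset$clones[query])
  clone_ids <- sort(clone_ids[!is.na(clone_ids)])
  carriers <- which(dataset$clones %in% clone_ids)
  related <- setdiff(carriers, query)
  structure(list(query_cells = query, related_cells = sort(related),
                 clone_ids = clone_ids, center = center, radius = radius),
            class = "clone_query_result")
}

#' @export
print.clone_query_result <- function(x, ...) {
  cat(sprintf("<clone_query_result> %d query cells, %d related, %d clones\n",
              length(x$query_cells), length(x$related_cells),
              length(x$clone_ids)))
  if (length(x$clone_ids)) {
    cat("  clones:", paste(utils::head(x$clone_ids, 10), collapse = ", "),
        if (length(x$clone_ids) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Per-cell class table of a clone query
#'
#' Background cells are retained with a `"background"` class so exports
#' preserve global context.
#'
#' @param dataset a `cell_embedding`.
#' @param result a [expand_clones()] result.
#' @return data.frame with columns `cell_id`, `class`
#'   (`query`/`related`/`background`) and `clone_id`.
#' @export
clone_class_table <- function(dataset, result) {
  stopifnot(inherits(result, "clone_query_result"))
  cls <- rep("background", n_cells(dataset))
  cls[result$related_cells] <- "related"
  cls[result$query_cells] <- "query"
  clones <- dataset$clones %||% rep(NA_character_, n_cells(dataset))
  data.frame(cell_id = dataset$cell_ids, class = cls,
             clone_id = ifelse(is.na(clones), "", clones))
}

#' Clonal-enrichment volume
#'
#' Builds a 0/1 indicator feature (1 for query and related cells) and
#' interpolates it with [volume_from_feature()] machinery, giving a smooth
#' volume that highlights clone-associated regions of the embedding even
#' when related cells are rare or dispersed.
#'
#' @param dataset a `cell_embedding`.
#' @param result a non-empty [expand_clones()] result.
#' @param resolution volume grid resolution.
#' @param ... passed to [fit_rbf()].
#' @return a `volume_scalar_field` for feature `"clone_indicator"`.
#' @export
clone_density_volume <- function(dataset, result, resolution = 20L, ...) {
  stopifnot(inherits(dataset, "cell_embedding"),
            inherits(result, "clone_query_result"))
  members <- union(result$query_cells, result$related_cells)
  if (!length(members)) {
    cs_stop("clone query selected no cells; nothing to interpolate",
            "cellstream_empty_selection_error")
  }
  indicator <- as.numeric(seq_len(n_cells(dataset)) %in% members)
  grid <- build_grid(dataset$coords, resolution = resolution)
  interp <- fit_rbf(dataset$coords, indicator, ...)
  evaluate_volume(interp, grid, feature_id = "clone_indicator",
                  modality_name = "clones")
}
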