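#' In-memory representation of a 3D single-cell embedding
#'
#' A `cell_embedding` bundles everything downstream analyses need: per-cell
#' 3D coordinates (typically a 3-component UMAP), optional per-cell velocity
#' vectors projected into the same space, categorical or continuous cell
#' annotations, one or more feature matrices ("modalities", e.g. RNA
#' expression or ADT epitope levels), and optional clone barcodes for
#' lineage-traced data.
#'
#' @param coords numeric matrix with one row per cell and 3 columns
#'   (embedding units). Matrices with more than 3 columns are truncated to
#'   the first three with a notice; downstream analysis is strictly 3D.
#' @param velocities optional numeric matrix, same shape rules as `coords`,
#'   holding the embedding-space velocity vector of each cell
#'   (embedding units per unit pseudo-time). `NULL` when the dataset
#'   carries no velocity layer.
#' @param cell_ids character vector of unique cell identifiers. Defaults to
#'   `"cell_0" ... "cell_<n-1>"`.
#' @param annotations data.frame of per-cell annotations (factors, character
#'   or numeric columns), or `NULL`.
#' @param modalities named list of feature matrices, each an
#'   `n_cells x n_features` numeric matrix with unique column names
#'   (feature ids). See [modality_matrix()].
#' @param clones optional character vector of clone labels; `NA` and `""`
#'   mark cells without a barcode.
#'
#' @return An object of class `cell_embedding`.
#' @seealso [validate_for_field()], [load_table()], [load_h5ad()],
#'   [make_field_dataset()]
#' @export
cell_embedding <- function(coords, velocities = NULL, cell_ids = NULL,
                           annotations = NULL, modalities = list(),
                           clones = NULL) {
  coords <- check_coord_matrix(coords, "coords")
  n <- nrow(coords)
  if (n < 1L) cs_stop("a dataset needs at least one cell", "cellstream_parameter_error")

  if (!is.null(velocities)) {
    velocities <- check_coord_matrix(velocities, "velocities")
    if (nrow(velocities) != n) {
      cs_stop("velocities has %d rows but coords has %d cells",
              "cellstream_alignment_error", nrow(velocities), n)
    }
  }

  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell_", seq_len(n) - 1L)
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) {
    cs_stop("cell_ids has length %d but there are %d cells",
            "cellstream_alignment_error", length(cell_ids), n)
  }
  if (anyDuplicated(cell_ids)) {
    cs_stop("cell ids must be unique (%d duplicated)",
            "cellstream_parameter_error", sum(duplicated(cell_ids)))
  }

  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (nrow(annotations) != n) {
      cs_stop("annotations has %d rows but there are %d cells",
              "cellstream_alignment_error", nrow(annotations), n)
    }
    rownames(annotations) <- cell_ids
  }

  if (length(modalities)) {
    if (is.null(names(modalities)) || any(!nzchar(names(modalities)))) {
      cs_stop("modalities must be a named list", "cellstream_parameter_error")
    }
    modalities <- lapply(names(modalities), function(nm) {
      modality_matrix(modalities[[nm]], modality_name = nm, n_cells = n)
    })
    names(modalities) <- vapply(modalities, function(m) attr(m, "modality_name"), "")
  }

  if (!is.null(clones)) {
    clones <- as.character(clones)
    if (length(clones) != n) {
      cs_stop("clones has length %d but there are %d cells",
              "cellstream_alignment_error", length(clones), n)
    }
    clones[!is.na(clones) & clones == ""] <- NA_character_
  }

  rownames(coords) <- cell_ids
  if (!is.null(velocities)) rownames(velocities) <- cell_ids

  structure(
    list(cell_ids = cell_ids, coords = coords, velocities = velocities,
         annotations = annotations, modalities = modalities, clones = clones),
    class = "cell_embedding"
  )
}

# Coerce to an n x 3 numeric matrix; >3 columns truncated (3D convention),
# <3 is a dimensionality error, non-finite values are rejected.
check_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) < 3L) {
    cs_stop("`%s` needs at least 3 columns, got %d",
            "cellstream_dimensionality_error", what, ncol(x))
  }
  if (ncol(x) > 3L) {
    cs_notice("`%s` has %d columns; using the first 3 (3D convention)",
              what, ncol(x))
    x <- x[, 1:3, drop = FALSE]
  }
  if (any(!is.finite(x))) {
    cs_stop("`%s` contains %d non-finite values",
            "cellstream_parameter_error", what, sum(!is.finite(x)))
  }
  colnames(x) <- c("x", "y", "z")
  x
}

#' Construct a modality feature matrix
#'
#' @param values numeric `n_cells x n_features` matrix; column names are the
#'   feature ids and must be unique.
#' @param modality_name modality label, e.g. `"RNA"` or `"ADT"`.
#' @param n_cells expected number of cells (checked when given).
#' @return The matrix with a `modality_name` attribute.
#' @export
modality_matrix <- function(values, modality_name, n_cells = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(n_cells) && nrow(values) != n_cells) {
    cs_stop("modality '%s' has %d rows but the dataset has %d cells",
            "cellstream_alignment_error", modality_name, nrow(values), n_cells)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature_", seq_len(ncol(values)) - 1L)
  }
  if (anyDuplicated(colnames(values))) {
    cs_stop("modality '%s' has duplicated feature ids",
            "cellstream_parameter_error", modality_name)
  }
  attr(values, "modality_name") <- modality_name
  values
}

#' Number of cells in a dataset
#' @param dataset a `cell_embedding`.
#' @return integer cell count.
#' @export
n_cells <- function(dataset) {
  stopifnot(inherits(dataset, "cell_embedding"))
  nrow(dataset$coords)
}

#' Get one modality's feature matrix
#' @param dataset a `cell_embedding`.
#' @param modality modality name.
#' @return the feature matrix.
#' @export
get_modality <- function(dataset, modality) {
  m <- dataset$modalities[[modality]]
  if (is.null(m)) {
    cs_stop("modality '%s' not found; available: %s",
            "cellstream_lookup_error", modality,
            paste(names(dataset$modalities), collapse = ", ") %||% "none")
  }
  m
}

#' Validate a dataset for vector-field and volume analyses
#'
#' Produces a report rather than failing: lists cell count, bounding box,
#' presence of velocities and flags whether the dataset can drive field-line
#' integration (`usable_for_field`, requires velocities) and volume
#' interpolation (`usable_for_volume`, requires only coordinates and a
#' modality).
#'
#' @param dataset a `cell_embedding`.
#' @return a list of class `field_validation` with elements `n_cells`,
#'   `has_velocities`, `n_nonfinite`, `bbox` (2 x 3, rows min/max),
#'   `usable_for_field`, `usable_for_volume`, `flags`.
#' @export
validate_for_field <- function(dataset) {
  stopifnot(inherits(dataset, "cell_embedding"))
  bbox <- rbind(min = apply(dataset$coords, 2, min),
                max = apply(dataset$coords, 2, max))
  has_vel <- !is.null(dataset$velocities)
  flags <- character(0)
  if (!has_vel) flags <- c(flags, "no-velocity")
  if (!length(dataset$modalities)) flags <- c(flags, "no-modality")
  structure(
    list(n_cells = n_cells(dataset),
         has_velocities = has_vel,
         n_nonfinite = sum(!is.finite(dataset$coords)) +
           if (has_vel) sum(!is.finite(dataset$velocities)) else 0L,
         bbox = bbox,
         usable_for_field = has_vel,
         usable_for_volume = length(dataset$modalities) > 0L,
         flags = flags),
    class = "field_validation"
  )
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("<cell_embedding> %d cells\n", n_cells(x)))
  cat(sprintf("  velocities : %s\n", if (is.null(x$velocities)) "absent" else "present"))
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %s\n", paste(names(x$annotations), collapse = ", ")))
  }
  if (length(x$modalities)) {
    for (nm in names(x$modalities)) {
      cat(sprintf("  modality %-6s: %d features\n", nm, ncol(x$modalities[[nm]])))
    }
  }
  if (!is.null(x$clones)) {
    cat(sprintf("  clones     : %d labelled, %d unlabelled\n",
                sum(!is.na(x$clones)), sum(is.na(x$clones))))
  }
  invisible(x)
}

#' @export
print.field_validation <- function(x, ...) {
  cat(sprintf("<field_validation> %d cells, %d non-finite values\n",
              x$n_cells, x$n_nonfinite))
  cat(sprintf("  bbox min: %s\n", paste(signif(x$bbox["min", ], 5), collapse = ", ")))
  cat(sprintf("  bbox max: %s\n", paste(signif(x$bbox["max", ], 5), collapse = ", ")))
  cat(sprintf("  usable_for_field : %s\n", x$usable_for_field))
  cat(sprintf("  usable_for_volume: %s\n", x$usable_for_volume))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
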