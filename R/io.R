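# Readers and writers for the three supported container formats:
# delimited text (CSV/TSV), h5ad (AnnData on-disk layout) and h5mu (MuData
# layout). HDF5 access goes through rhdf5. All matrices are densified on
# load; datasets at the scale this package targets fit in memory.
#
# Orientation note: HDF5 stores arrays row-major while R is column-major, so
# a (n_cells, k) array written by Python tools arrives in R with dim
# (k, n_cells). `orient_cells_rows()` resolves this by matching the known
# cell count.

#' Load a delimited text dataset
#'
#' Reads a CSV/TSV table with a header row into a [cell_embedding()]. The
#' `column_map` assigns table columns to roles: `x`, `y`, `z` (required),
#' `vx`, `vy`, `vz` (optional velocity components), `id` (optional cell id
#' column), `clone` (optional clone barcode column) and `annotations`
#' (character vector of annotation columns). Remaining numeric columns are
#' collected into a single modality unless `modality_columns = "none"`.
#'
#' @param path file path.
#' @param column_map named list assigning roles to column names; see above.
#' @param delimiter field separator, default `","`.
#' @param modality_columns `"auto"` (default) to turn leftover numeric
#'   columns into one modality, `"none"` to ignore them, or a character
#'   vector of column names.
#' @param modality_name name of the modality built from leftover columns.
#' @return a `cell_embedding`.
#' @export
load_table <- function(path,
                       column_map = list(x = "x", y = "y", z = "z",
                                         vx = "vx", vy = "vy", vz = "vz"),
                       delimiter = ",",
                       modality_columns = "auto",
                       modality_name = "RNA") {
  if (!file.exists(path)) {
    cs_stop("file not found: %s", "cellstream_io_error", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), comment.char = "",
                           quote = "\"")
  need <- function(role) {
    col <- column_map[[role]]
    if (is.null(col)) return(NULL)
    if (!col %in% names(raw)) {
      cs_stop("column '%s' (role %s) not in table; available: %s",
              "cellstream_lookup_error", col, role,
              paste(names(raw), collapse = ", "))
    }
    col
  }
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      cs_stop("non-numeric value '%s' in column '%s' at row %d",
              "cellstream_parse_error", raw[[col]][bad[1]], col, bad[1])
    }
    v
  }

  xyz <- vapply(c("x", "y", "z"), function(r) {
    col <- need(r)
    if (is.null(col)) cs_stop("column_map must assign '%s'",
                              "cellstream_parameter_error", r)
    col
  }, "")
  coords <- do.call(cbind, lapply(xyz, num_col))

  # velocity roles are optional: mapped columns absent from the table mean
  # "no velocity layer", but a partial triple is an error
  vel_cols <- unlist(lapply(c("vx", "vy", "vz"), function(r) {
    col <- column_map[[r]]
    if (is.null(col) || !col %in% names(raw)) NULL else col
  }))
  velocities <- NULL
  if (length(vel_cols) == 3L) {
    velocities <- do.call(cbind, lapply(vel_cols, num_col))
  } else if (length(vel_cols) > 0L) {
    cs_stop("velocity columns must cover all of vx, vy, vz (found %d)",
            "cellstream_dimensionality_error", length(vel_cols))
  }

  id_col <- need("id")
  cell_ids <- if (!is.null(id_col)) raw[[id_col]] else NULL

  clone_col <- need("clone")
  clones <- if (!is.null(clone_col)) raw[[clone_col]] else NULL

  ann_cols <- intersect(column_map$annotations %||% character(0), names(raw))
  used <- c(xyz, vel_cols, id_col, clone_col, ann_cols)

  # any leftover column that parses fully numeric is a candidate feature
  leftover <- setdiff(names(raw), used)
  if (identical(modality_columns, "auto")) {
    feat_cols <- leftover[vapply(leftover, function(col) {
      all(is.finite(suppressWarnings(as.numeric(raw[[col]]))))
    }, TRUE)]
    ann_cols <- c(ann_cols, setdiff(leftover, feat_cols))
  } else if (identical(modality_columns, "none")) {
    feat_cols <- character(0)
    ann_cols <- c(ann_cols, leftover)
  } else {
    feat_cols <- intersect(modality_columns, names(raw))
    ann_cols <- c(ann_cols, setdiff(leftover, feat_cols))
  }

  modalities <- list()
  if (length(feat_cols)) {
    vals <- do.call(cbind, lapply(feat_cols, num_col))
    colnames(vals) <- feat_cols
    modalities[[modality_name]] <- vals
  }

  annotations <- NULL
  if (length(ann_cols)) {
    annotations <- raw[, ann_cols, drop = FALSE]
    # numeric-looking annotation columns come back numeric
    for (col in ann_cols) {
      v <- suppressWarnings(as.numeric(annotations[[col]]))
      if (all(is.finite(v))) annotations[[col]] <- v
    }
  }

  cell_embedding(coords, velocities = velocities, cell_ids = cell_ids,
                 annotations = annotations, modalities = modalities,
                 clones = clones)
}

#' Write a dataset as a delimited text table
#'
#' Inverse of [load_table()]: columns `cell_id,x,y,z[,vx,vy,vz]`, one column
#' per annotation, a `clone` column when clone labels are present, and one
#' column per feature of `modality` (if any).
#'
#' @param dataset a `cell_embedding`.
#' @param path output path.
#' @param delimiter field separator.
#' @param modality which modality to include, or `NULL` for none.
#' @return `path`, invisibly.
#' @export
write_table <- function(dataset, path, delimiter = ",", modality = "RNA") {
  df <- data.frame(cell_id = dataset$cell_ids,
                   dataset$coords, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$velocities)) {
    v <- dataset$velocities
    colnames(v) <- c("vx", "vy", "vz")
    df <- cbind(df, v)
  }
  if (!is.null(dataset$annotations)) df <- cbind(df, dataset$annotations)
  if (!is.null(dataset$clones)) df$clone <- dataset$clones
  if (!is.null(modality) && modality %in% names(dataset$modalities)) {
    df <- cbind(df, dataset$modalities[[modality]])
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- HDF5 helpers -----------------------------------------------------------

h5_children <- function(listing, group) {
  listing$name[listing$group == group]
}

orient_cells_rows <- function(m, n, what) {
  if (length(dim(m)) != 2L) {
    cs_stop("'%s' is not a 2D array", "cellstream_dimensionality_error", what)
  }
  if (nrow(m) == n) return(m)
  if (ncol(m) == n) return(t(m))
  cs_stop("'%s' has dims %d x %d; neither matches the %d cells",
          "cellstream_alignment_error", what, nrow(m), ncol(m), n)
}

# Read an AnnData-style dataframe group (obs/var): index vector + columns,
# decoding categorical sub-groups (categories + 0-based codes, -1 = NA).
read_h5_dataframe <- function(path, group) {
  at <- rhdf5::h5readAttributes(path, group)
  idx_name <- as.character(at[["_index"]] %||% "_index")
  listing <- rhdf5::h5ls(path)
  kids <- h5_children(listing, group)
  if (!idx_name %in% kids) {
    cs_stop("no index dataset '%s' under %s", "cellstream_io_error",
            idx_name, group)
  }
  index <- as.character(rhdf5::h5read(path, paste0(group, "/", idx_name)))
  cols <- setdiff(kids, idx_name)
  if (!is.null(at[["column-order"]])) {
    cols <- intersect(as.character(at[["column-order"]]), cols)
  }
  out <- list()
  for (col in cols) {
    obj <- paste0(group, "/", col)
    is_grp <- listing$otype[listing$group == group & listing$name == col] == "H5I_GROUP"
    if (isTRUE(is_grp)) {
      cats <- as.character(rhdf5::h5read(path, paste0(obj, "/categories")))
      codes <- as.integer(rhdf5::h5read(path, paste0(obj, "/codes")))
      v <- factor(ifelse(codes < 0L, NA_character_, cats[codes + 1L]),
                  levels = cats)
    } else {
      v <- rhdf5::h5read(path, obj)
      v <- if (is.raw(v)) as.integer(v) else as.vector(v)
    }
    out[[col]] <- v
  }
  list(index = index, columns = out)
}

# Read X (dense dataset or csr/csc group) as a dense n_cells x n_features
# matrix in cell-row orientation.
read_h5_matrix <- function(path, obj, n_obs, n_var, what) {
  listing <- rhdf5::h5ls(path)
  parts <- strsplit(sub("^/", "", obj), "/")[[1]]
  grp <- paste0("/", paste(parts[-length(parts)], collapse = "/"))
  if (grp == "/") grp <- "/"
  nm <- parts[length(parts)]
  otype <- listing$otype[listing$group == grp & listing$name == nm]
  if (!length(otype)) return(NULL)
  if (otype == "H5I_GROUP") {
    at <- rhdf5::h5readAttributes(path, obj)
    enc <- as.character(at[["encoding-type"]] %||% "")
    data <- as.numeric(rhdf5::h5read(path, paste0(obj, "/data")))
    indices <- as.integer(rhdf5::h5read(path, paste0(obj, "/indices")))
    indptr <- as.integer(rhdf5::h5read(path, paste0(obj, "/indptr")))
    dims <- as.integer(at[["shape"]] %||% c(n_obs, n_var))
    dense <- matrix(0, dims[1], dims[2])
    if (grepl("csr", enc)) {
      rows <- rep.int(seq_len(dims[1]), diff(indptr))
      dense[cbind(rows, indices + 1L)] <- data
    } else {
      cols <- rep.int(seq_len(dims[2]), diff(indptr))
      dense[cbind(indices + 1L, cols)] <- data
    }
    return(orient_cells_rows(dense, n_obs, what))
  }
  m <- rhdf5::h5read(path, obj)
  storage.mode(m) <- "double"
  orient_cells_rows(m, n_obs, what)
}

# Read one AnnData-like group (a whole h5ad file, or one /mod/<name> of an
# h5mu file). Returns cell ids, obs columns, obsm arrays, X and var ids.
read_adata_group <- function(path, prefix = "") {
  listing <- rhdf5::h5ls(path)
  grp <- function(x) paste0(prefix, "/", x)
  root_kids <- h5_children(listing, if (prefix == "") "/" else prefix)
  if (!"obs" %in% root_kids) {
    cs_stop("no 'obs' group under %s in %s", "cellstream_io_error",
            if (prefix == "") "/" else prefix, path)
  }
  obs <- read_h5_dataframe(path, grp("obs"))
  n <- length(obs$index)

  obsm <- list()
  if ("obsm" %in% root_kids) {
    for (key in h5_children(listing, grp("obsm"))) {
      obsm[[key]] <- orient_cells_rows(
        rhdf5::h5read(path, paste0(grp("obsm"), "/", key)), n,
        paste0("obsm/", key))
    }
  }

  var_ids <- NULL
  X <- NULL
  if ("var" %in% root_kids) {
    var_ids <- read_h5_dataframe(path, grp("var"))$index
  }
  if ("X" %in% root_kids && !is.null(var_ids)) {
    X <- read_h5_matrix(path, grp("X"), n, length(var_ids), "X")
    if (!is.null(X)) colnames(X) <- var_ids
  }
  list(cell_ids = obs$index, obs = obs$columns, obsm = obsm,
       X = X, var_ids = var_ids)
}

pick_obsm <- function(obsm, key, what, n) {
  if (is.null(key)) return(NULL)
  if (!key %in% names(obsm)) {
    cs_stop("obsm key '%s' (%s) not found; available: %s",
            "cellstream_lookup_error", key, what,
            paste(names(obsm), collapse = ", ") %||% "none")
  }
  m <- obsm[[key]]
  if (ncol(m) < 3L) {
    cs_stop("obsm '%s' has %d columns; 3 are required",
            "cellstream_dimensionality_error", key, ncol(m))
  }
  if (ncol(m) > 3L) {
    cs_notice("obsm '%s' has %d columns; using the first 3", key, ncol(m))
  }
  m[, 1:3, drop = FALSE]
}

build_from_parts <- function(parts, coords_key, velocity_key, clone_key,
                             modalities) {
  coords <- pick_obsm(parts$obsm, coords_key, "coordinates",
                      length(parts$cell_ids))
  if (is.null(coords)) {
    cs_stop("a coordinates obsm key is required", "cellstream_parameter_error")
  }
  velocities <- pick_obsm(parts$obsm, velocity_key, "velocities",
                          length(parts$cell_ids))
  ann <- parts$obs
  clones <- NULL
  if (!is.null(clone_key)) {
    if (!clone_key %in% names(ann)) {
      cs_stop("clone annotation '%s' not found; available: %s",
              "cellstream_lookup_error", clone_key,
              paste(names(ann), collapse = ", ") %||% "none")
    }
    clones <- as.character(ann[[clone_key]])
    ann[[clone_key]] <- NULL
  }
  annotations <- if (length(ann)) as.data.frame(ann, stringsAsFactors = FALSE)
                 else NULL
  cell_embedding(coords, velocities = velocities, cell_ids = parts$cell_ids,
                 annotations = annotations, modalities = modalities,
                 clones = clones)
}

#' Load a single-modality h5ad dataset
#'
#' Reads the AnnData on-disk layout: the embedding and velocity arrays come
#' from `obsm`, cell annotations from `obs` (categoricals decoded), and the
#' expression matrix `X` (dense or CSR/CSC sparse, densified) becomes one
#' modality named `modality_name`.
#'
#' @param path h5ad file path.
#' @param coords_key `obsm` key of the 3D embedding (first 3 columns used).
#' @param velocity_key `obsm` key of the projected velocities, or `NULL` if
#'   the dataset has none.
#' @param clone_key optional `obs` column holding clone barcodes.
#' @param modality_name modality name for `X`, default `"RNA"`.
#' @return a `cell_embedding`.
#' @export
load_h5ad <- function(path, coords_key = "X_umap",
                      velocity_key = "velocity_umap", clone_key = NULL,
                      modality_name = "RNA") {
  if (!file.exists(path)) {
    cs_stop("file not found: %s", "cellstream_io_error", path)
  }
  parts <- read_adata_group(path, "")
  modalities <- list()
  if (!is.null(parts$X)) modalities[[modality_name]] <- parts$X
  build_from_parts(parts, coords_key, velocity_key, clone_key, modalities)
}

#' Load a multimodal h5mu dataset
#'
#' Reads the MuData layout: every group under `/mod` becomes one modality,
#' all aligned on a shared cell set. Embedding and velocity arrays are taken
#' from `obsm` of `coords_modality`; global `obs` columns (if any) become
#' annotations.
#'
#' @param path h5mu file path.
#' @param coords_key,velocity_key `obsm` keys inside `coords_modality`.
#' @param coords_modality name of the modality holding the embedding arrays.
#' @param clone_key optional global `obs` column holding clone barcodes.
#' @return a `cell_embedding` with one modality per `/mod` group.
#' @export
load_h5mu <- function(path, coords_key = "X_umap",
                      velocity_key = "velocity_umap",
                      coords_modality = "rna", clone_key = NULL) {
  if (!file.exists(path)) {
    cs_stop("file not found: %s", "cellstream_io_error", path)
  }
  listing <- rhdf5::h5ls(path)
  mods <- h5_children(listing, "/mod")
  if (!length(mods)) {
    cs_stop("no modalities under /mod in %s", "cellstream_io_error", path)
  }
  if (!coords_modality %in% mods) {
    cs_stop("coords_modality '%s' not found; available: %s",
            "cellstream_lookup_error", coords_modality,
            paste(mods, collapse = ", "))
  }
  parts_by_mod <- lapply(mods, function(m) read_adata_group(path, paste0("/mod/", m)))
  names(parts_by_mod) <- mods

  ref <- parts_by_mod[[coords_modality]]
  for (m in mods) {
    ids <- parts_by_mod[[m]]$cell_ids
    if (!identical(ids, ref$cell_ids)) {
      cs_stop("modality '%s' has %d cells but '%s' has %d; modalities must share one cell set",
              "cellstream_alignment_error", m, length(ids),
              coords_modality, length(ref$cell_ids))
    }
  }

  modalities <- list()
  for (m in mods) {
    if (!is.null(parts_by_mod[[m]]$X)) modalities[[m]] <- parts_by_mod[[m]]$X
  }

  # global annotations, if the file carries a root obs table
  glob <- tryCatch(read_h5_dataframe(path, "/obs"), error = function(e) NULL)
  parts <- ref
  if (!is.null(glob) && identical(glob$index, ref$cell_ids) && length(glob$columns)) {
    parts$obs <- utils::modifyList(parts$obs, glob$columns)
  }
  build_from_parts(parts, coords_key, velocity_key, clone_key, modalities)
}

# ---- HDF5 writers -----------------------------------------------------------

h5_attrs <- function(path, obj, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  for (nm in names(attrs)) {
    val <- attrs[[nm]]
    if (length(val)) {
      rhdf5::h5writeAttribute(val, oid, nm,
                              asScalar = length(val) == 1L && !is.list(val),
                              variableLengthString = TRUE,
                              encoding = "UTF-8")
    } else {
      # zero-length attribute (e.g. an empty column-order): create the
      # variable-length string attribute directly; there is no data to write
      sid <- rhdf5::H5Screate_simple(0L)
      tid <- rhdf5::H5Tcopy("H5T_C_S1")
      rhdf5::H5Tset_size(tid, NULL)
      aid <- rhdf5::H5Acreate(oid, nm, tid, sid)
      rhdf5::H5Aclose(aid)
      rhdf5::H5Sclose(sid)
    }
  }
  invisible(NULL)
}

# Write one AnnData-like group (prefix "" = whole file). Matrices are
# transposed before h5write so the on-disk logical shape is (n_cells, k),
# matching what Python writers produce.
write_adata_group <- function(dataset, path, prefix, coords_key, velocity_key,
                              modality = NULL, include_annotations = TRUE) {
  grp <- function(x) if (prefix == "") x else paste0(prefix, "/", x)
  if (prefix != "") rhdf5::h5createGroup(path, prefix)

  rhdf5::h5createGroup(path, grp("obs"))
  rhdf5::h5write(dataset$cell_ids, path, grp("obs/_index"))
  cols <- character(0)
  if (include_annotations && !is.null(dataset$annotations)) {
    for (col in names(dataset$annotations)) {
      v <- dataset$annotations[[col]]
      if (is.factor(v)) v <- as.character(v)
      rhdf5::h5write(v, path, grp(paste0("obs/", col)))
      enc <- if (is.character(v)) "string-array" else "array"
      h5_attrs(path, grp(paste0("obs/", col)),
               list(`encoding-type` = enc, `encoding-version` = "0.2.0"))
      cols <- c(cols, col)
    }
  }
  if (include_annotations && !is.null(dataset$clones)) {
    v <- dataset$clones
    v[is.na(v)] <- ""
    rhdf5::h5write(v, path, grp("obs/clone"))
    h5_attrs(path, grp("obs/clone"),
             list(`encoding-type` = "string-array",
                  `encoding-version` = "0.2.0"))
    cols <- c(cols, "clone")
  }
  h5_attrs(path, grp("obs"),
           list(`_index` = "_index", `column-order` = cols,
                `encoding-type` = "dataframe", `encoding-version` = "0.2.0"))
  h5_attrs(path, grp("obs/_index"),
           list(`encoding-type` = "string-array", `encoding-version` = "0.2.0"))

  rhdf5::h5createGroup(path, grp("obsm"))
  h5_attrs(path, grp("obsm"),
           list(`encoding-type` = "dict", `encoding-version` = "0.1.0"))
  rhdf5::h5write(t(dataset$coords), path, grp(paste0("obsm/", coords_key)))
  h5_attrs(path, grp(paste0("obsm/", coords_key)),
           list(`encoding-type` = "array", `encoding-version` = "0.2.0"))
  if (!is.null(dataset$velocities) && !is.null(velocity_key)) {
    rhdf5::h5write(t(dataset$velocities), path, grp(paste0("obsm/", velocity_key)))
    h5_attrs(path, grp(paste0("obsm/", velocity_key)),
             list(`encoding-type` = "array", `encoding-version` = "0.2.0"))
  }

  vals <- if (!is.null(modality)) dataset$modalities[[modality]] else NULL
  if (!is.null(vals)) {
    rhdf5::h5createGroup(path, grp("var"))
    rhdf5::h5write(colnames(vals), path, grp("var/_index"))
    h5_attrs(path, grp("var"),
             list(`_index` = "_index", `column-order` = character(0),
                  `encoding-type` = "dataframe", `encoding-version` = "0.2.0"))
    h5_attrs(path, grp("var/_index"),
             list(`encoding-type` = "string-array", `encoding-version` = "0.2.0"))
    rhdf5::h5write(t(vals), path, grp("X"))
    h5_attrs(path, grp("X"),
             list(`encoding-type` = "array", `encoding-version` = "0.2.0"))
  }
  if (prefix != "") {
    h5_attrs(path, prefix,
             list(`encoding-type` = "anndata", `encoding-version` = "0.1.0"))
  }
  invisible(NULL)
}

#' Write a dataset in the h5ad layout
#'
#' Stores coordinates and velocities under `obsm`, annotations and clone
#' labels under `obs`, and the chosen modality as `X`. The file round-trips
#' through [load_h5ad()] and follows the AnnData on-disk conventions
#' (cell-major arrays, string index datasets, encoding attributes).
#'
#' @param dataset a `cell_embedding`.
#' @param path output path (overwritten).
#' @param coords_key,velocity_key `obsm` keys to write.
#' @param modality which modality becomes `X`; default first, `NULL` for none.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(dataset, path, coords_key = "X_umap",
                       velocity_key = "velocity_umap",
                       modality = names(dataset$modalities)[1] %||% NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  write_adata_group(dataset, path, "", coords_key, velocity_key, modality)
  h5_attrs(path, "/", list(`encoding-type` = "anndata",
                           `encoding-version` = "0.1.0"))
  invisible(path)
}

#' Write a dataset in the h5mu layout
#'
#' One `/mod/<name>` group per modality, all sharing the cell set; the
#' embedding/velocity arrays go into `coords_modality`'s `obsm`, annotations
#' and clone labels into the global `obs`.
#'
#' @inheritParams write_h5ad
#' @param coords_modality modality whose `obsm` receives the embedding.
#' @return `path`, invisibly.
#' @export
write_h5mu <- function(dataset, path, coords_key = "X_umap",
                       velocity_key = "velocity_umap",
                       coords_modality = names(dataset$modalities)[1] %||% "rna") {
  if (!length(dataset$modalities)) {
    cs_stop("h5mu needs at least one modality", "cellstream_parameter_error")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "mod")
  for (m in names(dataset$modalities)) {
    write_adata_group(dataset, path, paste0("mod/", m),
                      coords_key,
                      if (m == coords_modality) velocity_key else NULL,
                      modality = m, include_annotations = FALSE)
  }
  # global obs: index + annotations + clones
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(dataset$cell_ids, path, "obs/_index")
  cols <- character(0)
  if (!is.null(dataset$annotations)) {
    for (col in names(dataset$annotations)) {
      v <- dataset$annotations[[col]]
      if (is.factor(v)) v <- as.character(v)
      rhdf5::h5write(v, path, paste0("obs/", col))
      cols <- c(cols, col)
    }
  }
  if (!is.null(dataset$clones)) {
    v <- dataset$clones
    v[is.na(v)] <- ""
    rhdf5::h5write(v, path, "obs/clone")
    cols <- c(cols, "clone")
  }
  h5_attrs(path, "obs",
           list(`_index` = "_index", `column-order` = cols,
                `encoding-type` = "dataframe", `encoding-version` = "0.2.0"))
  h5_attrs(path, "/", list(`encoding-type` = "mudata",
                           `encoding-version` = "0.1.0"))
  invisible(path)
}
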