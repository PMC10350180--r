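#' Read a single-neuron reconstruction from JSON
#'
#' Reads one neuron in the whole-brain reconstruction JSON dialect used by
#' public single-neuron projectome datasets: a top-level `neuron` object
#' (or a `neurons` array, in which case the first entry is taken) with a
#' `soma` record and `axon` / `dendrite` node arrays. Every node carries
#' `x`, `y`, `z` coordinates (micrometres, atlas frame), a within-structure
#' sample number, a parent sample number (`-1` attaches to the soma), and
#' an atlas parcel id. Both `allenId` and `structureIdValue` are accepted
#' as the parcel key by default; other field names can be supplied through
#' `schema`.
#'
#' Nodes lacking a parcel id are kept (they still contribute to path
#' distances) but labelled with the sentinel parcel `"unassigned"`, which
#' is excluded from count tabulation.
#'
#' @param path path to the JSON file.
#' @param schema named list overriding field names; recognized entries are
#'   `id_keys` (candidate parcel-id keys, tried in order), `sample`,
#'   `parent`, `x`, `y`, `z`.
#' @return a [neuron_reconstruction()].
#' @export
read_reconstruction_json <- function(path, schema = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- utils::modifyList(
    list(id_keys = c("allenId", "structureIdValue"),
         sample = "sampleNumber", parent = "parentNumber",
         x = "x", y = "y", z = "z"),
    schema
  )
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  neuron <- obj$neuron %||% obj
  if (!is.null(obj$neurons)) {
    neuron <- if (is.data.frame(obj$neurons)) {
      lapply(obj$neurons, `[[`, 1L)
    } else {
      obj$neurons[[1L]]
    }
  }
  if (is.null(neuron$soma)) {
    stop("malformed reconstruction JSON '", path, "': no soma record")
  }
  neuron_id <- as.character(
    neuron$idString %||% neuron$id %||%
      tools::file_path_sans_ext(basename(path))
  )

  field <- function(rec, key, default = NULL) {
    v <- rec[[key]]
    if (is.null(v)) default else v
  }
  parcel_of <- function(rec) {
    for (k in schema$id_keys) {
      v <- rec[[k]]
      if (!is.null(v) && length(v)) return(as.character(v))
    }
    rep(NA_character_, max(1L, length(rec[[schema$x]])))
  }
  as_node_frame <- function(rec, structure_name, id_offset) {
    if (is.null(rec) || NROW(rec) == 0L) {
      return(NULL)
    }
    rec <- as.data.frame(rec, stringsAsFactors = FALSE)
    n <- nrow(rec)
    xs <- field(rec, schema$x, rep(NA_real_, n))
    ys <- field(rec, schema$y, rep(NA_real_, n))
    zs <- field(rec, schema$z, rep(NA_real_, n))
    samples <- field(rec, schema$sample, seq_len(n))
    parents <- field(rec, schema$parent, rep(-1, n))
    data.frame(
      node_id = id_offset + seq_len(n),
      x = as.numeric(xs), y = as.numeric(ys), z = as.numeric(zs),
      sample = as.integer(samples), parent_sample = as.integer(parents),
      structure = structure_name, parcel_id = parcel_of(rec),
      stringsAsFactors = FALSE
    )
  }

  soma <- neuron$soma
  soma_df <- data.frame(
    node_id = 1L,
    x = as.numeric(field(soma, schema$x, NA_real_)),
    y = as.numeric(field(soma, schema$y, NA_real_)),
    z = as.numeric(field(soma, schema$z, NA_real_)),
    parent_id = NA_integer_, structure = "soma",
    parcel_id = parcel_of(soma)[1L], stringsAsFactors = FALSE
  )

  parts <- list()
  offset <- 1L
  for (str in c("axon", "dendrite")) {
    df <- as_node_frame(neuron[[str]], str, offset)
    if (!is.null(df)) {
      # resolve within-structure parent sample numbers to global node ids
      pid <- integer(nrow(df))
      root_ref <- df$parent_sample == -1
      pid[root_ref] <- 1L
      hit <- match(df$parent_sample[!root_ref], df$sample)
      if (any(is.na(hit))) {
        bad <- which(!root_ref)[which(is.na(hit))[1L]]
        stop("malformed reconstruction '", neuron_id, "' in ", path,
             ": ", str, " node ", df$sample[bad],
             " references missing parent ", df$parent_sample[bad])
      }
      pid[!root_ref] <- df$node_id[hit]
      df$parent_id <- pid
      parts[[str]] <- df[, c("node_id", "x", "y", "z", "parent_id",
                             "structure", "parcel_id")]
      offset <- offset + nrow(df)
    }
  }
  nodes <- rbind(soma_df, do.call(rbind, parts))
  neuron_reconstruction(neuron_id, nodes,
                        soma_layer = soma$layer %||% NULL)
}

#' Write a reconstruction to JSON
#'
#' Inverse of [read_reconstruction_json()]; used to emit synthetic
#' morphologies in the same dialect the reader consumes.
#'
#' @param neuron a [neuron_reconstruction()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reconstruction_json <- function(neuron, path) {
  nodes <- neuron$nodes
  soma <- nodes[1L, ]
  pack <- function(str) {
    sub <- nodes[nodes$structure == str, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sample <- seq_len(nrow(sub))
    parent <- ifelse(sub$parent_id == soma$node_id, -1L,
                     sample[match(sub$parent_id, sub$node_id)])
    data.frame(sampleNumber = sample, x = sub$x, y = sub$y, z = sub$z,
               parentNumber = parent, allenId = sub$parcel_id,
               stringsAsFactors = FALSE)
  }
  body <- list(neuron = list(
    idString = neuron$neuron_id,
    soma = list(x = soma$x, y = soma$y, z = soma$z,
                allenId = soma$parcel_id),
    axon = pack("axon"),
    dendrite = pack("dendrite")
  ))
  if (!is.null(neuron$soma_layer)) {
    body$neuron$soma$layer <- neuron$soma_layer
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a neuron-by-region count matrix from CSV
#'
#' Layout: a header row of region labels, a first column of neuron ids,
#' and non-negative integer counts in the remaining cells.
#'
#' @param path path to the CSV file.
#' @return numeric matrix with neuron ids as row names and region labels
#'   as column names.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix CSV needs an id column and at ",
                          "least one region column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate neuron ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    cell <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(cell) | cell < 0)
    if (length(bad)) {
      stop("invalid cell in ", path, " at row '", ids[bad[1L]],
           "', column '", colnames(m)[j], "': '", m[bad[1L], j],
           "' (counts must be non-negative numbers)")
    }
  }
  m <- matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m),
              dimnames = list(ids, colnames(m)))
  validate_projection_matrix(m)
  m
}

#' Write a count matrix to CSV
#'
#' Writing then reading back with [read_matrix_csv()] reproduces the
#' matrix exactly.
#'
#' @param matrix neuron-by-region count matrix with dimnames.
#' @param path output path.
#' @param id_column header for the first (neuron id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path, id_column = "neuron_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

swc_type_codes <- c(soma = 1L, axon = 2L, dendrite = 3L)

#' Export a reconstruction to SWC
#'
#' Standard 7-column SWC (`id type x y z radius parent`); the soma is the
#' first sample and the root's parent is `-1`. Atlas parcel labels have no
#' SWC column and are not preserved; topology and coordinates round-trip
#' exactly through [read_swc()].
#'
#' @param neuron a [neuron_reconstruction()].
#' @param path output path.
#' @param radius radius written for every sample (SWC requires one; the
#'   reconstruction model does not carry radii).
#' @return `path`, invisibly.
#' @export
export_swc <- function(neuron, path, radius = 1) {
  nodes <- neuron$nodes
  id <- seq_len(nrow(nodes))
  parent <- match(nodes$parent_id, nodes$node_id)
  parent[is.na(parent)] <- -1L
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   id, swc_type_codes[nodes$structure],
                   nodes$x, nodes$y, nodes$z, radius, parent)
  writeLines(c(paste0("# SWC export of neuron ", neuron$neuron_id), lines),
             path)
  invisible(path)
}

#' Read an SWC morphology
#'
#' @param path path to the SWC file.
#' @param neuron_id id for the resulting reconstruction; defaults to the
#'   file name without extension.
#' @return a [neuron_reconstruction()]; all parcel ids are
#'   `"unassigned"` (SWC carries no atlas labels). Type codes map 1 to
#'   soma, 3 to dendrite and everything else to axon.
#' @export
read_swc <- function(path, neuron_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  neuron_id <- neuron_id %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no samples in SWC file: ", path)
  fields <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  if (ncol(fields) < 7L) stop("malformed SWC (need 7 columns): ", path)
  tab <- apply(fields[, 1:7, drop = FALSE], 2L, as.numeric)
  tab <- matrix(tab, ncol = 7L)
  structure_of <- function(type) {
    ifelse(type == 1, "soma", ifelse(type == 3, "dendrite", "axon"))
  }
  nodes <- data.frame(
    node_id = as.integer(tab[, 1L]),
    x = tab[, 3L], y = tab[, 4L], z = tab[, 5L],
    parent_id = ifelse(tab[, 7L] < 0, NA_integer_, as.integer(tab[, 7L])),
    structure = structure_of(tab[, 2L]),
    parcel_id = "unassigned",
    stringsAsFactors = FALSE
  )
  neuron_reconstruction(neuron_id, nodes)
}

#' Read a soma table from CSV
#'
#' Columns: `neuron_id`, optional `class`, `x`, `y`, `z` (micrometres)
#' and optional `layer`.
#'
#' @param path path to the CSV file.
#' @return data frame with the columns above.
#' @export
read_soma_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  needed <- c("neuron_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("soma CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (any(!is.finite(coords))) {
    stop("soma CSV ", path, " has non-finite coordinates")
  }
  df
}

#' Read regional anterograde projection strengths from CSV
#'
#' Per-region averages over tracing experiments, as exported from a
#' regional connectivity atlas. Columns: `region`, `mean_volume`,
#' `mean_density`. The product of the two averages is the regional
#' projection weight entering the abundance deconvolution.
#'
#' @param path path to the CSV file.
#' @return data frame with columns `region`, `mean_volume`,
#'   `mean_density`, `weight`.
#' @export
read_regional_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  needed <- c("region", "mean_volume", "mean_density")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("regional CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$mean_volume < 0 | df$mean_density < 0)) {
    stop("regional CSV ", path, " has negative volume or density values")
  }
  df$weight <- df$mean_volume * df$mean_density
  df
}
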