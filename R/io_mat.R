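#' Read an AFQ MAT-file
#'
#' Reads the output object of the AFQ MATLAB tractometry pipeline: a struct
#' (conventionally named `afq`) holding, per diffusion metric, one
#' subjects-by-nodes Tract Profile matrix per tract, together with the tract
#' name list, subject identifiers and an optional metadata struct. Both MAT
#' dialects are supported and detected from the file header:
#'
#' * classic v7 files are parsed with scipy.io through a bundled bridge
#'   script (a `python` with scipy on the `PATH` is required for this dialect
#'   only);
#' * HDF5-layout (v7.3-style) files are read natively. The supported HDF5
#'   layout is the one written by [write_mat_fixture()]: an `afq` group with
#'   `sub_ids`, `fgnames`, a `vals/<metric>/<tract index>` tree, an optional
#'   `metadata` group and an optional `params_json` string.
#'
#' Field lookup is case-insensitive in both dialects. Metric names are
#' lower-cased; tract and subject order are preserved from the file.
#'
#' @param path path to the MAT-file.
#' @return A [tractometry_dataset()].
#' @export
read_afq_mat <- function(path) {
  if (!file.exists(path)) stop_tract("no such file: %s", path)
  magic <- readBin(path, "raw", n = 8L)
  hdf5_magic <- as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8L && identical(magic, hdf5_magic)) {
    parts <- read_mat_hdf5(path)
  } else if (length(magic) >= 6L &&
             identical(rawToChar(magic[1:6]), "MATLAB")) {
    parts <- read_mat_classic(path)
  } else {
    stop_tract("%s is neither an HDF5 nor a classic MAT-file", path)
  }
  dataset_from_mat_parts(parts, path)
}

# Shared assembly + shape checking for both MAT dialects.
dataset_from_mat_parts <- function(parts, path) {
  subject_ids <- parts$subject_ids
  tract_names <- parts$tract_names
  if (!length(subject_ids)) stop_tract("%s: no subject IDs found", path)
  if (!length(tract_names)) stop_tract("%s: no tract names found", path)

  n_sub <- length(subject_ids)
  n_nodes <- NA_integer_
  values <- list()
  for (m in names(parts$values)) {
    mats <- parts$values[[m]]
    if (length(mats) != length(tract_names)) {
      stop_tract("%s: metric %s has %d tract matrices but %d tract names",
                 path, sQuote(m), length(mats), length(tract_names))
    }
    values[[m]] <- list()
    for (ti in seq_along(mats)) {
      mat <- mats[[ti]]
      if (nrow(mat) != n_sub) {
        stop_tract("%s: metric %s, tract %s: %d rows for %d subjects",
                   path, sQuote(m), sQuote(tract_names[ti]), nrow(mat), n_sub)
      }
      if (is.na(n_nodes)) n_nodes <- ncol(mat)
      if (ncol(mat) != n_nodes) {
        stop_tract(
          "%s: inconsistent node count: metric %s, tract %s has %d nodes, expected %d",
          path, sQuote(m), sQuote(tract_names[ti]), ncol(mat), n_nodes)
      }
      mat[is.nan(mat)] <- NA_real_
      values[[m]][[tract_names[ti]]] <- mat
    }
  }
  if (!length(values)) stop_tract("%s: no value matrices found", path)

  metadata <- data.frame(subjectID = subject_ids, stringsAsFactors = FALSE)
  if (length(parts$metadata)) {
    for (col in names(parts$metadata)) {
      v <- parts$metadata[[col]]
      if (length(v) != n_sub) {
        stop_tract("%s: metadata column %s has %d values for %d subjects",
                   path, sQuote(col), length(v), n_sub)
      }
      metadata[[col]] <- v
    }
  } else {
    warn_tract("%s: no metadata field; metadata table is empty", path)
  }

  tractometry_dataset(subject_ids, tract_names, names(values), n_nodes,
                      values, metadata, parts$params %||% list())
}

# ---- classic (v7) dialect via the scipy bridge -----------------------------

python_binary <- function() {
  py <- getOption("tractometry.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop_tract("no python interpreter found; classic MAT v7 files need scipy")
  }
  py
}

run_mat_bridge <- function(command, infile, outfile) {
  script <- system.file("python", "mat_bridge.py", package = "tractometry")
  if (!nzchar(script)) stop_tract("mat_bridge.py not found in installation")
  out <- suppressWarnings(system2(python_binary(),
                                  shQuote(c(script, command, infile, outfile)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop_tract("MAT bridge failed (%s): %s", command,
               paste(out, collapse = " | "))
  }
  invisible(outfile)
}

read_mat_classic <- function(path) {
  json_path <- tempfile(fileext = ".json")
  on.exit(unlink(json_path))
  run_mat_bridge("mat2json", path, json_path)
  spec <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  values <- lapply(spec$values, function(tracts) {
    lapply(tracts, function(m) {
      data <- vapply(m$data, function(v) if (is.null(v)) NA_real_ else
        as.numeric(v), numeric(1))
      matrix(data, nrow = m$nrow, ncol = m$ncol, byrow = TRUE)
    })
  })
  names(values) <- tolower(names(spec$values))
  metadata <- lapply(spec$metadata, function(desc) {
    vals <- desc$values
    if (identical(desc$type, "numeric")) {
      vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    } else {
      vapply(vals, function(v) if (is.null(v)) NA_character_ else
        as.character(v), character(1))
    }
  })
  list(subject_ids = unlist(spec$subject_ids),
       tract_names = unlist(spec$tract_names),
       values = values, metadata = metadata,
       params = lapply(spec$params %||% list(), simplify_json_param))
}

simplify_json_param <- function(x) {
  if (is.list(x)) {
    if (length(x) && is.null(names(x)) &&
        all(vapply(x, function(v) is.null(v) || (is.atomic(v) &&
                                                 length(v) == 1L), logical(1)))) {
      return(unlist(lapply(x, function(v) v %||% NA)))
    }
    return(lapply(x, simplify_json_param))
  }
  x
}

# ---- HDF5 layout (v7.3-style) via rhdf5 ------------------------------------

h5_child <- function(listing, parent, aliases) {
  kids <- listing$name[listing$group == parent]
  hit <- kids[match(tolower(aliases), tolower(kids))]
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(NULL)
  paste0(ifelse(parent == "/", "/", paste0(parent, "/")), hit[1])
}

read_mat_hdf5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  listing <- rhdf5::h5ls(path, recursive = TRUE)
  root <- h5_child(listing, "/", c("afq"))
  if (is.null(root)) {
    tops <- listing$name[listing$group == "/"]
    if (length(tops) == 1L) root <- paste0("/", tops) else {
      stop_tract("%s: no 'afq' group found", path)
    }
  }
  sub_path <- h5_child(listing, root, c("sub_ids", "subject_ids", "subIDs"))
  fg_path <- h5_child(listing, root, c("fgnames", "tract_names"))
  vals_path <- h5_child(listing, root, c("vals", "values"))
  if (is.null(sub_path) || is.null(fg_path) || is.null(vals_path)) {
    stop_tract("%s: missing required fields (vals, fgnames, sub_ids)", path)
  }
  subject_ids <- as.character(rhdf5::h5read(path, sub_path))
  tract_names <- as.character(rhdf5::h5read(path, fg_path))

  metric_names <- listing$name[listing$group == vals_path]
  order_path <- h5_child(listing, root, c("metric_order", "metric_names"))
  if (!is.null(order_path)) {
    stated <- as.character(rhdf5::h5read(path, order_path))
    if (setequal(tolower(stated), tolower(metric_names))) {
      metric_names <- stated
    }
  }
  values <- list()
  for (m in metric_names) {
    mgroup <- paste0(vals_path, "/", m)
    tract_sets <- sort(listing$name[listing$group == mgroup])
    values[[tolower(m)]] <- lapply(tract_sets, function(dn) {
      mat <- rhdf5::h5read(path, paste0(mgroup, "/", dn))
      if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
      mat
    })
  }

  metadata <- list()
  meta_path <- h5_child(listing, root, "metadata")
  if (!is.null(meta_path)) {
    for (col in listing$name[listing$group == meta_path]) {
      v <- rhdf5::h5read(path, paste0(meta_path, "/", col))
      v <- as.vector(v)
      if (is.character(v)) v[!nzchar(v)] <- NA_character_
      if (is.numeric(v)) v[is.nan(v)] <- NA_real_
      metadata[[col]] <- v
    }
  }

  params <- list()
  pj <- h5_child(listing, root, "params_json")
  if (!is.null(pj)) {
    params <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, pj)),
                                 simplifyVector = TRUE)
  }
  list(subject_ids = subject_ids, tract_names = tract_names,
       values = values, metadata = metadata, params = params)
}

#' Write a MAT fixture for the AFQ reader
#'
#' Serializes a dataset into the MAT field structure that [read_afq_mat()]
#' expects (`afq.sub_ids`, `afq.fgnames`, `afq.vals.<metric>{tract}`,
#' `afq.metadata`), primarily as a test and interchange fixture.
#'
#' @param ds a [tractometry_dataset()].
#' @param path output file path.
#' @param version `"hdf5"` (default; v7.3-style layout, written natively and
#'   openable by any HDF5 reader) or `"v7"` (classic MAT, written through the
#'   scipy bridge).
#' @return `path`, invisibly.
#' @export
write_mat_fixture <- function(ds, path, version = c("hdf5", "v7")) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  version <- match.arg(version)
  if (version == "hdf5") write_mat_hdf5(ds, path) else write_mat_v7(ds, path)
  invisible(path)
}

write_mat_hdf5 <- function(ds, path) {
  on.exit(rhdf5::h5closeAll())
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "afq")
  rhdf5::h5write(ds$subject_ids, path, "afq/sub_ids")
  rhdf5::h5write(ds$tract_names, path, "afq/fgnames")
  # HDF5 group listings are alphabetical; keep the metric order explicit
  rhdf5::h5write(ds$metric_names, path, "afq/metric_order")
  rhdf5::h5createGroup(path, "afq/vals")
  for (m in ds$metric_names) {
    rhdf5::h5createGroup(path, paste0("afq/vals/", m))
    for (ti in seq_along(ds$tract_names)) {
      mat <- value_matrix(ds, m, ds$tract_names[ti])
      rhdf5::h5write(mat, path, sprintf("afq/vals/%s/t%03d", m, ti - 1L))
    }
  }
  meta_cols <- setdiff(names(ds$metadata), "subjectID")
  if (length(meta_cols)) {
    rhdf5::h5createGroup(path, "afq/metadata")
    for (col in meta_cols) {
      v <- ds$metadata[[col]]
      if (is.factor(v)) v <- as.character(v)
      if (is.character(v)) v[is.na(v)] <- ""
      rhdf5::h5write(v, path, paste0("afq/metadata/", col))
    }
  }
  if (length(ds$params)) {
    rhdf5::h5write(
      as.character(jsonlite::toJSON(ds$params, auto_unbox = TRUE,
                                    digits = NA, na = "null")),
      path, "afq/params_json")
  }
  invisible(path)
}

write_mat_v7 <- function(ds, path) {
  spec <- list(
    subject_ids = I(ds$subject_ids),
    tract_names = I(ds$tract_names),
    values = lapply(stats::setNames(ds$metric_names, ds$metric_names),
                    function(m) {
      lapply(ds$tract_names, function(tr) {
        mat <- value_matrix(ds, m, tr)
        list(nrow = nrow(mat), ncol = ncol(mat),
             data = I(as.vector(t(mat))))
      })
    }),
    metadata = {
      cols <- setdiff(names(ds$metadata), "subjectID")
      out <- lapply(stats::setNames(cols, cols), function(col) {
        v <- ds$metadata[[col]]
        if (is.factor(v)) v <- as.character(v)
        list(type = if (is.numeric(v)) "numeric" else "character",
             values = I(v))
      })
      out
    },
    params = ds$params)
  json_path <- tempfile(fileext = ".json")
  on.exit(unlink(json_path))
  jsonlite::write_json(spec, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  run_mat_bridge("json2mat", json_path, path)
  invisible(path)
}
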