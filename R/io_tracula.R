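#' Read a TRACULA-style group stats folder
#'
#' Reads a directory of per-(tract, metric) text tables, one file per
#' combination, into a [tractometry_dataset()]. The accepted dialect is fixed
#' and documented here, since stats folders in the wild vary:
#'
#' * file names are `<tract>.<metric>.txt` (e.g. `cst_left.fa.txt`);
#' * files are whitespace-delimited with no header; the first column is the
#'   subject ID and the remaining columns are the node values for that
#'   subject, `NA`/`nan` marking missing values.
#'
#' Per-tract node counts may differ between raw files; all tracts are
#' harmonized by linear interpolation onto the maximum node count present,
#' and the per-tract raw counts are recorded in
#' `params$tracula_source_nodes`. All files must agree on the subject set;
#' subject order is taken from the first file (files are processed in sorted
#' name order).
#'
#' @param dir directory containing the stats tables.
#' @return A [tractometry_dataset()].
#' @export
read_tracula_stats <- function(dir) {
  if (!dir.exists(dir)) stop_tract("no such directory: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.txt$"))
  parsed <- list()
  for (f in files) {
    m <- regmatches(f, regexec("^(.+)\\.([^.]+)\\.txt$", f))[[1]]
    if (length(m) != 3L) next
    tab <- parse_tracula_file(file.path(dir, f))
    parsed[[length(parsed) + 1L]] <-
      list(tract = m[2], metric = tolower(m[3]), file = f,
           subjects = tab$subjects, values = tab$values)
  }
  if (!length(parsed)) {
    stop_tract("no parseable <tract>.<metric>.txt files in %s", dir)
  }

  subject_ids <- parsed[[1]]$subjects
  for (p in parsed) {
    if (!setequal(p$subjects, subject_ids)) {
      only_here <- setdiff(p$subjects, subject_ids)
      only_first <- setdiff(subject_ids, p$subjects)
      stop_tract(
        "subject sets differ across files: %s vs %s%s%s",
        parsed[[1]]$file, p$file,
        if (length(only_here)) paste0("; only in ", p$file, ": ",
                                      paste(only_here, collapse = ", ")) else "",
        if (length(only_first)) paste0("; missing from ", p$file, ": ",
                                       paste(only_first, collapse = ", "))
        else "")
    }
  }

  tract_names <- unique(vapply(parsed, `[[`, character(1), "tract"))
  metric_names <- unique(vapply(parsed, `[[`, character(1), "metric"))
  raw_nodes <- integer(0)
  for (p in parsed) {
    prev <- if (p$tract %in% names(raw_nodes)) raw_nodes[[p$tract]] else 0L
    raw_nodes[p$tract] <- max(prev, ncol(p$values))
  }
  n_nodes <- max(vapply(parsed, function(p) ncol(p$values), integer(1)))

  values <- list()
  for (p in parsed) {
    mat <- p$values[match(subject_ids, p$subjects), , drop = FALSE]
    if (ncol(mat) != n_nodes) mat <- resample_profile_matrix(mat, n_nodes)
    values[[p$metric]][[p$tract]] <- mat
  }

  tractometry_dataset(
    subject_ids, tract_names, metric_names, n_nodes, values,
    metadata = NULL,
    params = list(source = "tracula",
                  tracula_source_nodes = as.list(raw_nodes)))
}

parse_tracula_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop_tract("%s: file is empty", path)
  rows <- strsplit(trimws(lines[keep]), "[ \t]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad_i <- which(ncols != ncols[1])[1]
    stop_tract("%s, line %d: expected %d columns, found %d",
               path, keep[bad_i], ncols[1], ncols[bad_i])
  }
  if (ncols[1] < 2L) stop_tract("%s: rows need a subject ID plus node values",
                                path)
  subjects <- vapply(rows, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(rows), ncols[1] - 1L)
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    missing <- tolower(cells) %in% c("na", "nan", ".")
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !missing)
    if (length(bad)) {
      stop_tract("%s, line %d: non-numeric value %s",
                 path, keep[i], sQuote(cells[bad[1]]))
    }
    vals[i, ] <- num
  }
  if (anyDuplicated(subjects)) {
    stop_tract("%s: duplicate subject ID %s", path,
               subjects[duplicated(subjects)][1])
  }
  list(subjects = subjects, values = vals)
}

# Linear interpolation of each row onto n_out equidistant nodes spanning the
# same arc-length fraction 0..1; rows with < 2 finite values become all-NA.
resample_profile_matrix <- function(mat, n_out) {
  x_in <- seq(0, 1, length.out = ncol(mat))
  x_out <- seq(0, 1, length.out = n_out)
  out <- matrix(NA_real_, nrow(mat), n_out)
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, ]
    ok <- !is.na(y)
    if (sum(ok) >= 2L) {
      out[i, ] <- stats::approx(x_in[ok], y[ok], xout = x_out)$y
    }
  }
  out
}
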