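#' In-memory tractometry dataset
#'
#' The central container of the package: Tract Profiles for a cohort, i.e. one
#' subjects-by-nodes matrix per (metric, tract) pair, plus a subject metadata
#' table and free-form analysis parameters. It is the in-memory twin of the
#' on-disk tidy bundle written by [write_tidy()].
#'
#' Each matrix in `values` has one row per subject (in `subject_ids` order) and
#' `n_nodes` columns, one per equidistant node along the tract core. Missing
#' measurements are `NA`. Diffusion metrics are named in lower case; by
#' convention `fa` is dimensionless in \[0, 1\] and diffusivities (`md`, `rd`,
#' `ad`) are positive.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param tract_names character vector of unique tract names, display order.
#' @param metric_names character vector of unique metric names (lower-cased).
#' @param n_nodes number of nodes per tract (default 100).
#' @param values named list: `values[[metric]][[tract]]` is a numeric matrix of
#'   dimension `length(subject_ids)` by `n_nodes`. Pairs may be absent.
#' @param metadata data frame with a `subjectID` column, one row per subject.
#'   Rows for unknown subjects are an error; subjects without a row get an
#'   all-`NA` row with a warning.
#' @param params named list of free-form analysis parameters.
#'
#' @return An object of class `tractometry_dataset`.
#' @seealso [validate_dataset()], [write_tidy()], [read_tidy()],
#'   [generate_dataset()]
#' @export
#' @examples
#' ds <- tractometry_dataset(
#'   subject_ids  = c("s1", "s2"),
#'   tract_names  = "Left CST",
#'   metric_names = "fa",
#'   n_nodes      = 4,
#'   values = list(fa = list("Left CST" = matrix(runif(8), 2, 4))),
#'   metadata = data.frame(subjectID = c("s1", "s2"), age = c(9, 34))
#' )
#' ds
tractometry_dataset <- function(subject_ids, tract_names, metric_names,
                                n_nodes = 100L, values = list(),
                                metadata = NULL, params = list()) {
  subject_ids <- as.character(subject_ids)
  tract_names <- as.character(tract_names)
  metric_names <- tolower(as.character(metric_names))
  if (anyDuplicated(subject_ids)) stop_tract("duplicate subject IDs")
  if (anyDuplicated(tract_names)) stop_tract("duplicate tract names")
  if (anyDuplicated(metric_names)) stop_tract("duplicate metric names")
  if (!is_count(n_nodes)) stop_tract("n_nodes must be a positive integer")
  n_nodes <- as.integer(n_nodes)

  names(values) <- tolower(names(values))
  for (m in names(values)) {
    if (!m %in% metric_names) {
      stop_tract("values carry unknown metric %s", sQuote(m))
    }
    for (tr in names(values[[m]])) {
      if (!tr %in% tract_names) {
        stop_tract("values carry unknown tract %s (metric %s)",
                   sQuote(tr), sQuote(m))
      }
      mat <- values[[m]][[tr]]
      if (!is.matrix(mat)) mat <- as.matrix(mat)
      storage.mode(mat) <- "double"
      if (nrow(mat) != length(subject_ids) || ncol(mat) != n_nodes) {
        stop_tract(
          "matrix for metric %s, tract %s is %d x %d; expected %d x %d",
          sQuote(m), sQuote(tr), nrow(mat), ncol(mat),
          length(subject_ids), n_nodes)
      }
      dimnames(mat) <- NULL
      values[[m]][[tr]] <- mat
    }
  }

  metadata <- normalize_metadata(metadata, subject_ids)

  structure(
    list(subject_ids = subject_ids, tract_names = tract_names,
         metric_names = metric_names, n_nodes = n_nodes,
         values = values, metadata = metadata, params = params),
    class = "tractometry_dataset")
}

# Align a metadata table to the subject roster: error on unknown subjects,
# all-NA rows (with warning) for subjects lacking metadata.
normalize_metadata <- function(metadata, subject_ids) {
  if (is.null(metadata)) metadata <- data.frame(subjectID = subject_ids)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"subjectID" %in% names(metadata)) {
    stop_tract("metadata must have a subjectID column")
  }
  metadata$subjectID <- as.character(metadata$subjectID)
  unknown <- setdiff(metadata$subjectID, subject_ids)
  if (length(unknown)) {
    stop_tract("metadata rows for unknown subjects: %s",
               paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(metadata$subjectID)) {
    stop_tract("duplicate metadata rows for subject %s",
               metadata$subjectID[duplicated(metadata$subjectID)][1])
  }
  absent <- setdiff(subject_ids, metadata$subjectID)
  if (length(absent)) {
    warn_tract("no metadata for subject(s) %s; filling with missing values",
               paste(absent, collapse = ", "))
  }
  idx <- match(subject_ids, metadata$subjectID)
  out <- metadata[idx, , drop = FALSE]
  out$subjectID <- subject_ids
  rownames(out) <- NULL
  out
}

#' @export
print.tractometry_dataset <- function(x, ...) {
  cat(sprintf(
    "<tractometry_dataset> %d subjects, %d tracts, %d nodes\n",
    length(x$subject_ids), length(x$tract_names), x$n_nodes))
  cat("  metrics:  ", paste(x$metric_names, collapse = ", "), "\n", sep = "")
  cat("  tracts:   ", paste(utils::head(x$tract_names, 4), collapse = ", "),
      if (length(x$tract_names) > 4) ", ..." else "", "\n", sep = "")
  meta_cols <- setdiff(names(x$metadata), "subjectID")
  cat("  metadata: ",
      if (length(meta_cols)) paste(meta_cols, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.tractometry_dataset <- function(object, ...) {
  present <- sum(vapply(object$values, length, integer(1)))
  cat(sprintf(
    "tractometry dataset: %d subjects x %d tracts x %d nodes, %d metrics\n",
    length(object$subject_ids), length(object$tract_names),
    object$n_nodes, length(object$metric_names)))
  cat(sprintf("  %d of %d (metric, tract) matrices present\n",
              present,
              length(object$metric_names) * length(object$tract_names)))
  rep <- validate_dataset(object)
  cat(sprintf("  validation: %d error(s), %d warning(s)\n",
              sum(rep$severity == "error"), sum(rep$severity == "warning")))
  invisible(object)
}

#' Extract one subjects-by-nodes matrix
#'
#' @param ds a [tractometry_dataset()].
#' @param metric,tract metric and tract name.
#' @return Numeric matrix (subjects by nodes), or an all-`NA` matrix if the
#'   pair is absent from the dataset.
#' @export
value_matrix <- function(ds, metric, tract) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  metric <- tolower(metric)
  if (!metric %in% ds$metric_names) stop_tract("unknown metric %s", sQuote(metric))
  if (!tract %in% ds$tract_names) stop_tract("unknown tract %s", sQuote(tract))
  mat <- ds$values[[metric]][[tract]]
  if (is.null(mat)) {
    mat <- matrix(NA_real_, length(ds$subject_ids), ds$n_nodes)
  }
  mat
}

# Replace one matrix, preserving class invariants.
set_value_matrix <- function(ds, metric, tract, mat) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  metric <- tolower(metric)
  stopifnot(metric %in% ds$metric_names, tract %in% ds$tract_names,
            nrow(mat) == length(ds$subject_ids), ncol(mat) == ds$n_nodes)
  dimnames(mat) <- NULL
  storage.mode(mat) <- "double"
  ds$values[[metric]][[tract]] <- mat
  ds
}

# Row index of a subject, with a friendly error.
subject_index <- function(ds, subject) {
  i <- match(subject, ds$subject_ids)
  if (is.na(i)) stop_tract("unknown subject %s", sQuote(subject))
  i
}
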