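#' Write a dataset as a tidy bundle
#'
#' Serializes a [tractometry_dataset()] to the on-disk exchange format: a
#' directory with four plain-text members.
#'
#' * `nodes.csv` — long table of per-node metric estimates, header exactly
#'   `subjectID,tractID,nodeID,<metric...>` (metrics in dataset order). Rows
#'   are ordered subject-major, then tract (dataset order), then ascending
#'   `nodeID`; `nodeID` runs `0 .. n_nodes - 1`.
#' * `subjects.csv` / `subjects.json` — the subject metadata, identical
#'   content in both formats, joinable to `nodes.csv` on `subjectID`.
#' * `params.json` — free-form analysis parameters.
#'
#' CSV dialect: comma separator, UTF-8, LF line endings, header row, cells
#' quoted only when they contain a comma, quote or newline; missing values are
#' empty cells (CSV) or `null` (JSON). Numbers are written with the fewest
#' digits that round-trip exactly.
#'
#' @param ds a valid [tractometry_dataset()].
#' @param outdir output directory (created if needed).
#' @return The normalized path of `outdir`, invisibly classed `tidy_bundle`.
#' @seealso [read_tidy()] for the inverse.
#' @export
write_tidy <- function(ds, outdir) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  rep <- validate_dataset(ds)
  if (!is_valid(rep)) {
    stop_tract("dataset is not valid: %s",
               paste(rep$message[rep$severity == "error"], collapse = "; "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop_tract("cannot create directory %s", outdir)

  S <- length(ds$subject_ids); Tt <- length(ds$tract_names); N <- ds$n_nodes
  subject_col <- rep(ds$subject_ids, each = Tt * N)
  tract_col <- rep(rep(ds$tract_names, each = N), times = S)
  node_col <- rep.int(0:(N - 1L), S * Tt)

  cols <- list(subjectID = csv_escape(subject_col),
               tractID = csv_escape(tract_col),
               nodeID = as.character(node_col))
  for (m in ds$metric_names) {
    v <- rep(NA_real_, S * Tt * N)
    for (ti in seq_len(Tt)) {
      mat <- ds$values[[m]][[ds$tract_names[ti]]]
      if (is.null(mat)) next
      # positions of (subject s, tract ti, node 1..N) in the long vector
      pos <- outer(seq_len(N), (seq_len(S) - 1L) * Tt * N, "+") + (ti - 1L) * N
      v[pos] <- t(mat)
    }
    cols[[m]] <- fmt_num(v)
  }
  lines <- c(paste(c("subjectID", "tractID", "nodeID", ds$metric_names),
                   collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  write_lf(lines, file.path(outdir, "nodes.csv"))

  write_metadata_csv(ds$metadata, file.path(outdir, "subjects.csv"))
  jsonlite::write_json(metadata_for_json(ds$metadata),
                       file.path(outdir, "subjects.json"),
                       dataframe = "rows", na = "null", digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  jsonlite::write_json(ds$params, file.path(outdir, "params.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  invisible(structure(normalizePath(outdir), class = "tidy_bundle"))
}

#' Read a tidy bundle back into a dataset
#'
#' Inverse of [write_tidy()]. Subject, tract and metric orders are taken from
#' first appearance in `nodes.csv`; metadata columns are typed numeric when
#' every non-missing cell parses as a number, and kept as text otherwise.
#'
#' @param dir directory containing `nodes.csv`, `subjects.csv`,
#'   `subjects.json` and `params.json`.
#' @return A [tractometry_dataset()].
#' @export
read_tidy <- function(dir) {
  nodes_path <- file.path(dir, "nodes.csv")
  subj_path <- file.path(dir, "subjects.csv")
  for (p in c(nodes_path, subj_path)) {
    if (!file.exists(p)) stop_tract("missing bundle file %s", p)
  }
  header <- strsplit(readLines(nodes_path, n = 1L, encoding = "UTF-8"),
                     ",", fixed = TRUE)[[1]]
  if (length(header) < 4L ||
      !identical(header[1:3], c("subjectID", "tractID", "nodeID"))) {
    stop_tract(
      "nodes.csv: header must start subjectID,tractID,nodeID,<metric...> (%s)",
      nodes_path)
  }
  metrics <- header[-(1:3)]
  nodes <- utils::read.csv(
    nodes_path, colClasses = c("character", "character", "integer",
                               rep("numeric", length(metrics))),
    check.names = FALSE, fileEncoding = "UTF-8")

  subject_ids <- unique(nodes$subjectID)
  tract_names <- unique(nodes$tractID)
  n_nodes <- max(nodes$nodeID) + 1L
  if (any(nodes$nodeID < 0L)) {
    stop_tract("nodes.csv: negative nodeID (%s)", nodes_path)
  }
  key <- paste(nodes$subjectID, nodes$tractID, nodes$nodeID, sep = "\r")
  if (anyDuplicated(key)) {
    d <- nodes[duplicated(key), , drop = FALSE][1, ]
    stop_tract("nodes.csv: duplicate node row (subject=%s tract=%s node=%d)",
               d$subjectID, d$tractID, d$nodeID)
  }

  metadata <- read_metadata_csv(subj_path)
  missing_meta <- setdiff(subject_ids, metadata$subjectID)
  if (length(missing_meta)) {
    stop_tract("subjects.csv lacks rows for subject(s): %s",
               paste(missing_meta, collapse = ", "))
  }

  si <- match(nodes$subjectID, subject_ids)
  vi <- nodes$nodeID + 1L
  values <- list()
  for (m in metrics) {
    values[[m]] <- list()
    for (tr in tract_names) {
      sel <- nodes$tractID == tr
      mat <- matrix(NA_real_, length(subject_ids), n_nodes)
      mat[cbind(si[sel], vi[sel])] <- nodes[[m]][sel]
      values[[m]][[tr]] <- mat
    }
  }

  params_path <- file.path(dir, "params.json")
  params <- if (file.exists(params_path)) {
    jsonlite::read_json(params_path, simplifyVector = TRUE)
  } else list()

  # metadata may describe subjects without node data; drop them with notice
  extra <- setdiff(metadata$subjectID, subject_ids)
  if (length(extra)) {
    warn_tract("dropping metadata for subject(s) without node data: %s",
               paste(extra, collapse = ", "))
    metadata <- metadata[metadata$subjectID %in% subject_ids, , drop = FALSE]
  }

  tractometry_dataset(subject_ids, tract_names, metrics, n_nodes,
                      values, metadata, params)
}

# ---- CSV helpers (fixed dialect: comma, UTF-8, LF, minimal quoting) --------

csv_escape <- function(x) {
  x <- as.character(x)
  need <- !is.na(x) & grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x[is.na(x)] <- ""
  x
}

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
}

metadata_col_as_text <- function(col) {
  if (is.numeric(col)) fmt_num(col) else csv_escape(col)
}

write_metadata_csv <- function(metadata, path) {
  cols <- lapply(metadata, metadata_col_as_text)
  lines <- c(paste(csv_escape(names(metadata)), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  write_lf(lines, path)
}

read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = "", fileEncoding = "UTF-8")
  if (!"subjectID" %in% names(df)) {
    stop_tract("%s lacks a subjectID column", path)
  }
  type_metadata(df)
}

# Column typing rule: numeric iff every non-missing cell parses as a number.
type_metadata <- function(df) {
  for (nm in setdiff(names(df), "subjectID")) {
    col <- df[[nm]]
    if (is.numeric(col)) next
    num <- suppressWarnings(as.numeric(col))
    if (!any(is.na(num) & !is.na(col))) df[[nm]] <- num
  }
  df
}

metadata_for_json <- function(metadata) {
  out <- metadata
  for (nm in names(out)) {
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  out
}
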