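#' Assemble a publishable site bundle
#'
#' Arranges a dataset into the directory layout of a shareable, statically
#' servable site: template assets at the root (a supplied template directory,
#' or a generated minimal index page when none is given), the tidy bundle
#' under `data/`, and a `manifest.json` mapping every bundled file (relative
#' path) to its byte size and SHA-256 hash, so published artifacts are
#' verifiable and re-assembly is reproducible.
#'
#' @param ds a valid [tractometry_dataset()].
#' @param outdir output directory.
#' @param template_dir optional directory of viewer assets to copy in.
#' @param overwrite allow writing into a non-empty `outdir`.
#' @return A `site_bundle`: list with `root`, `data_dir` and `manifest`
#'   (data frame: `path`, `size`, `sha256`).
#' @export
assemble_site <- function(ds, outdir, template_dir = NULL,
                          overwrite = FALSE) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  if (dir.exists(outdir) &&
      length(list.files(outdir, all.files = TRUE, no.. = TRUE)) &&
      !overwrite) {
    stop_tract("%s is not empty; pass overwrite = TRUE to assemble anyway",
               outdir)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(template_dir)) {
    if (!dir.exists(template_dir)) {
      stop_tract("template directory %s does not exist", template_dir)
    }
    for (f in list.files(template_dir, recursive = TRUE)) {
      dest <- file.path(outdir, f)
      dir.create(dirname(dest), showWarnings = FALSE, recursive = TRUE)
      file.copy(file.path(template_dir, f), dest, overwrite = TRUE)
    }
  } else {
    write_lf(placeholder_index(ds), file.path(outdir, "index.html"))
  }

  write_tidy(ds, file.path(outdir, "data"))
  manifest <- build_manifest(outdir, exclude = "manifest.json")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  new_site_bundle(outdir, manifest)
}

new_site_bundle <- function(root, manifest) {
  structure(list(root = normalizePath(root),
                 data_dir = file.path(normalizePath(root), "data"),
                 manifest = manifest),
            class = "site_bundle")
}

#' Load an assembled bundle and verify its manifest
#'
#' @param root bundle directory created by [assemble_site()].
#' @return A `site_bundle`; errors if a manifest entry is missing or its hash
#'   does not match the file on disk.
#' @export
read_site_bundle <- function(root) {
  mpath <- file.path(root, "manifest.json")
  if (!file.exists(mpath)) stop_tract("no manifest.json under %s", root)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(root, manifest$path[i])
    if (!file.exists(p)) stop_tract("manifest entry missing on disk: %s",
                                    manifest$path[i])
    h <- digest::digest(p, algo = "sha256", file = TRUE)
    if (!identical(h, manifest$sha256[i])) {
      stop_tract("hash mismatch for %s", manifest$path[i])
    }
  }
  new_site_bundle(root, manifest)
}

#' @export
print.site_bundle <- function(x, ...) {
  cat(sprintf("<site_bundle> %s\n  %d file(s), %s bytes\n", x$root,
              nrow(x$manifest), format(sum(x$manifest$size), big.mark = ",")))
  invisible(x)
}

build_manifest <- function(root, exclude = character()) {
  files <- sort(setdiff(list.files(root, recursive = TRUE), exclude))
  data.frame(
    path = files,
    size = vapply(file.path(root, files),
                  function(p) as.numeric(file.info(p)$size), numeric(1),
                  USE.NAMES = FALSE),
    sha256 = vapply(file.path(root, files),
                    function(p) digest::digest(p, algo = "sha256",
                                               file = TRUE),
                    character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

placeholder_index <- function(ds) {
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>Tractometry data bundle</title></head><body>",
    sprintf("<h1>Tractometry data bundle</h1><p>%d subjects, %d tracts, %d nodes; metrics: %s.</p>",
            length(ds$subject_ids), length(ds$tract_names), ds$n_nodes,
            paste(ds$metric_names, collapse = ", ")),
    "<p>Tidy tables are under <a href=\"data/\">data/</a>:",
    "nodes.csv, subjects.csv, subjects.json, params.json.</p>",
    "</body></html>")
}

#' Produce publish artifacts without touching the network
#'
#' A dry run of the publish step: copies the assembled site into a
#' ready-to-init repository directory and writes the registration payload
#' that a central index would receive (dataset summary plus analysis
#' parameters), validated against the schema shipped with the package. No
#' network traffic is performed; the run is idempotent (a second run emits
#' byte-identical artifacts).
#'
#' @param bundle a `site_bundle` from [assemble_site()].
#' @param outdir output directory for the artifact set.
#' @return List with `repo_dir`, `payload_path` and the `payload` itself.
#' @export
publish_dryrun <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "site_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  repo_dir <- file.path(outdir, "repo")
  unlink(repo_dir, recursive = TRUE)
  dir.create(repo_dir, recursive = TRUE)
  for (f in bundle$manifest$path) {
    dest <- file.path(repo_dir, f)
    dir.create(dirname(dest), showWarnings = FALSE, recursive = TRUE)
    file.copy(file.path(bundle$root, f), dest, overwrite = TRUE,
              copy.date = FALSE)
  }
  file.copy(file.path(bundle$root, "manifest.json"),
            file.path(repo_dir, "manifest.json"), overwrite = TRUE)

  ds <- read_tidy(bundle$data_dir)
  payload <- list(
    schema_version = "1.0",
    n_subjects = length(ds$subject_ids),
    n_tracts = length(ds$tract_names),
    n_nodes = ds$n_nodes,
    metric_names = as.list(ds$metric_names),
    tract_names = as.list(ds$tract_names),
    metadata_columns = as.list(setdiff(names(ds$metadata), "subjectID")),
    params = if (length(ds$params)) ds$params else structure(list(),
                                                             names = character(0)),
    files = lapply(seq_len(nrow(bundle$manifest)), function(i) {
      list(path = bundle$manifest$path[i],
           size = bundle$manifest$size[i],
           sha256 = bundle$manifest$sha256[i])
    }))
  schema <- jsonlite::read_json(
    system.file("schema", "publish-payload.schema.json",
                package = "tractometry"))
  problems <- check_against_schema(payload, schema)
  if (length(problems)) {
    stop_tract("publish payload violates its schema: %s",
               paste(problems, collapse = "; "))
  }
  payload_path <- file.path(outdir, "payload.json")
  jsonlite::write_json(payload, payload_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(repo_dir = repo_dir, payload_path = payload_path, payload = payload)
}

# Minimal JSON-schema checker covering the subset the shipped schema uses:
# type, required, properties, items. Returns character vector of problems.
check_against_schema <- function(x, schema, path = "$") {
  problems <- character(0)
  type <- schema$type
  if (!is.null(type)) {
    ok <- switch(type,
      object = is.list(x) && (length(x) == 0L || !is.null(names(x))),
      array = is.list(x) && is.null(names(x)) || (is.atomic(x) &&
                                                  length(x) != 1L),
      string = is_string(x),
      number = is.numeric(x) && length(x) == 1L,
      integer = is.numeric(x) && length(x) == 1L && x == as.integer(x),
      boolean = is.logical(x) && length(x) == 1L,
      TRUE)
    if (!isTRUE(ok)) {
      return(sprintf("%s: expected %s", path, type))
    }
  }
  for (req in schema$required %||% list()) {
    if (!req %in% names(x)) {
      problems <- c(problems, sprintf("%s: missing required field %s",
                                      path, req))
    }
  }
  for (nm in names(schema$properties %||% list())) {
    if (nm %in% names(x)) {
      problems <- c(problems,
                    check_against_schema(x[[nm]], schema$properties[[nm]],
                                         paste0(path, ".", nm)))
    }
  }
  if (!is.null(schema$items) && identical(schema$type, "array")) {
    for (i in seq_along(x)) {
      problems <- c(problems,
                    check_against_schema(x[[i]], schema$items,
                                         sprintf("%s[%d]", path, i)))
    }
  }
  problems
}
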