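#' Reproducible viewer state
#'
#' The full state of an interactive tractometry view, serializable to a URL
#' query string so a specific view can be bookmarked, shared and re-opened
#' exactly. [encode_state()] and [decode_state()] are exact inverses.
#'
#' Fields and their defaults (fields at their default are omitted from the
#' encoded string, so the all-defaults state encodes to `""`):
#'
#' | field               | query key          | default        |
#' |---------------------|--------------------|----------------|
#' | `metric`            | `metric`           | none           |
#' | `selected_tracts`   | `selectedTracts`   | empty          |
#' | `group_key`         | `groupKey`         | none           |
#' | `n_groups`          | `nGroups`          | `1`            |
#' | `error_band`        | `errorBand`        | `"se"`         |
#' | `brushes`           | `brushes`          | empty          |
#' | `selected_subjects` | `selectedSubjects` | empty          |
#' | `table_sort`        | `tableSort`        | none           |
#'
#' Grammar: keys appear in lexicographic order joined by `&`; list elements
#' are percent-encoded (RFC 3986 unreserved set kept) and comma-joined; a
#' brush is `tract:start-end` (nodes 0-based inclusive); `table_sort` is
#' `column:asc` or `column:desc`. Brushes are kept sorted by tract name so
#' equal states encode identically.
#'
#' @param metric plotted metric name, or `NULL`.
#' @param selected_tracts ordered character vector of tract names.
#' @param group_key metadata column used for grouping, or `NULL`.
#' @param n_groups number of bins (>= 1).
#' @param error_band `"se"` or `"sd"` — the band drawn around mean lines.
#' @param brushes named list, tract name -> [node_range()] (2-vectors are
#'   coerced).
#' @param selected_subjects ordered character vector of subject IDs.
#' @param table_sort `NULL` or `list(column = <string>, ascending = <flag>)`.
#' @return An object of class `viewer_state`.
#' @export
#' @examples
#' s <- viewer_state(metric = "fa", group_key = "age", n_groups = 3)
#' encode_state(s)
#' identical(decode_state(encode_state(s)), s)
viewer_state <- function(metric = NULL, selected_tracts = character(),
                         group_key = NULL, n_groups = 1L,
                         error_band = c("se", "sd"), brushes = list(),
                         selected_subjects = character(),
                         table_sort = NULL) {
  error_band <- match.arg(error_band)
  if (!is.null(metric) && !is_string(metric)) {
    stop_tract("metric must be NULL or a single string")
  }
  if (!is.null(group_key) && !is_string(group_key)) {
    stop_tract("group_key must be NULL or a single string")
  }
  if (!is_count(n_groups)) stop_tract("n_groups must be a positive integer")
  if (length(brushes)) {
    if (is.null(names(brushes)) || any(!nzchar(names(brushes)))) {
      stop_tract("brushes must be a named list (tract name -> node range)")
    }
    brushes <- lapply(brushes, function(r) {
      if (inherits(r, "node_range")) r else node_range(r[1], r[2])
    })
    brushes <- brushes[order(names(brushes))]
  } else {
    brushes <- stats::setNames(list(), character(0))
  }
  if (!is.null(table_sort)) {
    if (!is.list(table_sort) || !is_string(table_sort$column) ||
        !is.logical(table_sort$ascending %||% NA) ||
        is.na(table_sort$ascending %||% NA)) {
      stop_tract(
        "table_sort must be NULL or list(column = <string>, ascending = <flag>)")
    }
    table_sort <- list(column = table_sort$column,
                       ascending = table_sort$ascending)
  }
  structure(
    list(metric = metric,
         selected_tracts = as.character(selected_tracts),
         group_key = group_key,
         n_groups = as.integer(n_groups),
         error_band = error_band,
         brushes = brushes,
         selected_subjects = as.character(selected_subjects),
         table_sort = table_sort),
    class = "viewer_state")
}

#' @export
print.viewer_state <- function(x, ...) {
  q <- encode_state(x)
  cat("<viewer_state> ", if (nzchar(q)) q else "(all defaults)", "\n",
      sep = "")
  invisible(x)
}

#' Encode a viewer state as a canonical query string
#'
#' @param s a [viewer_state()].
#' @return A single string; `""` for the all-defaults state.
#' @export
encode_state <- function(s) {
  stopifnot(inherits(s, "viewer_state"))
  parts <- character(0)
  add <- function(key, value) parts[[key]] <<- paste0(key, "=", value)

  if (length(s$brushes)) {
    add("brushes", paste(vapply(names(s$brushes), function(tr) {
      r <- s$brushes[[tr]]
      sprintf("%s:%d-%d", percent_encode(tr), r[["start"]], r[["end"]])
    }, character(1)), collapse = ","))
  }
  if (!identical(s$error_band, "se")) add("errorBand", s$error_band)
  if (!is.null(s$group_key)) add("groupKey", percent_encode(s$group_key))
  if (!is.null(s$metric)) add("metric", percent_encode(s$metric))
  if (s$n_groups != 1L) add("nGroups", as.character(s$n_groups))
  if (length(s$selected_subjects)) {
    add("selectedSubjects",
        paste(percent_encode(s$selected_subjects), collapse = ","))
  }
  if (length(s$selected_tracts)) {
    add("selectedTracts",
        paste(percent_encode(s$selected_tracts), collapse = ","))
  }
  if (!is.null(s$table_sort)) {
    add("tableSort", sprintf("%s:%s", percent_encode(s$table_sort$column),
                             if (s$table_sort$ascending) "asc" else "desc"))
  }
  if (!length(parts)) return("")
  paste(parts[order(names(parts))], collapse = "&")
}

#' Decode a query string into a viewer state
#'
#' Missing keys take their defaults (or the corresponding field of
#' `defaults`); unknown keys are dropped with a warning; malformed values for
#' known keys raise an error naming the key.
#'
#' @param q query string (a leading `?` is tolerated).
#' @param defaults state supplying values for absent keys.
#' @return A [viewer_state()].
#' @export
decode_state <- function(q, defaults = viewer_state()) {
  stopifnot(is.character(q), length(q) == 1L,
            inherits(defaults, "viewer_state"))
  fields <- unclass(defaults)
  q <- sub("^\\?", "", q)
  if (nzchar(q)) {
    for (pair in strsplit(q, "&", fixed = TRUE)[[1]]) {
      if (!nzchar(pair)) next
      eq <- regexpr("=", pair, fixed = TRUE)
      if (eq < 0L) {
        stop_tract("malformed query component %s (no '=')", sQuote(pair))
      }
      key <- substr(pair, 1L, eq - 1L)
      value <- substring(pair, eq + 1L)
      fields <- decode_state_key(fields, key, value)
    }
  }
  do.call(viewer_state, fields)
}

decode_state_key <- function(fields, key, value) {
  split_list <- function(v) {
    if (!nzchar(v)) character(0) else
      percent_decode(strsplit(v, ",", fixed = TRUE)[[1]])
  }
  switch(key,
    metric = { fields$metric <- percent_decode(value) },
    groupKey = { fields$group_key <- percent_decode(value) },
    errorBand = {
      if (!value %in% c("se", "sd")) {
        stop_tract("errorBand must be 'se' or 'sd', got %s", sQuote(value))
      }
      fields$error_band <- value
    },
    nGroups = {
      n <- suppressWarnings(as.integer(value))
      if (is.na(n) || n < 1L || as.character(n) != value) {
        stop_tract("nGroups must be a positive integer, got %s",
                   sQuote(value))
      }
      fields$n_groups <- n
    },
    selectedTracts = { fields$selected_tracts <- split_list(value) },
    selectedSubjects = { fields$selected_subjects <- split_list(value) },
    brushes = {
      entries <- if (nzchar(value)) strsplit(value, ",", fixed = TRUE)[[1]]
                 else character(0)
      brushes <- list()
      for (e in entries) {
        m <- regmatches(e, regexec("^(.*):([0-9]+)-([0-9]+)$", e))[[1]]
        if (length(m) != 4L) {
          stop_tract("brushes entry %s is not tract:start-end", sQuote(e))
        }
        brushes[[percent_decode(m[2])]] <-
          node_range(as.integer(m[3]), as.integer(m[4]))
      }
      fields$brushes <- brushes
    },
    tableSort = {
      m <- regmatches(value, regexec("^(.*):(asc|desc)$", value))[[1]]
      if (length(m) != 3L) {
        stop_tract("tableSort value %s is not column:asc|desc", sQuote(value))
      }
      fields$table_sort <- list(column = percent_decode(m[2]),
                                ascending = m[3] == "asc")
    },
    {
      warn_tract("ignoring unknown state key %s", sQuote(key))
    })
  fields
}

#' JSON form of a viewer state
#'
#' @param s a [viewer_state()].
#' @return A JSON string (class `json`).
#' @export
state_json <- function(s) {
  stopifnot(inherits(s, "viewer_state"))
  x <- unclass(s)
  x$brushes <- lapply(x$brushes, function(r) list(start = r[["start"]],
                                                  end = r[["end"]]))
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}
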