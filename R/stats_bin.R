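#' Bin subjects into groups on a metadata column
#'
#' Reproduces the grouping behind linked mean-line plots: pick a metadata
#' column, sort subjects by it, and divide them into `n_groups` bins. Subjects
#' with a missing value in `key` are left *unassigned* (excluded from every
#' group) rather than imputed.
#'
#' Methods:
#' * `"quantile"` (default) — near-equal group sizes (differing by at most 1),
#'   assigned in sorted order with a stable tie-break on (value, subject ID);
#' * `"equal_width"` — `n_groups` equal-width intervals spanning
#'   `[min, max]` of the observed values;
#' * `"explicit_edges"` — user-supplied interval edges; intervals are
#'   half-open `[e_i, e_{i+1})` with the last interval closed, values outside
#'   the edges are unassigned, and `n_groups` is taken from the edges;
#' * `"categorical"` — one group per distinct level, levels in sorted order,
#'   `n_groups` ignored.
#'
#' Numeric group labels are rendered `"lo–hi"`; categorical labels are the
#' level names.
#'
#' @param ds a [tractometry_dataset()].
#' @param key metadata column name.
#' @param n_groups number of groups (ignored for `"categorical"`,
#'   derived from `edges` for `"explicit_edges"`).
#' @param method binning method, see above.
#' @param edges numeric interval edges; required iff
#'   `method = "explicit_edges"`.
#' @return A `group_assignment`: list with `key`, `method`, `n_groups`,
#'   `edges`, `labels` and `assignment` (named integer vector of 0-based group
#'   indices over all subjects, `NA` = unassigned).
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_subjects = 12, seed = 2))
#' bin_subjects(ds, "age", n_groups = 3)
bin_subjects <- function(ds, key, n_groups = 2L,
                         method = c("quantile", "equal_width",
                                    "explicit_edges", "categorical"),
                         edges = NULL) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  method <- match.arg(method)
  if (!key %in% names(ds$metadata)) {
    stop_tract("unknown metadata column %s", sQuote(key))
  }
  if (xor(method == "explicit_edges", !is.null(edges))) {
    stop_tract("edges must be given iff method = 'explicit_edges'")
  }
  v <- ds$metadata[[key]]
  if (is.factor(v)) v <- as.character(v)
  numeric_method <- method %in% c("quantile", "equal_width", "explicit_edges")
  if (numeric_method && !is.numeric(v)) {
    stop_tract("metadata column %s is not numeric (required for method %s)",
               sQuote(key), sQuote(method))
  }
  assigned <- which(!is.na(v))
  assignment <- rep(NA_integer_, length(ds$subject_ids))
  names(assignment) <- ds$subject_ids

  if (method == "categorical") {
    labels <- sort(unique(as.character(v[assigned])))
    assignment[assigned] <- match(as.character(v[assigned]), labels) - 1L
    n_groups <- length(labels)
    edges <- NULL
  } else if (method == "quantile") {
    if (!is_count(n_groups)) stop_tract("n_groups must be a positive integer")
    n_groups <- as.integer(n_groups)
    if (n_groups > length(assigned)) {
      stop_tract("n_groups (%d) exceeds the %d subjects with a %s value",
                 n_groups, length(assigned), sQuote(key))
    }
    ord <- assigned[order(v[assigned], ds$subject_ids[assigned])]
    sizes <- rep(length(ord) %/% n_groups, n_groups)
    extra <- length(ord) %% n_groups
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    assignment[ord] <- rep(seq_len(n_groups) - 1L, times = sizes)
    labels <- vapply(seq_len(n_groups) - 1L, function(g) {
      gv <- v[assigned][assignment[assigned] == g]
      range_label(min(gv), max(gv))
    }, character(1))
    edges <- NULL
  } else {
    if (method == "equal_width") {
      if (!is_count(n_groups)) stop_tract("n_groups must be a positive integer")
      n_groups <- as.integer(n_groups)
      rng <- range(v[assigned])
      edges <- seq(rng[1], rng[2], length.out = n_groups + 1L)
    } else {
      edges <- as.numeric(edges)
      if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
        stop_tract("edges must be a strictly increasing vector of length >= 2")
      }
      n_groups <- length(edges) - 1L
    }
    idx <- findInterval(v[assigned], edges, rightmost.closed = TRUE)
    idx[idx < 1L | idx > n_groups] <- NA_integer_
    assignment[assigned] <- idx - 1L
    labels <- vapply(seq_len(n_groups), function(g) {
      range_label(edges[g], edges[g + 1L])
    }, character(1))
  }

  unassigned <- sum(is.na(assignment))
  structure(
    list(key = key, method = method, n_groups = n_groups, edges = edges,
         labels = labels, assignment = assignment,
         n_unassigned = unassigned),
    class = "group_assignment")
}

range_label <- function(lo, hi) {
  paste0(format(lo, trim = TRUE, digits = 7), "–",
         format(hi, trim = TRUE, digits = 7))
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> key=%s method=%s, %d group(s)\n",
              sQuote(x$key), x$method, x$n_groups))
  tab <- tabulate(x$assignment + 1L, nbins = x$n_groups)
  for (g in seq_len(x$n_groups)) {
    cat(sprintf("  [%d] %-12s n=%d\n", g - 1L, x$labels[g], tab[g]))
  }
  if (x$n_unassigned) cat(sprintf("  unassigned: %d\n", x$n_unassigned))
  invisible(x)
}

#' Subjects belonging to one group of an assignment
#'
#' @param ga a `group_assignment` from [bin_subjects()].
#' @param group 0-based group index or a group label.
#' @return Character vector of subject IDs.
#' @export
group_members <- function(ga, group) {
  stopifnot(inherits(ga, "group_assignment"))
  if (is.character(group)) {
    gi <- match(group, ga$labels) - 1L
    if (is.na(gi)) stop_tract("unknown group label %s", sQuote(group))
  } else {
    gi <- as.integer(group)
    if (is.na(gi) || gi < 0L || gi >= ga$n_groups) {
      stop_tract("group index %s out of range 0..%d", group, ga$n_groups - 1L)
    }
  }
  names(ga$assignment)[!is.na(ga$assignment) & ga$assignment == gi]
}
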