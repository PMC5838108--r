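#' Inclusive node range
#'
#' A contiguous, 0-based, both-ends-inclusive range of tract nodes, the unit
#' of brushing: "between nodes 50 and 80" selects 31 nodes.
#'
#' @param start,end 0-based node indices, `start <= end`.
#' @return Integer vector `c(start, end)` of class `node_range`.
#' @export
node_range <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start > end) {
    stop_tract("invalid node range [%s, %s]", start, end)
  }
  structure(c(start = start, end = end), class = "node_range")
}

# 1-based column indices of a (possibly NULL = whole-tract) range.
range_cols <- function(range, n_nodes) {
  if (is.null(range)) return(seq_len(n_nodes))
  if (!inherits(range, "node_range")) range <- node_range(range[1], range[2])
  if (range[["end"]] > n_nodes - 1L) {
    stop_tract("node range [%d, %d] exceeds n_nodes = %d",
               range[["start"]], range[["end"]], n_nodes)
  }
  (range[["start"]]:range[["end"]]) + 1L
}

#' Per-node summary of a group's Tract Profiles
#'
#' Computes, at every node of one (tract, metric) pair, the count of
#' non-missing member values, their mean, sample standard deviation (n - 1
#' denominator, since norms are estimated from a sample) and standard error
#' `sd / sqrt(n)`. These are the "mean lines" with +/- 1 SE (group
#' comparison) or +/- 1 SD (normative range) bands. `sd` and `se` are missing
#' wherever fewer than two member values are present; all fields are missing
#' at nodes where every member is missing.
#'
#' @param ds a [tractometry_dataset()].
#' @param tract,metric tract and metric name.
#' @param members non-empty character vector of subject IDs.
#' @param label group label carried along for display/serialization.
#' @return A `profile_summary`: list with `tract`, `metric`, `label` and
#'   per-node vectors `n`, `mean`, `sd`, `se`.
#' @export
group_profile <- function(ds, tract, metric, members,
                          label = "group") {
  stopifnot(inherits(ds, "tractometry_dataset"))
  if (!length(members)) stop_tract("empty member list")
  unknown <- setdiff(members, ds$subject_ids)
  if (length(unknown)) {
    stop_tract("unknown subject(s): %s", paste(unknown, collapse = ", "))
  }
  mat <- value_matrix(ds, metric, tract)[match(members, ds$subject_ids), ,
                                         drop = FALSE]
  summarize_profile_matrix(mat, tract, metric, label)
}

summarize_profile_matrix <- function(mat, tract, metric, label) {
  if (nrow(mat) == 0L) {
    nn <- ncol(mat)
    return(structure(
      list(tract = tract, metric = metric, label = label,
           n = integer(nn), mean = rep(NA_real_, nn),
           sd = rep(NA_real_, nn), se = rep(NA_real_, nn)),
      class = "profile_summary"))
  }
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  sdv <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  sdv[n < 2L] <- NA_real_
  se <- sdv / sqrt(n)
  structure(
    list(tract = tract, metric = metric, label = label,
         n = as.integer(n), mean = mu, sd = sdv, se = se),
    class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("<profile_summary> %s / %s (%s), %d nodes\n",
              x$tract, x$metric, x$label, length(x$n)))
  cat(sprintf("  n: %s;  mean range: [%.4g, %.4g]\n",
              paste(range(x$n), collapse = "-"),
              suppressWarnings(min(x$mean, na.rm = TRUE)),
              suppressWarnings(max(x$mean, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.profile_summary <- function(x, ...) {
  data.frame(tract = x$tract, metric = x$metric, group = x$label,
             node = seq_along(x$n) - 1L, n = x$n, mean = x$mean,
             sd = x$sd, se = x$se, stringsAsFactors = FALSE)
}

#' Per-group profile summaries for a whole assignment
#'
#' One [group_profile()] per group of a [bin_subjects()] assignment, in group
#' index order — the set of mean lines redrawn whenever a new metadata column
#' is selected. Empty groups yield an all-missing summary with `n = 0`.
#'
#' @param ds a [tractometry_dataset()].
#' @param ga a `group_assignment`.
#' @param tract,metric tract and metric name.
#' @return List of `profile_summary`, named by group label.
#' @export
compare_groups <- function(ds, ga, tract, metric) {
  stopifnot(inherits(ga, "group_assignment"))
  out <- vector("list", ga$n_groups)
  names(out) <- ga$labels
  for (g in seq_len(ga$n_groups)) {
    members <- group_members(ga, g - 1L)
    out[[g]] <- if (length(members)) {
      group_profile(ds, tract, metric, members, label = ga$labels[g])
    } else {
      summarize_profile_matrix(
        matrix(NA_real_, 0L, ds$n_nodes), tract, metric, ga$labels[g])
    }
  }
  out
}

#' Normative z-score profile of one subject
#'
#' Scores a subject's Tract Profile node-wise against the norms of a
#' reference group: `z[v] = (x[v] - mean_ref[v]) / sd_ref[v]`, the quantity
#' shown on hover over a selected profile and the basis of individual lesion
#' localization. By default the subject is removed from the reference before
#' the norms are computed (leave-self-out), so patient-versus-controls
#' comparisons are untouched and self-inclusion never shrinks the score.
#'
#' `z` is missing wherever the subject value or the reference SD is missing,
#' or the reference SD is zero (a warning is emitted for the degenerate-SD
#' case).
#'
#' @param ds a [tractometry_dataset()].
#' @param subject subject ID to score.
#' @param tract,metric tract and metric name.
#' @param reference character vector of reference subject IDs.
#' @param exclude_self drop `subject` from `reference` first (default TRUE).
#' @param label reference group label carried along.
#' @return A `z_profile`: list with `subject`, `tract`, `metric`, `label`,
#'   `ref_n` (per-node reference count) and per-node `z`.
#' @export
subject_zscores <- function(ds, subject, tract, metric, reference,
                            exclude_self = TRUE, label = "reference") {
  stopifnot(inherits(ds, "tractometry_dataset"))
  i <- subject_index(ds, subject)
  if (exclude_self) reference <- setdiff(reference, subject)
  if (!length(reference)) {
    stop_tract("reference group is empty%s",
               if (exclude_self) " after removing the subject itself" else "")
  }
  ref <- group_profile(ds, tract, metric, reference, label = label)
  x <- value_matrix(ds, metric, tract)[i, ]
  z <- (x - ref$mean) / ref$sd
  degenerate <- !is.na(ref$sd) & ref$sd == 0
  if (any(degenerate & !is.na(x))) {
    warn_tract("reference SD is zero at %d node(s); z set to missing there",
               sum(degenerate & !is.na(x)))
  }
  z[degenerate] <- NA_real_
  structure(
    list(subject = subject, tract = tract, metric = metric, label = label,
         ref_n = ref$n, z = z),
    class = "z_profile")
}

#' @export
print.z_profile <- function(x, ...) {
  ok <- !is.na(x$z)
  cat(sprintf("<z_profile> subject %s vs %s on %s / %s\n",
              x$subject, x$label, x$tract, x$metric))
  if (any(ok)) {
    pk <- summarize_z(x, how = "peak")
    cat(sprintf("  peak z = %.3g at node %d (%d/%d nodes scored)\n",
                pk$value, pk$node, sum(ok), length(x$z)))
  } else cat("  all nodes missing\n")
  invisible(x)
}

#' @export
as.data.frame.z_profile <- function(x, ...) {
  data.frame(subject = x$subject, tract = x$tract, metric = x$metric,
             reference = x$label, node = seq_along(x$z) - 1L,
             ref_n = x$ref_n, z = x$z, stringsAsFactors = FALSE)
}

#' Reduce a z-profile to a single score
#'
#' A lesion is reported as one number per tract: with `how = "peak"` (the
#' default) the *signed* z value at the node of maximum `|z|` within the
#' range (ties broken toward the lowest node index), so "5.6 SD away from the
#' norms" keeps its sign; a mean would dilute a focal lesion, but
#' `how = "mean"` is available for diffuse effects.
#'
#' @param zp a `z_profile` from [subject_zscores()].
#' @param range optional [node_range()]; default is the whole tract.
#' @param how `"peak"` or `"mean"`.
#' @return List with `value` (the score) and, for `"peak"`, `node` (0-based
#'   argmax node; `NA` for `"mean"`).
#' @export
summarize_z <- function(zp, range = NULL, how = c("peak", "mean")) {
  stopifnot(inherits(zp, "z_profile"))
  how <- match.arg(how)
  cols <- range_cols(range, length(zp$z))
  z <- zp$z[cols]
  if (all(is.na(z))) stop_tract("no non-missing z values in the given range")
  if (how == "peak") {
    a <- abs(z)
    a[is.na(a)] <- -Inf
    i <- which.max(a)
    list(value = z[i], node = cols[i] - 1L, how = "peak")
  } else {
    list(value = mean(z, na.rm = TRUE), node = NA_integer_, how = "mean")
  }
}

#' Fraction of a group deviating from reference norms
#'
#' Scores every group member against the reference norms and reports the
#' fraction whose z-profile exceeds `threshold` (strictly) at one or more
#' nodes within `range` — e.g. "the majority of patients deviated by more
#' than 1 SD from control values" near the cerebral peduncle. `direction`
#' selects `|z|` (default, deviation without sign), `z` (positive only) or
#' `-z` (negative only).
#'
#' @param ds a [tractometry_dataset()].
#' @param group character vector of subject IDs to score (e.g. patients).
#' @param reference character vector of reference subject IDs (e.g.
#'   controls); must be disjoint from `group`.
#' @param tract,metric tract and metric name.
#' @param threshold positive deviation threshold in SD units.
#' @param range optional [node_range()] restricting the scan.
#' @param direction `"absolute"`, `"positive"` or `"negative"`.
#' @return Fraction in \[0, 1\], with attribute `deviant`: named logical over
#'   the group (`NA` where a member had no scoreable node).
#' @export
fraction_deviant <- function(ds, group, reference, tract, metric, threshold,
                             range = NULL,
                             direction = c("absolute", "positive",
                                           "negative")) {
  stopifnot(inherits(ds, "tractometry_dataset"))
  direction <- match.arg(direction)
  if (!length(group) || !length(reference)) {
    stop_tract("group and reference must be non-empty")
  }
  overlap <- intersect(group, reference)
  if (length(overlap)) {
    stop_tract("group and reference overlap: %s",
               paste(overlap, collapse = ", "))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop_tract("threshold must be a single non-negative number")
  }
  deviant <- vapply(group, function(s) {
    zp <- subject_zscores(ds, s, tract, metric, reference,
                          exclude_self = FALSE)
    z <- zp$z[range_cols(range, length(zp$z))]
    if (all(is.na(z))) return(NA)
    score <- switch(direction, absolute = abs(z), positive = z,
                    negative = -z)
    any(score > threshold, na.rm = TRUE)
  }, logical(1))
  frac <- sum(deviant, na.rm = TRUE) / length(group)
  structure(frac, deviant = deviant)
}

#' Node mask for brushed ranges
#'
#' Boolean per-node mask that is `TRUE` exactly on the union of the given
#' inclusive ranges — the link between a brushed region of the profile plot
#' and the highlighted portion of tract anatomy.
#'
#' @param n_nodes number of nodes.
#' @param ranges list of [node_range()] (or 2-vectors `c(start, end)`).
#' @return Logical vector of length `n_nodes`; element `v + 1` corresponds to
#'   node `v`.
#' @export
#' @examples
#' sum(brush_mask(100, list(node_range(50, 80))))  # 31
brush_mask <- function(n_nodes, ranges = list()) {
  stopifnot(is_count(n_nodes))
  mask <- rep(FALSE, n_nodes)
  for (r in ranges) mask[range_cols(r, n_nodes)] <- TRUE
  mask
}
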