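#' Validate a tractometry dataset
#'
#' Checks every structural invariant of a [tractometry_dataset()] and the
#' plausibility of metric values, returning findings rather than raising.
#' A dataset is *valid* when the report contains no error-severity finding;
#' out-of-range metric values (FA outside \[0, 1\], non-positive
#' diffusivities) are reported as warnings, because real pipelines do emit
#' occasional boundary artifacts.
#'
#' @param ds object to validate (normally a [tractometry_dataset()]).
#' @return A `validation_report`: data frame with columns `severity`
#'   (`"error"` or `"warning"`), `code`, `message` and `locus`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_subjects = 3, seed = 1))
#' rep <- validate_dataset(ds)
#' is_valid(rep)
validate_dataset <- function(ds) {
  findings <- list()
  add <- function(severity, code, message, locus = "") {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, code = code, message = message,
                 locus = locus, stringsAsFactors = FALSE)
  }

  if (!inherits(ds, "tractometry_dataset")) {
    add("error", "not_dataset", "object is not a tractometry_dataset")
    return(new_validation_report(findings))
  }

  if (anyDuplicated(ds$subject_ids)) {
    add("error", "dup_subject", "subject IDs are not unique")
  }
  if (anyDuplicated(ds$tract_names)) {
    add("error", "dup_tract", "tract names are not unique")
  }

  for (m in names(ds$values)) {
    for (tr in names(ds$values[[m]])) {
      mat <- ds$values[[m]][[tr]]
      locus <- sprintf("metric=%s tract=%s", m, tr)
      if (!is.matrix(mat)) {
        add("error", "not_matrix", "value entry is not a matrix", locus)
        next
      }
      if (nrow(mat) != length(ds$subject_ids)) {
        add("error", "bad_rows",
            sprintf("matrix has %d rows but dataset has %d subjects",
                    nrow(mat), length(ds$subject_ids)), locus)
      }
      if (ncol(mat) != ds$n_nodes) {
        add("error", "bad_cols",
            sprintf("matrix has %d columns but n_nodes is %d",
                    ncol(mat), ds$n_nodes), locus)
      }
      if (nrow(mat) == length(ds$subject_ids) && ncol(mat) == ds$n_nodes) {
        if (m == "fa") {
          bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
          for (k in seq_len(min(nrow(bad), 10L))) {
            add("warning", "fa_range",
                sprintf("FA value %g outside [0, 1]", mat[bad[k, 1], bad[k, 2]]),
                sprintf("subject=%s tract=%s node=%d",
                        ds$subject_ids[bad[k, 1]], tr, bad[k, 2] - 1L))
          }
        }
        if (m %in% c("md", "rd", "ad")) {
          bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
          for (k in seq_len(min(nrow(bad), 10L))) {
            add("warning", "diffusivity_range",
                sprintf("non-positive diffusivity %g",
                        mat[bad[k, 1], bad[k, 2]]),
                sprintf("subject=%s tract=%s node=%d",
                        ds$subject_ids[bad[k, 1]], tr, bad[k, 2] - 1L))
          }
        }
      }
    }
  }

  if (!is.data.frame(ds$metadata) || !"subjectID" %in% names(ds$metadata)) {
    add("error", "metadata_schema", "metadata lacks a subjectID column")
  } else {
    if (!identical(as.character(ds$metadata$subjectID), ds$subject_ids)) {
      missing_rows <- setdiff(ds$subject_ids, ds$metadata$subjectID)
      extra_rows <- setdiff(ds$metadata$subjectID, ds$subject_ids)
      if (length(missing_rows)) {
        add("error", "metadata_missing",
            sprintf("metadata lacks rows for: %s",
                    paste(missing_rows, collapse = ", ")))
      }
      if (length(extra_rows)) {
        add("error", "metadata_unknown",
            sprintf("metadata has rows for unknown subjects: %s",
                    paste(extra_rows, collapse = ", ")))
      }
      if (!length(missing_rows) && !length(extra_rows)) {
        add("error", "metadata_order",
            "metadata rows are not in subject_ids order")
      }
    }
  }

  new_validation_report(findings)
}

new_validation_report <- function(findings) {
  out <- if (length(findings)) {
    do.call(rbind, findings)
  } else {
    data.frame(severity = character(), code = character(),
               message = character(), locus = character(),
               stringsAsFactors = FALSE)
  }
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @rdname validate_dataset
#' @param report a `validation_report`.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  !any(report$severity == "error")
}

#' @export
print.validation_report <- function(x, ...) {
  ne <- sum(x$severity == "error"); nw <- sum(x$severity == "warning")
  cat(sprintf("<validation_report> %d error(s), %d warning(s)%s\n",
              ne, nw, if (ne == 0) " - dataset is valid" else ""))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s%s\n", x$severity[i], x$code[i], x$message[i],
                  if (nzchar(x$locus[i])) paste0(" (", x$locus[i], ")") else ""))
    }
  }
  invisible(x)
}
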