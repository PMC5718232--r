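# Log integrity and plan/log identity checks.

#' Check delivery-log integrity and identity against a plan
#'
#' Structural checks on the log (truncation against the header's declared
#' sample count, monotonic cumulative meterset, consistent leaf counts,
#' presence of beam-on samples) plus the patient/beam identity match with
#' the plan.  All findings are report codes, never exceptions, so a QA
#' pipeline can always render a report for a bad log.
#'
#' Finding codes: \code{TRUNCATED}, \code{NON_MONOTONIC_METERSET},
#' \code{LEAF_COUNT_MISMATCH}, \code{EMPTY_BEAM}, \code{ID_MISMATCH}.
#'
#' @param log a [delivery_log()]
#' @param plan a [treatment_plan()], or NULL to skip identity checks
#' @return an \code{integrity_report}: list with \code{intact} (no
#'   structural issue), \code{identity_match}, and \code{issues} (character
#'   vector of codes)
#' @export
check_integrity <- function(log, plan = NULL) {
  issues <- character(0)
  n <- log_sample_count(log)
  if (n != log$declared_sample_count)
    issues <- c(issues, "TRUNCATED")
  m <- log$samples$meterset
  if (n > 1 && any(diff(m) < -1e-9))
    issues <- c(issues, "NON_MONOTONIC_METERSET")
  if (n == 0 || !any(log$samples$beam_on))
    issues <- c(issues, "EMPTY_BEAM")
  identity_match <- TRUE
  if (!is.null(plan)) {
    beam_ids <- vapply(plan$beams, function(b) b$beam_id, character(1))
    if (log$patient_id != plan$patient_id || !(log$beam_id %in% beam_ids)) {
      identity_match <- FALSE
      issues <- c(issues, "ID_MISMATCH")
    }
    if (log$beam_id %in% beam_ids) {
      beam <- plan$beams[[match(log$beam_id, beam_ids)]]
      if (n > 0 && log_leaf_pairs(log) != n_leaf_pairs(beam))
        issues <- c(issues, "LEAF_COUNT_MISMATCH")
    }
  }
  structural <- setdiff(issues, "ID_MISMATCH")
  structure(
    list(intact = length(structural) == 0,
         identity_match = identity_match,
         issues = issues),
    class = "integrity_report"
  )
}

#' @export
print.integrity_report <- function(x, ...) {
  cat(sprintf("<integrity_report> intact: %s, identity_match: %s\n",
              x$intact, x$identity_match))
  if (length(x$issues)) cat("  issues:", paste(x$issues, collapse = ", "), "\n")
  invisible(x)
}
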