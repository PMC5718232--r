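# Canonical delivery-log dialect (version 1), modeled on the content of a
# Varian DynaLog file but with a documented byte layout:
#
#   IMRTQA-LOG 1
#   patient_id: <string>
#   beam_id: <string>
#   sampling_period_ms: <number>
#   total_mu: <%.4f>
#   n_leaf_pairs: <int>
#   n_samples: <int>                 (declared count; header truth)
#   S <t> <on> <gantry> <coll> <x1> <x2> <y1> <y2> <meterset> \
#     <exp_a ...> <exp_b ...> <act_a ...> <act_b ...>
#
# One "S" row per 50 ms sample: integer time index, beam state 0/1, angles
# and jaw positions (%.4f), cumulative meterset fraction (%.6f), then four
# blocks of n_leaf_pairs leaf positions (%.4f) — expected bank A, expected
# bank B, actual bank A, actual bank B.  A file whose row count differs from
# n_samples parses successfully but is reported non-intact by
# check_integrity().

#' Read a delivery log file
#'
#' Parses the canonical log dialect.  Truncation (fewer sample rows than the
#' header declares) is not an error: the log is returned and flagged
#' non-intact by [check_integrity()].
#'
#' @param path path to a log file
#' @return a [delivery_log()]
#' @section Errors: signals \code{PARSE_ERROR} for malformed files.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop_coded("PARSE_ERROR", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != log_magic)
    stop_coded("PARSE_ERROR", "missing IMRTQA-LOG 1 header line")
  i <- 2
  patient_id <- expect_key(lines, i, "patient_id"); i <- i + 1
  beam_id <- expect_key(lines, i, "beam_id"); i <- i + 1
  period <- parse_nums(expect_key(lines, i, "sampling_period_ms"), "period", i); i <- i + 1
  total_mu <- parse_nums(expect_key(lines, i, "total_mu"), "MU", i); i <- i + 1
  np <- as.integer(parse_nums(expect_key(lines, i, "n_leaf_pairs"), "leaf count", i)); i <- i + 1
  declared <- as.integer(parse_nums(expect_key(lines, i, "n_samples"), "sample count", i)); i <- i + 1
  rows <- lines[seq.int(i, length.out = max(0, length(lines) - i + 1))]
  rows <- rows[nzchar(trimws(rows))]
  n <- length(rows)
  ncol_expect <- 9 + 4 * np
  time_index <- integer(n); beam_on <- logical(n)
  gantry <- numeric(n); collimator <- numeric(n)
  jaws <- matrix(0, n, 4, dimnames = list(NULL, c("x1", "x2", "y1", "y2")))
  meterset <- numeric(n)
  exp_a <- matrix(0, n, np); exp_b <- matrix(0, n, np)
  act_a <- matrix(0, n, np); act_b <- matrix(0, n, np)
  for (k in seq_len(n)) {
    f <- split_fields(rows[k])
    if (f[1] != "S" || length(f) != 1 + ncol_expect)
      stop_coded("PARSE_ERROR", sprintf(
        "sample row %d: expected 'S' plus %d fields, got %d",
        k, ncol_expect, length(f) - 1))
    v <- parse_nums(f[-1], "sample values", i + k - 1)
    time_index[k] <- as.integer(v[1])
    beam_on[k] <- v[2] != 0
    gantry[k] <- v[3]; collimator[k] <- v[4]
    jaws[k, ] <- v[5:8]
    meterset[k] <- v[9]
    base <- 9
    exp_a[k, ] <- v[base + seq_len(np)]
    exp_b[k, ] <- v[base + np + seq_len(np)]
    act_a[k, ] <- v[base + 2 * np + seq_len(np)]
    act_b[k, ] <- v[base + 3 * np + seq_len(np)]
  }
  delivery_log(
    patient_id = patient_id, beam_id = beam_id,
    sampling_period_ms = period, total_mu = total_mu,
    samples = list(time_index = time_index, beam_on = beam_on,
                   gantry = gantry, collimator = collimator, jaws = jaws,
                   meterset = meterset, exp_a = exp_a, exp_b = exp_b,
                   act_a = act_a, act_b = act_b),
    declared_sample_count = declared
  )
}

#' Write a delivery log file
#'
#' Serializes to the canonical log dialect with fixed decimal precision so
#' round-trips are byte-exact.  The header's \code{n_samples} is the log's
#' \code{declared_sample_count}, so a truncated log round-trips as truncated.
#'
#' @param log a [delivery_log()]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_log <- function(log, path) {
  validate_delivery_log(log)
  s <- log$samples
  n <- log_sample_count(log)
  header <- c(
    log_magic,
    paste0("patient_id: ", log$patient_id),
    paste0("beam_id: ", log$beam_id),
    paste0("sampling_period_ms: ", format(log$sampling_period_ms)),
    paste0("total_mu: ", fmt_mu(log$total_mu)),
    paste0("n_leaf_pairs: ", log_leaf_pairs(log)),
    paste0("n_samples: ", log$declared_sample_count)
  )
  rows <- character(n)
  for (k in seq_len(n)) {
    rows[k] <- paste(
      "S", s$time_index[k], as.integer(s$beam_on[k]),
      fmt_deg(s$gantry[k]), fmt_deg(s$collimator[k]),
      paste(fmt_mm(s$jaws[k, ]), collapse = " "),
      fmt_frac(s$meterset[k]),
      paste(fmt_mm(s$exp_a[k, ]), collapse = " "),
      paste(fmt_mm(s$exp_b[k, ]), collapse = " "),
      paste(fmt_mm(s$act_a[k, ]), collapse = " "),
      paste(fmt_mm(s$act_b[k, ]), collapse = " "))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
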