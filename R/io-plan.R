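# Canonical plan dialect (version 1).
#
# A plan file is line-oriented UTF-8 text:
#
#   IMRTQA-PLAN 1
#   patient_name: <string>
#   patient_id: <string>
#   prescription_dose_gy: <%.4f>
#   n_beams: <int>
#   BEAM                            (repeated n_beams times)
#   beam_id: <string>
#   energy: <string>
#   gantry_deg: <%.4f>
#   collimator_deg: <%.4f>
#   jaws_mm: <x1> <x2> <y1> <y2>    (each %.4f)
#   total_mu: <%.4f>
#   leaf_boundaries_mm: <b0> ... <bN>  (each %.4f)
#   n_control_points: <int>
#   CP <index> <fraction %.6f>      (repeated; followed by two bank lines)
#   A <pos> ... <pos>               (bank A tips, %.4f)
#   B <pos> ... <pos>               (bank B tips, %.4f)
#
# All numbers use "." as the decimal mark and no grouping, independent of
# locale.  Files written by write_plan() are canonical: read_plan() followed
# by write_plan() reproduces them byte-for-byte.

plan_magic <- "IMRTQA-PLAN 1"
log_magic <- "IMRTQA-LOG 1"

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

parse_nums <- function(fields, what, line_no) {
  v <- suppressWarnings(as.numeric(fields))
  if (anyNA(v))
    stop_coded("PARSE_ERROR", sprintf("line %d: non-numeric %s", line_no, what))
  v
}

expect_key <- function(lines, i, key) {
  if (i > length(lines))
    stop_coded("PARSE_ERROR", sprintf("unexpected end of file, expected '%s:'", key))
  prefix <- paste0(key, ":")
  if (!startsWith(lines[i], prefix))
    stop_coded("PARSE_ERROR",
               sprintf("line %d: expected '%s:', got '%s'", i, key, lines[i]))
  sub("^\\s*", "", substring(lines[i], nchar(prefix) + 1))
}

#' Read a treatment plan file
#'
#' Parses the canonical plan text dialect (see the package README for the
#' format).  Angles are normalized to \[0, 360) and all positions are mm at
#' the isocenter plane.
#'
#' @param path path to a plan file
#' @param dialect currently only \code{"text"}, the canonical dialect
#' @return a [treatment_plan()]
#' @section Errors: signals a condition of class \code{PARSE_ERROR} for a
#'   malformed file and \code{INVARIANT_ERROR} for a well-formed file whose
#'   values violate the plan invariants (e.g. decreasing meterset fractions).
#' @export
read_plan <- function(path, dialect = c("text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_coded("PARSE_ERROR", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != plan_magic)
    stop_coded("PARSE_ERROR", "missing IMRTQA-PLAN 1 header line")
  i <- 2
  patient_name <- expect_key(lines, i, "patient_name"); i <- i + 1
  patient_id <- expect_key(lines, i, "patient_id"); i <- i + 1
  rx <- parse_nums(expect_key(lines, i, "prescription_dose_gy"), "dose", i); i <- i + 1
  n_beams <- as.integer(parse_nums(expect_key(lines, i, "n_beams"), "beam count", i)); i <- i + 1
  beams <- vector("list", n_beams)
  for (bi in seq_len(n_beams)) {
    if (i > length(lines) || lines[i] != "BEAM")
      stop_coded("PARSE_ERROR", sprintf("line %d: expected 'BEAM'", i))
    i <- i + 1
    beam_id <- expect_key(lines, i, "beam_id"); i <- i + 1
    energy <- expect_key(lines, i, "energy"); i <- i + 1
    gantry <- parse_nums(expect_key(lines, i, "gantry_deg"), "angle", i); i <- i + 1
    coll <- parse_nums(expect_key(lines, i, "collimator_deg"), "angle", i); i <- i + 1
    jaws <- parse_nums(split_fields(expect_key(lines, i, "jaws_mm")), "jaws", i); i <- i + 1
    if (length(jaws) != 4) stop_coded("PARSE_ERROR", "jaws_mm needs 4 values")
    mu <- parse_nums(expect_key(lines, i, "total_mu"), "MU", i); i <- i + 1
    lb <- parse_nums(split_fields(expect_key(lines, i, "leaf_boundaries_mm")),
                     "leaf boundaries", i); i <- i + 1
    n_cp <- as.integer(parse_nums(expect_key(lines, i, "n_control_points"),
                                  "CP count", i)); i <- i + 1
    cps <- vector("list", n_cp)
    for (ci in seq_len(n_cp)) {
      f <- split_fields(lines[i])
      if (length(f) != 3 || f[1] != "CP")
        stop_coded("PARSE_ERROR", sprintf("line %d: expected 'CP <index> <fraction>'", i))
      idx <- as.integer(parse_nums(f[2], "CP index", i))
      frac <- parse_nums(f[3], "CP fraction", i)
      i <- i + 1
      fa <- split_fields(lines[i])
      if (fa[1] != "A") stop_coded("PARSE_ERROR", sprintf("line %d: expected bank 'A'", i))
      bank_a <- parse_nums(fa[-1], "bank A", i); i <- i + 1
      fb <- split_fields(lines[i])
      if (fb[1] != "B") stop_coded("PARSE_ERROR", sprintf("line %d: expected bank 'B'", i))
      bank_b <- parse_nums(fb[-1], "bank B", i); i <- i + 1
      cps[[ci]] <- control_point(idx, frac, bank_a, bank_b)
    }
    beams[[bi]] <- beam_plan(beam_id, gantry, coll,
                             c(x1 = jaws[1], x2 = jaws[2], y1 = jaws[3], y2 = jaws[4]),
                             mu, energy, cps, lb)
  }
  treatment_plan(patient_name, patient_id, rx, beams)
}

#' Write a treatment plan file
#'
#' Serializes to the canonical plan dialect with fixed decimal precision
#' (positions and angles to 0.1 um, meterset fractions to 1e-6) so that
#' read/write round-trips are byte-exact.
#'
#' @param plan a [treatment_plan()]
#' @param path output file path
#' @param dialect currently only \code{"text"}
#' @return \code{path}, invisibly
#' @export
write_plan <- function(plan, path, dialect = c("text")) {
  dialect <- match.arg(dialect)
  validate_treatment_plan(plan)
  out <- c(
    plan_magic,
    paste0("patient_name: ", plan$patient_name),
    paste0("patient_id: ", plan$patient_id),
    paste0("prescription_dose_gy: ", fmt_mu(plan$prescription_dose)),
    paste0("n_beams: ", length(plan$beams))
  )
  for (b in plan$beams) {
    out <- c(out,
      "BEAM",
      paste0("beam_id: ", b$beam_id),
      paste0("energy: ", b$energy_label),
      paste0("gantry_deg: ", fmt_deg(b$gantry_angle)),
      paste0("collimator_deg: ", fmt_deg(b$collimator_angle)),
      paste0("jaws_mm: ", paste(fmt_mm(b$jaws), collapse = " ")),
      paste0("total_mu: ", fmt_mu(b$total_mu)),
      paste0("leaf_boundaries_mm: ", paste(fmt_mm(b$leaf_boundaries), collapse = " ")),
      paste0("n_control_points: ", length(b$control_points))
    )
    for (cp in b$control_points) {
      out <- c(out,
        paste("CP", cp$index, fmt_frac(cp$cumulative_meterset_fraction)),
        paste("A", paste(fmt_mm(cp$bank_a), collapse = " ")),
        paste("B", paste(fmt_mm(cp$bank_b), collapse = " ")))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
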