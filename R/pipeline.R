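# End-to-end QA pipeline: integrity -> parameter compare -> fluence ->
# gamma -> DVH compare, with one report bundle per run.

#' QA pipeline configuration
#'
#' Bundles the per-stage settings with their clinical defaults: parameter
#' tolerances 0.1 deg / 0.1 deg / 1 mm / 2 mm, fluence passing thresholds
#' 2% and 3% of maximum fluence, gamma 3%/3 mm, and a 3% DVH mean-dose
#' agreement threshold between the two dose calculations.
#'
#' @param tolerances a [tolerances()] object
#' @param gamma a [gamma_criteria()] object
#' @param fluence_thresholds_pct fluence error thresholds, % of max fluence
#' @param dvh_agreement_pct mean-dose agreement threshold between dose
#'   calculations, %
#' @param gamma_pass_threshold_pct minimum acceptable gamma pass rate, %
#'   (the 90% default is a package choice, configurable)
#' @param fluence_pixel_mm fluence grid pixel size
#' @param dvh_bin_gy DVH bin width
#' @return a \code{qa_config}
#' @export
qa_config <- function(tolerances = imrtqa::tolerances(),
                      gamma = gamma_criteria(),
                      fluence_thresholds_pct = c(2, 3),
                      dvh_agreement_pct = 3,
                      gamma_pass_threshold_pct = 90,
                      fluence_pixel_mm = 1,
                      dvh_bin_gy = 0.01) {
  if (dvh_agreement_pct <= 0 || any(fluence_thresholds_pct <= 0) ||
      gamma_pass_threshold_pct <= 0)
    stop_coded("INVARIANT_ERROR", "thresholds must be positive")
  structure(list(config_version = 1L, tolerances = tolerances, gamma = gamma,
                 fluence_thresholds_pct = fluence_thresholds_pct,
                 dvh_agreement_pct = dvh_agreement_pct,
                 gamma_pass_threshold_pct = gamma_pass_threshold_pct,
                 fluence_pixel_mm = fluence_pixel_mm, dvh_bin_gy = dvh_bin_gy),
            class = "qa_config")
}

#' Run the full calculation-based QA pipeline
#'
#' Executes, per beam: log integrity and identity checks, delivered-vs-
#' planned parameter comparison, and fluence reconstruction/differencing;
#' then, if two dose planes are supplied, the 2D gamma comparison; and if
#' two dose grids plus structures are supplied, the DVH index comparison.
#' Writes a report bundle (\code{report.json}, \code{report.txt},
#' \code{report.html}, \code{dvh_comparison.csv}) to \code{out_dir}.
#'
#' @param plan a [treatment_plan()] or path to a plan file
#' @param logs list of [delivery_log()]s or a directory of \code{.log} files
#' @param dose_ref,dose_eval optional [dose_plane()]s for gamma analysis
#' @param dose_grid_a,dose_grid_b optional [dose_grid()]s for DVH comparison
#' @param structures optional list of [structure_mask()]
#' @param config a [qa_config()]
#' @param out_dir output directory for the report bundle (NULL: no files)
#' @return a \code{qa_run}: list with \code{status} (0 all pass, 2 any
#'   warning), \code{beam_reports}, \code{gamma}, \code{dvh_table},
#'   \code{warnings} (character vector naming every failed check)
#' @export
run_qa <- function(plan, logs, dose_ref = NULL, dose_eval = NULL,
                   dose_grid_a = NULL, dose_grid_b = NULL, structures = NULL,
                   config = qa_config(), out_dir = NULL) {
  if (is.character(plan)) plan <- read_plan(plan)
  if (is.character(logs)) {
    paths <- sort(list.files(logs, pattern = "\\.log$", full.names = TRUE))
    logs <- lapply(paths, read_log)
  }
  warnings <- character(0)
  beam_ids <- vapply(plan$beams, function(b) b$beam_id, character(1))
  beam_reports <- list()
  for (log in logs) {
    bi <- match(log$beam_id, beam_ids)
    if (is.na(bi)) {
      warnings <- c(warnings, sprintf("log beam %s not in plan", log$beam_id))
      next
    }
    beam <- plan$beams[[bi]]
    grid <- default_fluence_grid(beam, pixel_mm = config$fluence_pixel_mm)
    rep_b <- compare_beam(beam, log, config$tolerances, grid, plan)
    beam_reports[[log$beam_id]] <- rep_b
    if (rep_b$overall_status == "WARNING") {
      bad <- rep_b$checks$name[rep_b$checks$status == "WARNING"]
      if (!rep_b$integrity$intact || !rep_b$integrity$identity_match)
        bad <- c(bad, rep_b$integrity$issues)
      warnings <- c(warnings, sprintf("beam %s: %s", log$beam_id,
                                      paste(bad, collapse = ", ")))
    }
  }
  gamma_res <- NULL
  if (!is.null(dose_ref) && !is.null(dose_eval)) {
    gamma_res <- gamma_map(dose_ref, dose_eval, config$gamma)
    if (gamma_res$pass_rate < config$gamma_pass_threshold_pct)
      warnings <- c(warnings, sprintf("gamma pass rate %.1f%% < %g%%",
                                      gamma_res$pass_rate,
                                      config$gamma_pass_threshold_pct))
  }
  dvh_table <- NULL
  if (!is.null(dose_grid_a) && !is.null(dose_grid_b) && length(structures)) {
    specs <- list(dvh_spec("MEAN"), dvh_spec("D_MIN"), dvh_spec("D_MAX"),
                  dvh_spec("V_REL", 95), dvh_spec("HOMOGENEITY", 5, 95))
    dvh_table <- compare_plans(dose_grid_a, dose_grid_b, structures, specs,
                               prescription = plan$prescription_dose,
                               agreement_pct = config$dvh_agreement_pct,
                               bin_gy = config$dvh_bin_gy)
    flagged <- dvh_table[dvh_table$flagged, , drop = FALSE]
    if (nrow(flagged))
      warnings <- c(warnings, sprintf(
        "DVH mean-dose disagreement > %g%% for: %s", config$dvh_agreement_pct,
        paste(unique(flagged$structure), collapse = ", ")))
  }
  status <- if (length(warnings)) 2L else 0L
  result <- structure(
    list(status = status, beam_reports = beam_reports, gamma = gamma_res,
         dvh_table = dvh_table, warnings = warnings),
    class = "qa_run")
  if (!is.null(out_dir)) write_qa_bundle(result, out_dir)
  result
}

qa_run_json <- function(run) {
  jsonlite::toJSON(list(
    report_version = 1L,
    status = run$status,
    warnings = as.list(run$warnings),
    beams = lapply(unname(run$beam_reports), report_to_list),
    gamma = if (!is.null(run$gamma)) list(
      pass_rate = run$gamma$pass_rate, mean_gamma = run$gamma$mean_gamma,
      evaluated_count = run$gamma$evaluated_count,
      dose_tol_pct = run$gamma$criteria$dose_tol_pct,
      dta_mm = run$gamma$criteria$dta_mm),
    dvh = if (!is.null(run$dvh_table)) run$dvh_table
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows", na = "null")
}

write_qa_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(as.character(qa_run_json(run)), file.path(out_dir, "report.json"))
  if (length(run$beam_reports)) {
    writeLines(render_report(unname(run$beam_reports), "text"),
               file.path(out_dir, "report.txt"))
    writeLines(render_report(unname(run$beam_reports), "html"),
               file.path(out_dir, "report.html"))
  }
  if (!is.null(run$dvh_table))
    write.csv(run$dvh_table, file.path(out_dir, "dvh_comparison.csv"),
              row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.qa_run <- function(x, ...) {
  cat(sprintf("<qa_run> status %d (%s)\n", x$status,
              if (x$status == 0) "all checks PASS" else "WARNINGS present"))
  for (w in x$warnings) cat("  WARNING:", w, "\n")
  invisible(x)
}
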