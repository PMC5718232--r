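# Delivered-vs-planned machine parameter comparison.

#' Clinical comparison tolerances
#'
#' Defaults are the clinical log-QA tolerances: 0.1 degrees for gantry and
#' collimator angle, 1 mm for jaw positions, 2 mm for MLC leaf positions.
#' The MU tolerance has no established clinical value; the 1% default is a
#' package choice, configurable.
#'
#' @param gantry_deg,collimator_deg angle tolerances in degrees
#' @param jaw_mm jaw position tolerance in mm
#' @param mlc_mm MLC leaf position tolerance in mm
#' @param mu_percent delivered-MU tolerance in percent of planned MU
#' @return a \code{tolerances} object
#' @export
tolerances <- function(gantry_deg = 0.1, collimator_deg = 0.1,
                       jaw_mm = 1.0, mlc_mm = 2.0, mu_percent = 1.0) {
  tol <- list(gantry_deg = gantry_deg, collimator_deg = collimator_deg,
              jaw_mm = jaw_mm, mlc_mm = mlc_mm, mu_percent = mu_percent)
  if (any(unlist(tol) <= 0))
    stop_coded("INVARIANT_ERROR", "all tolerances must be strictly positive")
  structure(tol, class = "tolerances")
}

check_row <- function(name, planned, deviation, tolerance) {
  list(name = name, planned = planned,
       max_observed_deviation = deviation, tolerance = tolerance,
       status = if (deviation > tolerance) "WARNING" else "PASS")
}

#' Maximal MLC leaf error of a delivery log
#'
#' Maximum over beam-on samples, both banks and all leaves of
#' |actual - expected| — the machine's own servo error channel.
#'
#' @param log a [delivery_log()]
#' @return maximal absolute leaf error in mm (0 for an identity delivery)
#' @export
max_mlc_error <- function(log) {
  on <- log$samples$beam_on
  if (!length(on) || !any(on)) stop_coded("EMPTY_BEAM", "no beam-on samples")
  s <- log$samples
  max(abs(s$act_a[on, , drop = FALSE] - s$exp_a[on, , drop = FALSE]),
      abs(s$act_b[on, , drop = FALSE] - s$exp_b[on, , drop = FALSE]))
}

# Max leaf-position deviation of the log's *expected* channel from the plan
# control-point trajectory (data-transfer check).  The plan aperture at
# cumulative meterset m is the aperture of control point k+1 for the segment
# with f_k <= m <= f_{k+1}; at an exact segment boundary both bracketing
# segments are admissible (the log holds the old shape on the closing sample
# and the new shape on the opening one at the same meterset), so the
# deviation is the minimum over the admissible apertures.
max_transfer_error <- function(beam, log) {
  s <- log$samples
  on <- which(s$beam_on)
  if (!length(on)) stop_coded("EMPTY_BEAM", "no beam-on samples")
  fr <- vapply(beam$control_points, function(cp) cp$cumulative_meterset_fraction,
               numeric(1))
  worst <- 0
  for (k in on) {
    m <- s$meterset[k]
    segs <- which(fr[-length(fr)] <= m + 1e-9 & fr[-1] >= m - 1e-9)
    if (!length(segs)) segs <- if (m <= fr[1]) 1 else length(fr) - 1
    dev_k <- min(vapply(segs, function(sg) {
      ap <- beam$control_points[[sg + 1]]
      max(abs(s$exp_a[k, ] - ap$bank_a), abs(s$exp_b[k, ] - ap$bank_b))
    }, numeric(1)))
    worst <- max(worst, dev_k)
  }
  worst
}

#' Compare a delivered beam against its plan
#'
#' Runs the full per-beam check battery: integrity, gantry and collimator
#' angle (circular deviation), the four jaws, delivered MU, the maximal MLC
#' servo error (actual vs expected leaf channels), the plan-transfer check
#' (expected leaf channel vs plan control points), segment counts, and the
#' planned/delivered fluence difference with 2%/3% passing rates.  All
#' scalar deviations are maxima over beam-on samples only.
#'
#' @param beam the planned [beam_plan()]
#' @param log the [delivery_log()] of that beam
#' @param tol a [tolerances()] object
#' @param grid fluence grid; default [default_fluence_grid()] of the beam
#' @param plan optional [treatment_plan()] for the identity check
#' @return a \code{beam_check_report}: list with \code{beam_id},
#'   \code{integrity}, \code{checks} (data.frame: name, planned,
#'   max_observed_deviation, tolerance, status), \code{max_mlc_error_mm},
#'   \code{max_transfer_error_mm}, \code{segment_count_planned},
#'   \code{segment_count_observed}, \code{fluence} (a \code{fluence_diff}),
#'   \code{fluence_pass_rate_2pct}, \code{fluence_pass_rate_3pct},
#'   \code{delivered_mu}, \code{overall_status}
#' @export
compare_beam <- function(beam, log, tol = tolerances(),
                         grid = default_fluence_grid(beam), plan = NULL) {
  if (log_leaf_pairs(log) != n_leaf_pairs(beam))
    stop_coded("LEAF_COUNT_MISMATCH", sprintf(
      "log has %d leaf pairs, plan %d", log_leaf_pairs(log), n_leaf_pairs(beam)))
  s <- log$samples
  on <- s$beam_on
  if (!length(on) || !any(on)) stop_coded("EMPTY_BEAM", "no beam-on samples")
  integrity <- check_integrity(log, plan)

  gantry_dev <- max(circular_diff(s$gantry[on], beam$gantry_angle))
  coll_dev <- max(circular_diff(s$collimator[on], beam$collimator_angle))
  jaw_dev <- vapply(c("x1", "x2", "y1", "y2"), function(j)
    max(abs(s$jaws[on, j] - beam$jaws[j])), numeric(1))
  del_mu <- delivered_mu(log)
  mu_dev_pct <- abs(del_mu - beam$total_mu) / beam$total_mu * 100
  mlc_err <- max_mlc_error(log)
  transfer_err <- max_transfer_error(beam, log)

  checks <- list(
    check_row("gantry", beam$gantry_angle, gantry_dev, tol$gantry_deg),
    check_row("collimator", beam$collimator_angle, coll_dev, tol$collimator_deg),
    check_row("jaw_x1", beam$jaws[["x1"]], jaw_dev[["x1"]], tol$jaw_mm),
    check_row("jaw_x2", beam$jaws[["x2"]], jaw_dev[["x2"]], tol$jaw_mm),
    check_row("jaw_y1", beam$jaws[["y1"]], jaw_dev[["y1"]], tol$jaw_mm),
    check_row("jaw_y2", beam$jaws[["y2"]], jaw_dev[["y2"]], tol$jaw_mm),
    check_row("mu", beam$total_mu, mu_dev_pct, tol$mu_percent),
    check_row("mlc", 0, mlc_err, tol$mlc_mm)
  )
  checks <- do.call(rbind, lapply(checks, as.data.frame))

  fl_planned <- planned_fluence(beam, grid)
  fl_delivered <- delivered_fluence(log, beam$leaf_boundaries,
                                    total_mu = log$total_mu, grid = grid)
  fl_diff <- fluence_difference(fl_planned, fl_delivered)

  overall <- if (any(checks$status == "WARNING") || !integrity$intact ||
                 !integrity$identity_match) "WARNING" else "PASS"
  structure(
    list(beam_id = beam$beam_id, integrity = integrity, checks = checks,
         max_mlc_error_mm = mlc_err, max_transfer_error_mm = transfer_err,
         segment_count_planned = n_segments(beam),
         segment_count_observed = log_segment_count(log),
         fluence = fl_diff,
         fluence_pass_rate_2pct = fl_diff$pass_rates[["2%"]],
         fluence_pass_rate_3pct = fl_diff$pass_rates[["3%"]],
         delivered_mu = del_mu,
         planned_fluence = fl_planned, delivered_fluence = fl_delivered,
         overall_status = overall),
    class = "beam_check_report"
  )
}

#' @export
print.beam_check_report <- function(x, ...) {
  cat(render_report(list(x), format = "text"), sep = "\n")
  invisible(x)
}

report_to_list <- function(r) {
  list(
    beam_id = r$beam_id,
    overall_status = r$overall_status,
    integrity = list(intact = r$integrity$intact,
                     identity_match = r$integrity$identity_match,
                     issues = as.list(r$integrity$issues)),
    checks = lapply(seq_len(nrow(r$checks)), function(i) as.list(r$checks[i, ])),
    max_mlc_error_mm = r$max_mlc_error_mm,
    max_transfer_error_mm = r$max_transfer_error_mm,
    segment_count_planned = r$segment_count_planned,
    segment_count_observed = r$segment_count_observed,
    delivered_mu = r$delivered_mu,
    fluence_pass_rate_2pct = r$fluence_pass_rate_2pct,
    fluence_pass_rate_3pct = r$fluence_pass_rate_3pct,
    fluence_panels = list("planned", "delivered", "difference")
  )
}

#' Render beam check reports
#'
#' One section per beam with the parameter table, MLC/transfer errors,
#' segment counts and fluence passing rates, referencing the three fluence
#' panels (planned, delivered, difference).  PASS and WARNING are rendered
#' distinctly; in HTML, green vs yellow as on a clinical QA sheet.  The JSON
#' output is schema-stable (fixed key set, one object per beam).
#'
#' @param reports list of \code{beam_check_report}s
#' @param format \code{"text"}, \code{"json"} or \code{"html"}
#' @return character vector of document lines (single JSON string for
#'   \code{"json"})
#' @export
render_report <- function(reports, format = c("text", "json", "html")) {
  format <- match.arg(format)
  if (inherits(reports, "beam_check_report")) reports <- list(reports)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(report_version = 1L, beams = lapply(reports, report_to_list)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)))
  }
  render_one <- function(r, html) {
    tag <- function(status, text) {
      if (!html) return(text)
      col <- if (status == "WARNING") "#ffd24d" else "#7ddf7d"
      sprintf("<span style=\"background:%s\">%s</span>", col, text)
    }
    lines <- character(0)
    add <- function(...) lines <<- c(lines, sprintf(...))
    add("== Beam %s: %s ==", r$beam_id,
        tag(r$overall_status, r$overall_status))
    add("integrity: intact=%s identity_match=%s%s",
        r$integrity$intact, r$integrity$identity_match,
        if (length(r$integrity$issues))
          paste0(" [", paste(r$integrity$issues, collapse = ", "), "]") else "")
    for (i in seq_len(nrow(r$checks))) {
      ck <- r$checks[i, ]
      status_txt <- if (ck$status == "WARNING")
        tag("WARNING", "WARNING: outside tolerance") else tag("PASS", "PASS")
      add("  %-10s planned %10.4f  max dev %8.4f  tol %6.3f  %s",
          ck$name, ck$planned, ck$max_observed_deviation, ck$tolerance,
          status_txt)
    }
    add("  max MLC error (actual vs expected): %.4f mm", r$max_mlc_error_mm)
    add("  max transfer error (expected vs plan): %.4f mm", r$max_transfer_error_mm)
    add("  segments: planned %d, observed %d",
        r$segment_count_planned, r$segment_count_observed)
    add("  delivered MU: %.3f", r$delivered_mu)
    add("  fluence pass rate: %.2f%% @2%%, %.2f%% @3%% of max fluence",
        r$fluence_pass_rate_2pct, r$fluence_pass_rate_3pct)
    add("  fluence panels: planned | delivered | difference")
    lines
  }
  body <- unlist(lapply(reports, render_one, html = (format == "html")))
  if (format == "html")
    body <- c("<html><body><pre>", body, "</pre></body></html>")
  body
}
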