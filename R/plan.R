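# Plan data model: control points, beams, treatment plans.
#
# Conventions: beam's-eye view, X is the leaf-travel axis.  Bank A holds the
# negative-X leaf tips, bank B the positive-X tips; the open interval of leaf
# pair i is (a_i, b_i), so b_i >= a_i always (a closed pair has b_i == a_i).
# All positions are signed mm projected to the isocenter plane.  Angles are
# IEC 61217 degrees normalized to [0, 360).

#' Construct a plan control point
#'
#' A control point carries a cumulative meterset fraction and the MLC
#' aperture at that fraction.  In step-and-shoot delivery the segment between
#' control points k and k+1 delivers its MU with the aperture of control
#' point k+1 held static.
#'
#' @param index integer control point index (0-based, as in DICOM)
#' @param cumulative_meterset_fraction fraction of beam MU delivered so far,
#'   in \[0, 1\]
#' @param bank_a,bank_b numeric vectors of leaf-tip positions (mm at
#'   isocenter), one element per leaf pair; \code{bank_b >= bank_a}
#' @return an object of class \code{control_point}
#' @export
control_point <- function(index, cumulative_meterset_fraction, bank_a, bank_b) {
  cp <- structure(
    list(
      index = as.integer(index),
      cumulative_meterset_fraction = as.numeric(cumulative_meterset_fraction),
      bank_a = as.numeric(bank_a),
      bank_b = as.numeric(bank_b)
    ),
    class = "control_point"
  )
  validate_control_point(cp)
  cp
}

validate_control_point <- function(cp) {
  f <- cp$cumulative_meterset_fraction
  if (!is.finite(f) || f < 0 || f > 1)
    stop_coded("INVARIANT_ERROR", "cumulative meterset fraction must be in [0, 1]")
  if (length(cp$bank_a) != length(cp$bank_b))
    stop_coded("INVARIANT_ERROR", "leaf banks must have equal length")
  if (any(cp$bank_b < cp$bank_a - 1e-9))
    stop_coded("INVARIANT_ERROR", "leaf crossing: bank B tip left of bank A tip")
  invisible(cp)
}

#' Construct a beam plan
#'
#' @param beam_id unique beam identifier string
#' @param gantry_angle,collimator_angle degrees, normalized to \[0, 360)
#' @param jaws named numeric vector \code{c(x1=, x2=, y1=, y2=)} in mm at
#'   isocenter, with \code{x2 > x1} and \code{y2 > y1}
#' @param total_mu total beam monitor units (> 0)
#' @param energy_label beam energy string (e.g. "6MV")
#' @param control_points list of [control_point()] with non-decreasing
#'   meterset fractions running from 0 to 1
#' @param leaf_boundaries strictly increasing vector of leaf-pair edge
#'   positions (mm) along the axis perpendicular to leaf travel; the number
#'   of leaf pairs is \code{length(leaf_boundaries) - 1}
#' @return an object of class \code{beam_plan}
#' @export
beam_plan <- function(beam_id, gantry_angle, collimator_angle, jaws, total_mu,
                      energy_label = "6MV", control_points, leaf_boundaries) {
  jaws <- as.numeric(jaws[c("x1", "x2", "y1", "y2")])
  names(jaws) <- c("x1", "x2", "y1", "y2")
  beam <- structure(
    list(
      beam_id = as.character(beam_id),
      gantry_angle = norm_angle(as.numeric(gantry_angle)),
      collimator_angle = norm_angle(as.numeric(collimator_angle)),
      jaws = jaws,
      total_mu = as.numeric(total_mu),
      energy_label = as.character(energy_label),
      control_points = control_points,
      leaf_boundaries = as.numeric(leaf_boundaries)
    ),
    class = "beam_plan"
  )
  validate_beam_plan(beam)
  beam
}

validate_beam_plan <- function(beam) {
  j <- beam$jaws
  if (anyNA(j) || j["x2"] <= j["x1"] || j["y2"] <= j["y1"])
    stop_coded("INVARIANT_ERROR", "jaws must satisfy x2 > x1 and y2 > y1")
  if (beam$total_mu <= 0)
    stop_coded("INVARIANT_ERROR", "total_mu must be positive")
  lb <- beam$leaf_boundaries
  if (length(lb) < 2 || any(diff(lb) <= 0))
    stop_coded("INVARIANT_ERROR", "leaf_boundaries must be strictly increasing")
  n_pairs <- length(lb) - 1
  cps <- beam$control_points
  if (length(cps) < 2)
    stop_coded("INVARIANT_ERROR", "a beam needs at least 2 control points")
  fr <- vapply(cps, function(cp) cp$cumulative_meterset_fraction, numeric(1))
  if (any(diff(fr) < -1e-12))
    stop_coded("INVARIANT_ERROR", "meterset fractions must be non-decreasing")
  if (abs(fr[1]) > 1e-9 || abs(fr[length(fr)] - 1) > 1e-9)
    stop_coded("INVARIANT_ERROR", "meterset fractions must run from 0 to 1")
  for (cp in cps) {
    validate_control_point(cp)
    if (length(cp$bank_a) != n_pairs)
      stop_coded("INVARIANT_ERROR", sprintf(
        "control point has %d leaf pairs, leaf_boundaries imply %d",
        length(cp$bank_a), n_pairs))
  }
  invisible(beam)
}

#' Number of leaf pairs of a beam
#' @param beam a [beam_plan()]
#' @return integer
#' @export
n_leaf_pairs <- function(beam) length(beam$leaf_boundaries) - 1L

#' Number of segments of a step-and-shoot beam
#'
#' One segment per consecutive control-point pair with a strictly positive
#' meterset increment.
#' @param beam a [beam_plan()]
#' @return integer segment count
#' @export
n_segments <- function(beam) {
  fr <- vapply(beam$control_points, function(cp) cp$cumulative_meterset_fraction,
               numeric(1))
  sum(diff(fr) > 1e-12)
}

#' Construct a treatment plan
#'
#' @param patient_name,patient_id patient identification strings
#' @param prescription_dose prescription dose in Gy (> 0)
#' @param beams list of [beam_plan()] with unique beam ids
#' @return an object of class \code{treatment_plan}
#' @export
treatment_plan <- function(patient_name, patient_id, prescription_dose, beams) {
  plan <- structure(
    list(
      patient_name = as.character(patient_name),
      patient_id = as.character(patient_id),
      prescription_dose = as.numeric(prescription_dose),
      beams = beams
    ),
    class = "treatment_plan"
  )
  validate_treatment_plan(plan)
  plan
}

validate_treatment_plan <- function(plan) {
  if (plan$prescription_dose <= 0)
    stop_coded("INVARIANT_ERROR", "prescription_dose must be positive")
  ids <- vapply(plan$beams, function(b) b$beam_id, character(1))
  if (anyDuplicated(ids))
    stop_coded("INVARIANT_ERROR", "beam ids must be unique")
  for (b in plan$beams) validate_beam_plan(b)
  invisible(plan)
}

#' Millennium-120-style leaf boundaries
#'
#' Default leaf geometry: 60 pairs spanning -200..+200 mm at isocenter,
#' with 10 outer 10 mm pairs, 40 central 5 mm pairs, and 10 outer 10 mm
#' pairs, per bank.
#' @return numeric vector of 61 boundary positions in mm
#' @export
millennium120_boundaries <- function() {
  widths <- c(rep(10, 10), rep(5, 40), rep(10, 10))
  c(-200, -200 + cumsum(widths))
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> patient '%s' (id %s), Rx %.2f Gy, %d beam(s)\n",
              x$patient_name, x$patient_id, x$prescription_dose,
              length(x$beams)))
  for (b in x$beams)
    cat(sprintf("  beam %s: gantry %.1f deg, %d CPs, %.1f MU\n",
                b$beam_id, b$gantry_angle, length(b$control_points),
                b$total_mu))
  invisible(x)
}
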