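# Delivery log data model.
#
# A delivery log is the machine's time-sampled record of one beam: beam
# on/off status, gantry/collimator angles, jaw positions, cumulative
# meterset fraction, and per-leaf expected and actual positions, sampled at
# a fixed period (50 ms on Varian Trilogy/iX-class machines).  Leaf channels
# are stored as sample-by-leaf matrices for efficiency.

#' Construct a delivery log
#'
#' @param patient_id patient identifier recorded by the machine
#' @param beam_id beam identifier
#' @param sampling_period_ms sampling period in milliseconds (default 50)
#' @param total_mu total MU the machine was set to deliver
#' @param samples list of per-sample channels:
#'   \describe{
#'     \item{time_index}{integer sample numbers}
#'     \item{beam_on}{logical}
#'     \item{gantry, collimator}{degrees}
#'     \item{jaws}{n x 4 matrix, columns x1 x2 y1 y2, mm}
#'     \item{meterset}{cumulative meterset fraction in \[0, 1\]}
#'     \item{exp_a, exp_b, act_a, act_b}{n x n_leaf_pairs matrices of
#'       expected/actual leaf positions per bank, mm at isocenter}
#'   }
#' @param declared_sample_count sample count announced in the file header;
#'   differs from \code{length(samples$time_index)} for a truncated log
#' @return an object of class \code{delivery_log}
#' @export
delivery_log <- function(patient_id, beam_id, sampling_period_ms = 50,
                         total_mu, samples,
                         declared_sample_count = length(samples$time_index)) {
  log <- structure(
    list(
      patient_id = as.character(patient_id),
      beam_id = as.character(beam_id),
      sampling_period_ms = as.numeric(sampling_period_ms),
      total_mu = as.numeric(total_mu),
      samples = samples,
      declared_sample_count = as.integer(declared_sample_count)
    ),
    class = "delivery_log"
  )
  validate_delivery_log(log)
  log
}

validate_delivery_log <- function(log) {
  s <- log$samples
  n <- length(s$time_index)
  lens <- c(length(s$beam_on), length(s$gantry), length(s$collimator),
            nrow(s$jaws), length(s$meterset),
            nrow(s$exp_a), nrow(s$exp_b), nrow(s$act_a), nrow(s$act_b))
  if (n > 0 && any(lens != n))
    stop_coded("INVARIANT_ERROR", "log sample channels have unequal lengths")
  np <- ncol(s$exp_a)
  if (n > 0 && (ncol(s$exp_b) != np || ncol(s$act_a) != np || ncol(s$act_b) != np))
    stop_coded("INVARIANT_ERROR", "leaf matrices have unequal leaf counts")
  if (n > 0 && (any(s$meterset < -1e-9) || any(s$meterset > 1 + 1e-9)))
    stop_coded("INVARIANT_ERROR", "cumulative meterset fraction outside [0, 1]")
  invisible(log)
}

#' Number of samples actually present in a log
#' @param log a [delivery_log()]
#' @return integer
#' @export
log_sample_count <- function(log) length(log$samples$time_index)

#' Number of leaf pairs recorded in a log
#' @param log a [delivery_log()]
#' @return integer
#' @export
log_leaf_pairs <- function(log) ncol(log$samples$exp_a)

#' Observed segment count of a step-and-shoot log
#'
#' A segment is a maximal run of consecutive beam-on samples; segments are
#' separated by beam-hold (beam-off) intervals during which leaves travel.
#' @param log a [delivery_log()]
#' @return integer number of beam-on runs
#' @export
log_segment_count <- function(log) {
  on <- log$samples$beam_on
  if (!length(on)) return(0L)
  sum(diff(c(FALSE, on)) == 1L)
}

#' Final delivered MU of a log
#'
#' Last cumulative meterset fraction times the machine's total MU setting.
#' @param log a [delivery_log()]
#' @return delivered MU
#' @export
delivered_mu <- function(log) {
  m <- log$samples$meterset
  if (!length(m)) return(0)
  m[length(m)] * log$total_mu
}

#' @export
print.delivery_log <- function(x, ...) {
  cat(sprintf(
    "<delivery_log> beam %s (patient %s): %d/%d samples @ %g ms, %d leaf pairs, %.1f MU\n",
    x$beam_id, x$patient_id, log_sample_count(x), x$declared_sample_count,
    x$sampling_period_ms, log_leaf_pairs(x), x$total_mu))
  invisible(x)
}
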