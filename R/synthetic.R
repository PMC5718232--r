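# Synthetic plans, delivery logs and phantoms with known ground truth.
#
# The simulator speaks strict step-and-shoot: leaves travel only while the
# beam is held off, each static segment delivers its meterset increment at a
# constant MU rate, and the log's expected channels replay the plan exactly.
# Injected errors perturb only their own channel, so every error class can
# be detected (and quantified) independently.

#' Delivery error model
#'
#' All-zero by default (identity delivery).  Each field perturbs one
#' channel of the simulated log:
#'
#' @param gantry_offset_deg constant gantry offset applied to logged gantry
#' @param collimator_offset_deg constant collimator offset
#' @param jaw_offset_mm named numeric, offsets per jaw (x1, x2, y1, y2)
#' @param leaf_noise_sigma_mm i.i.d. Gaussian noise (mm, per leaf per
#'   sample) added to actual leaf positions
#' @param leaf_systematic_mm data.frame with columns \code{bank} ("A"/"B"),
#'   \code{leaf} (pair index) and \code{offset_mm}: constant per-leaf offsets
#'   on the actual channel
#' @param mu_scale delivered-MU scale factor (1 = as planned)
#' @param dropped_segment_index segment that is silently not delivered
#'   (NA = none)
#' @param beam_hold_extra_samples extra beam-off samples inserted at each
#'   segment boundary
#' @param corrupt \code{"NONE"}, \code{"TRUNCATE"} (drop sample rows after
#'   \code{truncate_at} while keeping the declared count) or
#'   \code{"WRONG_PATIENT_ID"}
#' @param truncate_at sample count kept when \code{corrupt = "TRUNCATE"}
#' @return an \code{error_model}
#' @export
error_model <- function(gantry_offset_deg = 0, collimator_offset_deg = 0,
                        jaw_offset_mm = c(x1 = 0, x2 = 0, y1 = 0, y2 = 0),
                        leaf_noise_sigma_mm = 0,
                        leaf_systematic_mm = NULL,
                        mu_scale = 1,
                        dropped_segment_index = NA_integer_,
                        beam_hold_extra_samples = 0L,
                        corrupt = c("NONE", "TRUNCATE", "WRONG_PATIENT_ID"),
                        truncate_at = NA_integer_) {
  corrupt <- match.arg(corrupt)
  jaw <- c(x1 = 0, x2 = 0, y1 = 0, y2 = 0)
  jaw[names(jaw_offset_mm)] <- jaw_offset_mm
  if (leaf_noise_sigma_mm < 0) stop_coded("INVARIANT_ERROR", "sigma must be >= 0")
  if (mu_scale <= 0) stop_coded("INVARIANT_ERROR", "mu_scale must be > 0")
  structure(
    list(gantry_offset_deg = gantry_offset_deg,
         collimator_offset_deg = collimator_offset_deg,
         jaw_offset_mm = jaw, leaf_noise_sigma_mm = leaf_noise_sigma_mm,
         leaf_systematic_mm = leaf_systematic_mm, mu_scale = mu_scale,
         dropped_segment_index = dropped_segment_index,
         beam_hold_extra_samples = as.integer(beam_hold_extra_samples),
         corrupt = corrupt, truncate_at = truncate_at),
    class = "error_model"
  )
}

# Smoothly varying random aperture within the jaws: per open leaf pair a
# center following a low-frequency sine plus jitter and a random width,
# clipped to the jaw x-window.  Pairs outside the jaw y-window stay closed.
random_aperture <- function(boundaries, jaws) {
  n <- length(boundaries) - 1
  mid_y <- (boundaries[-1] + boundaries[-(n + 1)]) / 2
  open <- mid_y > jaws["y1"] & mid_y < jaws["y2"]
  a <- rep(0, n); b <- rep(0, n)
  if (any(open)) {
    span <- jaws["x2"] - jaws["x1"]
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0, 0.25 * span)
    center <- amp * sin(mid_y / 40 + phase) + rnorm(n, 0, 0.05 * span)
    width <- runif(n, 0.15 * span, 0.8 * span)
    a_open <- pmax(center - width / 2, jaws["x1"])
    b_open <- pmin(center + width / 2, jaws["x2"])
    bad <- b_open - a_open < 2
    b_open[bad] <- pmin(a_open[bad] + 2, jaws[["x2"]])
    a[open] <- round(a_open[open], 1)
    b[open] <- round(pmax(b_open, a_open + 1)[open], 1)
  }
  list(a = a, b = b)
}

#' Generate a random synthetic treatment plan
#'
#' Step-and-shoot beams with randomly shaped connected apertures.  By
#' default each beam draws its segment count uniformly from 4 to 12, the
#' typical range for clinical step-and-shoot IMRT beams.
#'
#' @param seed integer seed; the plan is a pure function of its arguments
#' @param n_beams number of beams
#' @param n_segments segments per beam; NULL (default) draws 4-12 per beam
#' @param leaf_boundaries leaf geometry (default [millennium120_boundaries()])
#' @param mu_total MU per beam
#' @param jaws jaw rectangle shared by all beams (mm)
#' @param patient_name,patient_id,prescription_dose plan identity fields
#' @return a [treatment_plan()]
#' @export
make_plan <- function(seed, n_beams = 1, n_segments = NULL,
                      leaf_boundaries = millennium120_boundaries(),
                      mu_total = 100,
                      jaws = c(x1 = -50, x2 = 50, y1 = -50, y2 = 50),
                      patient_name = "Synthetic^Phantom",
                      patient_id = "SYN-0001",
                      prescription_dose = 70) {
  set.seed(as.integer(seed))
  beams <- vector("list", n_beams)
  for (bi in seq_len(n_beams)) {
    k <- if (is.null(n_segments)) sample(4:12, 1) else n_segments
    gantry <- round(runif(1, 0, 359.9), 1)
    coll <- round(runif(1, 0, 359.9), 1)
    w <- runif(k, 0.5, 1.5)
    fr <- c(0, round(cumsum(w) / sum(w), 6))
    fr[k + 1] <- 1
    cps <- vector("list", k + 1)
    aps <- lapply(seq_len(k), function(i) random_aperture(leaf_boundaries, jaws))
    # CP 0 carries the first segment's shape (machine is pre-shaped at f = 0)
    cps[[1]] <- control_point(0L, 0, aps[[1]]$a, aps[[1]]$b)
    for (i in seq_len(k))
      cps[[i + 1]] <- control_point(i, fr[i + 1], aps[[i]]$a, aps[[i]]$b)
    beams[[bi]] <- beam_plan(sprintf("B%d", bi), gantry, coll, jaws, mu_total,
                             "6MV", cps, leaf_boundaries)
  }
  treatment_plan(patient_name, patient_id, prescription_dose, beams)
}

# plan aperture held during segment k (control point k+1)
segment_aperture <- function(beam, k) {
  cp <- beam$control_points[[k + 1]]
  list(a = cp$bank_a, b = cp$bank_b)
}

#' Simulate the delivery of a plan and record machine logs
#'
#' Strict step-and-shoot: each segment's meterset increment is delivered at
#' \code{mu_rate} with the beam on and the segment aperture static; between
#' segments the beam is held off while leaves travel linearly to the next
#' shape.  The log's expected leaf channels carry the plan trajectory; the
#' actual channels carry expected plus the injected errors.  Corruption
#' (truncation, wrong patient id) is applied last.
#'
#' @param plan a [treatment_plan()]
#' @param err an [error_model()] applied to every beam
#' @param sampling_period_ms log sampling period (default 50 ms)
#' @param mu_rate dose rate in MU/min (default 400)
#' @param seed integer seed for the leaf-noise stream; streams are split
#'   per beam so toggling other error classes never perturbs the noise
#' @return list of [delivery_log()], one per beam
#' @export
simulate_delivery <- function(plan, err = error_model(),
                              sampling_period_ms = 50, mu_rate = 400,
                              seed = 1) {
  dt_min <- sampling_period_ms / 60000
  lapply(seq_along(plan$beams), function(bi) {
    beam <- plan$beams[[bi]]
    np <- n_leaf_pairs(beam)
    fr <- vapply(beam$control_points, function(cp) cp$cumulative_meterset_fraction,
                 numeric(1))
    k_seg <- length(fr) - 1

    exp_a <- NULL; exp_b <- NULL; beam_on <- logical(0); meterset <- numeric(0)
    n_hold <- 2L + err$beam_hold_extra_samples
    add_rows <- function(mat, rows) rbind(mat, rows)
    cur_m <- 0
    prev_ap <- segment_aperture(beam, 1)
    # lead-in: machine shaped for segment 1, beam off
    for (h in seq_len(n_hold)) {
      exp_a <- add_rows(exp_a, prev_ap$a); exp_b <- add_rows(exp_b, prev_ap$b)
      beam_on <- c(beam_on, FALSE); meterset <- c(meterset, cur_m)
    }
    dropped_f <- 0
    for (k in seq_len(k_seg)) {
      ap <- segment_aperture(beam, k)
      df <- fr[k + 1] - fr[k]
      if (k > 1) {
        # beam-hold travel from previous shape to this one
        for (h in seq_len(n_hold)) {
          t <- h / n_hold
          exp_a <- add_rows(exp_a, (1 - t) * prev_ap$a + t * ap$a)
          exp_b <- add_rows(exp_b, (1 - t) * prev_ap$b + t * ap$b)
          beam_on <- c(beam_on, FALSE); meterset <- c(meterset, cur_m)
        }
      }
      prev_ap <- ap
      if (df <= 1e-12) next
      if (!is.na(err$dropped_segment_index) && k == err$dropped_segment_index) {
        dropped_f <- dropped_f + df
        next
      }
      seg_mu <- df * beam$total_mu
      n_int <- max(1L, ceiling(seg_mu / (mu_rate * dt_min)))
      for (j in 0:n_int) {
        exp_a <- add_rows(exp_a, ap$a); exp_b <- add_rows(exp_b, ap$b)
        beam_on <- c(beam_on, TRUE)
        meterset <- c(meterset, cur_m + df * j / n_int)
      }
      cur_m <- cur_m + df
    }
    n <- length(beam_on)
    exp_a <- matrix(exp_a, n, np); exp_b <- matrix(exp_b, n, np)

    # injected errors: independent noise stream per beam
    set.seed(as.integer(seed) + 7919L * bi)
    act_a <- exp_a; act_b <- exp_b
    if (err$leaf_noise_sigma_mm > 0) {
      act_a <- act_a + matrix(rnorm(n * np, 0, err$leaf_noise_sigma_mm), n, np)
      act_b <- act_b + matrix(rnorm(n * np, 0, err$leaf_noise_sigma_mm), n, np)
    }
    if (!is.null(err$leaf_systematic_mm)) {
      for (r in seq_len(nrow(err$leaf_systematic_mm))) {
        row <- err$leaf_systematic_mm[r, ]
        if (toupper(row$bank) == "A") act_a[, row$leaf] <- act_a[, row$leaf] + row$offset_mm
        else act_b[, row$leaf] <- act_b[, row$leaf] + row$offset_mm
      }
    }
    jaws_row <- beam$jaws + err$jaw_offset_mm[c("x1", "x2", "y1", "y2")]
    samples <- list(
      time_index = seq_len(n) - 1L,
      beam_on = beam_on,
      gantry = rep(norm_angle(beam$gantry_angle + err$gantry_offset_deg), n),
      collimator = rep(norm_angle(beam$collimator_angle + err$collimator_offset_deg), n),
      jaws = matrix(rep(jaws_row, each = n), n, 4,
                    dimnames = list(NULL, c("x1", "x2", "y1", "y2"))),
      meterset = meterset,
      exp_a = exp_a, exp_b = exp_b, act_a = act_a, act_b = act_b
    )
    total_mu_log <- beam$total_mu * err$mu_scale
    patient_id <- if (err$corrupt == "WRONG_PATIENT_ID")
      paste0(plan$patient_id, "X") else plan$patient_id
    declared <- n
    if (err$corrupt == "TRUNCATE" && !is.na(err$truncate_at) &&
        err$truncate_at < n) {
      keep <- seq_len(err$truncate_at)
      samples <- list(
        time_index = samples$time_index[keep], beam_on = samples$beam_on[keep],
        gantry = samples$gantry[keep], collimator = samples$collimator[keep],
        jaws = samples$jaws[keep, , drop = FALSE],
        meterset = samples$meterset[keep],
        exp_a = samples$exp_a[keep, , drop = FALSE],
        exp_b = samples$exp_b[keep, , drop = FALSE],
        act_a = samples$act_a[keep, , drop = FALSE],
        act_b = samples$act_b[keep, , drop = FALSE])
    }
    delivery_log(patient_id, beam$beam_id, sampling_period_ms, total_mu_log,
                 samples, declared_sample_count = declared)
  })
}

#' Phantom specification
#'
#' Geometric dose-and-structure phantoms standing in for patient data.
#' Structures are geometric primitives; the dose field is analytic,
#' evaluated at voxel centers.
#'
#' @param dim integer(3) voxel counts (x, y, z)
#' @param spacing mm per voxel, length 1 or 3
#' @param origin mm of voxel \[1,1,1\]
#' @param structures list of primitives, each a list with \code{name},
#'   \code{type} ("sphere", "box" or "slab") and geometry: sphere
#'   \code{center}/\code{radius} (mm); box \code{lo}/\code{hi} (mm); slab
#'   \code{axis} (1-3)/\code{from}/\code{to} (mm)
#' @param dose a list with \code{type}: "uniform" (\code{value} Gy),
#'   "gradient" (\code{axis}, \code{from_gy}, \code{to_gy} across the grid
#'   extent) or "blobs" (\code{centers} matrix, \code{sigmas}, \code{amps})
#' @return a \code{phantom_spec}
#' @export
phantom_spec <- function(dim = c(40, 40, 20), spacing = 3, origin = c(0, 0, 0),
                         structures = list(), dose = list(type = "uniform", value = 2)) {
  structure(list(dim = as.integer(dim), spacing = rep(spacing, length.out = 3),
                 origin = origin, structures = structures, dose = dose),
            class = "phantom_spec")
}

#' Build a phantom dose grid and structure masks
#'
#' @param spec a [phantom_spec()]
#' @param seed integer seed (used only if the dose spec includes
#'   \code{noise_sigma_gy})
#' @return list with \code{dose} (a [dose_grid()]) and \code{structures}
#'   (list of [structure_mask()])
#' @export
make_phantom <- function(spec, seed = 1) {
  d <- spec$dim; sp <- spec$spacing; or <- spec$origin
  xs <- or[1] + sp[1] * (seq_len(d[1]) - 1)
  ys <- or[2] + sp[2] * (seq_len(d[2]) - 1)
  zs <- or[3] + sp[3] * (seq_len(d[3]) - 1)
  cx <- array(rep(xs, times = d[2] * d[3]), d)
  cy <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  cz <- array(rep(zs, each = d[1] * d[2]), d)

  ds <- spec$dose
  values <- switch(ds$type,
    uniform = array(ds$value, d),
    gradient = {
      ax <- list(cx, cy, cz)[[ds$axis]]
      lo <- min(ax); hi <- max(ax)
      ds$from_gy + (ds$to_gy - ds$from_gy) * (ax - lo) / max(hi - lo, 1e-12)
    },
    blobs = {
      v <- array(0, d)
      for (i in seq_len(nrow(ds$centers))) {
        c0 <- ds$centers[i, ]
        r2 <- (cx - c0[1])^2 + (cy - c0[2])^2 + (cz - c0[3])^2
        v <- v + ds$amps[i] * exp(-r2 / (2 * ds$sigmas[i]^2))
      }
      v
    },
    stop_coded("SPEC_ERROR", paste("unknown dose type", ds$type))
  )
  if (!is.null(ds$noise_sigma_gy) && ds$noise_sigma_gy > 0) {
    set.seed(as.integer(seed))
    values <- pmax(0, values + array(rnorm(prod(d), 0, ds$noise_sigma_gy), d))
  }
  masks <- lapply(spec$structures, function(st) {
    m <- switch(st$type,
      sphere = (cx - st$center[1])^2 + (cy - st$center[2])^2 +
        (cz - st$center[3])^2 <= st$radius^2,
      box = cx >= st$lo[1] & cx <= st$hi[1] & cy >= st$lo[2] & cy <= st$hi[2] &
        cz >= st$lo[3] & cz <= st$hi[3],
      slab = {
        ax <- list(cx, cy, cz)[[st$axis]]
        ax >= st$from & ax <= st$to
      },
      stop_coded("SPEC_ERROR", paste("unknown structure type", st$type)))
    structure_mask(st$name, m)
  })
  list(dose = dose_grid(values, sp, or), structures = masks)
}
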