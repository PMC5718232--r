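# 2D gamma-index comparison of dose planes.
#
# Standard asymmetric gamma: reference pixels define the map, the evaluated
# plane is interpolated.  The distance-to-agreement search is an exhaustive
# minimization over a subdivided neighborhood (bilinear interpolation of the
# evaluated plane at steps of dta/10 within the search radius) — simple and
# directly checkable against a finer brute-force search.

#' Construct a dose plane
#'
#' @param values matrix of dose values indexed \code{[iy, ix]} (Gy or
#'   relative units; gamma only needs both planes in the same units)
#' @param spacing mm per pixel, length 1 or 2 (x, y)
#' @param origin mm position (x, y) of pixel \code{[1, 1]}
#' @return a \code{dose_plane}
#' @export
dose_plane <- function(values, spacing = 1, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop_coded("INVARIANT_ERROR", "dose values must be finite")
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop_coded("INVARIANT_ERROR", "spacing must be positive")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "dose_plane")
}

plane_x <- function(p) p$origin[1] + p$spacing[1] * (seq_len(ncol(p$values)) - 1)
plane_y <- function(p) p$origin[2] + p$spacing[2] * (seq_len(nrow(p$values)) - 1)

#' Gamma acceptance criteria
#'
#' Defaults are the clinical 3% dose-difference / 3 mm distance-to-agreement
#' criteria with global normalization to the reference plane's maximum.
#' The 10% low-dose cutoff is a package default (configurable, set 0 to
#' evaluate everything); no clinical standard value is implied.
#'
#' @param dose_tol_pct dose-difference criterion, % of normalization dose
#' @param dta_mm distance-to-agreement criterion in mm
#' @param normalization \code{"GLOBAL_MAX_REF"} (reference plane maximum) or
#'   \code{"PRESCRIPTION"} (explicit \code{norm_dose})
#' @param norm_dose normalization dose when \code{normalization =
#'   "PRESCRIPTION"}
#' @param low_dose_cutoff_pct reference pixels below this % of the
#'   normalization dose are excluded (NaN in the gamma map)
#' @param search_radius_mm radius of the DTA search (default 3 x dta)
#' @param step_mm search step (default dta / 10)
#' @return a \code{gamma_criteria} object
#' @export
gamma_criteria <- function(dose_tol_pct = 3, dta_mm = 3,
                           normalization = c("GLOBAL_MAX_REF", "PRESCRIPTION"),
                           norm_dose = NULL,
                           low_dose_cutoff_pct = 10,
                           search_radius_mm = 3 * dta_mm,
                           step_mm = dta_mm / 10) {
  normalization <- match.arg(normalization)
  if (dose_tol_pct <= 0 || dta_mm <= 0 || search_radius_mm <= 0 || step_mm <= 0)
    stop_coded("INVARIANT_ERROR", "gamma criteria must be positive")
  if (low_dose_cutoff_pct < 0 || low_dose_cutoff_pct >= 100)
    stop_coded("INVARIANT_ERROR", "low_dose_cutoff_pct must be in [0, 100)")
  structure(list(dose_tol_pct = dose_tol_pct, dta_mm = dta_mm,
                 normalization = normalization, norm_dose = norm_dose,
                 low_dose_cutoff_pct = low_dose_cutoff_pct,
                 search_radius_mm = search_radius_mm, step_mm = step_mm),
            class = "gamma_criteria")
}

norm_dose_of <- function(reference, criteria) {
  if (criteria$normalization == "GLOBAL_MAX_REF") max(reference$values)
  else {
    if (is.null(criteria$norm_dose))
      stop_coded("INVARIANT_ERROR", "PRESCRIPTION normalization needs norm_dose")
    criteria$norm_dose
  }
}

#' Compute a 2D gamma map
#'
#' For each reference pixel at or above the low-dose cutoff,
#' \deqn{\gamma(r) = \min_c \sqrt{ \|c-r\|^2/\mathrm{dta}^2 +
#'   (D_e(c)-D_r(r))^2/(\mathrm{tol}\cdot D_{norm})^2 }}
#' minimized over evaluated-plane positions \eqn{c} within the search
#' radius, sampled at \code{step_mm} with bilinear interpolation.  The two
#' planes may be on different grids; they must spatially overlap.
#'
#' @param reference,evaluated [dose_plane()]s in the same dose units
#' @param criteria a [gamma_criteria()]
#' @return a \code{gamma_result}: list with \code{gamma} (matrix, NaN where
#'   excluded), \code{pass_rate} (% of evaluated pixels with gamma <= 1),
#'   \code{mean_gamma}, \code{evaluated_count}, \code{criteria}
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria()) {
  dnorm_val <- norm_dose_of(reference, criteria)
  rx <- plane_x(reference); ry <- plane_y(reference)
  ex <- plane_x(evaluated); ey <- plane_y(evaluated)
  if (min(rx) > max(ex) || max(rx) < min(ex) ||
      min(ry) > max(ey) || max(ry) < min(ey))
    stop_coded("NO_OVERLAP", "dose planes do not overlap spatially")

  include <- reference$values >= criteria$low_dose_cutoff_pct / 100 * dnorm_val
  if (!any(include)) stop_coded("ALL_EXCLUDED", "low-dose cutoff removed every pixel")

  px <- rep(rx, each = nrow(reference$values))[as.vector(include)]
  py <- rep(ry, times = ncol(reference$values))[as.vector(include)]
  dr <- reference$values[include]

  dd_denom <- (criteria$dose_tol_pct / 100 * dnorm_val)^2
  dta2 <- criteria$dta_mm^2
  r <- criteria$search_radius_mm
  # lattice centered on 0 so the zero offset is exact (identity => gamma 0);
  # candidates falling outside the evaluated plane are projected onto its
  # boundary so edge pixels converge at the same rate as interior ones
  n_off <- floor(r / criteria$step_mm + 1e-9)
  off <- criteria$step_mm * (-n_off:n_off)
  ex_lo <- min(ex); ex_hi <- max(ex); ey_lo <- min(ey); ey_hi <- max(ey)
  best <- rep(Inf, length(dr))
  best_ox <- rep(0, length(dr)); best_oy <- rep(0, length(dr))
  probe <- function(qx, qy, track) {
    d2 <- (qx - px)^2 + (qy - py)^2
    in_r <- d2 <= r * r + 1e-12
    if (!any(in_r)) return(invisible())
    de <- bilinear_interp(evaluated$values, evaluated$origin,
                          evaluated$spacing, qx, qy)
    g2 <- d2 / dta2 + (de - dr)^2 / dd_denom
    better <- in_r & !is.na(g2) & g2 < best
    best[better] <<- g2[better]
    if (track) {
      best_ox[better] <<- qx[better] - px[better]
      best_oy[better] <<- qy[better] - py[better]
    }
    invisible()
  }
  for (oy in off) {
    qy <- pmin(pmax(py + oy, ey_lo), ey_hi)
    for (ox in off)
      probe(pmin(pmax(px + ox, ex_lo), ex_hi), qy, track = TRUE)
  }
  # local refinement at step/10 around each pixel's best coarse candidate
  fine <- criteria$step_mm / 10 * (-10:10)
  for (ly in fine) {
    qy <- pmin(pmax(py + best_oy + ly, ey_lo), ey_hi)
    for (lx in fine)
      probe(pmin(pmax(px + best_ox + lx, ex_lo), ex_hi), qy, track = FALSE)
  }
  gam <- matrix(NaN, nrow(reference$values), ncol(reference$values))
  gam[include] <- sqrt(best)
  finite <- is.finite(gam[include])
  structure(
    list(gamma = gam,
         # gamma exactly 1 is a pass; the epsilon keeps analytic boundary
         # cases (dose difference exactly at tolerance) from flipping on
         # floating-point noise
         pass_rate = 100 * sum(gam[include] <= 1 + 1e-9, na.rm = TRUE) /
           sum(include),
         mean_gamma = mean(gam[include][finite]),
         evaluated_count = sum(include),
         criteria = criteria),
    class = "gamma_result"
  )
}

#' Gamma pass rate
#'
#' Percentage of evaluated (non-excluded) pixels with gamma <= 1.
#' @param result a \code{gamma_result}, or a bare gamma matrix/vector
#' @return pass rate in %
#' @export
pass_rate <- function(result) {
  g <- if (inherits(result, "gamma_result")) result$gamma else result
  g <- g[!is.nan(g)]
  if (!length(g)) stop_coded("ALL_EXCLUDED", "no evaluated pixels")
  100 * sum(g <= 1 + 1e-9) / length(g)
}

#' Dose-difference histogram between two planes
#'
#' Pixel-wise (evaluated - reference) / normalization dose, binned at
#' \code{bin_pct} of the normalization dose.  Planes must share a grid.
#'
#' @param reference,evaluated [dose_plane()]s on the same grid
#' @param bin_pct bin width in % of the normalization dose
#' @param criteria [gamma_criteria()] supplying the normalization
#' @return list with \code{breaks} (% edges), \code{counts}, \code{mids};
#'   counts sum to the pixel count
#' @export
dose_diff_histogram <- function(reference, evaluated, bin_pct = 0.5,
                                criteria = gamma_criteria()) {
  if (!identical(dim(reference$values), dim(evaluated$values)) ||
      !isTRUE(all.equal(reference$spacing, evaluated$spacing)) ||
      !isTRUE(all.equal(reference$origin, evaluated$origin)))
    stop_coded("GRID_MISMATCH", "planes are on different grids")
  dnorm_val <- norm_dose_of(reference, criteria)
  d_pct <- 100 * (evaluated$values - reference$values) / dnorm_val
  lo <- floor(min(d_pct) / bin_pct) * bin_pct
  hi <- ceiling(max(d_pct) / bin_pct) * bin_pct
  if (hi <= lo) hi <- lo + bin_pct
  breaks <- seq(lo, hi + bin_pct / 2, by = bin_pct)
  h <- hist(as.vector(d_pct), breaks = breaks, plot = FALSE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Extract a line dose profile
#'
#' Bilinear interpolation of a dose plane along the segment from
#' \code{start} to \code{end}, at steps of \code{step} mm.
#'
#' @param plane a [dose_plane()]
#' @param start,end (x, y) mm endpoints; must lie inside the plane
#' @param step sample spacing along the segment in mm
#' @return data.frame with \code{distance} (mm from start), \code{x},
#'   \code{y}, \code{dose}
#' @export
line_profile <- function(plane, start, end, step = 1) {
  len <- sqrt(sum((end - start)^2))
  d <- unique(c(seq(0, len, by = step), len))
  x <- start[1] + (end[1] - start[1]) * d / max(len, .Machine$double.eps)
  y <- start[2] + (end[2] - start[2]) * d / max(len, .Machine$double.eps)
  dose <- bilinear_interp(plane$values, plane$origin, plane$spacing, x, y)
  if (anyNA(dose)) stop_coded("OUT_OF_BOUNDS", "profile leaves the dose plane")
  data.frame(distance = d, x = x, y = y, dose = dose)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %g%%/%g mm: pass rate %.2f%% (gamma<=1), mean gamma %.3f, %d px evaluated\n",
    x$criteria$dose_tol_pct, x$criteria$dta_mm, x$pass_rate, x$mean_gamma,
    x$evaluated_count))
  invisible(x)
}
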