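# Internal helpers: angles, formatting, interpolation.

#' Normalize an angle to [0, 360)
#' @param a angle in degrees (vector ok)
#' @return angle(s) in [0, 360)
#' @keywords internal
#' @noRd
norm_angle <- function(a) {
  a <- a %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

#' Angular difference on the circle
#'
#' Smallest absolute difference between two angles in degrees, so that
#' 359.95 vs 0.05 gives 0.1 rather than 359.9.
#' @param a,b angles in degrees (vectors recycle)
#' @return non-negative difference in degrees
#' @export
#' @examples
#' circular_diff(359.95, 0.05)  # 0.1
circular_diff <- function(a, b) {
  d <- abs(norm_angle(a) - norm_angle(b)) %% 360
  pmin(d, 360 - d)
}

# fixed-precision serialization formats shared by the plan and log dialects;
# byte-exact round-trips rely on these never changing within a dialect version
fmt_mm <- function(x) sprintf("%.4f", x)
fmt_frac <- function(x) sprintf("%.6f", x)
fmt_deg <- function(x) sprintf("%.4f", x)
fmt_mu <- function(x) sprintf("%.4f", x)

stop_coded <- function(code, msg) {
  cond <- structure(
    class = c(code, "imrtqa_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, msg), call = sys.call(-1))
  )
  stop(cond)
}

#' Bilinear interpolation on a regular 2D grid
#'
#' @param values matrix indexed \code{[iy, ix]}
#' @param origin numeric(2): (x, y) position in mm of \code{values[1, 1]}
#' @param spacing numeric(2): (dx, dy) mm per pixel
#' @param x,y query coordinates in mm (equal-length vectors)
#' @return interpolated values; NA outside the grid extent
#' @keywords internal
#' @noRd
bilinear_interp <- function(values, origin, spacing, x, y) {
  nx <- ncol(values); ny <- nrow(values)
  fx <- (x - origin[1]) / spacing[1]
  fy <- (y - origin[2]) / spacing[2]
  out <- rep(NA_real_, length(x))
  ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]
  i0 <- pmin(floor(fx), nx - 2); i0[nx == 1] <- 0
  j0 <- pmin(floor(fy), ny - 2); j0[ny == 1] <- 0
  tx <- fx - i0; ty <- fy - j0
  if (nx == 1) tx <- 0
  if (ny == 1) ty <- 0
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  v00 <- values[cbind(j0 + 1, i0 + 1)]
  v01 <- values[cbind(j0 + 1, i1 + 1)]
  v10 <- values[cbind(j1 + 1, i0 + 1)]
  v11 <- values[cbind(j1 + 1, i1 + 1)]
  out[ok] <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out
}

# 1D overlap fraction of pixel intervals [lo_i, hi_i) with window (a, b);
# exact for axis-aligned rectangles
overlap_frac <- function(edges, a, b) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  pmax(0, pmin(hi, b) - pmax(lo, a)) / (hi - lo)
}
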