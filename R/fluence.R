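# MU-weighted fluence reconstruction at the isocenter plane.
#
# Fluence here is pure geometry: each static aperture (MLC open intervals
# clipped by the jaws) contributes its MU to every pixel it exposes, with
# partial pixels weighted by the exact area-overlap fraction (separable 1D
# overlaps, exact for axis-aligned rectangles).  No leaf transmission,
# tongue-and-groove, rounded leaf ends or scatter — the map is "MU seen
# through the open aperture", which is the quantity the delivery-log QA
# compares, not dose.

#' Define a fluence grid
#'
#' @param x_min,x_max,y_min,y_max grid extent in mm at isocenter
#' @param pixel_mm pixel size in mm (default 1)
#' @return a \code{fluence_grid} with pixel edge/center coordinates
#' @export
fluence_grid <- function(x_min, x_max, y_min, y_max, pixel_mm = 1) {
  if (x_max <= x_min || y_max <= y_min || pixel_mm <= 0)
    stop_coded("INVARIANT_ERROR", "degenerate fluence grid")
  nx <- max(1L, as.integer(ceiling((x_max - x_min) / pixel_mm - 1e-9)))
  ny <- max(1L, as.integer(ceiling((y_max - y_min) / pixel_mm - 1e-9)))
  structure(
    list(x_min = x_min, x_max = x_min + nx * pixel_mm,
         y_min = y_min, y_max = y_min + ny * pixel_mm,
         pixel_mm = pixel_mm, nx = nx, ny = ny,
         x_edges = x_min + pixel_mm * (0:nx),
         y_edges = y_min + pixel_mm * (0:ny)),
    class = "fluence_grid"
  )
}

#' Default fluence grid for a beam
#'
#' 1 mm pixels over the jaw rectangle padded by 10 mm on each side.
#' @param beam a [beam_plan()]
#' @param pixel_mm pixel size in mm
#' @param pad_mm padding beyond the jaws in mm
#' @return a [fluence_grid()]
#' @export
default_fluence_grid <- function(beam, pixel_mm = 1, pad_mm = 10) {
  j <- beam$jaws
  fluence_grid(j["x1"] - pad_mm, j["x2"] + pad_mm,
               j["y1"] - pad_mm, j["y2"] + pad_mm, pixel_mm)
}

# Pixel openness of one static aperture: ny x nx matrix of area fractions in
# [0, 1].  bank_a/bank_b are leaf-tip positions per pair, boundaries the
# leaf-pair edges along y, jaws the clipping rectangle.
aperture_openness <- function(bank_a, bank_b, boundaries, jaws, grid) {
  open <- matrix(0, grid$ny, grid$nx)
  xfrac_jaw <- overlap_frac(grid$x_edges, jaws["x1"], jaws["x2"])
  for (i in seq_along(bank_a)) {
    if (bank_b[i] - bank_a[i] <= 0) next
    ylo <- max(boundaries[i], jaws["y1"])
    yhi <- min(boundaries[i + 1], jaws["y2"])
    if (yhi <= ylo) next
    yfrac <- overlap_frac(grid$y_edges, ylo, yhi)
    if (!any(yfrac > 0)) next
    xfrac <- pmin(overlap_frac(grid$x_edges, bank_a[i], bank_b[i]), xfrac_jaw)
    open <- open + outer(yfrac, xfrac)
  }
  open
}

new_fluence_map <- function(grid, values, source) {
  structure(list(grid = grid, values = values, source = source),
            class = "fluence_map")
}

#' Reconstruct the planned fluence map of a beam
#'
#' Step-and-shoot accumulation: for each consecutive control-point pair
#' (k, k+1) the meterset increment times the beam MU is deposited through
#' the aperture of control point k+1 (the shape held while that segment's
#' dose is delivered), weighted per pixel by the exact aperture-overlap
#' fraction.
#'
#' @param beam a [beam_plan()]
#' @param grid a [fluence_grid()]; default [default_fluence_grid()]
#' @return a \code{fluence_map} (grid, matrix of MU per pixel indexed
#'   \code{[iy, ix]}, source \code{"PLANNED"})
#' @export
planned_fluence <- function(beam, grid = default_fluence_grid(beam)) {
  validate_beam_plan(beam)
  cps <- beam$control_points
  values <- matrix(0, grid$ny, grid$nx)
  for (k in seq_len(length(cps) - 1)) {
    dmu <- (cps[[k + 1]]$cumulative_meterset_fraction -
              cps[[k]]$cumulative_meterset_fraction) * beam$total_mu
    if (dmu <= 0) next
    ap <- cps[[k + 1]]
    values <- values + dmu * aperture_openness(ap$bank_a, ap$bank_b,
                                               beam$leaf_boundaries,
                                               beam$jaws, grid)
  }
  new_fluence_map(grid, values, "PLANNED")
}

#' Reconstruct the delivered fluence map from a log
#'
#' For each consecutive pair of beam-on samples, the meterset increment
#' times the beam MU is deposited through the aperture defined by the
#' *actual* leaf positions and jaws at the later sample.  Beam-off
#' intervals contribute nothing.
#'
#' @param log a [delivery_log()]
#' @param leaf_boundaries leaf-pair edge positions (mm); must match the
#'   log's leaf count
#' @param total_mu beam MU used to scale meterset increments; defaults to
#'   the log's own \code{total_mu}
#' @param grid a [fluence_grid()]
#' @return a \code{fluence_map} with source \code{"DELIVERED"}
#' @export
delivered_fluence <- function(log, leaf_boundaries, total_mu = log$total_mu,
                              grid) {
  s <- log$samples
  n <- log_sample_count(log)
  if (n == 0 || !any(s$beam_on)) stop_coded("EMPTY_BEAM", "no beam-on samples")
  if (length(leaf_boundaries) - 1 != log_leaf_pairs(log))
    stop_coded("LEAF_COUNT_MISMATCH", "leaf_boundaries do not match log leaf count")
  values <- matrix(0, grid$ny, grid$nx)
  # consecutive beam-on pairs sharing one static aperture (the common case in
  # step-and-shoot) are pooled so each distinct aperture is rasterized once
  pend_mu <- 0; pend_ap <- NULL
  flush <- function() {
    if (pend_mu > 0 && !is.null(pend_ap))
      values <<- values + pend_mu *
        aperture_openness(pend_ap$a, pend_ap$b, leaf_boundaries, pend_ap$jaws, grid)
  }
  for (k in seq_len(n - 1)) {
    if (!s$beam_on[k] || !s$beam_on[k + 1]) next
    dmu <- (s$meterset[k + 1] - s$meterset[k]) * total_mu
    if (dmu <= 0) next
    ap <- list(a = s$act_a[k + 1, ], b = s$act_b[k + 1, ], jaws = s$jaws[k + 1, ])
    if (!is.null(pend_ap) && identical(pend_ap, ap)) {
      pend_mu <- pend_mu + dmu
    } else {
      flush()
      pend_ap <- ap; pend_mu <- dmu
    }
  }
  flush()
  new_fluence_map(grid, values, "DELIVERED")
}

#' Pixel-by-pixel fluence difference and passing rates
#'
#' Differences two fluence maps on the same grid and reports the percentage
#' of analysis-region pixels whose absolute error is less than 2% and 3% of
#' the maximal fluence of the reference (planned) map.  The analysis region
#' is by default the union of pixels that are non-zero in either map;
#' all-grid analysis is available via \code{region = "full"}.
#'
#' @param planned,delivered \code{fluence_map}s on identical grids
#' @param thresholds_pct error thresholds as % of the planned map's maximum
#' @param region \code{"union"} (default) or \code{"full"}
#' @return a \code{fluence_diff}: list with \code{diff} (delivered -
#'   planned, MU), \code{max_fluence}, \code{pass_rates} (named %, one per
#'   threshold), \code{region_pixels}
#' @export
fluence_difference <- function(planned, delivered, thresholds_pct = c(2, 3),
                               region = c("union", "full")) {
  region <- match.arg(region)
  gp <- planned$grid; gd <- delivered$grid
  if (!isTRUE(all.equal(gp[c("x_min", "y_min", "pixel_mm", "nx", "ny")],
                        gd[c("x_min", "y_min", "pixel_mm", "nx", "ny")])))
    stop_coded("GRID_MISMATCH", "fluence maps are on different grids")
  d <- delivered$values - planned$values
  max_fluence <- max(planned$values)
  in_region <- if (region == "union") planned$values > 0 | delivered$values > 0
               else matrix(TRUE, gp$ny, gp$nx)
  n_region <- sum(in_region)
  pass <- vapply(thresholds_pct, function(p) {
    if (n_region == 0) return(NA_real_)
    100 * sum(abs(d[in_region]) < p / 100 * max_fluence) / n_region
  }, numeric(1))
  names(pass) <- sprintf("%g%%", thresholds_pct)
  structure(
    list(diff = d, max_fluence = max_fluence, pass_rates = pass,
         thresholds_pct = thresholds_pct, region_pixels = n_region,
         grid = gp),
    class = "fluence_diff"
  )
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %s: %dx%d px @ %g mm, max %.2f MU\n",
              x$source, x$grid$ny, x$grid$nx, x$grid$pixel_mm, max(x$values)))
  invisible(x)
}

#' @export
print.fluence_diff <- function(x, ...) {
  cat(sprintf("<fluence_diff> max |diff| %.3f MU (max fluence %.2f MU)\n",
              max(abs(x$diff)), x$max_fluence))
  for (nm in names(x$pass_rates))
    cat(sprintf("  pass rate @ %s of max: %.2f%%\n", nm, x$pass_rates[[nm]]))
  invisible(x)
}

#' Write a fluence map to a text grid container
#'
#' Header lines with grid metadata, then one row of pixel values per grid
#' row (y increasing), tab-separated.
#' @param map a \code{fluence_map}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_fluence <- function(map, path) {
  g <- map$grid
  header <- c("IMRTQA-FLUENCE 1",
              paste0("source: ", map$source),
              sprintf("x_min_mm: %s", fmt_mm(g$x_min)),
              sprintf("y_min_mm: %s", fmt_mm(g$y_min)),
              sprintf("pixel_mm: %s", fmt_mm(g$pixel_mm)),
              sprintf("nx: %d", g$nx), sprintf("ny: %d", g$ny))
  rows <- apply(map$values, 1, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a fluence map written by [write_fluence()]
#' @param path input path
#' @return a \code{fluence_map}
#' @export
read_fluence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "IMRTQA-FLUENCE 1")
    stop_coded("PARSE_ERROR", "missing IMRTQA-FLUENCE 1 header")
  src <- expect_key(lines, 2, "source")
  x_min <- as.numeric(expect_key(lines, 3, "x_min_mm"))
  y_min <- as.numeric(expect_key(lines, 4, "y_min_mm"))
  px <- as.numeric(expect_key(lines, 5, "pixel_mm"))
  nx <- as.integer(expect_key(lines, 6, "nx"))
  ny <- as.integer(expect_key(lines, 7, "ny"))
  vals <- do.call(rbind, lapply(lines[7 + seq_len(ny)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  grid <- fluence_grid(x_min, x_min + nx * px, y_min, y_min + ny * px, px)
  new_fluence_map(grid, vals, src)
}
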