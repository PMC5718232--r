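# Cumulative DVHs and dose-volume indices.

#' Construct a 3D dose grid
#'
#' @param values 3D array of dose in Gy, indexed \code{[ix, iy, iz]}
#' @param spacing mm per voxel, length 1 or 3 (x, y, z); default 3 mm
#'   isotropic, a common TPS export grid
#' @param origin mm position (x, y, z) of voxel \code{[1, 1, 1]}
#' @return a \code{dose_grid}
#' @export
dose_grid <- function(values, spacing = 3, origin = c(0, 0, 0)) {
  if (!all(is.finite(values)) || any(values < 0))
    stop_coded("INVARIANT_ERROR", "dose values must be finite and non-negative")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop_coded("INVARIANT_ERROR", "spacing must be positive")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' Construct a structure mask
#'
#' @param name structure name (e.g. "PTV", "cord")
#' @param mask 3D logical array aligned voxel-for-voxel with its dose grid
#' @return a \code{structure_mask}
#' @export
structure_mask <- function(name, mask) {
  structure(list(name = as.character(name), mask = mask),
            class = "structure_mask")
}

#' Compute a cumulative DVH
#'
#' \code{cumulative_volume_pct[j]} is the percentage of structure voxels
#' with dose >= \code{dose_edges[j]}; edges are uniform at \code{bin_gy}
#' from 0 past the structure maximum, so the curve starts at 100% and ends
#' at 0%.  The voxel doses are retained on the curve for exact MEAN/MIN/MAX
#' indices.
#'
#' @param dose a [dose_grid()]
#' @param structure a [structure_mask()] with the same array shape
#' @param bin_gy dose bin width in Gy (default 0.01)
#' @param prescription prescription dose in Gy (for relative indices)
#' @return a \code{dvh_curve}: list with \code{dose_edges},
#'   \code{cumulative_volume_pct}, \code{voxel_count}, \code{voxel_doses},
#'   \code{prescription_dose}, \code{structure}
#' @export
compute_dvh <- function(dose, structure, bin_gy = 0.01, prescription) {
  if (!identical(dim(dose$values), dim(structure$mask)))
    stop_coded("SHAPE_MISMATCH", "dose grid and mask shapes differ")
  d <- dose$values[structure$mask]
  n <- length(d)
  if (n == 0) stop_coded("EMPTY_STRUCTURE", paste("empty structure:", structure$name))
  edges <- seq(0, (floor(max(d) / bin_gy) + 1) * bin_gy, by = bin_gy)
  # vectorized recount: volume at edge e = #(d >= e) / n
  vol <- 100 * (n - findInterval(edges - 1e-12, sort(d))) / n
  structure(
    list(dose_edges = edges, cumulative_volume_pct = vol,
         voxel_count = n, voxel_doses = d,
         prescription_dose = prescription, structure = structure$name),
    class = "dvh_curve"
  )
}

#' Specify a DVH index
#'
#' Supported kinds:
#' \describe{
#'   \item{V_REL(p)}{% of volume receiving at least p% of prescription}
#'   \item{V_ABS(d)}{% of volume receiving at least d Gy}
#'   \item{D_PCT(v)}{minimum dose (Gy) to the hottest v% of the volume}
#'   \item{D_MIN, D_MAX, MEAN}{voxel-dose extremes and mean, in Gy}
#'   \item{HOMOGENEITY(p, q)}{(D_PCT(p) - D_PCT(q)) / prescription x 100 —
#'     the dose-spread indices often written D5%-95% and D3%-93%}
#' }
#' @param kind one of \code{"V_REL"}, \code{"V_ABS"}, \code{"D_PCT"},
#'   \code{"D_MIN"}, \code{"D_MAX"}, \code{"MEAN"}, \code{"HOMOGENEITY"}
#' @param ... numeric parameters of the kind (p, d, v, or p and q)
#' @return a \code{dvh_index_spec}
#' @export
dvh_spec <- function(kind = c("V_REL", "V_ABS", "D_PCT", "D_MIN", "D_MAX",
                              "MEAN", "HOMOGENEITY"), ...) {
  kind <- match.arg(kind)
  params <- c(...)
  need <- c(V_REL = 1, V_ABS = 1, D_PCT = 1, D_MIN = 0, D_MAX = 0,
            MEAN = 0, HOMOGENEITY = 2)[[kind]]
  if (length(params) != need)
    stop_coded("INVALID_SPEC", sprintf("%s needs %d parameter(s)", kind, need))
  if (kind %in% c("V_REL", "D_PCT", "HOMOGENEITY") &&
      any(params < 0 | params > 200))
    stop_coded("INVALID_SPEC", "percentage parameter out of range")
  structure(list(kind = kind, params = as.numeric(params)), class = "dvh_index_spec")
}

format_spec <- function(spec) {
  if (!length(spec$params)) return(spec$kind)
  sprintf("%s(%s)", spec$kind, paste(spec$params, collapse = ","))
}

# D_PCT(v): smallest dose whose cumulative volume is <= v%, linearly
# interpolated between bracketing edges; ties broken toward the lower dose.
d_pct_from_curve <- function(curve, v) {
  vol <- curve$cumulative_volume_pct
  edges <- curve$dose_edges
  if (v >= vol[1]) return(edges[1])
  j <- which(vol <= v)[1]
  if (is.na(j)) return(edges[length(edges)])
  if (j == 1) return(edges[1])
  v0 <- vol[j - 1]; v1 <- vol[j]
  if (v1 == v0) return(edges[j - 1])
  edges[j - 1] + (edges[j] - edges[j - 1]) * (v0 - v) / (v0 - v1)
}

#' Evaluate a DVH index
#'
#' @param curve a \code{dvh_curve} from [compute_dvh()]
#' @param spec a [dvh_spec()]
#' @return the index value: volumes in % of the structure, doses in Gy,
#'   HOMOGENEITY in % of prescription
#' @export
dvh_index <- function(curve, spec) {
  d <- curve$voxel_doses
  rx <- curve$prescription_dose
  switch(spec$kind,
    V_REL = 100 * sum(d >= spec$params[1] / 100 * rx - 1e-12) / length(d),
    V_ABS = 100 * sum(d >= spec$params[1] - 1e-12) / length(d),
    D_PCT = d_pct_from_curve(curve, spec$params[1]),
    D_MIN = min(d),
    D_MAX = max(d),
    MEAN = mean(d),
    HOMOGENEITY = 100 * (d_pct_from_curve(curve, spec$params[1]) -
                           d_pct_from_curve(curve, spec$params[2])) / rx,
    stop_coded("INVALID_SPEC", paste("unknown kind", spec$kind))
  )
}

# Trilinear resampling of grid b onto the voxel centers of grid a.
# Outside b's extent the dose is taken as 0 (no extrapolation).
resample_grid <- function(b, a) {
  dims <- dim(a$values)
  xs <- a$origin[1] + a$spacing[1] * (seq_len(dims[1]) - 1)
  ys <- a$origin[2] + a$spacing[2] * (seq_len(dims[2]) - 1)
  zs <- a$origin[3] + a$spacing[3] * (seq_len(dims[3]) - 1)
  out <- array(0, dims)
  nb <- dim(b$values)
  for (iz in seq_len(dims[3])) {
    fz <- (zs[iz] - b$origin[3]) / b$spacing[3]
    if (fz < 0 || fz > nb[3] - 1) next
    k0 <- min(floor(fz), max(nb[3] - 2, 0)); tz <- if (nb[3] == 1) 0 else fz - k0
    k1 <- min(k0 + 1, nb[3] - 1)
    # bilinear in (x, y) on the two bracketing slices, then linear in z
    sl0 <- b$values[, , k0 + 1]; sl1 <- b$values[, , k1 + 1]
    xy <- expand.grid(x = xs, y = ys)
    v0 <- bilinear_interp(t(sl0), b$origin[1:2], b$spacing[1:2], xy$x, xy$y)
    v1 <- bilinear_interp(t(sl1), b$origin[1:2], b$spacing[1:2], xy$x, xy$y)
    v <- (1 - tz) * v0 + tz * v1
    v[is.na(v)] <- 0
    out[, , iz] <- matrix(v, dims[1], dims[2])
  }
  dose_grid(out, a$spacing, a$origin)
}

#' Compare DVH indices between two dose calculations
#'
#' Resamples grid \code{dose_b} trilinearly onto \code{dose_a}'s frame (the
#' reference), computes each requested index for each structure under both
#' dose sets, and tabulates value_a, value_b, ratio b/a, absolute and
#' percent difference.  Rows whose index is a MEAN dose are flagged when the
#' percent difference exceeds \code{agreement_pct}.
#'
#' @param dose_a reference [dose_grid()]
#' @param dose_b comparison [dose_grid()] (any frame; resampled)
#' @param structures list of [structure_mask()] on \code{dose_a}'s frame
#' @param specs list of [dvh_spec()]
#' @param prescription prescription dose in Gy, a single value or a named
#'   vector per structure name
#' @param agreement_pct mean-dose agreement threshold in % (default 3)
#' @param bin_gy DVH bin width
#' @return data.frame: structure, index, value_a, value_b, ratio,
#'   abs_diff, pct_diff, flagged
#' @export
compare_plans <- function(dose_a, dose_b, structures, specs, prescription,
                          agreement_pct = 3, bin_gy = 0.01) {
  b_on_a <- if (identical(dim(dose_a$values), dim(dose_b$values)) &&
                isTRUE(all.equal(dose_a$spacing, dose_b$spacing)) &&
                isTRUE(all.equal(dose_a$origin, dose_b$origin)))
    dose_b else resample_grid(dose_b, dose_a)
  if (!identical(dim(b_on_a$values), dim(dose_a$values)))
    stop_coded("SHAPE_MISMATCH", "resampling failed to match grids")
  rows <- list()
  for (st in structures) {
    rx <- if (length(prescription) > 1) prescription[[st$name]] else prescription
    ca <- compute_dvh(dose_a, st, bin_gy, rx)
    cb <- compute_dvh(b_on_a, st, bin_gy, rx)
    for (spec in specs) {
      va <- dvh_index(ca, spec)
      vb <- dvh_index(cb, spec)
      pct <- if (abs(va) > 1e-12) 100 * (vb - va) / va else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        structure = st$name, index = format_spec(spec),
        value_a = va, value_b = vb,
        ratio = if (abs(va) > 1e-12) vb / va else NA_real_,
        abs_diff = vb - va, pct_diff = pct,
        flagged = spec$kind == "MEAN" && is.finite(pct) &&
          abs(pct) > agreement_pct + 1e-9,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d voxels, mean %.2f Gy, D_max %.2f Gy (Rx %.2f Gy)\n",
              x$structure, x$voxel_count, mean(x$voxel_doses),
              max(x$voxel_doses), x$prescription_dose))
  invisible(x)
}
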