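# Toy fixtures and independent oracles shared across tests.
# Oracles are deliberately naive (fine rasterization, exhaustive search,
# direct recounts) and never call the code paths they check.

toy_boundaries <- c(-15, -5, 5, 15)  # 3 leaf pairs, one 10 mm, one 10 mm span each

# Build a step-and-shoot toy beam from a list of apertures (each
# list(a =, b =) per-pair leaf tips) and the cumulative fractions at the
# end of each segment.
make_toy_beam <- function(apertures, end_fractions, mu = 100,
                          jaws = c(x1 = -50, x2 = 50, y1 = -15, y2 = 15),
                          gantry = 180, coll = 0,
                          boundaries = toy_boundaries,
                          beam_id = "B1") {
  stopifnot(length(apertures) == length(end_fractions))
  cps <- list(control_point(0L, 0, apertures[[1]]$a, apertures[[1]]$b))
  for (k in seq_along(apertures))
    cps[[k + 1]] <- control_point(k, end_fractions[k],
                                  apertures[[k]]$a, apertures[[k]]$b)
  beam_plan(beam_id, gantry, coll, jaws, mu, "6MV", cps, boundaries)
}

open_field_beam <- function(mu = 100, half = c(-50, 50)) {
  ap <- list(a = rep(half[1], 3), b = rep(half[2], 3))
  make_toy_beam(list(ap), 1, mu = mu)
}

toy_plan <- function(beam, patient_id = "12345", name = "Toy^Patient",
                     rx = 70) {
  treatment_plan(name, patient_id, rx, list(beam))
}

# ---- fluence oracle: 0.05 mm rasterization with box averaging -------------

# Rasterize one aperture at sub-pixel resolution and box-average onto the
# fluence grid.  `step` must divide pixel_mm exactly.
oracle_openness <- function(a, b, boundaries, jaws, grid, step = 0.05) {
  bs <- round(grid$pixel_mm / step)
  stopifnot(abs(bs * step - grid$pixel_mm) < 1e-9)
  fx <- grid$x_min + step * (seq_len(grid$nx * bs) - 0.5)
  fy <- grid$y_min + step * (seq_len(grid$ny * bs) - 0.5)
  pair_of <- findInterval(fy, boundaries)
  fine <- matrix(0, length(fy), length(fx))
  x_in_jaw <- fx > jaws["x1"] & fx < jaws["x2"]
  for (iy in seq_along(fy)) {
    p <- pair_of[iy]
    if (p < 1 || p > length(a)) next
    if (fy[iy] <= jaws["y1"] || fy[iy] >= jaws["y2"]) next
    fine[iy, ] <- as.numeric(fx > a[p] & fx < b[p] & x_in_jaw)
  }
  gy <- (seq_along(fy) - 1) %/% bs + 1
  gx <- (seq_along(fx) - 1) %/% bs + 1
  coarse <- t(rowsum(t(rowsum(fine, gy)), gx)) / bs^2
  coarse
}

oracle_planned_fluence <- function(beam, grid, step = 0.05) {
  vals <- matrix(0, grid$ny, grid$nx)
  cps <- beam$control_points
  for (k in seq_len(length(cps) - 1)) {
    dmu <- (cps[[k + 1]]$cumulative_meterset_fraction -
              cps[[k]]$cumulative_meterset_fraction) * beam$total_mu
    if (dmu <= 0) next
    vals <- vals + dmu * oracle_openness(cps[[k + 1]]$bank_a,
                                         cps[[k + 1]]$bank_b,
                                         beam$leaf_boundaries, beam$jaws,
                                         grid, step)
  }
  vals
}

# ---- gamma oracle: exhaustive minimization on a 0.05 mm lattice -----------

# Independent bilinear interpolation (clamped to the grid; NA outside).
oracle_bilinear <- function(values, origin, spacing, x, y) {
  nx <- ncol(values); ny <- nrow(values)
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    fx <- (x[i] - origin[1]) / spacing[1]
    fy <- (y[i] - origin[2]) / spacing[2]
    if (fx < 0 || fx > nx - 1 || fy < 0 || fy > ny - 1) next
    i0 <- min(floor(fx), nx - 2); j0 <- min(floor(fy), ny - 2)
    if (nx == 1) i0 <- 0
    if (ny == 1) j0 <- 0
    tx <- if (nx == 1) 0 else fx - i0
    ty <- if (ny == 1) 0 else fy - j0
    i1 <- min(i0 + 1, nx - 1); j1 <- min(j0 + 1, ny - 1)
    out[i] <- (1 - ty) * ((1 - tx) * values[j0 + 1, i0 + 1] +
                            tx * values[j0 + 1, i1 + 1]) +
      ty * ((1 - tx) * values[j1 + 1, i0 + 1] + tx * values[j1 + 1, i1 + 1])
  }
  out
}

oracle_gamma <- function(reference, evaluated, criteria, step = 0.05) {
  dnorm_val <- if (criteria$normalization == "GLOBAL_MAX_REF")
    max(reference$values) else criteria$norm_dose
  ex0 <- evaluated$origin[1]; ey0 <- evaluated$origin[2]
  exn <- ex0 + evaluated$spacing[1] * (ncol(evaluated$values) - 1)
  eyn <- ey0 + evaluated$spacing[2] * (nrow(evaluated$values) - 1)
  gx <- seq(ex0, exn, by = step)
  gy <- seq(ey0, eyn, by = step)
  de <- matrix(NA_real_, length(gy), length(gx))
  for (j in seq_along(gy))
    de[j, ] <- oracle_bilinear(evaluated$values, evaluated$origin,
                               evaluated$spacing, gx, rep(gy[j], length(gx)))
  r <- criteria$search_radius_mm
  denom <- (criteria$dose_tol_pct / 100 * dnorm_val)^2
  nyr <- nrow(reference$values); nxr <- ncol(reference$values)
  rx <- reference$origin[1] + reference$spacing[1] * (seq_len(nxr) - 1)
  ry <- reference$origin[2] + reference$spacing[2] * (seq_len(nyr) - 1)
  gam <- matrix(NaN, nyr, nxr)
  cutoff <- criteria$low_dose_cutoff_pct / 100 * dnorm_val
  for (jy in seq_len(nyr)) for (jx in seq_len(nxr)) {
    dr <- reference$values[jy, jx]
    if (dr < cutoff) next
    xs <- which(abs(gx - rx[jx]) <= r)
    ys <- which(abs(gy - ry[jy]) <= r)
    if (!length(xs) || !length(ys)) next
    dx2 <- (gx[xs] - rx[jx])^2
    dy2 <- (gy[ys] - ry[jy])^2
    d2 <- outer(dy2, dx2, "+")
    keep <- d2 <= r^2 + 1e-12
    g2 <- d2 / criteria$dta_mm^2 + (de[ys, xs, drop = FALSE] - dr)^2 / denom
    gam[jy, jx] <- sqrt(min(g2[keep]))
  }
  gam
}

# ---- misc -----------------------------------------------------------------

expect_coded_error <- function(expr, code) {
  expect_error(expr, class = code)
}

# a small uniform-dose slab phantom shared by DVH tests
uniform_phantom <- function(value = 70, dim = c(10, 10, 5)) {
  make_phantom(phantom_spec(
    dim = dim, spacing = 3,
    structures = list(list(name = "PTV", type = "box",
                           lo = c(3, 3, 0), hi = c(21, 21, 12))),
    dose = list(type = "uniform", value = value)))
}
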