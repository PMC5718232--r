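# DVH computation and index comparison.

test_that("uniform and two-level doses give the expected step curves", {
  ph <- uniform_phantom(70)
  curve <- compute_dvh(ph$dose, ph$structures[[1]], bin_gy = 0.5,
                       prescription = 70)
  expect_equal(curve$cumulative_volume_pct[curve$dose_edges <= 70],
               rep(100, sum(curve$dose_edges <= 70)))
  expect_equal(curve$cumulative_volume_pct[curve$dose_edges > 70],
               rep(0, sum(curve$dose_edges > 70)))
  expect_equal(curve$cumulative_volume_pct[1], 100)
  expect_equal(tail(curve$cumulative_volume_pct, 1), 0)

  # half the voxels at 70 Gy, half at 35 Gy: box spans 8 voxel columns in x,
  # the lower 4 of which are set to 35 Gy
  ph2 <- make_phantom(phantom_spec(
    dim = c(10, 10, 5), spacing = 3,
    structures = list(list(name = "PTV", type = "box",
                           lo = c(3, 3, 0), hi = c(24, 24, 12))),
    dose = list(type = "uniform", value = 70)))
  v <- ph2$dose$values
  v[1:5, , ] <- 35
  dg <- dose_grid(v, ph2$dose$spacing, ph2$dose$origin)
  c2 <- compute_dvh(dg, ph2$structures[[1]], bin_gy = 0.5, prescription = 70)
  expect_equal(c2$cumulative_volume_pct[c2$dose_edges <= 35],
               rep(100, sum(c2$dose_edges <= 35)))
  mid <- c2$dose_edges > 35 & c2$dose_edges <= 70
  expect_equal(c2$cumulative_volume_pct[mid], rep(50, sum(mid)))
  expect_equal(dvh_index(c2, dvh_spec("V_REL", 95)), 50)  # >= 66.5 Gy
})

test_that("DVH curves match a direct recount at every edge", {
  set.seed(8)
  dim3 <- c(12, 12, 6)
  vals <- array(rlnorm(prod(dim3), log(30), 0.4), dim3)
  dg <- dose_grid(vals, 3)
  mask <- structure_mask("S", array(runif(prod(dim3)) < 0.5, dim3))
  for (bin in c(0.01, 0.37)) {
    curve <- compute_dvh(dg, mask, bin_gy = bin, prescription = 50)
    d <- vals[mask$mask]
    recount <- vapply(curve$dose_edges,
                      function(e) 100 * sum(d >= e - 1e-12) / length(d),
                      numeric(1))
    expect_equal(curve$cumulative_volume_pct, recount)
    expect_true(all(diff(curve$cumulative_volume_pct) <= 0))
  }
})

test_that("indices on a linear gradient match closed forms", {
  # gradient 0 -> 100 Gy along x over the grid, slab structure spanning x
  ph <- make_phantom(phantom_spec(
    dim = c(101, 5, 5), spacing = 1,
    structures = list(list(name = "slab", type = "slab", axis = 1,
                           from = 0, to = 100)),
    dose = list(type = "gradient", axis = 1, from_gy = 0, to_gy = 100)))
  curve <- compute_dvh(ph$dose, ph$structures[[1]], bin_gy = 0.01,
                       prescription = 100)
  expect_equal(dvh_index(curve, dvh_spec("D_PCT", 5)), 95, tolerance = 0.02)
  expect_equal(dvh_index(curve, dvh_spec("D_PCT", 95)), 5, tolerance = 0.02)
  expect_equal(dvh_index(curve, dvh_spec("HOMOGENEITY", 5, 95)), 90,
               tolerance = 0.05)
  expect_equal(dvh_index(curve, dvh_spec("MEAN")), 50, tolerance = 1e-9)
  expect_equal(dvh_index(curve, dvh_spec("D_MIN")), 0)
  expect_equal(dvh_index(curve, dvh_spec("D_MAX")), 100)
  expect_equal(dvh_index(curve, dvh_spec("V_ABS", 50)), 100 * 51 / 101,
               tolerance = 1e-9)

  # uniform dose: homogeneity spread collapses to zero (within a bin width)
  phu <- uniform_phantom(70)
  cu <- compute_dvh(phu$dose, phu$structures[[1]], bin_gy = 0.01,
                    prescription = 70)
  expect_lt(abs(dvh_index(cu, dvh_spec("HOMOGENEITY", 5, 95))), 0.05)
  expect_equal(dvh_index(cu, dvh_spec("V_REL", 95)), 100)
  expect_equal(dvh_index(cu, dvh_spec("MEAN")), 70)
})

test_that("halving the bin width moves indices by at most one original bin", {
  set.seed(15)
  dim3 <- c(10, 10, 4)
  dg <- dose_grid(array(rlnorm(prod(dim3), log(40), 0.3), dim3), 3)
  mask <- structure_mask("S", array(TRUE, dim3))
  c1 <- compute_dvh(dg, mask, bin_gy = 0.4, prescription = 50)
  c2 <- compute_dvh(dg, mask, bin_gy = 0.2, prescription = 50)
  for (v in c(5, 50, 95))
    expect_lt(abs(dvh_index(c1, dvh_spec("D_PCT", v)) -
                    dvh_index(c2, dvh_spec("D_PCT", v))), 0.4 + 1e-12)
})

test_that("whole-voxel translation of dose and mask leaves indices unchanged", {
  ph <- uniform_phantom(60)
  v <- ph$dose$values
  set.seed(2)
  v <- v * (1 + 0.1 * array(runif(length(v)), dim(v)))
  m <- ph$structures[[1]]$mask
  shift <- function(a, k) {
    out <- array(if (is.logical(a)) FALSE else 0, dim(a))
    out[(1 + k):dim(a)[1], , ] <- a[1:(dim(a)[1] - k), , ]
    out
  }
  d1 <- dose_grid(v, 3); m1 <- structure_mask("S", m)
  d2 <- dose_grid(shift(v, 2), 3); m2 <- structure_mask("S", shift(m, 2))
  for (spec in list(dvh_spec("MEAN"), dvh_spec("D_PCT", 50),
                    dvh_spec("V_REL", 95)))
    expect_equal(dvh_index(compute_dvh(d2, m2, 0.05, 60), spec),
                 dvh_index(compute_dvh(d1, m1, 0.05, 60), spec))
})

test_that("compare_plans tabulates identity, uniform scaling and recounts", {
  ph <- uniform_phantom(70)
  specs <- list(dvh_spec("MEAN"), dvh_spec("D_MAX"), dvh_spec("V_REL", 95))
  t_same <- compare_plans(ph$dose, ph$dose, ph$structures, specs, 70)
  expect_true(all(t_same$abs_diff == 0))
  expect_true(all(t_same$ratio == 1))
  expect_false(any(t_same$flagged))

  d97 <- dose_grid(ph$dose$values * 0.97, ph$dose$spacing, ph$dose$origin)
  t97 <- compare_plans(ph$dose, d97, ph$structures, specs, 70)
  mean_row <- t97[t97$index == "MEAN", ]
  expect_equal(mean_row$ratio, 0.97, tolerance = 1e-12)
  expect_equal(mean_row$pct_diff, -3, tolerance = 1e-9)
  expect_false(mean_row$flagged)  # exactly at the 3% boundary, not beyond
  d94 <- dose_grid(ph$dose$values * 0.94, ph$dose$spacing, ph$dose$origin)
  t94 <- compare_plans(ph$dose, d94, ph$structures, specs, 70)
  expect_true(t94[t94$index == "MEAN", "flagged"])

  # random paired grids: table equals element-wise recomputation
  set.seed(23)
  dim3 <- c(10, 10, 5)
  a <- dose_grid(array(rlnorm(prod(dim3), log(30), 0.3), dim3), 3)
  b <- dose_grid(a$values * array(runif(prod(dim3), 0.9, 1.1), dim3), 3)
  mask <- structure_mask("S", array(runif(prod(dim3)) < 0.6, dim3))
  tab <- compare_plans(a, b, list(mask), specs, 60)
  for (i in seq_len(nrow(tab))) {
    sp <- specs[[i]]
    va <- dvh_index(compute_dvh(a, mask, 0.01, 60), sp)
    vb <- dvh_index(compute_dvh(b, mask, 0.01, 60), sp)
    expect_equal(tab$value_a[i], va)
    expect_equal(tab$value_b[i], vb)
    expect_equal(tab$abs_diff[i], vb - va)
  }
})

test_that("trilinear resampling recovers an identical co-registered grid", {
  set.seed(30)
  dim3 <- c(12, 10, 6)
  a <- dose_grid(array(runif(prod(dim3), 10, 60), dim3), 3)
  mask <- structure_mask("S", array(TRUE, dim3))
  spec <- list(dvh_spec("MEAN"))
  # same dose sampled on a finer grid with compatible extent: mean dose of
  # the resampled comparison stays within interpolation error
  fine_dim <- c(23, 19, 11)
  xs <- 1.5 * (seq_len(23) - 1); ys <- 1.5 * (seq_len(19) - 1)
  zs <- 1.5 * (seq_len(11) - 1)
  fine <- array(0, fine_dim)
  for (iz in seq_along(zs)) {
    k0 <- min(floor(zs[iz] / 3), dim3[3] - 2); tz <- zs[iz] / 3 - k0
    for (iy in seq_along(ys)) {
      j0 <- min(floor(ys[iy] / 3), dim3[2] - 2); ty <- ys[iy] / 3 - j0
      for (ix in seq_along(xs)) {
        i0 <- min(floor(xs[ix] / 3), dim3[1] - 2); tx <- xs[ix] / 3 - i0
        c00 <- a$values[i0 + 1, j0 + 1, k0 + 1] * (1 - tx) +
          a$values[i0 + 2, j0 + 1, k0 + 1] * tx
        c10 <- a$values[i0 + 1, j0 + 2, k0 + 1] * (1 - tx) +
          a$values[i0 + 2, j0 + 2, k0 + 1] * tx
        c01 <- a$values[i0 + 1, j0 + 1, k0 + 2] * (1 - tx) +
          a$values[i0 + 2, j0 + 1, k0 + 2] * tx
        c11 <- a$values[i0 + 1, j0 + 2, k0 + 2] * (1 - tx) +
          a$values[i0 + 2, j0 + 2, k0 + 2] * tx
        fine[ix, iy, iz] <- (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
          (c01 * (1 - ty) + c11 * ty) * tz
      }
    }
  }
  b <- dose_grid(fine, 1.5)
  tab <- compare_plans(a, b, list(mask), spec, 50)
  expect_lt(abs(tab$pct_diff[1]), 0.5)
})

test_that("empty structures and shape mismatches are rejected", {
  ph <- uniform_phantom(70)
  empty <- structure_mask("void", array(FALSE, dim(ph$dose$values)))
  expect_coded_error(compute_dvh(ph$dose, empty, 0.1, 70), "EMPTY_STRUCTURE")
  small <- dose_grid(array(1, c(2, 2, 2)), 3)
  expect_coded_error(compute_dvh(small, ph$structures[[1]], 0.1, 70),
                     "SHAPE_MISMATCH")
  expect_coded_error(dvh_spec("V_REL"), "INVALID_SPEC")
  expect_coded_error(dvh_spec("HOMOGENEITY", 5), "INVALID_SPEC")
})
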