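# 2D gamma analysis, dose-difference histograms, line profiles.

flat_plane <- function(value, n = 15, spacing = 2) {
  dose_plane(matrix(value, n, n), spacing = spacing)
}

# 1D-style gradient along x: 0 -> 2 Gy over 100 mm, a few rows tall
gradient_plane <- function(shift_mm = 0, spacing = 2, ny = 5, nx = 51) {
  x <- spacing * (seq_len(nx) - 1)
  vals <- matrix(rep(0.02 * (x - shift_mm), each = ny), ny, nx)
  vals[vals < 0] <- 0
  dose_plane(vals, spacing = spacing)
}

test_that("identity planes give all-zero gamma and a 100% pass rate", {
  ref <- gradient_plane()
  crit <- gamma_criteria(low_dose_cutoff_pct = 0)
  res <- gamma_map(ref, ref, crit)
  expect_true(all(res$gamma == 0))
  expect_equal(res$pass_rate, 100)
  expect_equal(res$evaluated_count, length(ref$values))
})

test_that("a uniform +3% offset on a flat field forces gamma = 1 exactly", {
  ref <- flat_plane(1.00)
  ev <- flat_plane(1.03)
  res <- gamma_map(ref, ev, gamma_criteria(dose_tol_pct = 3, dta_mm = 3))
  expect_true(all(abs(res$gamma - 1) < 1e-6))
  # and +2% passes everywhere with gamma = 2/3
  res2 <- gamma_map(ref, flat_plane(1.02), gamma_criteria())
  expect_true(all(abs(res2$gamma - 2 / 3) < 1e-6))
  expect_equal(res2$pass_rate, 100)
})

test_that("gradient shifted by 3 mm passes, by 6 mm fails, matching theory", {
  ref <- gradient_plane()
  crit <- gamma_criteria(low_dose_cutoff_pct = 10)
  res3 <- gamma_map(ref, gradient_plane(shift_mm = 3), crit)
  expect_true(all(res3$gamma[!is.nan(res3$gamma)] <= 1 + 1e-9))
  expect_equal(res3$pass_rate, 100)

  res6 <- gamma_map(ref, gradient_plane(shift_mm = 6), crit)
  # interior optimum splits the 6 mm between space and dose:
  # gamma = sqrt(min_s (s^2 + (s-6)^2) / dta^2) = 6 / sqrt(2 * 3^2) = sqrt(2)
  interior <- res6$gamma[, 10:42]
  interior <- interior[!is.nan(interior)]
  expect_true(all(abs(interior - sqrt(2)) < 0.02))
  expect_equal(res6$pass_rate, 0)
})

test_that("gamma agrees with the exhaustive 0.05 mm brute-force oracle", {
  set.seed(9)
  base <- 1 + 0.5 * outer(sin(seq(0, 3, length.out = 12)),
                          cos(seq(0, 3, length.out = 12)))
  ref <- dose_plane(base, spacing = 3)
  ev <- dose_plane(base * (1 + 0.02 * matrix(runif(144, -1, 1), 12, 12)),
                   spacing = 3, origin = c(1, -1))
  crit <- gamma_criteria(low_dose_cutoff_pct = 0)
  res <- gamma_map(ref, ev, crit)
  oracle <- oracle_gamma(ref, ev, crit, step = 0.05)
  expect_lt(max(abs(res$gamma - oracle)), 0.02)
})

test_that("loosening either criterion never increases gamma anywhere", {
  ref <- gradient_plane()
  ev <- gradient_plane(shift_mm = 4)
  crit <- gamma_criteria(low_dose_cutoff_pct = 0)
  g33 <- gamma_map(ref, ev, crit)$gamma
  g53 <- gamma_map(ref, ev, gamma_criteria(dose_tol_pct = 5,
                                           low_dose_cutoff_pct = 0))$gamma
  g35 <- gamma_map(ref, ev, gamma_criteria(dta_mm = 5,
                                           low_dose_cutoff_pct = 0))$gamma
  expect_true(all(g53 <= g33 + 1e-9))
  expect_true(all(g35 <= g33 + 1e-9))
})

test_that("gamma is invariant under a common dose scale", {
  ref <- gradient_plane()
  ev <- gradient_plane(shift_mm = 4)
  crit <- gamma_criteria(low_dose_cutoff_pct = 0)
  g1 <- gamma_map(ref, ev, crit)$gamma
  ref2 <- dose_plane(ref$values * 2, ref$spacing, ref$origin)
  ev2 <- dose_plane(ev$values * 2, ev$spacing, ev$origin)
  g2 <- gamma_map(ref2, ev2, crit)$gamma
  expect_equal(g2, g1, tolerance = 1e-12)
})

test_that("pass_rate recounts the gamma array and errors when all excluded", {
  g <- matrix(c(rep(0.5, 8), rep(1.5, 8)), 4, 4)
  expect_equal(pass_rate(g), 50)
  res <- gamma_map(gradient_plane(), gradient_plane(shift_mm = 2),
                   gamma_criteria(low_dose_cutoff_pct = 20))
  manual <- res$gamma[!is.nan(res$gamma)]
  expect_equal(pass_rate(res), 100 * sum(manual <= 1) / length(manual))
  expect_coded_error(pass_rate(matrix(NaN, 2, 2)), "ALL_EXCLUDED")
  expect_coded_error(
    gamma_map(flat_plane(0.01), flat_plane(0.01),
              gamma_criteria(normalization = "PRESCRIPTION", norm_dose = 1,
                             low_dose_cutoff_pct = 10)),
    "ALL_EXCLUDED")
})

test_that("non-overlapping planes are rejected", {
  a <- dose_plane(matrix(1, 5, 5), spacing = 1, origin = c(0, 0))
  b <- dose_plane(matrix(1, 5, 5), spacing = 1, origin = c(100, 100))
  expect_coded_error(gamma_map(a, b, gamma_criteria()), "NO_OVERLAP")
})

test_that("dose-difference histogram bins exactly and sums to pixel count", {
  ref <- flat_plane(1.00)
  same <- dose_diff_histogram(ref, ref)
  expect_equal(sum(same$counts), length(ref$values))
  expect_equal(sum(same$counts[same$mids != 0 & abs(same$mids) > 0.26]), 0)

  up <- dose_diff_histogram(ref, flat_plane(1.03), bin_pct = 1)
  occupied <- up$mids[up$counts > 0]
  expect_length(occupied, 1)
  expect_equal(occupied, 3.5)  # +3% falls in the [3, 4) bin

  set.seed(4)
  ev <- dose_plane(ref$values + matrix(rnorm(225, 0, 0.02), 15, 15),
                   spacing = ref$spacing)
  h <- dose_diff_histogram(ref, ev, bin_pct = 0.5)
  d_pct <- 100 * (ev$values - ref$values) / max(ref$values)
  for (i in seq_along(h$counts)) {
    recount <- sum(d_pct >= h$breaks[i] & d_pct < h$breaks[i + 1])
    expect_identical(h$counts[i], as.integer(recount))
  }
  expect_coded_error(dose_diff_histogram(ref, gradient_plane()), "GRID_MISMATCH")
})

test_that("line profiles interpolate bilinearly and reject exits", {
  ref <- flat_plane(2)
  prof <- line_profile(ref, c(0, 4), c(20, 4), step = 1)
  expect_true(all(prof$dose == 2))

  # axis-aligned profile at pixel centers returns stored values
  vals <- matrix(seq_len(20), 4, 5)
  p <- dose_plane(vals, spacing = 2)
  prof2 <- line_profile(p, c(0, 4), c(8, 4), step = 2)
  expect_equal(prof2$dose, vals[3, ])

  # bilinear plane f(x, y) = x + y is reproduced along a diagonal
  xy <- outer(2 * (0:4), 2 * (0:4), function(y, x) x + y)
  pl <- dose_plane(xy, spacing = 2)
  d <- line_profile(pl, c(0, 0), c(8, 8), step = 0.5)
  expect_equal(d$dose, d$x + d$y, tolerance = 1e-12)

  expect_coded_error(line_profile(ref, c(0, 0), c(1000, 0)), "OUT_OF_BOUNDS")
})
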