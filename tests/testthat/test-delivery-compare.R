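# Delivered-vs-planned parameter comparison.

sim_one <- function(err = error_model(), seed = 21, n_segments = 3) {
  plan <- make_plan(seed, n_segments = n_segments,
                    leaf_boundaries = toy_boundaries)
  list(plan = plan,
       log = simulate_delivery(plan, err, seed = seed)[[1]])
}

test_that("identity delivery passes every check with exactly zero deviations", {
  s <- sim_one()
  rep <- compare_beam(s$plan$beams[[1]], s$log, plan = s$plan)
  expect_identical(rep$overall_status, "PASS")
  expect_true(all(rep$checks$status == "PASS"))
  expect_true(all(rep$checks$max_observed_deviation == 0))
  expect_identical(rep$max_mlc_error_mm, 0)
  expect_equal(rep$max_transfer_error_mm, 0)
  expect_equal(rep$segment_count_observed, rep$segment_count_planned)
})

test_that("single injected constant offsets are recovered at their magnitude", {
  cases <- list(
    list(err = error_model(gantry_offset_deg = 0.07), check = "gantry", dev = 0.07),
    list(err = error_model(collimator_offset_deg = 0.23), check = "collimator", dev = 0.23),
    list(err = error_model(jaw_offset_mm = c(x1 = 1.5)), check = "jaw_x1", dev = 1.5),
    list(err = error_model(jaw_offset_mm = c(y2 = -0.8)), check = "jaw_y2", dev = 0.8),
    list(err = error_model(mu_scale = 1.05), check = "mu", dev = 5)
  )
  for (cs in cases) {
    s <- sim_one(cs$err)
    rep <- compare_beam(s$plan$beams[[1]], s$log, plan = s$plan)
    got <- rep$checks$max_observed_deviation[rep$checks$name == cs$check]
    expect_equal(got, cs$dev, tolerance = 1e-3)
    # all other scalar channels stay untouched
    others <- setdiff(rep$checks$name, c(cs$check, "mlc"))
    expect_true(all(rep$checks$max_observed_deviation[
      rep$checks$name %in% others] < 1e-9))
  }
})

test_that("PASS flips to WARNING when crossing each clinical tolerance", {
  near_far <- list(
    list(check = "gantry",
         below = error_model(gantry_offset_deg = 0.09),
         above = error_model(gantry_offset_deg = 0.11)),
    list(check = "collimator",
         below = error_model(collimator_offset_deg = 0.09),
         above = error_model(collimator_offset_deg = 0.11)),
    list(check = "jaw_x2",
         below = error_model(jaw_offset_mm = c(x2 = 0.9)),
         above = error_model(jaw_offset_mm = c(x2 = 1.1))),
    list(check = "mlc",
         below = error_model(leaf_systematic_mm =
                               data.frame(bank = "A", leaf = 2, offset_mm = 1.9)),
         above = error_model(leaf_systematic_mm =
                               data.frame(bank = "A", leaf = 2, offset_mm = 2.1))),
    list(check = "mu",
         below = error_model(mu_scale = 1.009),
         above = error_model(mu_scale = 1.011))
  )
  for (cs in near_far) {
    s_lo <- sim_one(cs$below)
    s_hi <- sim_one(cs$above)
    st_lo <- compare_beam(s_lo$plan$beams[[1]], s_lo$log)$checks
    st_hi <- compare_beam(s_hi$plan$beams[[1]], s_hi$log)$checks
    expect_identical(st_lo$status[st_lo$name == cs$check], "PASS",
                     label = paste(cs$check, "below tolerance"))
    expect_identical(st_hi$status[st_hi$name == cs$check], "WARNING",
                     label = paste(cs$check, "above tolerance"))
  }
})

test_that("angle deviations are computed on the circle", {
  ap <- list(a = rep(-20, 3), b = rep(20, 3))
  beam <- make_toy_beam(list(ap), 1, gantry = 359.95)
  plan <- toy_plan(beam)
  log <- simulate_delivery(plan, error_model(gantry_offset_deg = 0.1))[[1]]
  # logged gantry is 0.05 after normalization; deviation must be 0.1, not 359.9
  expect_true(all(abs(log$samples$gantry - 0.05) < 1e-9))
  rep <- compare_beam(beam, log)
  dev <- rep$checks$max_observed_deviation[rep$checks$name == "gantry"]
  expect_equal(dev, 0.1, tolerance = 1e-9)
})

test_that("max_mlc_error equals a direct recount of |actual - expected|", {
  s <- sim_one(error_model(leaf_noise_sigma_mm = 0.15), seed = 77)
  got <- max_mlc_error(s$log)
  ss <- s$log$samples
  on <- ss$beam_on
  recount <- 0
  for (k in which(on))
    recount <- max(recount,
                   abs(ss$act_a[k, ] - ss$exp_a[k, ]),
                   abs(ss$act_b[k, ] - ss$exp_b[k, ]))
  expect_identical(got, recount)
  expect_gt(got, 0.15)  # max of ~thousands of N(0, 0.15) draws

  # single leaf, single known offset
  s2 <- sim_one(error_model(leaf_systematic_mm =
                              data.frame(bank = "B", leaf = 1, offset_mm = 0.4)))
  expect_equal(max_mlc_error(s2$log), 0.4, tolerance = 1e-9)
})

test_that("enlarging tolerances never converts PASS into WARNING", {
  s <- sim_one(error_model(gantry_offset_deg = 0.15,
                           jaw_offset_mm = c(x1 = 1.2),
                           leaf_noise_sigma_mm = 0.3), seed = 31)
  tight <- compare_beam(s$plan$beams[[1]], s$log, tolerances())$checks
  loose <- compare_beam(s$plan$beams[[1]], s$log,
                        tolerances(gantry_deg = 1, collimator_deg = 1,
                                   jaw_mm = 5, mlc_mm = 5,
                                   mu_percent = 5))$checks
  for (nm in tight$name) {
    if (tight$status[tight$name == nm] == "PASS")
      expect_identical(loose$status[loose$name == nm], "PASS")
  }
  expect_true(any(tight$status == "WARNING"))
  expect_true(all(loose$status == "PASS"))
})

test_that("compare_beam rejects mismatched leaf counts and empty beams", {
  s <- sim_one()
  beam_other <- open_field_beam()  # same 3 pairs
  beam_other$leaf_boundaries <- c(-10, 0, 10)  # 2 pairs
  beam_other$control_points <- lapply(beam_other$control_points, function(cp) {
    cp$bank_a <- cp$bank_a[1:2]; cp$bank_b <- cp$bank_b[1:2]; cp
  })
  expect_coded_error(compare_beam(beam_other, s$log), "LEAF_COUNT_MISMATCH")

  off <- s$log
  off$samples$beam_on[] <- FALSE
  expect_coded_error(compare_beam(s$plan$beams[[1]], off), "EMPTY_BEAM")
  expect_coded_error(max_mlc_error(off), "EMPTY_BEAM")
})

test_that("reports render with PASS/WARNING marked distinctly in all formats", {
  s_ok <- sim_one()
  s_bad <- sim_one(error_model(jaw_offset_mm = c(x1 = 1.5)))
  rep_ok <- compare_beam(s_ok$plan$beams[[1]], s_ok$log, plan = s_ok$plan)
  rep_bad <- compare_beam(s_bad$plan$beams[[1]], s_bad$log, plan = s_bad$plan)

  txt_ok <- render_report(list(rep_ok), "text")
  expect_false(any(grepl("WARNING", txt_ok)))
  txt_bad <- render_report(list(rep_bad), "text")
  expect_length(grep("WARNING: outside tolerance", txt_bad), 1)

  html <- render_report(list(rep_bad), "html")
  expect_true(any(grepl("<html>", html)))

  js <- jsonlite::fromJSON(render_report(list(rep_ok, rep_bad), "json"),
                           simplifyVector = FALSE)
  expect_equal(js$report_version, 1)
  expect_length(js$beams, 2)
  expect_identical(js$beams[[1]]$overall_status, "PASS")
  expect_identical(js$beams[[2]]$overall_status, "WARNING")
  expect_setequal(
    names(js$beams[[1]]),
    c("beam_id", "overall_status", "integrity", "checks", "max_mlc_error_mm",
      "max_transfer_error_mm", "segment_count_planned",
      "segment_count_observed", "delivered_mu", "fluence_pass_rate_2pct",
      "fluence_pass_rate_3pct", "fluence_panels"))
})
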