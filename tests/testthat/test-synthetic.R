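test_that("the degeneration schedule anchors baseline and collapse exactly", {
  p <- degeneration_params()
  wk3 <- degeneration_trajectory(3, p, "RCS")
  expect_equal(wk3$gcc_um, 85)
  expect_equal(wk3$inl_onl_um, 200)
  expect_equal(wk3$pr_um, 60)
  expect_equal(wk3$dcp_dropout, 0)
  expect_equal(wk3$rho, 1)

  wk6 <- degeneration_trajectory(6, p, "RCS")
  expect_equal(wk6$inl_onl_um / wk3$inl_onl_um, 0.307)

  ctl <- degeneration_trajectory(12, p, "control")
  expect_equal(ctl$dcp_dropout, 0)
  expect_equal(ctl$rho, 1)
  expect_equal(ctl$n_lesions, 0L)

  expect_error(degeneration_trajectory(21, p, "RCS"), "outside the schedule")
})

test_that("per-animal multipliers are lognormal and week-constant", {
  p <- degeneration_params()
  a3 <- degeneration_trajectory(3, p, "RCS", animal_seed = 42)
  a6 <- degeneration_trajectory(6, p, "RCS", animal_seed = 42)
  b3 <- degeneration_trajectory(3, p, "RCS", animal_seed = 43)
  expect_false(isTRUE(all.equal(a3$gcc_um, b3$gcc_um)))
  # percent change is unaffected by a week-constant multiplier
  expect_equal(a6$inl_onl_um / a3$inl_onl_um, 0.307)
})

test_that("noise-free B-scans have exact band reflectivities", {
  p <- degeneration_params()
  spec <- degeneration_trajectory(3, p, "RCS")
  rb <- render_bscan(spec, speckle_shape = 0, curvature_sag_px = 0, seed = 1)
  px <- rb$image$pixels
  b <- rb$boundaries[1, ]
  # sample well inside each band to avoid partial-volume rows
  q <- 1 / 65535
  expect_lt(abs(mean(px[(ceiling(b[1]) + 3):(floor(b[2]) - 3), 1]) - 0.55), q)
  expect_lt(abs(mean(px[(ceiling(b[2]) + 3):(floor(b[3]) - 3), 1]) - 0.25), q)
  expect_lt(abs(mean(px[(ceiling(b[3]) + 3):(floor(b[4]) - 3), 1]) - 0.45), q)
  expect_lt(abs(px[20, 1] - 0.04), q)
})

test_that("B-scan rendering is deterministic and speckle preserves band means", {
  p <- degeneration_params()
  spec <- degeneration_trajectory(6, p, "RCS")
  r1 <- render_bscan(spec, speckle_shape = 4, seed = 7)
  r2 <- render_bscan(spec, speckle_shape = 4, seed = 7)
  expect_identical(r1$image$pixels, r2$image$pixels)
  r3 <- render_bscan(spec, speckle_shape = 4, seed = 8)
  expect_false(identical(r1$image$pixels, r3$image$pixels))

  wide <- render_bscan(spec, width_px = 500, speckle_shape = 4,
                       curvature_sag_px = 0, seed = 9)
  px <- wide$image$pixels
  b <- wide$boundaries[1, ]
  # INL-ONL band mean within 2% of its reflectivity on a 500-column render
  band <- px[(ceiling(b[2]) + 2):(floor(b[3]) - 2), ]
  expect_lt(abs(mean(band) - 0.25) / 0.25, 0.02)
})

test_that("deleting capillaries can only lower the vessel-mask signal", {
  p <- degeneration_params()
  geom <- generate_eye_geometry(p, "OD", seed = 3)
  s0 <- degeneration_trajectory(3, p, "RCS")
  s5 <- s0; s5$dcp_dropout <- 0.5
  a0 <- render_angiograms(s0, geom, p, seed = 10)
  a5 <- render_angiograms(s5, geom, p, seed = 10)
  expect_lt(mean(a5$dcp$pixels[geom$rois$vessel_mask]),
            mean(a0$dcp$pixels[geom$rois$vessel_mask]))
  expect_error(render_angiograms({s9 <- s0; s9$dcp_dropout <- 1; s9}, geom, p, 1),
               "below 1")
})

test_that("a degenerated RPE yields a sharper choroidal angiogram", {
  p <- degeneration_params()
  geom <- generate_eye_geometry(p, "OD", seed = 4)
  hi <- degeneration_trajectory(3, p, "RCS")   # rho = 1
  lo <- hi; lo$rho <- 0.2
  a_hi <- render_angiograms(hi, geom, p, seed = 11)
  a_lo <- render_angiograms(lo, geom, p, seed = 11)
  expect_gt(choroid_sharpness(a_lo$choroid)$value,
            choroid_sharpness(a_hi$choroid)$value)
})

test_that("superficial plexus renders are week-invariant by construction", {
  p <- degeneration_params()
  geom <- generate_eye_geometry(p, "OS", seed = 5)
  wk3 <- render_angiograms(degeneration_trajectory(3, p, "RCS"), geom, p, seed = 12)
  wk18 <- render_angiograms(degeneration_trajectory(18, p, "RCS"), geom, p, seed = 12)
  expect_identical(wk3$svp$pixels, wk18$svp$pixels)
  expect_false(identical(wk3$dcp$pixels, wk18$dcp$pixels))
})

test_that("expected DCP vessel index decreases monotonically with dropout", {
  p <- degeneration_params()
  geom <- generate_eye_geometry(p, "OD", seed = 6)
  base <- degeneration_trajectory(3, p, "RCS")
  levels <- c(0, 0.2, 0.4, 0.6)
  mean_vi <- vapply(levels, function(q) {
    sp <- base; sp$dcp_dropout <- q
    mean(vapply(1:15, function(s) {
      vessel_index(render_angiograms(sp, geom, p, seed = s)$dcp, geom$rois)$value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_vi) < 0))
})

test_that("expected sharpness increases monotonically as RPE integrity falls", {
  p <- degeneration_params()
  geom <- generate_eye_geometry(p, "OD", seed = 7)
  base <- degeneration_trajectory(3, p, "RCS")
  levels <- c(1, 0.7, 0.4, 0.2)
  mean_sh <- vapply(levels, function(rho) {
    sp <- base; sp$rho <- rho
    mean(vapply(1:15, function(s) {
      choroid_sharpness(render_angiograms(sp, geom, p, seed = s)$choroid)$value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sh) > 0))
})

test_that("simulated cohorts are complete, consistent, and reproducible", {
  p <- degeneration_params(n_rcs = 2, n_control = 3,
                           control_ages = c(3, 9, 15),
                           bscan = list(width_px = 160, height_px = 288,
                                        pitch_z_um = 1.95, n_pages = 4,
                                        curvature_sag_px = 6))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- simulate_cohort(p, d1)
  expect_equal(nrow(c1$cohort), 2 * 2 * 6 + 3 * 2)
  expect_true(all(file.exists(c1$cohort$svp_path)))
  expect_true(all(file.exists(c1$cohort$bscan_stack_path)))
  expect_true(all(file.exists(c1$cohort$roi_path)))
  # ground-truth thickness partition: TRT equals the sum of the layers
  gt <- c1$ground_truth
  expect_equal(gt$trt_um, gt$gcc_um + gt$inl_onl_um + gt$pr_um)

  c2 <- simulate_cohort(p, d2)
  expect_equal(c1$ground_truth[setdiff(names(gt), c())],
               c2$ground_truth, ignore_attr = TRUE)
  a <- tiff::readTIFF(c1$cohort$dcp_path[1], as.is = TRUE)
  b <- tiff::readTIFF(c2$cohort$dcp_path[1], as.is = TRUE)
  expect_identical(a, b)

  expect_error(simulate_cohort(p, d1), "not empty")
})

test_that("default cohort sizes follow the study design", {
  p <- degeneration_params()
  expect_equal(p$n_rcs * 2 * length(p$weeks), 72)
  expect_equal(p$n_control * 2, 28)
  expect_equal(length(p$control_ages), p$n_control)
})
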