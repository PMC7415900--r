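test_that("scan field scales linearly with axial length", {
  g <- scan_geometry(c(15, 9), 6.3, 24)
  f <- scan_field_in_eye(g)
  expect_equal(unname(f), c(15, 9) * 6.3 / 24)

  same <- scan_geometry(c(15, 9), 24, 24)
  expect_equal(unname(scan_field_in_eye(same)), c(15, 9))

  half <- scan_geometry(c(10, 10), 12, 24)
  expect_equal(unname(scan_field_in_eye(half)), c(5, 5))

  expect_error(scan_geometry(c(15, 9), -1, 24), "positive")

  # exact linearity in subject axial length
  ax <- seq(2, 30, length.out = 7)
  w <- vapply(ax, function(a) scan_field_in_eye(scan_geometry(c(15, 9), a, 24))[1],
              numeric(1))
  expect_equal(w, 15 * ax / 24)
})

test_that("ONH is recovered near a corner and absent on uniform images", {
  p <- degeneration_params()
  for (s in c(2, 9)) {
    eye <- if (s %% 2) "OD" else "OS"
    geom <- generate_eye_geometry(p, eye, seed = s)
    a <- render_angiograms(degeneration_trajectory(3, p, "RCS"), geom, p,
                           seed = s + 100)
    est <- locate_onh(a$structural)
    expect_lt(sqrt(sum((est - geom$onh)^2)), 5)
  }
  uni <- intensity_image(matrix(0.5, 160, 160), kind = "enface_structural")
  expect_error(locate_onh(uni), "ONH not found")
})

test_that("measurement sites sit at the requested distances from the ONH", {
  s <- select_measurement_sites(c(250, 400), c(7.8, 3.0), n_bscans = 800,
                                width_px = 500, distances_mm = 1)
  expect_equal(unique(s$bscan_index), 733L)
  expect_equal(sort(unique(s$column)), c(250 - 64, 250 + 64))

  s0 <- select_measurement_sites(c(250, 400), c(7.8, 3.0), 800, 500,
                                 distances_mm = 0)
  expect_equal(unique(s0$bscan_index), 400L)

  # 0.5 mm from the far edge: the 1 mm site flips to the opposite side
  expect_message(
    sflip <- select_measurement_sites(c(250, 633), c(7.8, 3.0), 800, 500,
                                      distances_mm = 1),
    "opposite side"
  )
  expect_equal(unique(sflip$bscan_index), 300L)

  expect_error(select_measurement_sites(c(250, 400), c(7.8, 3.0), 800, 500,
                                        distances_mm = 5),
               "outside the scan field")
})

test_that("boundaries are recovered within one pixel on noise-free B-scans", {
  p <- degeneration_params()
  for (wk in c(3, 9, 18)) {
    spec <- degeneration_trajectory(wk, p, "RCS")
    rb <- render_bscan(spec, speckle_shape = 0, seed = 1)
    for (col in c(40, 80, 120)) {
      prof <- detect_boundaries(rb$image, col)
      expect_true(attr(prof, "valid"))
      expect_lt(max(abs(prof$row - rb$boundaries[col, ])), 1)
      expect_true(all(diff(prof$row) > 0))
    }
  }
})

test_that("degenerate two-band scans flag interior boundaries undetected", {
  px <- matrix(0.04, 200, 40)
  px[60:140, ] <- 0.5   # one merged tissue band
  px[141:147, ] <- 0.85 # bright outer band
  px[148:200, ] <- 0.1
  b <- intensity_image(px, pitch_z_um = 1.95, kind = "bscan")
  prof <- detect_boundaries(b, 20)
  det <- setNames(prof$detected, prof$boundary)
  expect_true(det[["ilm"]])
  expect_true(det[["rpe"]])
  expect_false(det[["gcc_inl"]])
  expect_false(det[["inl_pr"]])
  expect_false(attr(prof, "valid"))
})

test_that("detection is invariant to intensity scaling and reflection", {
  p <- degeneration_params()
  spec <- degeneration_trajectory(6, p, "RCS")
  rb <- render_bscan(spec, speckle_shape = 4, seed = 3)
  prof <- detect_boundaries(rb$image, 80)

  scaled <- rb$image
  scaled$pixels <- scaled$pixels * 0.5
  expect_equal(detect_boundaries(scaled, 80)$row, prof$row)

  flipped <- rb$image
  flipped$pixels <- flipped$pixels[, rev(seq_len(ncol(flipped$pixels)))]
  expect_equal(detect_boundaries(flipped, 160 - 80 + 1)$row, prof$row,
               tolerance = 1e-8)
})

test_that("thickness records average valid sites in micrometers", {
  mk <- function(rows) {
    out <- tibble::tibble(boundary = c("ilm", "gcc_inl", "inl_pr", "rpe"),
                          row = rows, detected = TRUE)
    attr(out, "valid") <- TRUE
    out
  }
  one <- layer_thicknesses(list(mk(c(40, 70, 110, 140))), 1.95)
  expect_equal(one$trt_um, 100 * 1.95)
  expect_equal(one$gcc_um, 30 * 1.95)
  expect_equal(one$n_sites, 1)

  four <- layer_thicknesses(rep(list(mk(c(40, 70, 110, 140))), 4), 1.95)
  expect_equal(four[, 1:4], one[, 1:4])
  expect_equal(four$n_sites, 4)

  p <- degeneration_params()
  spec <- degeneration_trajectory(3, p, "RCS")
  rb <- render_bscan(spec, speckle_shape = 0, seed = 2)
  profs <- lapply(c(60, 100), function(cc) detect_boundaries(rb$image, cc))
  rec <- layer_thicknesses(profs, 1.95)
  truth <- mean(rb$boundaries[c(60, 100), 4] - rb$boundaries[c(60, 100), 1]) * 1.95
  expect_lt(abs(rec$trt_um - truth), 2 * 1.95)

  invalid <- mk(c(40, 70, 110, 140))
  attr(invalid, "valid") <- FALSE
  expect_error(layer_thicknesses(list(invalid), 1.95), "No valid")
})

test_that("percent change reports thinning relative to the reference", {
  expect_equal(percent_change(200, 100), 50)
  expect_equal(percent_change(123, 123), 0)
  expect_equal(percent_change(200, 61.4), 69.3)
  expect_error(percent_change(0, 10), "positive")

  # the default schedule reproduces the rapid nuclear-layer collapse
  p <- degeneration_params()
  t3 <- degeneration_trajectory(3, p, "RCS")$inl_onl_um
  t6 <- degeneration_trajectory(6, p, "RCS")$inl_onl_um
  expect_equal(percent_change(t3, t6), 69.3)
})
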