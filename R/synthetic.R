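#' Parameters of the synthetic degeneration cohort
#'
#' Defines the study conditions the generator emulates: six follow-up visits
#' every three weeks from week 3 to 18; fractional layer-thinning schedules
#' anchored to the degeneration phenotype (rapid inner-nuclear collapse of
#' 69.3% of baseline thickness between weeks 3 and 6, slow ganglion-cell-
#' complex loss totalling 12.1% by week 18, photoreceptor/debris loss of 6.4%
#' by week 6 accelerating to 45.2% of baseline by week 12 and then
#' stabilizing); deep-plexus capillary dropout rising steeply between weeks 3
#' and 6 and more gradually afterwards while the superficial plexus stays
#' constant; an RPE-integrity parameter `rho` decaying from 1 toward 0.2 by
#' week 9 that blurs and flattens the choroidal angiogram while intact; and
#' choriocapillaris dropout lesions appearing from week 15. Baseline absolute
#' thicknesses are plausible configuration values, not measured ones; only
#' relative (percent) changes are meaningful downstream.
#'
#' @param weeks Follow-up weeks (default `seq(3, 18, 3)`).
#' @param baseline_um Named baseline thicknesses in micrometers
#'   (`gcc`, `inl_onl`, `pr`).
#' @param rcs_fraction Named list of per-week fraction-of-baseline schedules
#'   for the RCS group.
#' @param control_fraction Same for age-matched controls (mild nuclear and
#'   photoreceptor thinning with age, no vascular change).
#' @param dcp_dropout,svp_dropout Per-week capillary dropout fractions.
#' @param rpe_integrity Per-week RPE integrity `rho` in (0, 1].
#' @param choriocap_lesions Per-week count of choriocapillaris dropout discs.
#' @param noise List: `speckle_shape` (gamma shape of B-scan speckle, 0
#'   disables), `angio_speckle_shape` (enface speckle), `vignetting`
#'   (peripheral falloff strength in \[0, 1\)).
#' @param biovar_sigma Lognormal sigma of per-animal thickness multipliers.
#' @param field_px,field_mm Enface grid size and physical extent.
#' @param bscan List: `width_px`, `height_px`, `pitch_z_um`, `n_pages`
#'   (B-scans per stack), `curvature_sag_px`.
#' @param n_rcs,n_control Animals per group.
#' @param control_ages Visit age (weeks) per control animal.
#' @param seed Base seed; all artifacts are pure functions of (params, seed).
#' @return A list of class `octa_degen_params`.
#' @export
degeneration_params <- function(
    weeks = seq(3, 18, by = 3),
    baseline_um = c(gcc = 85, inl_onl = 200, pr = 60),
    rcs_fraction = list(
      gcc = c(1, 0.976, 0.952, 0.928, 0.903, 0.879),
      inl_onl = c(1, 0.307, 0.295, 0.285, 0.275, 0.255),
      pr = c(1, 0.936, 0.742, 0.548, 0.545, 0.542)
    ),
    control_fraction = list(
      gcc = rep(1, 6),
      inl_onl = seq(1, 0.92, length.out = 6),
      pr = seq(1, 0.93, length.out = 6)
    ),
    dcp_dropout = c(0, 0.35, 0.42, 0.48, 0.52, 0.55),
    svp_dropout = rep(0, 6),
    rpe_integrity = c(1, 0.6, 0.2, 0.2, 0.2, 0.2),
    choriocap_lesions = c(0, 0, 0, 0, 2, 4),
    noise = list(speckle_shape = 4, angio_speckle_shape = 25, vignetting = 0.3),
    biovar_sigma = 0.05,
    field_px = c(160, 160), field_mm = c(3.9, 2.4),
    bscan = list(width_px = 160, height_px = 288, pitch_z_um = 1.95,
                 n_pages = 16, curvature_sag_px = 6),
    n_rcs = 6, n_control = 14,
    control_ages = rep(seq(3, 18, by = 3), length.out = 14),
    seed = 20200624) {
  p <- list(weeks = weeks, baseline_um = baseline_um, rcs_fraction = rcs_fraction,
            control_fraction = control_fraction, dcp_dropout = dcp_dropout,
            svp_dropout = svp_dropout, rpe_integrity = rpe_integrity,
            choriocap_lesions = choriocap_lesions, noise = noise,
            biovar_sigma = biovar_sigma, field_px = field_px, field_mm = field_mm,
            bscan = bscan, n_rcs = n_rcs, n_control = n_control,
            control_ages = control_ages, seed = seed)
  kk <- length(weeks)
  stopifnot(
    all(lengths(rcs_fraction) == kk), all(lengths(control_fraction) == kk),
    length(dcp_dropout) == kk, length(rpe_integrity) == kk
  )
  if (any(unlist(rcs_fraction) <= 0)) abort("Thickness schedule must stay strictly positive.")
  if (any(diff(rpe_integrity) > 1e-12)) abort("`rpe_integrity` must be non-increasing.")
  if (any(diff(dcp_dropout) < -1e-12)) abort("`dcp_dropout` must be non-decreasing.")
  if (any(dcp_dropout >= 1)) abort("Dropout fractions must be below 1.")
  structure(p, class = "octa_degen_params")
}

interp_schedule <- function(week, weeks, values) {
  stats::approx(weeks, values, xout = week, rule = 1)$y
}

derive_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 1000003 + as.numeric(x)) %% 2147483629
  as.integer(s)
}

#' Per-week degeneration state of one animal
#'
#' Piecewise-linear interpolation of the group schedule at `week`, with a
#' per-animal lognormal thickness multiplier (constant across weeks, one per
#' layer) applied when `animal_seed` is given. Controls have zero capillary
#' dropout, full RPE integrity and no lesions at every age.
#'
#' @param week Visit week (must lie within the schedule).
#' @param params [degeneration_params()].
#' @param group `"RCS"` or `"control"`.
#' @param animal_seed Optional integer seed for the animal's biological
#'   variability multipliers.
#' @return List: `gcc_um`, `inl_onl_um`, `pr_um`, `dcp_dropout`,
#'   `svp_dropout`, `rho`, `n_lesions`.
#' @export
degeneration_trajectory <- function(week, params, group = c("RCS", "control"),
                                    animal_seed = NULL) {
  group <- match.arg(group)
  if (week < min(params$weeks) || week > max(params$weeks)) {
    abort(sprintf("Week %s lies outside the schedule [%s, %s].",
                  week, min(params$weeks), max(params$weeks)))
  }
  frac <- if (group == "RCS") params$rcs_fraction else params$control_fraction
  mult <- c(gcc = 1, inl_onl = 1, pr = 1)
  if (!is.null(animal_seed) && params$biovar_sigma > 0) {
    mult <- withr::with_seed(animal_seed,
      exp(rnorm(3, 0, params$biovar_sigma)))
    names(mult) <- c("gcc", "inl_onl", "pr")
  }
  th <- vapply(c("gcc", "inl_onl", "pr"), function(l) {
    params$baseline_um[[l]] * mult[[l]] *
      interp_schedule(week, params$weeks, frac[[l]])
  }, numeric(1))
  if (group == "RCS") {
    list(gcc_um = th[["gcc"]], inl_onl_um = th[["inl_onl"]], pr_um = th[["pr"]],
         dcp_dropout = interp_schedule(week, params$weeks, params$dcp_dropout),
         svp_dropout = interp_schedule(week, params$weeks, params$svp_dropout),
         rho = interp_schedule(week, params$weeks, params$rpe_integrity),
         n_lesions = round(interp_schedule(week, params$weeks, params$choriocap_lesions)))
  } else {
    list(gcc_um = th[["gcc"]], inl_onl_um = th[["inl_onl"]], pr_um = th[["pr"]],
         dcp_dropout = 0, svp_dropout = 0, rho = 1, n_lesions = 0L)
  }
}

#' Render a synthetic layered B-scan
#'
#' Horizontal reflectivity bands (vitreous 0.04, GCC 0.55, INL-ONL 0.25,
#' PR/debris 0.45, RPE `0.55 + 0.35 * rho`, sub-RPE 0.12) under a gentle
#' quadratic retinal curvature, with partial-volume mixing at fractional band
#' boundaries, optional multiplicative gamma speckle, and 16-bit
#' quantization. Ground-truth boundary rows (continuous depth from the top
#' edge) are recorded at every column for ILM, GCC/(INL-ONL),
#' (INL-ONL)/(PR-debris) and the top of the RPE band.
#'
#' @param layer_spec Output of [degeneration_trajectory()].
#' @param width_px,height_px Image size.
#' @param pitch_z_um Axial pitch.
#' @param speckle_shape Gamma shape of multiplicative speckle; 0 disables.
#' @param curvature_sag_px Quadratic sag of the ILM across the field.
#' @param seed Integer seed (rendering is deterministic given the seed).
#' @return List: `image` (an [intensity_image()] of kind `"bscan"`),
#'   `boundaries` (width x 4 matrix of true rows: ilm, gcc_inl, inl_pr, rpe).
#' @export
render_bscan <- function(layer_spec, width_px = 160, height_px = 288,
                         pitch_z_um = 1.95, speckle_shape = 4,
                         curvature_sag_px = 6, seed = 1L) {
  W <- width_px; H <- height_px
  refl <- c(0.04, 0.55, 0.25, 0.45, 0.55 + 0.35 * layer_spec$rho, 0.12)
  th_px <- c(layer_spec$gcc_um, layer_spec$inl_onl_um, layer_spec$pr_um) / pitch_z_um
  rpe_px <- 12 / pitch_z_um
  x <- (seq_len(W) - 0.5) / W
  ilm0 <- 60
  ilm <- ilm0 + curvature_sag_px * (2 * x - 1)^2
  b <- rbind(ilm, ilm + th_px[1], ilm + sum(th_px[1:2]), ilm + sum(th_px),
             ilm + sum(th_px) + rpe_px)
  if (max(b) > H - 4) abort("Layer bands exceed the image height.")
  img <- matrix(0, H, W)
  rows <- seq_len(H)
  for (j in seq_len(W)) {
    edges <- c(0, b[, j], H)
    col <- numeric(H)
    for (band in seq_len(6)) {
      lo <- edges[band]; hi <- edges[band + 1]
      cover <- pmax(0, pmin(hi, rows) - pmax(lo, rows - 1))
      col <- col + refl[band] * cover
    }
    img[, j] <- col
  }
  if (speckle_shape > 0) {
    img <- withr::with_seed(seed, {
      img * rgamma(H * W, shape = speckle_shape, rate = speckle_shape)
    })
  }
  img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
  list(
    image = intensity_image(img, pitch_z_um = pitch_z_um, kind = "bscan"),
    boundaries = t(b[1:4, , drop = FALSE])
  )
}

# ---- enface geometry -------------------------------------------------------

point_segment_dist <- function(px, py, seg) {
  dx <- seg[, 3] - seg[, 1]; dy <- seg[, 4] - seg[, 2]
  L2 <- pmax(dx^2 + dy^2, 1e-12)
  t <- pmin(pmax(((px - seg[, 1]) * dx + (py - seg[, 2]) * dy) / L2, 0), 1)
  sqrt((px - (seg[, 1] + t * dx))^2 + (py - (seg[, 2] + t * dy))^2)
}

#' Fixed vascular geometry of one synthetic eye
#'
#' Generated once per (animal, eye) and reused at every visit so that the
#' only week-to-week vascular change is the programmed dropout: major radial
#' vessels fanning out from a corner ONH, a sparse superficial capillary
#' mesh, a dense deep capillary lattice with a seeded deletion order, a
#' choroidal texture, intercapillary exclusion zones (kept free of
#' capillaries, used as background ROIs), and the auto-placed ROI polygons.
#'
#' @param params [degeneration_params()].
#' @param eye `"OD"` or `"OS"` (controls which corner hosts the ONH).
#' @param seed Integer seed.
#' @return List of geometry elements consumed by [render_angiograms()].
#' @export
generate_eye_geometry <- function(params, eye = "OD", seed = 1L) {
  H <- params$field_px[1]; W <- params$field_px[2]
  withr::with_seed(seed, {
    onh <- c(x = if (eye == "OD") 0.14 * W else 0.86 * W, y = 0.85 * H)
    n_major <- sample(6:8, 1)
    base_ang <- atan2(0.5 * H - onh["y"], 0.5 * W - onh["x"])
    angs <- base_ang + seq(-0.55 * pi, 0.55 * pi, length.out = n_major) +
      rnorm(n_major, 0, 0.05)
    major <- do.call(rbind, lapply(angs, function(a) {
      len <- 1.3 * sqrt(H^2 + W^2)
      tt <- seq(0, 1, length.out = 24)
      bend <- rnorm(1, 0, 0.12)
      ax <- a + bend * tt
      xs <- onh["x"] + cumsum(c(0, diff(tt * len)) * cos(ax))
      ys <- onh["y"] + cumsum(c(0, diff(tt * len)) * sin(ax))
      cbind(xs[-length(xs)], ys[-length(ys)], xs[-1], ys[-1])
    }))

    # intercapillary exclusion zones: away from majors and the ONH
    zones <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(zones) < 4 && tries < 4000) {
      tries <- tries + 1
      cand <- c(runif(1, 0.15 * W, 0.85 * W), runif(1, 0.15 * H, 0.85 * H))
      dmaj <- min(point_segment_dist(cand[1], cand[2], major))
      donh <- sqrt(sum((cand - onh)^2))
      dz <- if (nrow(zones)) min(sqrt((zones[, 1] - cand[1])^2 + (zones[, 2] - cand[2])^2)) else Inf
      if (dmaj > 18 && donh > 35 && dz > 28) zones <- rbind(zones, cand)
    }
    if (nrow(zones) < 4) abort("Could not place intercapillary background zones.")

    rand_segments <- function(n, len_lo, len_hi, avoid_zones = TRUE) {
      out <- matrix(NA_real_, 0, 4)
      while (nrow(out) < n) {
        m <- n - nrow(out)
        x0 <- runif(m, 1, W - 1); y0 <- runif(m, 1, H - 1)
        a <- runif(m, 0, 2 * pi); l <- runif(m, len_lo, len_hi)
        x1 <- pmin(pmax(x0 + l * cos(a), 1), W - 1)
        y1 <- pmin(pmax(y0 + l * sin(a), 1), H - 1)
        keep <- rep(TRUE, m)
        if (avoid_zones) {
          mx <- (x0 + x1) / 2; my <- (y0 + y1) / 2
          for (z in seq_len(nrow(zones))) {
            dz <- pmin(sqrt((x0 - zones[z, 1])^2 + (y0 - zones[z, 2])^2),
                       sqrt((x1 - zones[z, 1])^2 + (y1 - zones[z, 2])^2),
                       sqrt((mx - zones[z, 1])^2 + (my - zones[z, 2])^2))
            keep <- keep & dz > 11
          }
        }
        out <- rbind(out, cbind(x0, y0, x1, y1)[keep, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    }

    svp_cap <- rand_segments(180, 6, 14)
    dcp <- rand_segments(650, 7, 15)
    dcp_order <- sample(nrow(dcp))
    cho <- rand_segments(700, 8, 18, avoid_zones = FALSE)

    # vessel ROI: a square over the densest lattice area away from majors/zones
    best <- NULL; best_score <- -Inf
    midx <- (dcp[, 1] + dcp[, 3]) / 2; midy <- (dcp[, 2] + dcp[, 4]) / 2
    # clearance from major vessels / background zones, relaxed stepwise if a
    # crowded geometry leaves no strictly clear spot
    # Chebyshev clearance from zones stays above the two square half-sizes
    # (12 + 5) so the vessel and background masks can never overlap
    for (clr in c(16, 12, 8)) {
      for (cx in seq(0.18 * W, 0.82 * W, length.out = 15)) {
        for (cy in seq(0.18 * H, 0.82 * H, length.out = 15)) {
          dmaj <- min(point_segment_dist(cx, cy, major))
          dzc <- min(pmax(abs(zones[, 1] - cx), abs(zones[, 2] - cy)))
          if (dmaj < clr || dzc < 18) next
          dens <- sum(abs(midx - cx) < 12 & abs(midy - cy) < 12)
          if (dens > best_score) { best_score <- dens; best <- c(cx, cy) }
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) abort("Could not place a vessel ROI.")
    sq <- function(cx, cy, h) rbind(c(cx - h, cy - h), c(cx + h, cy - h),
                                    c(cx + h, cy + h), c(cx - h, cy + h))
    rois <- roi_set(
      vessel = sq(best[1], best[2], 12),
      background = lapply(1:3, function(z) sq(zones[z, 1], zones[z, 2], 5)),
      image_shape = c(H, W)
    )

    list(onh = onh, major = major, svp_cap = svp_cap, dcp = dcp,
         dcp_order = dcp_order, cho = cho, zones = zones, rois = rois,
         H = H, W = W)
  })
}

vignette_field <- function(H, W, strength) {
  x <- (seq_len(W) - 0.5) / W - 0.5
  y <- (seq_len(H) - 0.5) / H - 0.5
  r2 <- outer(y^2, x^2, `+`) / 0.5
  1 - strength * r2
}

stamp_discs <- function(img, centers, radius, factor) {
  H <- nrow(img); W <- ncol(img)
  for (i in seq_len(nrow(centers))) {
    blob <- draw_segments_cpp(H, W, centers[i, 1], centers[i, 2],
                              centers[i, 1], centers[i, 2], radius, 1)
    img <- img * (1 - (1 - factor) * blob)
  }
  img
}

#' Render the three enface angiograms and the structural image for one visit
#'
#' Uses the fixed eye geometry plus the week's degeneration state. The SVP
#' shows the major vessels and the (unchanging) superficial capillary mesh;
#' the DCP lattice has the scheduled fraction of its segments deleted in the
#' eye's fixed deletion order (so greater dropout strictly removes more
#' signal); the choroidal texture is blurred with `sigma = 4 * rho` and its
#' contrast scaled by `1 - 0.7 * rho`, so a degenerating RPE (small `rho`)
#' yields a sharper, higher-contrast choroid; scheduled choriocapillaris
#' lesions are stamped as dark discs. All enface images share a smooth
#' multiplicative vignetting field and mild multiplicative speckle, and are
#' quantized to 16 bits.
#'
#' @param layer_spec Output of [degeneration_trajectory()].
#' @param geom Output of [generate_eye_geometry()].
#' @param params [degeneration_params()].
#' @param seed Integer seed for the visit's noise.
#' @return List: `svp`, `dcp`, `choroid`, `structural` ([intensity_image()]s),
#'   `rois`, `onh`.
#' @export
render_angiograms <- function(layer_spec, geom, params, seed = 1L) {
  H <- geom$H; W <- geom$W
  if (H < 128 || W < 128) abort("Enface field must be at least 128 x 128 px.")
  if (layer_spec$dcp_dropout >= 1 || layer_spec$svp_dropout >= 1) {
    abort("Dropout fractions must be below 1.")
  }
  pitch <- list(pitch_x_um = params$field_mm[1] * 1000 / W,
                pitch_y_um = params$field_mm[2] * 1000 / H,
                pitch_z_um = params$bscan$pitch_z_um)
  vig <- vignette_field(H, W, params$noise$vignetting)
  shp <- params$noise$angio_speckle_shape

  finish <- function(img, seed_off, kind = "enface_angiogram", plexus = NULL) {
    img <- img * vig
    if (shp > 0) {
      img <- withr::with_seed(derive_seed(seed, seed_off), {
        img * rgamma(H * W, shape = shp, rate = shp)
      })
    }
    img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535
    intensity_image(img, pitch_x_um = pitch$pitch_x_um, pitch_y_um = pitch$pitch_y_um,
                    kind = kind, plexus = plexus)
  }

  draw <- function(segs, width, intensity, base = NULL) {
    if (nrow(segs) == 0L) {
      return(if (is.null(base)) matrix(0, H, W) else base)
    }
    draw_segments_cpp(H, W, segs[, 1], segs[, 2], segs[, 3], segs[, 4],
                      rep(width, nrow(segs)), rep(intensity, nrow(segs)),
                      base)
  }

  keep_frac <- function(segs, ord, dropout) {
    n_del <- floor(dropout * nrow(segs))
    if (n_del == 0L) return(segs)
    segs[-ord[seq_len(n_del)], , drop = FALSE]
  }

  svp_img <- matrix(0.06, H, W)
  svp_img <- draw(keep_frac(geom$svp_cap, seq_len(nrow(geom$svp_cap)),
                            layer_spec$svp_dropout), 0.9, 0.45, svp_img)
  svp_img <- draw(geom$major, 2.2, 0.95, svp_img)

  dcp_img <- matrix(0.06, H, W)
  dcp_img <- draw(keep_frac(geom$dcp, geom$dcp_order, layer_spec$dcp_dropout),
                  0.9, 0.6, dcp_img)

  rho <- layer_spec$rho
  cho_tex <- draw(geom$cho, 1.6, 0.75, matrix(0.12, H, W))
  cho_blur <- gauss_blur_cpp(cho_tex, max(0.3, 4 * rho))
  cho_img <- 0.45 + (cho_blur - mean(cho_blur)) * (1 - 0.7 * rho) /
    max(sd(cho_blur), 1e-6) * 0.16
  cho_img <- pmin(pmax(cho_img, 0), 1)
  if (layer_spec$n_lesions > 0) {
    centers <- withr::with_seed(derive_seed(seed, 77), {
      cbind(runif(layer_spec$n_lesions, 0.2 * W, 0.8 * W),
            runif(layer_spec$n_lesions, 0.2 * H, 0.8 * H))
    })
    cho_img <- stamp_discs(cho_img, centers, 5, 0.35)
  }

  str_base <- withr::with_seed(derive_seed(seed, 99), {
    0.5 + 0.08 * scale_unit(gauss_blur_cpp(matrix(runif(H * W), H, W), 5))
  })
  str_img <- draw(geom$major, 2.2, 0.78, str_base)
  onh_blob <- draw_segments_cpp(H, W, geom$onh["x"], geom$onh["y"],
                                geom$onh["x"], geom$onh["y"], 6.5, 1)
  str_img <- str_img * (1 - 0.92 * onh_blob)

  list(
    svp = finish(svp_img, 1, plexus = "SVP"),
    dcp = finish(dcp_img, 2, plexus = "DCP"),
    choroid = finish(cho_img, 3, plexus = "choroid"),
    structural = finish(str_img, 4, kind = "enface_structural"),
    rois = geom$rois,
    onh = geom$onh
  )
}

scale_unit <- function(m) {
  r <- range(m)
  if (diff(r) <= 0) return(m * 0)
  (m - r[1]) / diff(r) * 2 - 1
}

#' Simulate a full synthetic cohort to disk
#'
#' Writes, for every (animal, eye, week) visit, the three enface angiograms,
#' the structural enface, a multi-page B-scan stack, and a shared per-eye ROI
#' file; plus `cohort.csv` and `ground_truth.json`. The default design is 6
#' RCS animals followed at 6 visits in both eyes (72 image sets) and 14
#' control animals imaged once in both eyes (28 image sets). Everything is a
#' pure function of (params, seed).
#'
#' @param params [degeneration_params()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty existing directory.
#' @param write_bscans Write B-scan stacks (disable for vascular-only runs).
#' @return Invisibly, a list with `cohort` (tibble), `ground_truth` (tibble),
#'   `params`, `dir`.
#' @export
simulate_cohort <- function(params = degeneration_params(), out_dir,
                            force = FALSE, write_bscans = TRUE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(sprintf("Output directory '%s' is not empty (use force = TRUE).", out_dir))
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "rois"), showWarnings = FALSE)

  visits <- dplyr::bind_rows(
    tidyr::expand_grid(animal_id = sprintf("RCS%d", seq_len(params$n_rcs)),
                       eye = c("OD", "OS"), week = params$weeks) |>
      dplyr::mutate(group = "RCS"),
    tidyr::expand_grid(animal_id = sprintf("C%02d", seq_len(params$n_control)),
                       eye = c("OD", "OS")) |>
      dplyr::mutate(group = "control",
                    week = params$control_ages[as.integer(sub("C", "", .data$animal_id))])
  )

  geoms <- list()
  rows <- list(); truth <- list()
  for (r in seq_len(nrow(visits))) {
    v <- visits[r, ]
    akey <- paste(v$animal_id, v$eye)
    a_idx <- match(v$animal_id, unique(visits$animal_id))
    aseed <- derive_seed(params$seed, a_idx, match(v$eye, c("OD", "OS")))
    if (is.null(geoms[[akey]])) {
      geoms[[akey]] <- generate_eye_geometry(params, eye = v$eye, seed = aseed)
      write_roi_set(geoms[[akey]]$rois,
                    file.path(out_dir, "rois", paste0(v$animal_id, "_", v$eye, ".json")))
    }
    geom <- geoms[[akey]]
    spec <- degeneration_trajectory(v$week, params, v$group,
                                    animal_seed = derive_seed(params$seed, a_idx, 555))
    vseed <- derive_seed(aseed, v$week)
    ang <- render_angiograms(spec, geom, params, seed = vseed)

    stem <- file.path(out_dir, "images", sprintf("%s_%s_wk%02d", v$animal_id, v$eye, v$week))
    write_image(ang$svp, paste0(stem, "_svp.tif"))
    write_image(ang$dcp, paste0(stem, "_dcp.tif"))
    write_image(ang$choroid, paste0(stem, "_choroid.tif"))
    write_image(ang$structural, paste0(stem, "_structural.tif"))
    stack_path <- paste0(stem, "_bscans.tif")
    if (write_bscans) {
      pages <- lapply(seq_len(params$bscan$n_pages), function(pg) {
        render_bscan(spec,
                     width_px = params$bscan$width_px, height_px = params$bscan$height_px,
                     pitch_z_um = params$bscan$pitch_z_um,
                     speckle_shape = params$noise$speckle_shape,
                     curvature_sag_px = params$bscan$curvature_sag_px,
                     seed = derive_seed(vseed, pg))$image
      })
      write_bscan_stack(pages, stack_path)
    } else {
      stack_path <- NA_character_
    }

    rows[[r]] <- tibble::tibble(
      animal_id = v$animal_id, eye = v$eye, group = v$group, week = v$week,
      svp_path = paste0(stem, "_svp.tif"), dcp_path = paste0(stem, "_dcp.tif"),
      choroid_path = paste0(stem, "_choroid.tif"),
      structural_path = paste0(stem, "_structural.tif"),
      bscan_stack_path = stack_path,
      roi_path = file.path(out_dir, "rois", paste0(v$animal_id, "_", v$eye, ".json"))
    )
    truth[[r]] <- tibble::tibble(
      animal_id = v$animal_id, eye = v$eye, group = v$group, week = v$week,
      gcc_um = spec$gcc_um, inl_onl_um = spec$inl_onl_um, pr_um = spec$pr_um,
      trt_um = spec$gcc_um + spec$inl_onl_um + spec$pr_um,
      dcp_dropout = spec$dcp_dropout, rho = spec$rho, n_lesions = spec$n_lesions,
      onh_x = unname(geom$onh["x"]), onh_y = unname(geom$onh["y"])
    )
  }
  cohort <- validate_cohort(dplyr::bind_rows(rows))
  ground_truth <- dplyr::bind_rows(truth)
  write_table(cohort, file.path(out_dir, "cohort.csv"))
  jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA, dataframe = "rows")
  invisible(list(cohort = cohort, ground_truth = ground_truth,
                 params = params, dir = out_dir))
}
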