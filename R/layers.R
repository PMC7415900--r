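#' Scan-field geometry scaling between eyes
#'
#' Wide-field scan protocols are specified for a reference (human) eye; in a
#' smaller eye the same scan angle covers a proportionally smaller retinal
#' area. Each nominal field dimension is scaled by the ratio of the subject's
#' axial length to the reference axial length. For the rat eye (axial length
#' 6.3 mm) a nominal 15 x 9 mm field becomes about 3.9 x 2.4 mm.
#'
#' @param nominal_fov_mm `c(width, height)` of the nominal scan field, mm.
#' @param subject_axial_length_mm Axial length of the imaged eye, mm.
#' @param reference_axial_length_mm Axial length the protocol assumes
#'   (default 24 mm).
#' @return An object of class `octa_scan_geometry`.
#' @export
scan_geometry <- function(nominal_fov_mm = c(15, 9),
                          subject_axial_length_mm = 6.3,
                          reference_axial_length_mm = 24) {
  if (any(c(nominal_fov_mm, subject_axial_length_mm, reference_axial_length_mm) <= 0)) {
    abort("All scan geometry lengths must be strictly positive.")
  }
  structure(
    list(nominal_fov_mm = nominal_fov_mm,
         subject_axial_length_mm = subject_axial_length_mm,
         reference_axial_length_mm = reference_axial_length_mm),
    class = "octa_scan_geometry"
  )
}

#' @rdname scan_geometry
#' @param geom An `octa_scan_geometry`.
#' @return For `scan_field_in_eye()`, `c(width_mm, height_mm)` of the actual
#'   field in the subject eye.
#' @export
scan_field_in_eye <- function(geom) {
  stopifnot(inherits(geom, "octa_scan_geometry"))
  ratio <- geom$subject_axial_length_mm / geom$reference_axial_length_mm
  out <- geom$nominal_fov_mm * ratio
  names(out) <- c("width_mm", "height_mm")
  out
}

#' Locate the optic nerve head on a structural enface image
#'
#' After heavy Gaussian smoothing (sigma = 10 px) the ONH appears as the
#' darkest disc-like region where vessels converge. The function thresholds
#' the smoothed image at its 5th intensity percentile, takes the connected
#' component containing the global minimum, and returns its centroid. An
#' error is raised when no sufficiently dark candidate exists (the smoothed
#' minimum must sit at least 0.05 below the smoothed mean).
#'
#' @param structural An [intensity_image()] of kind `"enface_structural"`.
#' @return `c(x_px, y_px)` pixel-center coordinates of the ONH centroid.
#' @export
locate_onh <- function(structural) {
  stopifnot(inherits(structural, "octa_image"))
  if (structural$kind != "enface_structural") {
    abort("ONH localization expects an enface structural image.")
  }
  # replace bright structure (vessels, surface reflections) with the global
  # median so it cannot tilt the smoothed dip, then smooth heavily
  px <- structural$pixels
  bright <- px > quantile(px, 0.9)
  px[bright] <- median(px)
  s <- gauss_blur_cpp(px, 10)
  # remove smooth illumination (vignetting) with a fitted second-order
  # surface so only local structure remains
  H <- nrow(s); W <- ncol(s)
  xs <- as.vector((col(s) - 0.5) / W - 0.5)
  ys <- as.vector((row(s) - 0.5) / H - 0.5)
  X <- cbind(1, xs, ys, xs^2, ys^2, xs * ys)
  res <- matrix(as.vector(s) - X %*% qr.solve(crossprod(X), crossprod(X, as.vector(s))), H, W)
  if (min(res) > -0.04) abort("ONH not found: no dark candidate region.")
  # half-depth contour of the dip containing the global minimum
  thr <- min(quantile(res, 0.05), 0.5 * min(res))
  mask <- res <= thr
  lab <- label_components_cpp(mask)
  amin <- arrayInd(which.min(res), dim(res))
  comp <- lab == lab[amin[1], amin[2]]
  idx <- which(comp, arr.ind = TRUE)
  w <- thr - res[comp]
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  est <- c(sum(w * idx[, 2]) - 0.5, sum(w * idx[, 1]) - 0.5)
  # refine with a local quadratic vertex fit, which stays unbiased when the
  # dip is truncated by the image border
  cx <- col(res) - 0.5; cy <- row(res) - 0.5
  d2 <- (cx - est[1])^2 + (cy - est[2])^2
  sel <- which(d2 <= 12^2)
  if (length(sel) > 12) {
    dx <- cx[sel] - est[1]; dy <- cy[sel] - est[2]
    Q <- cbind(1, dx, dy, dx^2, dy^2, dx * dy)
    b <- tryCatch(qr.solve(crossprod(Q), crossprod(Q, res[sel])), error = function(e) NULL)
    if (!is.null(b)) {
      Hm <- matrix(c(2 * b[4], b[6], b[6], 2 * b[5]), 2, 2)
      if (all(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values > 1e-9)) {
        v <- -solve(Hm, c(b[2], b[3]))
        if (sqrt(sum(v^2)) <= 10) est <- est + v
      }
    }
  }
  c(x_px = est[1], y_px = est[2])
}

#' Select thickness measurement sites relative to the ONH
#'
#' Picks B-scans at the requested slow-axis distances from the ONH (rounded
#' to the nearest scan) and, on each, two columns offset laterally by
#' `lateral_offset_mm` on either side of the ONH column: with the defaults,
#' two B-scans about 1 mm and 2 mm from the ONH and two sites per B-scan,
#' four sites in total. When a requested distance does not fit on the default
#' side of the ONH the opposite side is used (sign flip, reported via a
#' message); if neither side fits, an error is raised.
#'
#' @param onh `c(column_px, bscan_index)` of the ONH in stack coordinates.
#' @param pitch `c(lateral_um_per_px, slow_um_per_bscan)`.
#' @param n_bscans,width_px Extent of the stack.
#' @param distances_mm Slow-axis distances from the ONH (default `c(1, 2)`).
#' @param lateral_offset_mm Lateral half-offset of the two per-B-scan sites.
#' @param margin_px Columns are kept at least this far from the lateral image
#'   edges so the detector's averaging band has full support (default 8).
#' @return Tibble with columns `bscan_index`, `column`, `distance_mm`, `side`.
#' @export
select_measurement_sites <- function(onh, pitch, n_bscans, width_px,
                                     distances_mm = c(1, 2),
                                     lateral_offset_mm = 0.5,
                                     margin_px = 8L) {
  onh_col <- onh[1]; onh_b <- onh[2]  # may be fractional
  rows <- lapply(distances_mm, function(d) {
    off <- d * 1000 / pitch[2]
    idx <- round(onh_b + off)
    side <- 1
    if (idx > n_bscans || idx < 1) {
      idx <- round(onh_b - off)
      side <- -1
      if (idx > n_bscans || idx < 1) {
        abort(sprintf("Distance %.2f mm from the ONH lies outside the scan field.", d))
      }
      inform(sprintf("Distance %.2f mm measured on the opposite side of the ONH.", d))
    }
    lat <- round(lateral_offset_mm * 1000 / pitch[1])
    cols <- c(onh_col - lat, onh_col + lat)
    if (all(cols < 1 | cols > width_px)) {
      abort("Lateral measurement columns lie outside the B-scan.")
    }
    cols <- pmin(pmax(round(cols), 1L + margin_px), width_px - margin_px)
    tibble::tibble(bscan_index = as.integer(round(idx)), column = as.integer(cols),
                   distance_mm = d, side = side)
  })
  dplyr::bind_rows(rows)
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a 256-bin histogram. Used to set the
#' significance threshold on vertical gradient magnitudes during boundary
#' detection.
#'
#' @param x Numeric vector.
#' @return Threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  nb <- 256L
  h <- tabulate(pmin(pmax(floor((x - r[1]) / diff(r) * nb) + 1L, 1L), nb), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nb) - 0.5) / nb * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

local_peaks <- function(g, sign = 1) {
  n <- length(g)
  if (n < 3L) return(integer(0))
  v <- sign * g
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
          is.finite(v[2:(n - 1)])) + 1L
}

parabolic_refine <- function(g, r) {
  if (r <= 1L || r >= length(g)) return(r)
  denom <- g[r - 1L] - 2 * g[r] + g[r + 1L]
  if (!is.finite(denom) || abs(denom) < 1e-15) return(r)
  delta <- 0.5 * (g[r - 1L] - g[r + 1L]) / denom
  r + max(-0.5, min(0.5, delta))
}

#' Detect retinal layer boundaries along an A-scan band
#'
#' Averages the B-scan over a `(2 * window_px + 1)`-column band centered on
#' `column`, lightly smooths the averaged depth profile, and locates layer
#' boundaries as vertical-gradient extrema: the inner limiting membrane (ILM)
#' is the first positive gradient peak exceeding an Otsu threshold on the
#' absolute gradient; the RPE top is the positive gradient peak onto the
#' bright RPE band, anchored immediately above the strongest negative edge
#' below the ILM (the drop from the RPE band into the weakly scattering
#' sub-RPE space, the most contrasted outer edge at every disease stage);
#' the GCC/(INL-ONL) interface is the strongest
#' negative extremum between ILM and RPE, and the (INL-ONL)/(PR-debris)
#' interface the strongest positive peak between that and the RPE. Each detected
#' boundary is refined to sub-pixel precision by a 3-point parabolic fit on
#' the gradient. Boundaries that cannot be found, or that violate the fixed
#' top-to-bottom ordering, are flagged undetected rather than guessed.
#'
#' Reported rows are continuous depth coordinates measured in pixel units
#' from the top image edge (pixel row i has its center at i - 0.5).
#'
#' @param bscan A B-scan [intensity_image()], vitreous at the top.
#' @param column Center column of the averaging band (1-based).
#' @param window_px Half-width of the averaging band (default 7).
#' @return A tibble of class `octa_boundary_profile` with columns `boundary`
#'   (`ilm`, `gcc_inl`, `inl_pr`, `rpe`), `row`, `detected`, and attributes
#'   `column` and `valid` (all four detected and ordered).
#' @export
detect_boundaries <- function(bscan, column, window_px = 7L) {
  stopifnot(inherits(bscan, "octa_image"))
  H <- bscan$height_px; W <- bscan$width_px
  if (column < 1L || column > W) abort("`column` lies outside the B-scan.")
  jlo <- max(1L, column - window_px)
  jhi <- min(W, column + window_px)
  p <- rowMeans(bscan$pixels[, jlo:jhi, drop = FALSE])
  # light vertical smoothing (symmetric, no boundary shift)
  k <- c(1, 4, 6, 4, 1) / 16
  pe <- c(rep(p[1], 2), p, rep(p[H], 2))
  p <- vapply(seq_len(H), function(i) sum(pe[i:(i + 4)] * k), numeric(1))
  g <- c(0, 0.5 * (p[3:H] - p[1:(H - 2)]), 0)

  thr <- otsu_threshold(abs(g[2:(H - 1)]))
  pos <- local_peaks(g, 1)
  neg <- local_peaks(g, -1)

  na_row <- NA_real_
  ilm <- gcc_inl <- inl_pr <- rpe <- na_row

  cand_ilm <- pos[g[pos] >= thr]
  if (length(cand_ilm)) ilm <- parabolic_refine(g, cand_ilm[1])

  rpe_i <- NA_integer_
  if (is.finite(ilm)) {
    # outer anchor: strongest drop below the ILM (RPE band -> sub-RPE space)
    drops <- neg[neg > ceiling(ilm) + 4L]
    if (length(drops)) {
      drop_i <- drops[which.min(g[drops])]
      # step-contrast matched filter for the band top, then snap to the
      # nearest positive gradient peak
      win <- seq(max(ceiling(ilm) + 5L, drop_i - 10L), drop_i - 3L)
      win <- win[win >= 10L & win <= H - 5L]
      if (length(win)) {
        # fixed-length boxcar step filter (8 rows above, 5 below), refined by
        # a parabolic fit on the score
        score <- vapply(win, function(t) {
          mean(p[t:(t + 4L)]) - mean(p[(t - 8L):(t - 1L)])
        }, numeric(1))
        i_star <- which.max(score)
        vertex <- if (i_star > 1L && i_star < length(score)) {
          win[i_star] + (parabolic_refine(score, i_star) - i_star)
        } else {
          win[i_star]
        }
        # the fine gradient peak is unbiased; use it when it confirms the
        # robust coarse anchor, otherwise keep the anchor
        near <- pos[abs(pos - vertex) <= 2 & pos > ceiling(ilm) + 4L & pos < drop_i]
        if (length(near)) {
          rpe_i <- near[which.min(abs(near - vertex))]
          rpe <- parabolic_refine(g, rpe_i)
        } else {
          rpe_i <- win[i_star]
          rpe <- vertex
        }
      }
    }
  }
  if (is.finite(ilm) && is.finite(rpe)) {
    # interior interfaces: matched-filter anchor (4-row boxcars) refined by
    # the nearest gradient extremum, as for the RPE; anchoring avoids the
    # selection bias of raw gradient maxima under multiplicative speckle
    # (speckle gradients are stronger in brighter bands)
    step_anchor <- function(lo, hi, sign) {
      win <- seq(lo, hi)
      win <- win[win >= 5L & win <= H - 4L]
      if (length(win) < 3L) return(NA_real_)
      score <- sign * vapply(win, function(t) {
        mean(p[t:(t + 3L)]) - mean(p[(t - 4L):(t - 1L)])
      }, numeric(1))
      i <- which.max(score)
      if (score[i] < 0.15 * abs(g[rpe_i]) && score[i] < 0.2 * thr) return(NA_real_)
      vertex <- if (i > 1L && i < length(score)) {
        win[i] + (parabolic_refine(score, i) - i)
      } else win[i]
      cand <- if (sign > 0) pos else neg
      near <- cand[abs(cand - vertex) <= 2 & cand >= lo & cand <= hi]
      if (length(near)) {
        parabolic_refine(g, near[which.min(abs(near - vertex))])
      } else vertex
    }
    lo <- ceiling(ilm) + 4L; hi <- rpe_i - 4L
    g1 <- step_anchor(lo, hi, -1)
    if (is.finite(g1)) {
      gcc_inl <- g1
      i2 <- step_anchor(ceiling(g1) + 4L, hi, 1)
      if (is.finite(i2)) inl_pr <- i2
    }
  }

  rows <- c(ilm = ilm, gcc_inl = gcc_inl, inl_pr = inl_pr, rpe = rpe) - 0.5
  detected <- is.finite(rows)
  ord <- rows[detected]
  if (length(ord) > 1L && any(diff(ord) <= 0)) {
    # ordering violated: keep only ILM and RPE if they are consistent
    keep <- c("ilm", "rpe")
    bad <- setdiff(names(rows)[detected], keep)
    rows[bad] <- NA_real_
    detected <- is.finite(rows)
  }
  out <- tibble::tibble(
    boundary = c("ilm", "gcc_inl", "inl_pr", "rpe"),
    row = unname(rows),
    detected = unname(detected)
  )
  attr(out, "column") <- column
  attr(out, "valid") <- all(detected)
  class(out) <- c("octa_boundary_profile", class(out))
  out
}

#' Layer thicknesses from boundary profiles
#'
#' Averages per-site boundary separations over all valid profiles (all four
#' boundaries detected and ordered) and converts to micrometers: GCC = ILM to
#' GCC/INL, INL-ONL = GCC/INL to the nuclear/debris interface, PR/debris =
#' nuclear/debris to RPE, total retina = ILM to RPE.
#'
#' @param profiles List of [detect_boundaries()] results.
#' @param pitch_z_um Axial pixel pitch, micrometers per pixel.
#' @return Tibble with `gcc_um`, `inl_onl_um`, `pr_debris_um`, `trt_um`,
#'   `n_sites`.
#' @export
layer_thicknesses <- function(profiles, pitch_z_um) {
  stopifnot(length(profiles) >= 1L, pitch_z_um > 0)
  valid <- Filter(function(p) isTRUE(attr(p, "valid")), profiles)
  if (length(valid) == 0L) abort("No valid boundary profiles to average.")
  per <- vapply(valid, function(p) {
    r <- stats::setNames(p$row, p$boundary)
    c(gcc = r["gcc_inl"] - r["ilm"],
      inl_onl = r["inl_pr"] - r["gcc_inl"],
      pr = r["rpe"] - r["inl_pr"],
      trt = r["rpe"] - r["ilm"])
  }, numeric(4))
  m <- rowMeans(per) * pitch_z_um
  tibble::tibble(
    gcc_um = unname(m[1]), inl_onl_um = unname(m[2]),
    pr_debris_um = unname(m[3]), trt_um = unname(m[4]),
    n_sites = length(valid)
  )
}

#' Percent change relative to a reference
#'
#' `100 * (t_ref - t) / t_ref`; positive values mean thinning (loss) relative
#' to the reference.
#'
#' @param t_ref Reference value (> 0).
#' @param t Later value.
#' @return Percent change.
#' @export
percent_change <- function(t_ref, t) {
  if (any(t_ref <= 0)) abort("Reference value must be strictly positive.")
  100 * (t_ref - t) / t_ref
}
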