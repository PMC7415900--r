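#' 3x3 median smoothing of an enface angiogram
#'
#' Each output pixel is the median of its 3x3 neighborhood; borders are
#' handled by edge replication. This is the standard despeckling step applied
#' to enface angiograms before the vessel index.
#'
#' @param img An enface angiogram [intensity_image()].
#' @return The filtered image.
#' @export
median_filter_3x3 <- function(img) {
  stopifnot(inherits(img, "octa_image"))
  if (img$kind != "enface_angiogram") abort("Median prefilter applies to enface angiograms.")
  if (img$height_px < 3L || img$width_px < 3L) abort("Image must be at least 3x3.")
  out <- img
  out$pixels <- median3x3_cpp(img$pixels)
  out
}

#' 3x3 Gaussian (binomial) smoothing
#'
#' Convolution with the separable binomial kernel (1, 2, 1)/4 along each axis
#' (3x3 weights summing to 1, sigma ~ 0.85 px), edge-replicated borders. This
#' is the smoothing stage of the choroidal sharpness index.
#'
#' @param img An [intensity_image()], at least 3x3.
#' @return The smoothed image.
#' @export
gaussian3_smooth <- function(img) {
  stopifnot(inherits(img, "octa_image"))
  if (img$height_px < 3L || img$width_px < 3L) abort("Image must be at least 3x3.")
  out <- img
  out$pixels <- binom3_cpp(img$pixels)
  out
}

#' Central-difference gradient magnitude
#'
#' Per interior pixel, `sqrt(gx^2 + gy^2)` with
#' `gx = (I(i, j+1) - I(i, j-1)) / 2` and `gy = (I(i+1, j) - I(i-1, j)) / 2`.
#' The one-pixel border is set to 0 and excluded from the interior count.
#'
#' @param img An [intensity_image()] or numeric matrix, at least 3x3.
#' @return Numeric matrix of gradient magnitudes (border zero).
#' @export
gradient_magnitude <- function(img) {
  px <- if (inherits(img, "octa_image")) img$pixels else img
  if (nrow(px) < 3L || ncol(px) < 3L) abort("Image must be at least 3x3.")
  gradmag_cpp(px)
}

#' Vessel index of a retinal plexus angiogram
#'
#' The vessel index is the mean intensity over the vessel region minus the
#' mean intensity over the pooled intercapillary background regions:
#' `VI = sum(I[vessel]) / A_vessel - mean(I[background])`. Background pixels
#' are pooled across all background polygons (area-weighted). With
#' `prefilter = TRUE` the 3x3 median filter is applied first and the filtered
#' image feeds both terms.
#'
#' @param img An enface angiogram [intensity_image()] (plexus SVP or DCP).
#' @param roi An [roi_set()] matching the image shape.
#' @param prefilter Apply [median_filter_3x3()] first (default `TRUE`).
#' @return An object of class `octa_vi` with elements `value`,
#'   `vessel_area_px`, `background_mean`, `plexus`.
#' @export
vessel_index <- function(img, roi, prefilter = TRUE) {
  stopifnot(inherits(img, "octa_image"), inherits(roi, "octa_roi"))
  if (!identical(as.integer(c(img$height_px, img$width_px)), roi$image_shape)) {
    abort("ROI image_shape does not match the image.")
  }
  if (any(roi$vessel_mask & roi$background_mask)) abort("Vessel and background masks overlap.")
  if (!any(roi$vessel_mask) || !any(roi$background_mask)) abort("Empty ROI mask.")
  if (isTRUE(prefilter)) img <- median_filter_3x3(img)
  px <- img$pixels
  bg <- mean(px[roi$background_mask])
  vi <- sum(px[roi$vessel_mask]) / sum(roi$vessel_mask) - bg
  structure(
    list(value = vi, vessel_area_px = sum(roi$vessel_mask),
         background_mean = bg, plexus = img$plexus),
    class = "octa_vi"
  )
}

#' @export
print.octa_vi <- function(x, ...) {
  cat(sprintf("<octa_vi> %s VI = %.4f (vessel %d px, background mean %.4f)\n",
              x$plexus %||% "?", x$value, x$vessel_area_px, x$background_mean))
  invisible(x)
}

#' Sharpness index of a choroidal angiogram
#'
#' The sharpness index is the sum, over the interior of the image, of the
#' gradient magnitude of the 3x3-Gaussian-smoothed angiogram. As the RPE
#' degenerates and scatters less, choroidal vessels come into focus and the
#' index rises. Because the raw sum grows with image area, a per-interior-
#' pixel mean is reported alongside and is the value used by the statistics
#' stage by default.
#'
#' @param img A choroidal enface angiogram [intensity_image()], at least 5x5.
#' @return An object of class `octa_sharpness` with elements `value`
#'   (raw sum), `per_pixel_value`, `image_shape`.
#' @export
choroid_sharpness <- function(img) {
  stopifnot(inherits(img, "octa_image"))
  if (!identical(img$plexus, "choroid")) {
    warn("Sharpness index is intended for the choroidal plexus.")
  }
  if (img$height_px < 5L || img$width_px < 5L) {
    abort("Image must be at least 5x5 (smoothing support plus border exclusion).")
  }
  g <- gradmag_cpp(binom3_cpp(img$pixels))
  n_int <- (img$height_px - 2L) * (img$width_px - 2L)
  v <- sum(g)
  structure(
    list(value = v, per_pixel_value = v / n_int,
         image_shape = c(img$height_px, img$width_px)),
    class = "octa_sharpness"
  )
}

#' @export
print.octa_sharpness <- function(x, ...) {
  cat(sprintf("<octa_sharpness> sum = %.4f, per interior pixel = %.6f (%dx%d px)\n",
              x$value, x$per_pixel_value, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Normalize a longitudinal metric to its group baseline
#'
#' Divides every value by the mean of its group's values at the baseline week
#' (for cross-sectional controls, the youngest age group), so the group mean
#' at baseline is exactly 1. Normalizing twice is idempotent.
#'
#' @param data Tibble with columns `animal_id`, `eye`, `week`, `value`, and
#'   optionally `group` (normalization is per group when present).
#' @param baseline_week Baseline week; default is the earliest week per group.
#' @return The input tibble with `value` replaced by the normalized value and
#'   a `baseline_week` attribute.
#' @export
normalize_series <- function(data, baseline_week = NULL) {
  data <- tibble::as_tibble(data)
  if (!"group" %in% names(data)) data$group <- "all"
  out <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      bw <- baseline_week %||% min(d$week)
      base <- d$value[d$week == bw]
      if (length(base) == 0L) {
        abort(sprintf("No baseline (week %s) values for group '%s'.", bw, key$group))
      }
      have_base <- unique(paste(d$animal_id, d$eye))
      miss <- setdiff(have_base,
                      unique(paste(d$animal_id[d$week == bw], d$eye[d$week == bw])))
      is_followup <- anyDuplicated(paste(d$animal_id, d$eye)) > 0L
      if (is_followup && length(miss)) {
        abort(paste0("Missing baseline week ", bw, " for: ", paste(miss, collapse = "; ")))
      }
      d$value <- d$value / mean(base)
      d
    }) |>
    dplyr::ungroup()
  if (identical(unique(out$group), "all")) out$group <- NULL
  attr(out, "baseline_week") <- baseline_week
  out
}
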