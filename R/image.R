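#' Grayscale intensity image with physical pixel pitch
#'
#' The unit of all image math in the package: a 2D grid of intensities in
#' \[0, 1\] plus the lateral (and, for B-scans, axial) pixel pitch in
#' micrometers and a kind label. Angiogram images additionally carry the
#' plexus they were projected from.
#'
#' @param pixels Numeric matrix with values in \[0, 1\]; rows are image rows.
#' @param pitch_x_um,pitch_y_um Lateral pixel pitch, micrometers per pixel.
#' @param pitch_z_um Axial pitch (B-scans only), micrometers per pixel.
#' @param kind One of `"enface_angiogram"`, `"enface_structural"`, `"bscan"`.
#' @param plexus For enface angiograms, one of `"SVP"`, `"DCP"`, `"choroid"`.
#'
#' @return An object of class `octa_image`.
#' @export
intensity_image <- function(pixels,
                            pitch_x_um = 7.8, pitch_y_um = 3.0,
                            pitch_z_um = NA_real_,
                            kind = c("enface_angiogram", "enface_structural", "bscan"),
                            plexus = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("`pixels` must have at least one row and one column.")
  }
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < -1e-12 || rng[2] > 1 + 1e-12) {
    abort("Pixel values must lie in [0, 1] and contain no NA.")
  }
  if (!all(c(pitch_x_um, pitch_y_um) > 0)) abort("Pixel pitches must be strictly positive.")
  if (kind == "bscan" && (is.na(pitch_z_um) || pitch_z_um <= 0)) {
    abort("B-scans require a strictly positive axial pitch `pitch_z_um`.")
  }
  if (kind == "enface_angiogram") {
    if (is.null(plexus) || !plexus %in% c("SVP", "DCP", "choroid")) {
      abort("Enface angiograms require `plexus` in {SVP, DCP, choroid}.")
    }
  } else if (!is.null(plexus)) {
    abort("`plexus` may only be set for enface angiograms.")
  }
  structure(
    list(
      pixels = pmin(pmax(pixels, 0), 1),
      height_px = nrow(pixels), width_px = ncol(pixels),
      pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um, pitch_z_um = pitch_z_um,
      kind = kind, plexus = plexus
    ),
    class = "octa_image"
  )
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf(
    "<octa_image> %s %dx%d px, pitch %.3g x %.3g um/px%s%s\n",
    x$kind, x$height_px, x$width_px, x$pitch_x_um, x$pitch_y_um,
    if (!is.na(x$pitch_z_um)) sprintf(", axial %.3g um/px", x$pitch_z_um) else "",
    if (!is.null(x$plexus)) paste0(", plexus ", x$plexus) else ""
  ))
  invisible(x)
}

#' Default pixel pitches
#'
#' Enface pitches derive from the wide-field scan geometry in the rat eye:
#' a 3.9 mm fast axis sampled by 500 A-scans (7.8 um/px) and a 2.4 mm slow
#' axis sampled by 800 B-scans (3.0 um/px). The axial pitch is a
#' configuration value (instrument exports do not carry it); the default is
#' 1.95 um/px.
#'
#' @return A list with elements `pitch_x_um`, `pitch_y_um`, `pitch_z_um`.
#' @export
pitch_defaults <- function() {
  list(pitch_x_um = 3900 / 500, pitch_y_um = 2400 / 800, pitch_z_um = 1.95)
}

read_gray_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    if (!is.null(info$bit.depth) && !info$bit.depth %in% c(8L, 16L)) {
      abort(sprintf("Unsupported PNG bit depth %s in '%s' (need 8 or 16).",
                    info$bit.depth, path))
    }
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] == 2L) {
        px <- px[, , 1L]  # gray + alpha: drop alpha
      } else {
        abort(sprintf("Multi-channel image not supported: '%s'.", path))
      }
    }
    return(unclass(px))
  }
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(px)) abort(sprintf("'%s' is multi-page; use read_bscan_stack().", path))
    bits <- attr(px, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
    if (!bits %in% c(8L, 16L)) {
      abort(sprintf("Unsupported TIFF bit depth %s in '%s' (need 8 or 16).", bits, path))
    }
    if (length(dim(px)) == 3L) abort(sprintf("Multi-channel image not supported: '%s'.", path))
    return(px / (2^bits - 1))
  }
  abort(sprintf("Unsupported image format '%s' (need PNG or TIFF): '%s'.", ext, path))
}

#' Read a grayscale image file
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF and scales intensities to
#' \[0, 1\] by dividing by the dtype maximum (255 or 65535). Physical pitch is
#' supplied by `pitch_config` since instrument exports do not store it.
#'
#' @param path File path.
#' @param pitch_config List with `pitch_x_um`, `pitch_y_um`, `pitch_z_um`;
#'   see [pitch_defaults()].
#' @param kind,plexus Image metadata, see [intensity_image()].
#' @return An [intensity_image()].
#' @export
read_image <- function(path, pitch_config = pitch_defaults(),
                       kind = "enface_angiogram", plexus = NULL) {
  if (!file.exists(path)) abort(sprintf("Image file not found: '%s'.", path))
  px <- read_gray_matrix(path)
  intensity_image(px,
    pitch_x_um = pitch_config$pitch_x_um, pitch_y_um = pitch_config$pitch_y_um,
    pitch_z_um = pitch_config$pitch_z_um %||% NA_real_,
    kind = kind, plexus = plexus
  )
}

quantize_unit <- function(px, maxval) {
  # tiff::writeTIFF truncates; offset the quantized level by just under half a
  # step so the writer stores round(px * maxval) and the round trip stays
  # within 1/(2*maxval).
  q <- round(px * maxval)
  pmin((q + 0.499) / maxval, 1)
}

#' Write a grayscale image file
#'
#' Writes an [intensity_image()] as single-channel PNG (8-bit) or TIFF
#' (8- or 16-bit). Reading the file back reproduces the pixels within half a
#' quantization step, `1 / (2 * dtype_max)`.
#'
#' @param img An [intensity_image()].
#' @param path Destination path; extension selects the format.
#' @param bits Bit depth, 8 or 16 (PNG supports 8 only).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "octa_image"))
  if (!bits %in% c(8L, 16L)) abort("`bits` must be 8 or 16.")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) abort("PNG output is 8-bit; use TIFF for 16-bit.")
    png::writePNG(img$pixels, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(quantize_unit(img$pixels, 2^bits - 1), path,
                    bits.per.sample = as.integer(bits))
  } else {
    abort(sprintf("Unsupported output format '%s' (need PNG or TIFF).", ext))
  }
  invisible(path)
}

#' Read a multi-page TIFF B-scan stack
#'
#' Pages are in slow-scan order. Each page becomes a B-scan
#' [intensity_image()].
#'
#' @param path Multi-page TIFF path.
#' @param pitch_config Pitches attached to each page; see [read_image()].
#' @return List of `octa_image` objects of kind `"bscan"`.
#' @export
read_bscan_stack <- function(path, pitch_config = pitch_defaults()) {
  if (!file.exists(path)) abort(sprintf("B-scan stack not found: '%s'.", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(px) {
    bits <- attr(px, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
    intensity_image(px / (2^bits - 1),
      pitch_x_um = pitch_config$pitch_x_um, pitch_y_um = pitch_config$pitch_y_um,
      pitch_z_um = pitch_config$pitch_z_um, kind = "bscan"
    )
  })
}

#' Write a B-scan stack as multi-page TIFF
#'
#' @param imgs List of B-scan [intensity_image()] objects.
#' @param path Destination TIFF path.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_bscan_stack <- function(imgs, path, bits = 16L) {
  stopifnot(length(imgs) >= 1L)
  pages <- lapply(imgs, function(im) quantize_unit(im$pixels, 2^bits - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
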