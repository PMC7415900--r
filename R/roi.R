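#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. Pixel centers sit at half-integer coordinates measured
#' from the top-left image corner (x = column, y = row).
#'
#' @param polygon Two-column numeric matrix of (x, y) vertices, in order.
#' @param image_shape Integer vector `c(height_px, width_px)`.
#' @return Logical matrix of dimension `image_shape`.
#' @export
rasterize_polygon <- function(polygon, image_shape) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) abort("A polygon needs at least 3 vertices.")
  H <- image_shape[1]; W <- image_shape[2]
  if (any(polygon[, 1] < 0 | polygon[, 1] > W | polygon[, 2] < 0 | polygon[, 2] > H)) {
    abort("Polygon vertices must lie within the image bounds.")
  }
  n <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  area2 <- sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)
  if (abs(area2) < 1e-12) abort("Degenerate (zero-area) polygon.")
  cx <- seq_len(W) - 0.5
  cy <- seq_len(H) - 0.5
  px <- rep(cx, each = H)
  py <- rep(cy, times = W)
  crossings <- integer(H * W)
  for (e in seq_len(n)) {
    x1 <- xs[e]; y1 <- ys[e]
    x2 <- xs[e %% n + 1L]; y2 <- ys[e %% n + 1L]
    if (y1 == y2) next
    straddles <- (y1 > py) != (y2 > py)
    xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    crossings <- crossings + as.integer(straddles & px < xint)
  }
  matrix(crossings %% 2L == 1L, H, W)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a1 <- poly[i, ]; a2 <- poly[i %% n + 1L, ]
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L)) next
      b1 <- poly[j, ]; b2 <- poly[j %% n + 1L, ]
      if (segments_intersect(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' Vessel and background regions of interest over an angiogram
#'
#' One vessel polygon plus one or more intercapillary background polygons,
#' with their rasterized masks. Vessel and background masks must be disjoint
#' and non-empty.
#'
#' @param vessel Two-column (x, y) vertex matrix for the vessel region.
#' @param background List of vertex matrices for background regions (>= 1).
#' @param image_shape `c(height_px, width_px)` of the target angiogram.
#' @return An object of class `octa_roi`.
#' @export
roi_set <- function(vessel, background, image_shape) {
  vessel <- as.matrix(vessel)
  background <- lapply(background, as.matrix)
  if (length(background) < 1L) abort("At least one background polygon is required.")
  for (p in c(list(vessel), background)) {
    if (!polygon_is_simple(p)) abort("Polygons must be simple (non-self-intersecting).")
  }
  vmask <- rasterize_polygon(vessel, image_shape)
  bmasks <- lapply(background, rasterize_polygon, image_shape = image_shape)
  bmask <- Reduce(`|`, bmasks)
  if (!any(vmask)) abort("Vessel polygon rasterizes to an empty mask.")
  if (any(!vapply(bmasks, any, logical(1)))) {
    abort("Every background polygon must rasterize to a non-empty mask.")
  }
  if (any(vmask & bmask)) abort("Vessel and background masks overlap.")
  structure(
    list(vessel_polygon = vessel, background_polygons = background,
         image_shape = as.integer(image_shape),
         vessel_mask = vmask, background_mask = bmask),
    class = "octa_roi"
  )
}

#' @export
print.octa_roi <- function(x, ...) {
  cat(sprintf("<octa_roi> %dx%d px, vessel %d px, background %d px (%d polygons)\n",
              x$image_shape[1], x$image_shape[2], sum(x$vessel_mask),
              sum(x$background_mask), length(x$background_polygons)))
  invisible(x)
}

#' Read / write an ROI set as JSON
#'
#' Schema: `{"image_shape": [H, W], "vessel": [[x, y], ...],
#' "background": [[[x, y], ...], ...]}`. Vertices round-trip losslessly.
#'
#' @param path JSON file path.
#' @return [roi_set()] object.
#' @export
read_roi_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bg <- j$background
  if (is.array(bg) && length(dim(bg)) == 3L) {
    bg <- lapply(seq_len(dim(bg)[1]), function(i) bg[i, , ])
  }
  roi_set(vessel = j$vessel, background = bg, image_shape = j$image_shape)
}

#' @rdname read_roi_set
#' @param roi An [roi_set()] object.
#' @export
write_roi_set <- function(roi, path) {
  stopifnot(inherits(roi, "octa_roi"))
  jsonlite::write_json(
    list(image_shape = roi$image_shape,
         vessel = roi$vessel_polygon,
         background = roi$background_polygons),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor"
  )
  invisible(path)
}
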