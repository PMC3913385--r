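# Disclosed-plaque coverage: red/green 8-bit ratio image, >= 1 threshold,
# histogram-based percentage coverage inside the tooth ROI.

#' Red/green channel-ratio image
#'
#' Divides the red channel by the green channel in 8-bit integer
#' arithmetic, mimicking an image-calculator channel division. The result
#' is an almost entirely black image whose pixel values are small
#' non-negative integers (typically 0--3): disclosed plaque fluoresces
#' red at least as strongly as green (value >= 1) while sound enamel is
#' green-dominant (value 0).
#'
#' Zero-green handling: a pixel with `G = 0` and `R > 0` is saturated to
#' 255 (maximally plaque-like); a fully dark pixel (`R = G = 0`) carries
#' no evidence and maps to 0.
#'
#' @param img a [fluorescence_image()].
#' @param rounding `"floor"` (default; truncating division, so value
#'   `>= 1` exactly when `R >= G`) or `"round"` (half-up), provided for
#'   sensitivity analysis.
#' @return an object of class `ratio_image` with integer matrix `pixels`
#'   and `origin_image_id`.
#' @export
ratio_image <- function(img, rounding = c("floor", "round")) {
  stopifnot(inherits(img, "fluorescence_image"))
  rounding <- match.arg(rounding)
  r <- img$pixels[, , 1]
  g <- img$pixels[, , 2]
  out <- matrix(0L, nrow = nrow(r), ncol = ncol(r))
  pos <- g > 0L
  out[pos] <- if (rounding == "floor") r[pos] %/% g[pos]
              else (2L * r[pos] + g[pos]) %/% (2L * g[pos])  # half-up
  out[!pos & r > 0L] <- 255L
  structure(list(pixels = out, origin_image_id = img$image_id),
            class = "ratio_image")
}

#' Threshold a ratio image into a plaque mask
#'
#' Pixels whose ratio value is `>= threshold` are classified as plaque
#' covered; value 0 is plaque-free.
#'
#' @param ratio a [ratio_image()].
#' @param threshold integer `>= 1` (default 1).
#' @return a [binary_mask()].
#' @export
classify_plaque <- function(ratio, threshold = 1L) {
  stopifnot(inherits(ratio, "ratio_image"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1)
    stop("threshold must be an integer >= 1")
  binary_mask(ratio$pixels >= threshold,
              origin_image_id = ratio$origin_image_id)
}

#' Percentage plaque coverage within a tooth ROI
#'
#' The full disclosed-plaque measurement: (optionally) deinterlace, build
#' the red/green ratio image, threshold it, intersect with the rasterized
#' tooth polygon, and report the plaque-covered pixel fraction as a
#' percentage of the ROI area.
#'
#' @param img a [fluorescence_image()].
#' @param roi a [polygon_roi()] delineating the tooth; all vertices must
#'   lie within the image bounds and the ROI must cover at least one pixel
#'   centre.
#' @param threshold plaque classification threshold, see
#'   [classify_plaque()].
#' @param deinterlace_first apply [deinterlace()] before the ratio
#'   (default `TRUE`).
#' @param field deinterlace field parity, see [deinterlace()].
#' @param rounding ratio division rounding, see [ratio_image()].
#' @return a `coverage_result`: list with `image_id`, `tooth_id`,
#'   `roi_pixels`, `plaque_pixels`, `coverage_pct` in `[0, 100]` and
#'   `plaque_area_mm2` (`NA` without calibration).
#' @export
coverage <- function(img, roi, threshold = 1L, deinterlace_first = TRUE,
                     field = "odd_rows", rounding = "floor") {
  stopifnot(inherits(img, "fluorescence_image"), inherits(roi, "polygon_roi"))
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  v <- roi$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > w) || any(v[, 2] < 0) || any(v[, 2] > h))
    stop("ROI for tooth '", roi$tooth_id, "' exceeds image bounds")
  if (deinterlace_first) img <- deinterlace(img, field = field)
  rat <- ratio_image(img, rounding = rounding)
  plaque <- classify_plaque(rat, threshold = threshold)
  mask <- rasterize_polygon(roi, h, w, origin_image_id = img$image_id)
  n_roi <- sum(mask$pixels)
  if (n_roi == 0L)
    stop("ROI for tooth '", roi$tooth_id, "' covers no pixel centres")
  n_plaque <- sum(mask$pixels & plaque$pixels)
  list(
    image_id = img$image_id,
    tooth_id = roi$tooth_id,
    roi_pixels = n_roi,
    plaque_pixels = n_plaque,
    coverage_pct = 100 * n_plaque / n_roi,
    plaque_area_mm2 = if (is.null(img$mm_per_pixel)) NA_real_
                      else n_plaque * img$mm_per_pixel^2
  )
}
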