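# Red-fluorescent (undisclosed) plaque: delta-R% relative to a plaque-free
# reference ellipse, and red-fluorescent area.

#' Red-fluorescence elevation over a plaque-free reference
#'
#' Mature plaque near the gingival margin fluoresces red because of
#' bacterial porphyrins. The measure is ratio-based and therefore robust
#' to global illumination changes: with per-pixel real-valued ratio
#' `r = R/G` and reference ratio `r0` (the mean over a plaque-free
#' elliptical reference region on the same tooth), each ROI pixel's
#' elevation is `dR = 100 (r - r0) / r0`. Pixels with `dR` at or above the
#' detection threshold are counted as red-fluorescent, and `delta_r_pct`
#' is the mean elevation over those detected pixels (0 when none are
#' detected). Pixels with `G = 0` are excluded from both the reference and
#' the detection, as their ratio is undefined.
#'
#' Unlike the disclosed-plaque coverage measure, arithmetic here is
#' real-valued: the elevation is a continuous quantity, not an 8-bit
#' classification.
#'
#' @param img a [fluorescence_image()].
#' @param roi a [polygon_roi()] delineating the tooth.
#' @param reference an [ellipse_roi()] over plaque-free enamel; must lie
#'   entirely inside the tooth ROI.
#' @param detection_threshold_pct minimum percentage elevation for a pixel
#'   to count as red-fluorescent (default 20).
#' @return a `delta_r_result`: list with `image_id`, `tooth_id`,
#'   `reference_ratio`, `delta_r_pct`, `detected_pixels`, `roi_pixels` and
#'   `red_area_mm2` (`NA` without calibration).
#' @export
delta_r <- function(img, roi, reference, detection_threshold_pct = 20) {
  stopifnot(inherits(img, "fluorescence_image"),
            inherits(roi, "polygon_roi"),
            inherits(reference, "ellipse_roi"))
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  roi_mask <- rasterize_polygon(roi, h, w)$pixels
  ref_mask <- rasterize_ellipse(reference, h, w)$pixels
  if (!any(ref_mask))
    stop("reference ellipse covers no pixel centres")
  if (any(ref_mask & !roi_mask))
    stop("reference ellipse extends outside the tooth ROI for tooth '",
         roi$tooth_id, "'")
  rch <- img$pixels[, , 1]
  gch <- img$pixels[, , 2]
  valid <- gch > 0L
  if (!any(ref_mask & valid) || mean(gch[ref_mask]) <= 0)
    stop("degenerate reference: no green signal in the reference region")
  ratio <- matrix(NA_real_, h, w)
  ratio[valid] <- rch[valid] / gch[valid]
  r0 <- mean(ratio[ref_mask & valid])
  sel <- roi_mask & valid
  dr <- 100 * (ratio[sel] - r0) / r0
  detected <- dr >= detection_threshold_pct
  n_det <- sum(detected)
  list(
    image_id = img$image_id,
    tooth_id = roi$tooth_id,
    reference_ratio = r0,
    delta_r_pct = if (n_det > 0L) mean(dr[detected]) else 0,
    detected_pixels = n_det,
    roi_pixels = sum(roi_mask),
    red_area_mm2 = if (is.null(img$mm_per_pixel)) NA_real_
                   else n_det * img$mm_per_pixel^2
  )
}
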