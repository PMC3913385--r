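# Image and ROI data structures, file I/O, and the deinterlacing pre-filter.
#
# Coordinate convention used throughout: pixel (row i, col j) -- both
# zero-based -- occupies the half-open square [j, j+1) x [i, i+1) with
# centre (j + 0.5, i + 0.5); x = column, y = row, origin at the top-left
# corner of the image.

#' Construct a fluorescence image
#'
#' An 8-bit RGB intraoral fluorescence image. Sound enamel fluoresces green
#' under violet illumination while bacterial porphyrins in mature plaque
#' (and disclosed plaque) fluoresce red; the downstream plaque measures are
#' built on the red/green channel contrast.
#'
#' @param pixels integer array of dimension `H x W x 3` (red, green, blue),
#'   values in 0--255, `H >= 2`, `W >= 2`.
#' @param image_id identifier string carried through to results.
#' @param mm_per_pixel optional positive scalar giving the physical
#'   calibration; when `NULL`, areas downstream are reported in pixels and
#'   mm^2 fields are `NA`.
#' @return an object of class `fluorescence_image` with elements `pixels`,
#'   `image_id`, `mm_per_pixel`.
#' @export
fluorescence_image <- function(pixels, image_id = "", mm_per_pixel = NULL) {
  pixels <- as.array(pixels)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array (red, green, blue)")
  if (d[1] < 2L || d[2] < 2L)
    stop("image must be at least 2 x 2")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != floor(pixels)))
    stop("channel values must be integers in [0, 255]")
  storage.mode(pixels) <- "integer"
  if (!is.null(mm_per_pixel)) {
    if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
        !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
      stop("mm_per_pixel must be a positive scalar")
  }
  structure(
    list(pixels = pixels, image_id = as.character(image_id),
         mm_per_pixel = mm_per_pixel),
    class = "fluorescence_image"
  )
}

#' @export
print.fluorescence_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fluorescence_image '%s': %d x %d, 8-bit RGB%s>\n",
              x$image_id, d[1], d[2],
              if (is.null(x$mm_per_pixel)) ""
              else sprintf(", %.4g mm/px", x$mm_per_pixel)))
  invisible(x)
}

#' Read an 8-bit RGB fluorescence image from PNG or TIFF
#'
#' Only 8-bit RGB (or RGBA; the alpha plane is dropped) rasters are
#' accepted: greyscale or 16-bit inputs are rejected with an error naming
#' the offending property.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param mm_per_pixel optional physical calibration, see
#'   [fluorescence_image()].
#' @param image_id identifier; defaults to the file name without extension.
#' @return a [fluorescence_image()].
#' @export
read_image <- function(path, mm_per_pixel = NULL,
                       image_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(raw)
    depth <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 8L
  } else {
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)")
  }
  if (any(depth != 8L))
    stop("image is not 8-bit (bit depth ", paste(depth, collapse = "/"),
         "): ", path)
  d <- dim(raw)
  if (length(d) < 3L || d[3] < 3L)
    stop("image is not RGB (",
         if (length(d) < 3L) "single channel" else paste0(d[3], " channels"),
         "): ", path)
  px <- round(raw[, , 1:3, drop = FALSE] * 255)
  fluorescence_image(px, image_id = image_id, mm_per_pixel = mm_per_pixel)
}

#' Write a fluorescence image to PNG or TIFF
#'
#' Lossless 8-bit output; a write/read round trip preserves every pixel
#' value exactly.
#'
#' @param img a [fluorescence_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "fluorescence_image"))
  ext <- tolower(sub(".*\\.", "", path))
  arr <- img$pixels / 255
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format '", ext, "'")
  }
  invisible(path)
}

#' Remove horizontal interlacing artifacts
#'
#' Video-capture interlacing leaves alternate scan lines inconsistent with
#' their neighbours. The filter replaces every row of one field parity,
#' per channel, by the rounded mean of its two vertical neighbours
#' (boundary rows of that parity are copied from their single neighbour);
#' rows of the other parity are untouched. Row parity is zero-based, so
#' `odd_rows` replaces the 2nd, 4th, ... scan lines.
#'
#' @param img a [fluorescence_image()] with at least 3 rows.
#' @param field which field to replace: `"odd_rows"` (default) or
#'   `"even_rows"`.
#' @return a [fluorescence_image()] of identical dimensions.
#' @export
deinterlace <- function(img, field = c("odd_rows", "even_rows")) {
  stopifnot(inherits(img, "fluorescence_image"))
  field <- match.arg(field)
  h <- dim(img$pixels)[1]
  if (h < 3L) stop("deinterlace needs at least 3 rows, got ", h)
  # zero-based parity: odd_rows -> R indices 2, 4, ...
  rows <- if (field == "odd_rows") seq(2L, h, by = 2L) else seq(1L, h, by = 2L)
  px <- img$pixels
  for (i in rows) {
    if (i == 1L) {
      px[i, , ] <- img$pixels[2L, , ]
    } else if (i == h) {
      px[i, , ] <- img$pixels[h - 1L, , ]
    } else {
      # rounded (half-up) mean of the two neighbours, integer-exact
      px[i, , ] <- (img$pixels[i - 1L, , ] + img$pixels[i + 1L, , ] + 1L) %/% 2L
    }
  }
  fluorescence_image(px, image_id = img$image_id,
                     mm_per_pixel = img$mm_per_pixel)
}

#' Construct a polygon region of interest around a tooth
#'
#' @param vertices numeric matrix (or list of pairs) of `>= 3` `(x, y)`
#'   pixel coordinates; the polygon is closed implicitly (last vertex
#'   connects to the first) and must be simple (non-self-intersecting).
#' @param tooth_id FDI two-digit tooth label, e.g. `"13"`, `"43"`.
#' @return an object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices, tooth_id = "") {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, unlist))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("polygon needs >= 3 (x, y) vertices")
  if (anyNA(vertices) || !all(is.finite(vertices)))
    stop("polygon vertices must be finite")
  structure(list(vertices = unname(vertices), tooth_id = as.character(tooth_id)),
            class = "polygon_roi")
}

#' Construct a plaque-free elliptical reference region
#'
#' @param center `(x, y)` pixel coordinates of the ellipse centre.
#' @param semi_axes `(a, b)` semi-axis lengths in pixels, both `> 0`.
#' @param rotation_deg rotation of the `a` axis, degrees counter-clockwise.
#' @return an object of class `ellipse_roi`.
#' @export
ellipse_roi <- function(center, semi_axes, rotation_deg = 0) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  if (length(center) != 2L || anyNA(center))
    stop("center must be (x, y)")
  if (length(semi_axes) != 2L || anyNA(semi_axes) || any(semi_axes <= 0))
    stop("semi-axes must be two strictly positive lengths")
  structure(list(center = center, semi_axes = semi_axes,
                 rotation_deg = as.numeric(rotation_deg)),
            class = "ellipse_roi")
}

#' Construct a binary pixel mask
#'
#' @param pixels logical `H x W` matrix.
#' @param origin_image_id id of the image the mask refers to.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, origin_image_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("mask must not contain NA")
  structure(list(pixels = pixels, origin_image_id = as.character(origin_image_id)),
            class = "binary_mask")
}

# TRUE when any two non-adjacent edges of the closed polygon properly cross.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  cross <- function(o, p, q) {
    (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share an endpoint), incl. the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- cross(a[i, ], b[i, ], a[j, ])
      d2 <- cross(a[i, ], b[i, ], b[j, ])
      d3 <- cross(a[j, ], b[j, ], a[i, ])
      d4 <- cross(a[j, ], b[j, ], b[i, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a polygon ROI to a binary mask
#'
#' Pixel `(i, j)` is set exactly when its centre `(j + 0.5, i + 0.5)` lies
#' strictly inside the polygon under the even-odd rule; centres exactly on
#' an edge are excluded. This makes pixel counts deterministic and exact
#' for integer-aligned rectangles.
#'
#' @param roi a [polygon_roi()].
#' @param height,width raster dimensions in pixels.
#' @param origin_image_id carried into the mask.
#' @return a [binary_mask()] of dimension `height x width`.
#' @export
rasterize_polygon <- function(roi, height, width, origin_image_id = "") {
  stopifnot(inherits(roi, "polygon_roi"))
  v <- roi$vertices
  if (.polygon_self_intersects(v))
    stop("polygon for tooth '", roi$tooth_id, "' is self-intersecting")
  # pixel-centre grid, vectorised even-odd crossing count per edge
  px <- rep(seq_len(width) - 0.5, each = height)   # x of centres, col-major
  py <- rep(seq_len(height) - 0.5, times = width)  # y of centres
  n <- nrow(v)
  inside <- logical(height * width)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  binary_mask(matrix(inside, nrow = height, ncol = width),
              origin_image_id = origin_image_id)
}

#' Rasterize an elliptical ROI to a binary mask
#'
#' A pixel is set when its centre satisfies the rotated-ellipse inequality
#' `(u/a)^2 + (v/b)^2 <= 1`, where `(u, v)` are the centre's coordinates in
#' the ellipse frame.
#'
#' @inheritParams rasterize_polygon
#' @param roi an [ellipse_roi()].
#' @return a [binary_mask()].
#' @export
rasterize_ellipse <- function(roi, height, width, origin_image_id = "") {
  stopifnot(inherits(roi, "ellipse_roi"))
  a <- roi$semi_axes[1]; b <- roi$semi_axes[2]
  th <- roi$rotation_deg * pi / 180
  px <- rep(seq_len(width) - 0.5, each = height) - roi$center[1]
  py <- rep(seq_len(height) - 0.5, times = width) - roi$center[2]
  u <- cos(th) * px + sin(th) * py
  v <- -sin(th) * px + cos(th) * py
  inside <- (u / a)^2 + (v / b)^2 <= 1
  binary_mask(matrix(inside, nrow = height, ncol = width),
              origin_image_id = origin_image_id)
}

#' Read regions of interest from a JSON file
#'
#' The file holds a JSON array of objects, each with `image_id`, `type`
#' (`"polygon"` or `"ellipse"`) and, for polygons, `tooth_id` and
#' `vertices` (an array of `[x, y]` pairs); ellipses carry `center`,
#' `semi_axes` and optionally `rotation_deg`. Coordinates are pixel units
#' under the package's top-left origin convention.
#'
#' @param path path to the ROI JSON file.
#' @return a list of records, each `list(image_id, tooth_id, roi)` where
#'   `roi` is a [polygon_roi()] or [ellipse_roi()].
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    type <- rec$type
    roi <- if (identical(type, "polygon")) {
      polygon_roi(rec$vertices, tooth_id = rec$tooth_id %||% "")
    } else if (identical(type, "ellipse")) {
      ellipse_roi(unlist(rec$center), unlist(rec$semi_axes),
                  rotation_deg = rec$rotation_deg %||% 0)
    } else {
      stop("unknown ROI type '", type, "' in ", path)
    }
    list(image_id = rec$image_id %||% "", tooth_id = rec$tooth_id %||% "",
         roi = roi)
  })
}

#' Write regions of interest to a JSON file
#'
#' Inverse of [read_rois()].
#'
#' @param rois list of records as returned by [read_rois()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(rec) {
    roi <- rec$roi
    if (inherits(roi, "polygon_roi")) {
      list(image_id = rec$image_id, tooth_id = rec$tooth_id, type = "polygon",
           vertices = lapply(seq_len(nrow(roi$vertices)),
                             function(i) as.numeric(roi$vertices[i, ])))
    } else {
      list(image_id = rec$image_id, tooth_id = rec$tooth_id, type = "ellipse",
           center = roi$center, semi_axes = roi$semi_axes,
           rotation_deg = roi$rotation_deg)
    }
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
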