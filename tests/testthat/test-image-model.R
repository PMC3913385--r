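test_that("PNG and TIFF write/read round trips preserve every pixel", {
  set.seed(11)
  img <- rand_img(7, 5)
  for (ext in c("png", "tiff")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path, mm_per_pixel = 0.05)
    expect_identical(back$pixels, img$pixels)
    expect_equal(back$mm_per_pixel, 0.05)
  }
})

test_that("an all-black image reads back as all zeros", {
  path <- withr::local_tempfile(fileext = ".png")
  write_image(make_img(matrix(0L, 4, 4), matrix(0L, 4, 4)), path)
  img <- read_image(path)
  expect_true(all(img$pixels == 0L))
  expect_equal(dim(img$pixels), c(4L, 4L, 3L))
})

test_that("non-8-bit and non-RGB inputs are rejected with a named property", {
  p16 <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(array(runif(4 * 4 * 3), c(4, 4, 3)), p16,
                  bits.per.sample = 16L)
  expect_error(read_image(p16), "8-bit")

  pgray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16), 4, 4), pgray)
  expect_error(read_image(pgray), "RGB")
})

test_that("image constructor enforces its invariants", {
  expect_error(fluorescence_image(array(0L, c(1, 4, 3))), "2 x 2")
  expect_error(fluorescence_image(array(300L, c(4, 4, 3))), "\\[0, 255\\]")
  expect_error(fluorescence_image(array(0L, c(4, 4, 2))), "H x W x 3")
  expect_error(fluorescence_image(array(0L, c(4, 4, 3)), mm_per_pixel = -1),
               "positive")
})

test_that("deinterlace replaces the selected field by neighbour means", {
  # constant image is a fixed point
  const <- make_img(matrix(7L, 5, 4), matrix(9L, 5, 4), matrix(1L, 5, 4))
  expect_identical(deinterlace(const)$pixels, const$pixels)

  # 3-row columns [0, 100, 0]: the zero-based odd row (middle) is averaged
  col3 <- make_img(matrix(c(0L, 100L, 0L), 3, 2),
                   matrix(c(0L, 100L, 0L), 3, 2))
  expect_true(all(deinterlace(col3, "odd_rows")$pixels == 0L))
  # even_rows replaces rows 0 and 2 (boundary copies of the middle row)
  expect_true(all(deinterlace(col3, "even_rows")$pixels[, , 1] == 100L))

  expect_error(deinterlace(make_img(matrix(0L, 2, 4), matrix(0L, 2, 4))),
               "3 rows")
})

test_that("deinterlace matches a row-by-row oracle on random images", {
  set.seed(21)
  for (field in c("odd_rows", "even_rows")) {
    img <- rand_img(9, 6)
    out <- deinterlace(img, field)$pixels
    rows <- if (field == "odd_rows") seq(2, 9, 2) else seq(1, 9, 2)
    expected <- img$pixels
    for (i in rows) for (j in 1:6) for (k in 1:3) {
      a <- if (i > 1) img$pixels[i - 1, j, k] else NA
      b <- if (i < 9) img$pixels[i + 1, j, k] else NA
      expected[i, j, k] <- if (is.na(a)) b else if (is.na(b)) a
        else floor((a + b) / 2 + 0.5)
    }
    storage.mode(expected) <- "integer"
    expect_identical(out, expected)
  }
})

test_that("deinterlace is idempotent", {
  set.seed(22)
  img <- rand_img(12, 8)
  once <- deinterlace(img)
  expect_identical(deinterlace(once)$pixels, once$pixels)
})

test_that("polygon rasterization is exact on integer rectangles", {
  rect <- polygon_roi(rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3)))
  mask <- rasterize_polygon(rect, 10, 10)
  expect_equal(sum(mask$pixels), 12L)
  expect_true(all(mask$pixels[1:3, 1:4]))
})

test_that("degenerate collinear polygons rasterize to an empty mask", {
  flat <- polygon_roi(rbind(c(0, 2), c(3, 2), c(6, 2)))
  expect_equal(sum(rasterize_polygon(flat, 8, 8)$pixels), 0L)
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- polygon_roi(rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4)))
  expect_error(rasterize_polygon(bowtie, 8, 8), "self-intersecting")
})

test_that("polygon rasterization agrees with the point-in-polygon oracle", {
  set.seed(31)
  for (rep in 1:40) {
    h <- sample(8:64, 1); w <- sample(8:64, 1)
    roi <- rand_star_polygon(w / 2 + runif(1, -2, 2), h / 2 + runif(1, -2, 2),
                             min(h, w) / 6, min(h, w) / 2 - 1,
                             sample(3:9, 1))
    expect_identical(rasterize_polygon(roi, h, w)$pixels,
                     oracle_polygon_mask(roi$vertices, h, w))
  }
})

test_that("ellipse rasterization matches the rotated-ellipse inequality", {
  # sub-pixel circle at a pixel centre covers exactly that pixel
  dot <- rasterize_ellipse(ellipse_roi(c(3.5, 2.5), c(0.6, 0.6)), 8, 8)
  expect_equal(sum(dot$pixels), 1L)
  expect_true(dot$pixels[3, 4])

  ell <- ellipse_roi(c(10, 7), c(6, 3), rotation_deg = 25)
  mask <- rasterize_ellipse(ell, 16, 20)$pixels
  brute <- matrix(FALSE, 16, 20)
  th <- 25 * pi / 180
  for (i in 1:16) for (j in 1:20) {
    dx <- (j - 0.5) - 10; dy <- (i - 0.5) - 7
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    brute[i, j] <- (u / 6)^2 + (v / 3)^2 <= 1
  }
  expect_identical(mask, brute)

  # 90 degree rotation swaps the roles of the semi-axes
  a <- rasterize_ellipse(ellipse_roi(c(10, 10), c(7, 3), 90), 20, 20)$pixels
  b <- rasterize_ellipse(ellipse_roi(c(10, 10), c(3, 7), 0), 20, 20)$pixels
  expect_identical(a, b)

  expect_error(ellipse_roi(c(5, 5), c(-1, 2)), "positive")
})

test_that("ROI JSON files round trip through write_rois/read_rois", {
  recs <- list(
    list(image_id = "S1_13", tooth_id = "13",
         roi = polygon_roi(rbind(c(1, 1), c(9, 2), c(5, 8)), "13")),
    list(image_id = "S1_13", tooth_id = "13",
         roi = ellipse_roi(c(5, 3), c(2, 1), 15))
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(recs, path)
  back <- read_rois(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$roi$vertices, recs[[1]]$roi$vertices)
  expect_equal(back[[2]]$roi$semi_axes, c(2, 1))
  expect_equal(back[[2]]$roi$rotation_deg, 15)
})
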