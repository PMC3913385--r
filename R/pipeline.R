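# End-to-end orchestration: images -> per-tooth measurements -> subject
# summaries -> statistics -> report directory.

#' Build a pipeline run configuration
#'
#' @param images_dir directory of 8-bit RGB PNG/TIFF images named
#'   `<subject_id>_<tooth_id>.<ext>`.
#' @param roi_file ROI JSON file, see [read_rois()]; polygon entries
#'   drive coverage, and an ellipse entry sharing an `image_id` provides
#'   the plaque-free reference for red-fluorescence quantification.
#' @param cohort_csv cohort CSV, see [read_cohort()].
#' @param out_dir report output directory.
#' @param threshold plaque classification threshold (default 1).
#' @param rounding ratio division rounding mode (`"floor"` or
#'   `"round"`).
#' @param deinterlace_first,field deinterlacing controls, see
#'   [deinterlace()].
#' @param detection_threshold_pct red-fluorescence detection threshold
#'   (default 20).
#' @param mm_per_pixel optional physical calibration applied to all
#'   images.
#' @param smoking_encoding `"ordinal"` or `"binary"`, see
#'   [encode_smoking()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(images_dir, roi_file, cohort_csv, out_dir,
                       threshold = 1L, rounding = "floor",
                       deinterlace_first = TRUE, field = "odd_rows",
                       detection_threshold_pct = 20, mm_per_pixel = NULL,
                       smoking_encoding = "ordinal") {
  cfg <- list(images_dir = images_dir, roi_file = roi_file,
              cohort_csv = cohort_csv, out_dir = out_dir,
              threshold = threshold, rounding = rounding,
              deinterlace_first = deinterlace_first, field = field,
              detection_threshold_pct = detection_threshold_pct,
              mm_per_pixel = mm_per_pixel,
              smoking_encoding = smoking_encoding)
  for (p in c("images_dir", "roi_file", "cohort_csv")) {
    if (!file.exists(cfg[[p]])) stop(p, " does not exist: ", cfg[[p]])
  }
  structure(cfg, class = "run_config")
}

.find_image <- function(dir, image_id) {
  for (ext in c(".png", ".tif", ".tiff")) {
    p <- file.path(dir, paste0(image_id, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read ROIs and images, deinterlace, compute per-tooth
#' plaque coverage and (where a reference ellipse is available)
#' red-fluorescence elevation, join with the cohort CSV on `subject_id`
#' (taken from the image naming convention
#' `<subject_id>_<tooth_id>`), apply the exclusion rules, summarize per
#' subject, and emit the case-vs-control characteristics table, the
#' logistic regression table, the coverage/delta-R Pearson correlation
#' and the exclusion log. Every stage logs record counts in and out; the
#' run is deterministic given fixed inputs.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress console stage logging (a `run.log` file is
#'   always written).
#' @return invisibly, a list with `measurements`, `summaries`,
#'   `exclusions`, `table1`, `table2`, `correlation` and the output
#'   directory; the same tables are written under `cfg$out_dir` as
#'   `measurements.csv`, `subject_summaries.csv`, `exclusions.csv`,
#'   `table1.csv`, `table2.csv`, `correlation.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  rois <- stage("read_rois", read_rois(cfg$roi_file))
  polys <- Filter(function(r) inherits(r$roi, "polygon_roi"), rois)
  ells <- Filter(function(r) inherits(r$roi, "ellipse_roi"), rois)
  ell_by_image <- stats::setNames(ells, vapply(ells, `[[`, "", "image_id"))
  log_msg("stage read_rois: %d polygon, %d ellipse entries",
          length(polys), length(ells))

  rows <- list()
  for (rec in polys) {
    path <- .find_image(cfg$images_dir, rec$image_id)
    if (is.null(path))
      stop("pipeline stage 'measure' failed: no image file for image_id '",
           rec$image_id, "'", call. = FALSE)
    img <- stage("read_image",
                 read_image(path, mm_per_pixel = cfg$mm_per_pixel,
                            image_id = rec$image_id))
    cov <- stage("coverage",
                 coverage(img, rec$roi, threshold = cfg$threshold,
                          deinterlace_first = cfg$deinterlace_first,
                          field = cfg$field, rounding = cfg$rounding))
    ref <- ell_by_image[[rec$image_id]]
    dr <- if (!is.null(ref))
      stage("delta_r",
            delta_r(img, rec$roi, ref$roi,
                    detection_threshold_pct = cfg$detection_threshold_pct))
    else NULL
    subject_id <- sub(paste0("_", rec$tooth_id, "$"), "", rec$image_id)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id,
      image_id = rec$image_id,
      tooth_id = rec$tooth_id,
      roi_pixels = cov$roi_pixels,
      plaque_pixels = cov$plaque_pixels,
      coverage_pct = cov$coverage_pct,
      plaque_area_mm2 = cov$plaque_area_mm2,
      reference_ratio = if (is.null(dr)) NA_real_ else dr$reference_ratio,
      delta_r_pct = if (is.null(dr)) NA_real_ else dr$delta_r_pct,
      detected_pixels = if (is.null(dr)) NA_real_ else dr$detected_pixels,
      red_area_mm2 = if (is.null(dr)) NA_real_ else dr$red_area_mm2,
      stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, rows)
  log_msg("stage measure: %d tooth measurements from %d images",
          nrow(measurements), length(unique(measurements$image_id)))

  cohort <- stage("read_cohort", read_cohort(cfg$cohort_csv))
  log_msg("stage read_cohort: %d subject rows", nrow(cohort))

  ex <- stage("exclusions", apply_exclusions(cohort))
  log_msg("stage exclusions: %d in, %d retained, %d excluded",
          nrow(cohort), nrow(ex$retained), nrow(ex$exclusions))

  summaries <- stage("summarize",
                     summarize_subjects(ex$retained, measurements))
  log_msg("stage summarize: %d subject summaries", nrow(summaries))

  tab1 <- stage("table1", build_table1(summaries))
  tab2 <- stage("table2",
                build_table2(summaries,
                             smoking_encoding = cfg$smoking_encoding))
  corr <- stage("correlation",
                pearson_r(summaries$mean_coverage_pct,
                          summaries$mean_delta_r_pct))
  log_msg("stage analyze: table1 %d rows, table2 %d rows, r = %.3f (n = %d)",
          nrow(tab1), nrow(tab2$table), corr$r, corr$n)

  wcsv <- function(d, f) utils::write.csv(d, file.path(cfg$out_dir, f),
                                          row.names = FALSE)
  wcsv(measurements, "measurements.csv")
  wcsv(summaries, "subject_summaries.csv")
  wcsv(ex$exclusions, "exclusions.csv")
  wcsv(tab1, "table1.csv")
  wcsv(tab2$table, "table2.csv")
  jsonlite::write_json(list(r = corr$r, n = corr$n),
                       file.path(cfg$out_dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(list(measurements = measurements, summaries = summaries,
                 exclusions = ex$exclusions, table1 = tab1,
                 table2 = tab2$table, fit = tab2$fit, correlation = corr,
                 out_dir = cfg$out_dir))
}
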