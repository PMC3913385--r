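# Synthetic QLF-like tooth images with ground-truth plaque masks, and
# cohorts with Table-1-like covariates plus a known logistic link from
# plaque coverage to case status. These generators stand in for the
# study's raw data, which were not deposited, so the whole pipeline can
# be exercised and benchmarked offline against known ground truth.

# Run expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Inverse-CDF draw from a normal truncated to [lo, hi]; deterministic in
# the RNG stream (one uniform per draw).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

.clamp8 <- function(x) {
  x <- round(x); x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Simulate a QLF-like tooth image with ground-truth plaque
#'
#' Renders an elliptical tooth of green-fluorescing enamel with a
#' contiguous plaque band at its gingival (lower) edge occupying a
#' controllable fraction of the tooth area; plaque pixels carry an
#' elevated red/green ratio. Optional Gaussian channel noise and a
#' horizontal interlacing artifact emulate the video-capture degradations
#' the analysis pipeline has to cope with. The exact plaque mask is
#' returned as ground truth, together with a polygonal tooth ROI
#' (inscribed in the tooth ellipse) and a plaque-free reference ellipse
#' in the enamel zone.
#'
#' Two usage modes: disclosed-style images use a strong plaque contrast
#' (`r_plaque` well above 1, default 1.8) so the integer ratio threshold
#' detects the band; undisclosed-style images instead set
#' `delta_r_target`, which places the plaque ratio at
#' `r_enamel * (1 + delta_r_target/100)` for red-fluorescence
#' quantification.
#'
#' @param width,height image dimensions in pixels (default 512 x 512).
#' @param plaque_fraction target areal fraction `f` of the tooth covered
#'   by the plaque band, in `[0, 1]`.
#' @param r_enamel enamel red/green ratio, `< 1` (default 0.6).
#' @param r_plaque plaque red/green ratio, `> r_enamel` (default 1.8).
#' @param delta_r_target optional percentage elevation of the plaque
#'   ratio over enamel; when given it overrides `r_plaque` and the plaque
#'   green level equals the enamel green level.
#' @param green_enamel,green_plaque green-channel levels (default 200 and
#'   120).
#' @param blue_level constant blue channel on the tooth (default 30).
#' @param noise_sd Gaussian channel noise standard deviation (default 0).
#' @param interlace_amplitude additive intensity offset applied to
#'   odd (zero-based) scan lines (default 0).
#' @param scattered place the plaque as random speckle over the tooth
#'   instead of a gingival band (default `FALSE`).
#' @param n_vertices vertices of the polygonal tooth ROI (default 64).
#' @param mm_per_pixel optional calibration carried into the image.
#' @param image_id identifier (default `"sim"`).
#' @param seed optional RNG seed; generation is deterministic given the
#'   seed.
#' @return list with `image` ([fluorescence_image()]), `roi`
#'   ([polygon_roi()]), `reference` ([ellipse_roi()]) and `truth`
#'   ([binary_mask()], the exact plaque mask).
#' @export
simulate_tooth_image <- function(width = 512, height = 512,
                                 plaque_fraction = 0.25,
                                 r_enamel = 0.6, r_plaque = 1.8,
                                 delta_r_target = NULL,
                                 green_enamel = 200, green_plaque = 120,
                                 blue_level = 30,
                                 noise_sd = 0, interlace_amplitude = 0,
                                 scattered = FALSE, n_vertices = 64,
                                 mm_per_pixel = NULL, image_id = "sim",
                                 seed = NULL) {
  if (plaque_fraction < 0 || plaque_fraction > 1)
    stop("plaque_fraction must be in [0, 1]")
  if (r_enamel >= 1) stop("enamel ratio must be < 1")
  if (!is.null(delta_r_target)) {
    r_plaque <- r_enamel * (1 + delta_r_target / 100)
    green_plaque <- green_enamel
  }
  if (noise_sd < 0) stop("noise sd must be >= 0")
  with_seed(seed, {
    cx <- width / 2; cy <- height / 2
    a <- 0.38 * width; b <- 0.44 * height
    tooth <- rasterize_ellipse(ellipse_roi(c(cx, cy), c(a, b)),
                               height, width)$pixels
    n_tooth <- sum(tooth)
    target <- round(plaque_fraction * n_tooth)
    plaque <- matrix(FALSE, height, width)
    if (target > 0) {
      if (scattered) {
        idx <- sample(which(tooth), target)
        plaque[idx] <- TRUE
      } else {
        # gingival band: fill rows from the bottom of the tooth until the
        # cumulative pixel count is as close as possible to the target
        per_row <- rowSums(tooth)
        cum <- cumsum(rev(per_row))     # from bottom row upward
        k <- which.min(abs(cum - target))
        if (cum[k] == 0) k <- 0
        if (k > 0) {
          rows <- seq(height - k + 1L, height)
          plaque[rows, ] <- tooth[rows, ]
        }
      }
    }
    r <- matrix(0, height, width); g <- r; bl <- r
    enamel <- tooth & !plaque
    g[enamel] <- green_enamel
    r[enamel] <- green_enamel * r_enamel
    g[plaque] <- green_plaque
    r[plaque] <- green_plaque * r_plaque
    bl[tooth] <- blue_level
    if (noise_sd > 0) {
      r <- r + stats::rnorm(length(r), 0, noise_sd)
      g <- g + stats::rnorm(length(g), 0, noise_sd)
      bl <- bl + stats::rnorm(length(bl), 0, noise_sd)
    }
    if (interlace_amplitude != 0) {
      odd <- seq(2L, height, by = 2L)
      r[odd, ] <- r[odd, ] + interlace_amplitude
      g[odd, ] <- g[odd, ] + interlace_amplitude
      bl[odd, ] <- bl[odd, ] + interlace_amplitude
    }
    px <- array(0L, dim = c(height, width, 3))
    px[, , 1] <- .clamp8(r); px[, , 2] <- .clamp8(g); px[, , 3] <- .clamp8(bl)
    img <- fluorescence_image(px, image_id = image_id,
                              mm_per_pixel = mm_per_pixel)
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    roi <- polygon_roi(cbind(cx + a * cos(theta), cy + b * sin(theta)),
                       tooth_id = "sim")
    reference <- ellipse_roi(c(cx, cy - 0.5 * b), c(0.22 * a, 0.12 * b))
    list(image = img, roi = roi, reference = reference,
         truth = binary_mask(plaque, origin_image_id = image_id))
  })
}

#' Default generative parameters for synthetic cohorts
#'
#' Case/control covariate moments (coverage, red-fluorescence elevation,
#' maternal age, BMI, smoking frequencies) calibrated to the antenatal
#' case-control cohort the package models (51 cases, 40 controls), the
#' coverage-to-delta-R link targeting a Pearson correlation of 0.55, the
#' logistic coefficients used for case assignment, and the
#' preterm-delivery model in which the probability of delivering before
#' 37 weeks increases with plaque coverage.
#'
#' @return a nested list of parameters; override individual entries and
#'   pass the result to [simulate_cohort()].
#' @export
cohort_sim_defaults <- function() {
  list(
    coverage = list(case = c(mean = 25.50, sd = 17.45),
                    control = c(mean = 20.58, sd = 14.39)),
    age = list(case = c(mean = 28.69, sd = 5.91),
               control = c(mean = 30.78, sd = 6.41)),
    bmi = list(case = c(mean = 26.05, sd = 5.29),
               control = c(mean = 26.21, sd = 5.32)),
    smoking = list(case = c(31, 5, 15) / 51, control = c(30, 4, 6) / 40),
    # delta_r = intercept + slope * coverage + N(0, sd); slope and sd are
    # chosen so the population coverage/delta-R correlation is 0.55 given
    # the truncated-mixture coverage sd (~14.3) and a delta-R sd of ~16.6
    delta_r_link = list(intercept = 50.2, slope = 0.6374, sd = 13.87,
                        target_r = 0.55),
    coefficients = list(intercept = -2.0, coverage = -0.042, delta_r = 0.036,
                        smoking = -0.822, bmi = 0.005, age = 0.030),
    preterm = list(intercept = -2.17, slope = 0.03,
                   bin_probs = c(extreme = 2, moderate = 3, mild = 11) / 16)
  )
}

.draw_group_covariates <- function(n, grp, par) {
  list(
    coverage = rtruncnorm(n, par$coverage[[grp]]["mean"],
                          par$coverage[[grp]]["sd"], 0, 100),
    age = rtruncnorm(n, par$age[[grp]]["mean"], par$age[[grp]]["sd"], 16, 48),
    bmi = rtruncnorm(n, par$bmi[[grp]]["mean"], par$bmi[[grp]]["sd"], 15, 50),
    smoking = sample(.smoking_levels, n, replace = TRUE,
                     prob = par$smoking[[grp]])
  )
}

.fdi_anterior <- c("13", "12", "11", "21", "22", "23",
                   "33", "32", "31", "41", "42", "43")

#' Simulate a case-control cohort with known generative structure
#'
#' Two assignment modes. `"by_group"` draws fixed numbers of cases and
#' controls with group-specific covariate distributions, mirroring the
#' observed cohort structure. `"logistic"` draws `n` subjects from pooled
#' covariate distributions and assigns case status by a Bernoulli draw
#' with logistic probability from the configured coefficients — the mode
#' to use for parameter-recovery and calibration studies, since the
#' generating coefficients are then the estimands.
#'
#' Red-fluorescence elevation is linked linearly to coverage with
#' Gaussian noise, targeting a configured population correlation.
#' Delivery gestation is drawn so the preterm (< 37 weeks) probability
#' increases with coverage. Per-tooth measurements (10--12 anterior
#' teeth, FDI 13--23 and 33--43) scatter around each subject's mean.
#'
#' @param n_case,n_control group sizes for `"by_group"` mode (defaults 51
#'   and 40).
#' @param n total subjects for `"logistic"` mode.
#' @param assignment `"by_group"` or `"logistic"`.
#' @param params generative parameters, see [cohort_sim_defaults()].
#' @param include_teeth also generate per-tooth measurement rows (default
#'   `TRUE`).
#' @param tooth_sd per-tooth scatter around the subject mean (default 8).
#' @param seed optional RNG seed; the output is deterministic given the
#'   seed.
#' @return list with `cohort` (subject rows in the cohort-CSV schema),
#'   `measurements` (per-tooth rows, or `NULL`) and `truth` (the
#'   subject-level generative coverage and delta-R values).
#' @export
simulate_cohort <- function(n_case = 51, n_control = 40, n = NULL,
                            assignment = c("by_group", "logistic"),
                            params = cohort_sim_defaults(),
                            include_teeth = TRUE, tooth_sd = 8,
                            seed = NULL) {
  assignment <- match.arg(assignment)
  with_seed(seed, {
    if (assignment == "by_group") {
      cs <- .draw_group_covariates(n_case, "case", params)
      ct <- .draw_group_covariates(n_control, "control", params)
      cov_pct <- c(cs$coverage, ct$coverage)
      age <- c(cs$age, ct$age)
      bmi <- c(cs$bmi, ct$bmi)
      smoking <- c(cs$smoking, ct$smoking)
      n_tot <- n_case + n_control
      lk <- params$delta_r_link
      dr <- lk$intercept + lk$slope * cov_pct +
        stats::rnorm(n_tot, 0, lk$sd)
      dr <- pmax(dr, 0)
      group <- rep(c("case", "control"), c(n_case, n_control))
    } else {
      if (is.null(n)) stop("logistic assignment needs n")
      n_tot <- n
      # pooled distributions: 51/40 mixture of the group parameters
      w <- c(51, 40) / 91
      pool <- function(p) c(mean = sum(w * c(p$case["mean"], p$control["mean"])),
                            sd = sqrt(sum(w * (c(p$case["sd"], p$control["sd"])^2 +
                                               c(p$case["mean"], p$control["mean"])^2)) -
                                      sum(w * c(p$case["mean"], p$control["mean"]))^2))
      pc <- pool(params$coverage); pa <- pool(params$age); pb <- pool(params$bmi)
      cov_pct <- rtruncnorm(n_tot, pc["mean"], pc["sd"], 0, 100)
      age <- rtruncnorm(n_tot, pa["mean"], pa["sd"], 16, 48)
      bmi <- rtruncnorm(n_tot, pb["mean"], pb["sd"], 15, 50)
      sp <- (51 * params$smoking$case + 40 * params$smoking$control) / 91
      smoking <- sample(.smoking_levels, n_tot, replace = TRUE, prob = sp)
      lk <- params$delta_r_link
      dr <- pmax(lk$intercept + lk$slope * cov_pct +
                   stats::rnorm(n_tot, 0, lk$sd), 0)
      cf <- params$coefficients
      eta <- cf$intercept + cf$coverage * cov_pct + cf$delta_r * dr +
        cf$smoking * encode_smoking(smoking) + cf$bmi * bmi + cf$age * age
      group <- ifelse(stats::runif(n_tot) < stats::plogis(eta),
                      "case", "control")
    }
    pre <- params$preterm
    p_pre <- stats::plogis(pre$intercept + pre$slope * cov_pct)
    preterm <- stats::runif(n_tot) < p_pre
    bin <- sample(names(pre$bin_probs), n_tot, replace = TRUE,
                  prob = pre$bin_probs)
    lo <- c(extreme = 24, moderate = 28, mild = 34)[bin]
    hi <- c(extreme = 28, moderate = 34, mild = 37)[bin]
    weeks <- ifelse(preterm, lo + stats::runif(n_tot) * (hi - lo),
                    37 + stats::runif(n_tot) * 5)
    n_teeth <- sample(10:12, n_tot, replace = TRUE, prob = c(0.08, 0.12, 0.80))
    cohort <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n_tot)),
      group = group,
      maternal_age = age,
      bmi = bmi,
      smoking = smoking,
      natural_anterior_teeth = n_teeth,
      antibiotics_recent = FALSE,
      visit_index = 1L,
      delivery_weeks = weeks,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(subject_id = cohort$subject_id,
                        coverage_pct = cov_pct, delta_r_pct = dr,
                        stringsAsFactors = FALSE)
    measurements <- NULL
    if (include_teeth) {
      idx <- rep(seq_len(n_tot), n_teeth)
      tooth_id <- unlist(lapply(n_teeth, function(k) .fdi_anterior[seq_len(k)]))
      m <- length(idx)
      measurements <- data.frame(
        subject_id = cohort$subject_id[idx],
        tooth_id = tooth_id,
        coverage_pct = pmin(pmax(cov_pct[idx] +
                                   stats::rnorm(m, 0, tooth_sd), 0), 100),
        delta_r_pct = pmax(dr[idx] + stats::rnorm(m, 0, tooth_sd), 0),
        stringsAsFactors = FALSE
      )
    }
    list(cohort = cohort, measurements = measurements, truth = truth)
  })
}

#' Build the recruitment-accounting cohort fixture
#'
#' A 109-subject synthetic cohort constructed to mirror the study's
#' recruitment accounting: 91 analyzable subjects (51 cases, 40
#' controls), 7 with fewer than 10 natural anterior teeth, 5 with recent
#' antibiotic use, 4 with missing BMI/smoking/age, and 2 who withdrew
#' before imaging. Running [apply_exclusions()] on it retains exactly the
#' 91 complete subjects.
#'
#' @param seed RNG seed (default 1).
#' @return list with `cohort` (109 rows, including a `withdrawn` column)
#'   and `measurements` (per-tooth rows for non-withdrawn subjects).
#' @export
make_accounting_cohort <- function(seed = 1) {
  with_seed(seed, {
    base <- simulate_cohort(n_case = 60, n_control = 49,
                            assignment = "by_group", include_teeth = TRUE)
    cohort <- base$cohort
    cohort$withdrawn <- FALSE
    # the 18 excluded subjects: 9 cases, 9 controls, spread over both groups
    case_idx <- which(cohort$group == "case")[1:9]
    ctrl_idx <- which(cohort$group == "control")[1:9]
    excl <- c(case_idx, ctrl_idx)
    few_teeth <- excl[1:7]
    antibiotics <- excl[8:12]
    missing_cov <- excl[13:16]
    withdrawn <- excl[17:18]
    cohort$natural_anterior_teeth[few_teeth] <-
      sample(4:9, 7, replace = TRUE)
    cohort$antibiotics_recent[antibiotics] <- TRUE
    cohort$bmi[missing_cov[1:2]] <- NA
    cohort$smoking[missing_cov[3]] <- NA
    cohort$maternal_age[missing_cov[4]] <- NA
    cohort$withdrawn[withdrawn] <- TRUE
    measurements <- base$measurements[
      !(base$measurements$subject_id %in% cohort$subject_id[withdrawn]), ]
    list(cohort = cohort, measurements = measurements)
  })
}

#' Render a measurement table as an image set on disk
#'
#' Writes one simulated disclosed-style tooth image per measurement row,
#' named `<subject_id>_<tooth_id>.png`, with the plaque band fraction set
#' to the row's coverage percentage, plus a single ROI JSON file holding
#' each image's tooth polygon and plaque-free reference ellipse.
#'
#' @param measurements data frame with `subject_id`, `tooth_id`,
#'   `coverage_pct` columns.
#' @param dir output directory (created if needed).
#' @param width,height image dimensions (small sizes keep rendering
#'   fast).
#' @param noise_sd,interlace_amplitude image degradations, see
#'   [simulate_tooth_image()].
#' @param seed RNG seed.
#' @return path of the ROI JSON file, invisibly.
#' @export
write_image_set <- function(measurements, dir, width = 96, height = 96,
                            noise_sd = 0, interlace_amplitude = 0,
                            seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rois <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(measurements))) {
      id <- paste0(measurements$subject_id[i], "_", measurements$tooth_id[i])
      # modulate the plaque contrast with the row's delta-R value (when
      # present) so the rendered images carry between-tooth variation in
      # red-fluorescence elevation, not just in coverage; the contrast is
      # kept well above 1 so the disclosed-plaque threshold still fires
      r_plq <- if ("delta_r_pct" %in% names(measurements))
        min(max(1.5 + measurements$delta_r_pct[i] / 200, 1.2), 2.1) else 1.8
      sim <- simulate_tooth_image(
        width = width, height = height,
        plaque_fraction = measurements$coverage_pct[i] / 100,
        r_plaque = r_plq,
        noise_sd = noise_sd, interlace_amplitude = interlace_amplitude,
        image_id = id)
      write_image(sim$image, file.path(dir, paste0(id, ".png")))
      sim$roi$tooth_id <- measurements$tooth_id[i]
      rois[[length(rois) + 1L]] <- list(image_id = id,
                                        tooth_id = measurements$tooth_id[i],
                                        roi = sim$roi)
      rois[[length(rois) + 1L]] <- list(image_id = id,
                                        tooth_id = measurements$tooth_id[i],
                                        roi = sim$reference)
    }
  })
  path <- file.path(dir, "rois.json")
  write_rois(rois, path)
  invisible(path)
}
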