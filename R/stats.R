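# Case-control statistical battery: pooled two-sample t-tests (raw or
# summary input), chi-squared tests, Pearson correlation, multiple
# logistic regression with Wald odds ratios, and the report tables.

#' Student's pooled-variance two-sample t-test
#'
#' Two-sided pooled-variance t-test, accepting either raw samples (`x`,
#' `y`) or published summary statistics (`mean1`, `sd1`, `n1`, ...), so
#' printed group summaries can be re-tested without the raw data.
#'
#' @param x,y optional raw numeric samples; when supplied their summary
#'   statistics are computed internally and the remaining arguments are
#'   ignored.
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t_statistic`, `df` (`n1 + n2 - 2`) and `p_value`.
#' @export
t_test_two_sample <- function(x = NULL, y = NULL,
                              mean1 = NULL, sd1 = NULL, n1 = NULL,
                              mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("both raw samples x and y are needed")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (any(vapply(list(mean1, sd1, n1, mean2, sd2, n2), is.null, logical(1))))
    stop("supply either raw samples or all six summary statistics")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      warning("both groups are constant and equal; p set to 1")
      return(list(t_statistic = 0, df = df, p_value = 1))
    }
    stop("zero pooled variance with unequal means")
  }
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t_statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson's chi-squared test of independence without continuity
#' correction, with `df = (rows - 1)(cols - 1)`.
#'
#' @param table numeric matrix of non-negative counts with at least two
#'   non-empty rows and columns.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero marginal")
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2 x 2 table")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length `>= 3` with non-zero
#'   variance.
#' @return list with `r` in `[-1, 1]` and `n`, the number of pairs.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance")
  list(r = stats::cor(x, y), n = length(x))
}

#' Multiple logistic regression with Wald odds ratios
#'
#' Maximum-likelihood logistic fit (binomial IRLS) of a binary outcome on
#' the supplied predictor columns, intercept included. Wald standard
#' errors come from the inverse observed information; per predictor the
#' odds ratio is `exp(beta)` with normal-approximation 95% CI
#' `exp(beta +/- 1.96 se)` and two-sided Wald p from the standard normal.
#'
#' @param outcome binary vector (0/1, logical, or a factor whose second
#'   level is the event).
#' @param predictors data frame of numeric predictor columns.
#' @return object of class `logistic_fit`: list with `coefficients` (data
#'   frame: `term`, `beta`, `std_error`, `wald_p`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`), `n`, `converged`, `log_likelihood`,
#'   `outcome_name`.
#' @export
logistic_fit <- function(outcome, predictors) {
  outcome_name <- deparse(substitute(outcome))
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(unique(outcome)) < 2)
    stop("outcome has a single class; nothing to model")
  predictors <- as.data.frame(predictors)
  n <- length(outcome)
  if (nrow(predictors) != n) stop("outcome and predictors disagree in length")
  if (n <= ncol(predictors) + 1)
    stop("need n greater than number of predictors + 1")
  dat <- cbind(.y = outcome, predictors)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  # a boundary warning alone is not separation; require diverged estimates
  diverged <- warned_sep && (max(abs(co[-1, 1])) > 10 || max(co[, 2]) > 50)
  if (diverged || !fit$converged) {
    sep_term <- rownames(co)[-1][which.max(abs(co[-1, 1]))]
    stop("logistic fit did not converge (possible complete separation in '",
         sep_term, "')")
  }
  beta <- co[, 1]; se <- co[, 2]
  res <- data.frame(
    term = rownames(co),
    beta = beta,
    std_error = se,
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    odds_ratio = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = res, n = n, converged = fit$converged,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 outcome_name = outcome_name),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d, logLik = %.3f)\n",
              x$n, x$log_likelihood))
  print(cbind(term = x$coefficients$term,
              round(x$coefficients[, -1], 3)), row.names = FALSE)
  invisible(x)
}

#' Encode smoking status as a model covariate
#'
#' `"ordinal"` (default) codes nonsmoker/stopped/smoker as 0/1/2, giving
#' smoking a single degree of freedom in the model; `"binary"` codes any
#' smoking during pregnancy as 1.
#'
#' @param smoking character vector with levels `nonsmoker`, `stopped`,
#'   `smoker`.
#' @param encoding `"ordinal"` or `"binary"`.
#' @return numeric vector.
#' @export
encode_smoking <- function(smoking, encoding = c("ordinal", "binary")) {
  encoding <- match.arg(encoding)
  code <- match(smoking, .smoking_levels) - 1L
  if (anyNA(code[!is.na(smoking)]))
    stop("unknown smoking level(s)")
  if (encoding == "binary") as.numeric(code == 2L) else as.numeric(code)
}

#' Relative difference between two group means
#'
#' The percentage difference between group means, expressed relative to
#' the larger of the two means.
#'
#' @param m1,m2 group means.
#' @return percentage in `[0, 100]` for same-signed positive means.
#' @export
group_difference_pct <- function(m1, m2) {
  100 * abs(m1 - m2) / max(m1, m2)
}

.tab1_cont <- function(variable, x_case, x_ctrl, digits = 2) {
  tt <- t_test_two_sample(x = x_case, y = x_ctrl)
  data.frame(variable = variable, level = NA_character_,
             case_mean = round(mean(x_case), digits),
             case_sd = round(stats::sd(x_case), digits),
             case_n = NA_real_, case_pct = NA_real_,
             control_mean = round(mean(x_ctrl), digits),
             control_sd = round(stats::sd(x_ctrl), digits),
             control_n = NA_real_, control_pct = NA_real_,
             p_value = round(tt$p_value, 3), test = "t",
             stringsAsFactors = FALSE)
}

.tab1_cat <- function(variable, f_case, f_ctrl, test_p = TRUE) {
  lev <- levels(f_case)
  nc <- as.numeric(table(f_case)); nk <- as.numeric(table(f_ctrl))
  p <- if (test_p) {
    tab <- rbind(nc, nk)
    keep <- colSums(tab) > 0
    # degenerate tables (a single populated category or group) carry no test
    tryCatch(round(chi_squared_test(tab[, keep, drop = FALSE])$p_value, 3),
             error = function(e) NA_real_)
  } else NA_real_
  data.frame(variable = variable, level = lev,
             case_mean = NA_real_, case_sd = NA_real_,
             case_n = nc, case_pct = round(100 * nc / sum(nc)),
             control_mean = NA_real_, control_sd = NA_real_,
             control_n = nk, control_pct = round(100 * nk / sum(nk)),
             p_value = c(p, rep(NA_real_, length(lev) - 1)),
             test = "chi_squared", stringsAsFactors = FALSE)
}

#' Build the case-vs-control characteristics table
#'
#' Summarises a cohort of subject summaries by group: continuous
#' variables as mean (sd) with a pooled t-test p-value; categorical
#' variables as n (%) with a Pearson chi-squared p-value (no continuity
#' correction). Covers mean plaque coverage, mean red-fluorescence
#' elevation, maternal age (continuous and by the 35-year cut), smoking
#' status, BMI (continuous and by the under/normal/overweight cuts) and
#' the delivery-outcome bins (tabulated without a test; unknown outcomes
#' are dropped from that tabulation). Means and sds are rounded to 2 dp,
#' p-values to 3 dp, percentages to whole percent.
#'
#' @param summaries data frame from [summarize_subjects()].
#' @return a data frame, one row per variable (or per category level).
#' @export
build_table1 <- function(summaries) {
  if (!all(c("case", "control") %in% summaries$group))
    stop("both case and control groups are required")
  cs <- summaries[summaries$group == "case", ]
  ct <- summaries[summaries$group == "control", ]
  age_cut <- function(a) factor(ifelse(a <= 35, "<=35", ">35"),
                                levels = c("<=35", ">35"))
  bmi_cut <- function(b) factor(ifelse(b < 19, "underweight",
                                ifelse(b <= 25, "normal", "overweight")),
                                levels = c("underweight", "normal", "overweight"))
  smoke <- function(s) factor(s, levels = .smoking_levels)
  deliv <- function(w) {
    f <- classify_delivery(w)
    factor(as.character(f[f != "unknown"]),
           levels = c("extreme", "moderate", "mild", "term"))
  }
  rbind(
    .tab1_cont("mean_plaque_coverage_pct", cs$mean_coverage_pct,
               ct$mean_coverage_pct),
    .tab1_cont("mean_red_fluorescence_delta_r_pct", cs$mean_delta_r_pct,
               ct$mean_delta_r_pct),
    .tab1_cont("maternal_age_years", cs$maternal_age, ct$maternal_age),
    .tab1_cat("maternal_age_group", age_cut(cs$maternal_age),
              age_cut(ct$maternal_age)),
    .tab1_cat("smoking_status", smoke(cs$smoking), smoke(ct$smoking)),
    .tab1_cont("bmi_pre_pregnancy", cs$bmi, ct$bmi),
    .tab1_cat("bmi_group", bmi_cut(cs$bmi), bmi_cut(ct$bmi)),
    .tab1_cat("delivery_outcome", deliv(cs$delivery_weeks),
              deliv(ct$delivery_weeks), test_p = FALSE)
  )
}

#' Fit and tabulate the case-control logistic model
#'
#' Multiple logistic regression of case/control status on mean plaque
#' coverage and mean red-fluorescence elevation, controlling for smoking,
#' pre-pregnancy BMI and maternal age. Returns the coefficient table
#' (intercept dropped) with odds ratios and 95% Wald CIs, rounded to 3 dp.
#'
#' @param summaries data frame from [summarize_subjects()].
#' @param smoking_encoding see [encode_smoking()].
#' @return list with `table` (rounded data frame) and `fit` (the full
#'   [logistic_fit()] object).
#' @export
build_table2 <- function(summaries, smoking_encoding = "ordinal") {
  outcome <- as.numeric(summaries$group == "case")
  preds <- data.frame(
    plaque_coverage = summaries$mean_coverage_pct,
    red_fluorescence = summaries$mean_delta_r_pct,
    smoking = encode_smoking(summaries$smoking, smoking_encoding),
    bmi = summaries$bmi,
    maternal_age = summaries$maternal_age
  )
  fit <- logistic_fit(outcome, preds)
  tab <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  tab[, -1] <- round(tab[, -1], 3)
  rownames(tab) <- NULL
  list(table = tab, fit = fit)
}
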