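test_that("summary-statistic t-test matches t.test on the raw data", {
  set.seed(61)
  for (rep in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ours <- t_test_two_sample(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                              mean2 = mean(y), sd2 = sd(y), n2 = length(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    raw <- t_test_two_sample(x = x, y = y)
    expect_equal(raw$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("t-test p-value agrees with numerical integration of the t density", {
  tt <- t_test_two_sample(mean1 = 25.50, sd1 = 17.45, n1 = 51,
                          mean2 = 20.58, sd2 = 14.39, n2 = 40)
  tail <- integrate(function(u) dt(u, tt$df), abs(tt$t_statistic), Inf,
                    rel.tol = 1e-12)$value
  expect_equal(tt$p_value, 2 * tail, tolerance = 1e-6)
})

test_that("t-test degenerate and error cases behave as documented", {
  expect_warning(res <- t_test_two_sample(mean1 = 3, sd1 = 0, n1 = 5,
                                          mean2 = 3, sd2 = 0, n2 = 5),
                 "constant")
  expect_equal(res$p_value, 1)
  expect_equal(res$t_statistic, 0)
  expect_error(t_test_two_sample(mean1 = 1, sd1 = 1, n1 = 1,
                                 mean2 = 2, sd2 = 1, n2 = 5), "n >= 2")
  # identical groups: t = 0, p = 1
  eq <- t_test_two_sample(mean1 = 5, sd1 = 2, n1 = 10,
                          mean2 = 5, sd2 = 2, n2 = 10)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
})

test_that("chi-squared matches the brute-force expected-count formula", {
  set.seed(62)
  for (rep in 1:10) {
    tab <- matrix(sample(5:60, 6, TRUE), 2, 3)
    got <- chi_squared_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$df, 2)
    tail <- integrate(function(u) dchisq(u, 2), stat, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(got$p_value, tail, tolerance = 1e-6)
  }
})

test_that("chi-squared degenerate and error cases", {
  # identical row proportions -> statistic 0, p 1
  same <- chi_squared_test(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(chi_squared_test(rbind(c(0, 0), c(3, 4))), "zero marginal")
  expect_error(chi_squared_test(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("Pearson correlation matches direct summation", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  set.seed(63)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  got <- pearson_r(x, y)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, num / den, tolerance = 1e-12)
  expect_equal(got$n, 40L)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("logistic fit satisfies the odds-ratio/CI identities", {
  sim <- simulate_cohort(n = 400, assignment = "logistic", seed = 64,
                         include_teeth = FALSE)
  fit <- logistic_fit(as.numeric(sim$cohort$group == "case"),
                      data.frame(coverage = sim$truth$coverage_pct,
                                 bmi = sim$cohort$bmi,
                                 age = sim$cohort$maternal_age))
  co <- fit$coefficients
  expect_equal(co$odds_ratio, exp(co$beta), tolerance = 1e-12)
  expect_equal(co$ci_lower, exp(co$beta - 1.96 * co$std_error),
               tolerance = 1e-12)
  expect_equal(co$ci_upper, exp(co$beta + 1.96 * co$std_error),
               tolerance = 1e-12)
  expect_true(all(co$ci_lower <= co$odds_ratio & co$odds_ratio <= co$ci_upper))
  expect_equal(co$wald_p, 2 * pnorm(-abs(co$beta / co$std_error)),
               tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("logistic fit agrees with direct likelihood maximisation", {
  set.seed(65)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.4 * x2))
  fit <- logistic_fit(y, data.frame(x1 = x1, x2 = x2))
  # independent oracle: minimise the negative log-likelihood numerically
  nll <- function(b) {
    eta <- b[1] + b[2] * x1 + b[3] * x2
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14))
  expect_equal(fit$coefficients$beta, unname(opt$par), tolerance = 1e-4)
  se_oracle <- sqrt(diag(solve(opt$hessian)))
  expect_equal(fit$coefficients$std_error, unname(se_oracle),
               tolerance = 1e-3)
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-6)
})

test_that("logistic fit rejects separation and degenerate outcomes", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_error(logistic_fit(y, data.frame(x = x)), "separation")
  expect_error(logistic_fit(rep(1, 30), data.frame(x = rnorm(30))),
               "single class")
  expect_error(logistic_fit(rep(c(0, 1), 2), data.frame(a = rnorm(4),
                                                        b = rnorm(4),
                                                        c = rnorm(4))),
               "number of predictors")
})

test_that("relative group difference is taken against the larger mean", {
  expect_equal(group_difference_pct(10, 8), 20)
  expect_equal(group_difference_pct(8, 10), 20)
  expect_equal(group_difference_pct(5, 5), 0)
})

test_that("the characteristics table is well formed on a simulated cohort", {
  sim <- simulate_cohort(seed = 66)
  s <- summarize_subjects(sim$cohort, sim$measurements)
  tab <- build_table1(s)
  expect_true(all(c("mean_plaque_coverage_pct", "smoking_status",
                    "delivery_outcome") %in% tab$variable))
  # group percentages within each categorical variable sum to 100 +/- 1
  for (v in unique(tab$variable[tab$test == "chi_squared"])) {
    rows <- tab[tab$variable == v, ]
    expect_lte(abs(sum(rows$case_pct) - 100), 1)
    expect_lte(abs(sum(rows$control_pct) - 100), 1)
  }
  # continuous rows carry a pooled t p-value in [0, 1]
  cont <- tab[tab$test == "t", ]
  expect_true(all(cont$p_value >= 0 & cont$p_value <= 1))
  # delivery outcome is tabulated without a test
  expect_true(all(is.na(tab$p_value[tab$variable == "delivery_outcome"])))

  tab2 <- build_table2(s)
  expect_equal(tab2$table$term,
               c("plaque_coverage", "red_fluorescence", "smoking", "bmi",
                 "maternal_age"))
  expect_equal(tab2$table$odds_ratio, round(exp(tab2$fit$coefficients$beta[-1]), 3))
})
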