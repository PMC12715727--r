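test_that("prevalence with Wilson intervals matches the reference", {
  m <- matrix(0L, 100, 7, dimnames = list(NULL, hrb_behaviors()))
  m[1:50, 1] <- 1L
  m[, 2] <- 1L
  pv <- prevalence(m)
  expect_equal(pv$proportion[1], 0.5)
  # independent oracle: prop.test without continuity correction is Wilson
  ref <- stats::prop.test(50, 100, correct = FALSE)$conf.int
  expect_equal(pv$ci_low[1], ref[1], tolerance = 1e-10)
  expect_equal(pv$ci_high[1], ref[2], tolerance = 1e-10)
  expect_equal(round(pv$ci_low[1], 3), 0.404)
  expect_equal(round(pv$ci_high[1], 3), 0.596)
  expect_equal(pv$proportion[2], 1)
  expect_equal(pv$ci_high[2], 1)
  expect_equal(pv$rank[2], 1L)
  expect_true(all(prevalence(matrix(0L, 5, 7))$proportion == 0))
})

test_that("Wilson CI contains the estimate and narrows with N", {
  widths <- vapply(c(1e2, 1e4, 1e6), function(N) {
    ci <- hrbnet:::wilson_ci(round(0.3 * N), N)
    expect_true(ci["low"] <= 0.3 && 0.3 <= ci["high"])
    unname(diff(ci))
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("Spearman rho handles ties like the midrank oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x^3)$rho, -1)
  for (s in 1:10) {
    set.seed(s)
    n <- sample(4:8, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_correlation(a, b)$rho,
                 suppressWarnings(cor(a, b, method = "spearman")))
  }
  # invariance under strictly monotone transforms
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_correlation(a, b)$rho,
               spearman_correlation(exp(a), 2 * b + 1)$rho)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Spearman p-value matches the t approximation", {
  set.seed(7)
  x <- rnorm(40); y <- x + rnorm(40)
  res <- spearman_correlation(x, y)
  tstat <- res$rho * sqrt(38 / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 38))
})

test_that("logistic fit agrees with an independent convex minimizer", {
  set.seed(11)
  tab <- generate_survey_table(synthetic_config(n_records = 400, seed = 31))
  y <- as.integer(attr(tab, "behavior_count") >= 2)
  fit <- fit_cooccurrence_logistic(tab, y)
  d <- data.frame(
    y = y,
    gender = factor(tab$gender, levels = c("male", "female")),
    age_decade = tab$age / 10,
    education = hrbnet:::education_band(tab$education_years),
    residence = factor(tab$residence, levels = c("city", "town", "rural")),
    co_residence = factor(tab$co_residence,
                          levels = c("household", "alone", "institution")),
    economic_status = factor(tab$economic_status,
                             levels = c("very_poor", "poor", "so_so",
                                        "rich", "very_rich")))
  Xm <- stats::model.matrix(~ gender + age_decade + education + residence +
                              co_residence + economic_status, d)
  nll <- function(beta) {
    eta <- drop(Xm %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(beta) {
    mu <- plogis(drop(Xm %*% beta))
    drop(crossprod(Xm, mu - y))
  }
  ref <- stats::optim(rep(0, ncol(Xm)), nll, gr, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(fit$coefficients - ref$par)), 1e-6)
})

test_that("null covariates get OR near 1 with CI covering 1", {
  set.seed(13)
  n <- 6000
  cov <- data.frame(
    gender = sample(c("male", "female"), n, replace = TRUE),
    age = sample(65:100, n, replace = TRUE),
    residence = sample(c("city", "town", "rural"), n, replace = TRUE),
    education_years = sample(0:12, n, replace = TRUE),
    co_residence = sample(c("household", "alone"), n, replace = TRUE),
    economic_status = sample(c("very_poor", "poor", "so_so", "rich"),
                             n, replace = TRUE))
  y <- rbinom(n, 1, 0.5)  # independent of everything
  fit <- fit_cooccurrence_logistic(cov, y)
  fem <- fit$terms[fit$terms$variable == "gender" &
                     fit$terms$level == "female", ]
  expect_lt(abs(fem$or - 1), 0.15)
  expect_true(fem$ci_low <= 1 && 1 <= fem$ci_high)
  expect_true(fit$converged)
  # reference rows are flagged with OR fixed at 1
  refs <- fit$terms[fit$terms$reference, ]
  expect_true(all(refs$or == 1))
  expect_equal(refs$level,
               c("male", "0", "city", "household", "very_poor"))
})

test_that("complete separation is detected and named", {
  set.seed(17)
  n <- 300
  cov <- data.frame(
    gender = sample(c("male", "female"), n, replace = TRUE),
    age = sample(65:90, n, replace = TRUE),
    residence = sample(c("city", "town"), n, replace = TRUE),
    education_years = sample(0:8, n, replace = TRUE),
    co_residence = sample(c("household", "alone"), n, replace = TRUE),
    economic_status = sample(c("poor", "so_so"), n, replace = TRUE))
  y <- as.integer(cov$gender == "female")  # perfectly separated by gender
  expect_error(suppressWarnings(fit_cooccurrence_logistic(cov, y)),
               "separation.*gender")
})

test_that("mode imputation fills only the imputable demographics", {
  tab <- generate_survey_table(
    synthetic_config(n_records = 800, mcar_rate = 0.15, seed = 19))
  y <- as.integer(attr(tab, "behavior_count") >= 2)
  fit_cc <- fit_cooccurrence_logistic(tab, y)
  fit_mi <- fit_cooccurrence_logistic(tab, y, mode_impute = TRUE)
  expect_gt(fit_cc$n_dropped, 0)
  expect_equal(fit_mi$n_dropped, 0)
  expect_equal(fit_mi$n_used, 800)
})
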