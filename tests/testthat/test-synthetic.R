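test_that("threshold calibration hits target marginals", {
  # with W = 0 the solution is the logit, reached in one step
  tgt <- c(0.2, 0.5, 0.8)
  par0 <- calibrate_thresholds(matrix(0, 3, 3), tgt)
  expect_equal(par0$tau, stats::qlogis(tgt), tolerance = 1e-8)
  # with couplings, calibrated marginals still match
  ip <- two_block_ising()
  m <- hrbnet:::pmf_marginals(enumerate_joint_pmf(ip))
  expect_equal(unname(m), unname(default_prevalence()), tolerance = 1e-8)
  expect_error(calibrate_thresholds(matrix(0, 2, 2), c(0, 0.5)),
               "strictly in")
})

test_that("planted two-block structure has the right support", {
  ip <- two_block_ising()
  b <- planted_blocks()
  W <- ip$W
  expect_equal(W, t(W))
  for (pr in combn(b$addictive, 2, simplify = FALSE))
    expect_equal(W[pr[1], pr[2]], 1.2)
  for (pr in combn(b$lifestyle, 2, simplify = FALSE))
    expect_equal(W[pr[1], pr[2]], 1.0)
  expect_true(all(W[b$addictive, b$lifestyle] == 0))
})

test_that("config validation rejects malformed distributions", {
  cd <- default_covariate_distributions()
  cd$gender <- c(male = 0.7, female = 0.7)
  expect_error(synthetic_config(covariate_distributions = cd), "sums to")
  expect_error(synthetic_config(n_records = 0), "n_records")
})

test_that("round trip: coding the emitted raw fields recovers the matrix", {
  cfg <- synthetic_config(n_records = 400, seed = 21)
  tab <- generate_survey_table(cfg)
  coded <- code_behaviors(tab)
  expect_equal(unname(coded), unname(attr(tab, "behaviors")))
  # indicator consistency with the conditional count sampling
  expect_equal(as.integer(attr(tab, "behavior_count") >= 2),
               as.integer(attr(tab, "indicator")))
  # determinism
  tab2 <- generate_survey_table(cfg)
  expect_identical(tab, tab2)
})

test_that("generated covariates respect their vocabularies", {
  tab <- generate_survey_table(synthetic_config(n_records = 300, seed = 5))
  expect_true(all(tab$gender %in% c("male", "female")))
  expect_true(all(tab$age >= 65))
  expect_true(all(tab$residence %in% c("city", "town", "rural")))
  expect_true(all(tab$economic_status %in%
                    c("very_poor", "poor", "so_so", "rich", "very_rich")))
  expect_true(all(tab$qol_rating %in% LETTERS[1:5]))
  v <- apply_exclusions(tab)
  expect_equal(nrow(v$table), 300)  # generator output passes exclusions
})

test_that("intercept-only effects give the analytic >=2 rate", {
  # logistic(log 1.78) = 1.78 / 2.78
  eff <- default_cooccurrence_log_odds()
  eff$female <- 0; eff$age_per_decade <- 0
  eff$education[] <- 0; eff$residence[] <- 0
  eff$co_residence[] <- 0; eff$economic_status[] <- 0
  tab <- generate_survey_table(
    synthetic_config(n_records = 20000, cooccurrence_log_odds = eff,
                     seed = 8))
  expect_equal(mean(attr(tab, "indicator")), 1.78 / 2.78, tolerance = 0.012)
})

test_that("outcome link strength zero removes the count-outcome link", {
  tab <- generate_survey_table(
    synthetic_config(n_records = 20000, outcome_link_strength = 0, seed = 9))
  sc <- score_outcomes(tab)
  rho <- spearman_correlation(attr(tab, "behavior_count"), sc$qol_score)$rho
  expect_lt(abs(rho), 0.02)
})

test_that("default link strength yields Spearman near -0.17", {
  tab <- generate_survey_table(synthetic_config(n_records = 30000, seed = 10))
  sc <- score_outcomes(tab)
  rho <- spearman_correlation(attr(tab, "behavior_count"), sc$qol_score)$rho
  expect_lt(abs(rho - (-0.17)), 0.025)
})

test_that("MCAR mask only touches the imputable demographics", {
  tab <- generate_survey_table(
    synthetic_config(n_records = 500, mcar_rate = 0.2, seed = 12))
  expect_gt(sum(is.na(tab$education_years)), 0)
  expect_false(anyNA(tab$gender))
  expect_false(anyNA(tab$sleep_hours))
})

test_that("pathological parameters that empty a stratum raise an error", {
  ip <- ising_parameters(rep(-800, 7), matrix(0, 7, 7))
  expect_error(generate_survey_table(
    synthetic_config(n_records = 10, ising = ip, seed = 1)),
    "empty stratum")
})

test_that("write_survey produces a readable CSV and provenance sidecar", {
  cfg <- synthetic_config(n_records = 50, seed = 2)
  tab <- generate_survey_table(cfg)
  path <- file.path(tempdir(), "surv.csv")
  write_survey(tab, path, cfg)
  back <- read_survey(path)
  expect_equal(nrow(back), 50)
  expect_equal(back$gender, tab$gender)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 2)
  expect_equal(side$n_records, 50)
})
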