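#' Calibrate Ising thresholds to target marginal prevalences
#'
#' Solves for node thresholds tau such that the enumerated Ising model with
#' coupling matrix `W` has the requested marginal prevalences. Uses Newton's
#' method on the exact (enumerated) likelihood: the Jacobian of the marginal
#' map is the model covariance matrix of the states, which is positive
#' definite for finite parameters, so the iteration converges quickly at
#' p = 7.
#'
#' @param W Symmetric coupling matrix, zero diagonal.
#' @param target_marginals Vector of desired P(x_i = 1), each in (0, 1).
#' @param tol Convergence tolerance on the marginals (max abs error).
#' @param max_iter Maximum Newton iterations.
#' @return An [ising_parameters()] object whose enumerated marginals match
#'   `target_marginals` within `tol`.
#' @export
calibrate_thresholds <- function(W, target_marginals, tol = 1e-10,
                                 max_iter = 100) {
  p <- length(target_marginals)
  if (any(target_marginals <= 0 | target_marginals >= 1))
    stop("target marginals must lie strictly in (0, 1)")
  tau <- stats::qlogis(target_marginals)  # exact when W = 0
  for (it in seq_len(max_iter)) {
    params <- ising_parameters(tau, W)
    pmf <- enumerate_joint_pmf(params)
    m <- pmf_marginals(pmf)
    err <- m - target_marginals
    if (max(abs(err)) < tol) return(params)
    exx <- crossprod(pmf$states, pmf$states * pmf$probs)
    jac <- exx - tcrossprod(m)  # Cov(x) under the model
    step <- solve(jac + diag(1e-12, p), err)
    # damped step guards against overshoot at strong couplings
    step <- pmin(pmax(step, -4), 4)
    tau <- tau - step
  }
  stop("threshold calibration did not converge in ", max_iter, " iterations")
}

#' Two-block planted Ising parameters
#'
#' Constructs the package's canonical planted network: a positive clique on
#' the "addictive" behaviors \{salty diet, smoking, drinking\} (columns
#' 3, 4, 5) and a second positive block on the "activity-eating" behaviors
#' \{fruit, vegetable, exercise, sleep\} (columns 1, 2, 6, 7), with no
#' cross-block couplings. Thresholds are calibrated so marginal prevalences
#' equal `target_prevalence`.
#'
#' @param w_addictive Coupling weight on every within-block pair of the
#'   addictive clique.
#' @param w_lifestyle Coupling weight on every within-block pair of the
#'   activity-eating block.
#' @param target_prevalence Length-7 marginal prevalences in canonical
#'   column order.
#' @return An [ising_parameters()] object.
#' @export
two_block_ising <- function(w_addictive = 1.2, w_lifestyle = 1.0,
                            target_prevalence = default_prevalence()) {
  blocks <- planted_blocks()
  W <- matrix(0, 7, 7, dimnames = list(hrb_behaviors(), hrb_behaviors()))
  for (pr in combn(blocks$addictive, 2, simplify = FALSE))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- w_addictive
  for (pr in combn(blocks$lifestyle, 2, simplify = FALSE))
    W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- w_lifestyle
  calibrate_thresholds(W, target_prevalence)
}

#' @rdname two_block_ising
#' @export
planted_blocks <- function() {
  list(addictive = c(3L, 4L, 5L), lifestyle = c(1L, 2L, 6L, 7L))
}

#' Default marginal prevalences for the synthetic generator
#'
#' Spans roughly 0.1-0.75 with irregular exercise the most prevalent
#' behavior and insufficient vegetable intake the least, the ordering
#' reported for Chinese older adults.
#'
#' @return Named length-7 vector of prevalences.
#' @export
default_prevalence <- function() {
  setNames(c(0.45, 0.10, 0.15, 0.20, 0.18, 0.75, 0.30), hrb_behaviors())
}

#' Default covariate category distributions
#'
#' Frequencies of the demographic categories among community-dwelling
#' Chinese older adults (complete cases), used by [generate_survey_table()].
#'
#' @return Named list of probability vectors (each sums to 1).
#' @export
default_covariate_distributions <- function() {
  list(
    gender = c(male = 0.4615, female = 0.5385),
    age_band = c("65-74" = 0.2370, "75-84" = 0.2905,
                 "85-94" = 0.2504, "95+" = 0.2221),
    residence = c(city = 0.2236, town = 0.3339, rural = 0.4425),
    education_band = c("0" = 0.4713, "1-6" = 0.3318, "7-9" = 0.1014,
                       "10-12" = 0.0595, "13+" = 0.0360),
    co_residence = c(household = 0.8059, alone = 0.1636, institution = 0.0305),
    economic_status = c(very_poor = 0.0126, poor = 0.0885, so_so = 0.7006,
                        rich = 0.1721, very_rich = 0.0262)
  )
}

#' Default planted co-occurrence effects (log-odds scale)
#'
#' Per-level log odds ratios for the probability that a record carries two
#' or more risk behaviors, relative to reference levels male / age 0 /
#' education 0 years / city / living with household members / very poor.
#' The default values are the planted truths the parameter-recovery tests
#' fit back.
#'
#' @return Named list: `intercept` (log odds at all references) plus
#'   per-covariate named log-OR vectors.
#' @export
default_cooccurrence_log_odds <- function() {
  list(
    intercept = log(1.78),
    female = log(1.86),
    age_per_decade = log(1.15),
    education = c("1-6" = log(0.79), "7-9" = log(0.67),
                  "10-12" = log(0.51), "13+" = log(0.46)),
    residence = c(town = log(2.30), rural = log(2.42)),
    co_residence = c(alone = log(1.18), institution = log(0.96)),
    economic_status = c(poor = log(0.74), so_so = log(0.35),
                        rich = log(0.21), very_rich = log(0.22))
  )
}

#' Synthetic survey configuration
#'
#' Bundles everything [generate_survey_table()] needs: sample size, the
#' Ising model for the 7 behaviors, covariate category distributions, the
#' planted log-odds model of the ">= 2 behaviors" indicator, the strength of
#' the negative association between behavior count and the two ordinal
#' self-rated outcomes, and the seed.
#'
#' `outcome_link_strength` is the loading of behavior count on the latent
#' continuous outcome score (latent = -strength * count + N(0,1) noise,
#' then cut into 5 levels). The default 0.15 was calibrated once so the
#' generated Spearman correlation between count and outcome score is about
#' -0.17 at large n under the default Ising parameters.
#'
#' @param n_records Number of records (>= 1).
#' @param ising An [ising_parameters()] object for the 7 behaviors.
#' @param covariate_distributions See [default_covariate_distributions()].
#' @param cooccurrence_log_odds See [default_cooccurrence_log_odds()].
#' @param outcome_link_strength Non-negative real.
#' @param mcar_rate Missing-completely-at-random rate applied to the three
#'   imputable demographics (education, co-residence, economic status).
#' @param seed Integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 1000,
                             ising = two_block_ising(),
                             covariate_distributions =
                               default_covariate_distributions(),
                             cooccurrence_log_odds =
                               default_cooccurrence_log_odds(),
                             outcome_link_strength = 0.15,
                             mcar_rate = 0,
                             seed = 1L) {
  stopifnot(n_records >= 1, outcome_link_strength >= 0,
            mcar_rate >= 0, mcar_rate < 1)
  if (!inherits(ising, "ising_parameters") || ising$p != 7)
    stop("ising must be a 7-node ising_parameters object")
  for (nm in names(covariate_distributions)) {
    s <- sum(covariate_distributions[[nm]])
    if (abs(s - 1) > 1e-9)
      stop("covariate distribution '", nm, "' sums to ", s, ", not 1")
  }
  structure(list(n_records = as.integer(n_records), ising = ising,
                 covariate_distributions = covariate_distributions,
                 cooccurrence_log_odds = cooccurrence_log_odds,
                 outcome_link_strength = outcome_link_strength,
                 mcar_rate = mcar_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# age ranges per band; education years per band
.age_ranges <- list("65-74" = 65:74, "75-84" = 75:84,
                    "85-94" = 85:94, "95+" = 95:110)
.edu_years <- list("0" = 0L, "1-6" = 1:6, "7-9" = 7:9,
                   "10-12" = 10:12, "13+" = 13:16)

#' Generate a synthetic survey table
#'
#' Draws a fully synthetic survey-style dataset: demographics from the
#' configured categorical distributions; a ">= 2 risk behaviors" indicator
#' from the planted logistic model; the 7-vector of behaviors by exact
#' sampling from the Ising joint distribution conditioned on behavior count
#' >= 2 or <= 1 so the indicator's planted odds ratios are recoverable by
#' refitting; ordinal quality-of-life and health ratings from a latent
#' normal score loading negatively on behavior count; and raw response
#' fields (sleep hours, fruit/vegetable frequency letters, flavor,
#' yes/no items) from which [code_behaviors()] re-derives the behavior
#' matrix exactly.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame (one row per record) with raw survey columns. The
#'   sampled behavior matrix, indicator, and behavior counts are attached as
#'   attributes `behaviors`, `indicator`, and `behavior_count`.
#' @export
generate_survey_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_records
  cd <- config$covariate_distributions
  eff <- config$cooccurrence_log_odds
  pmf <- enumerate_joint_pmf(config$ising)
  counts <- rowSums(pmf$states)
  hi <- counts >= 2
  p_hi <- sum(pmf$probs[hi]); p_lo <- sum(pmf$probs[!hi])
  if (p_hi <= 0) stop("generation error: empty stratum 'count >= 2'")
  if (p_lo <= 0) stop("generation error: empty stratum 'count <= 1'")

  with_seed(config$seed, {
    draw <- function(tab) names(tab)[sample.int(length(tab), n, replace = TRUE,
                                                prob = tab)]
    gender <- draw(cd$gender)
    age_band <- draw(cd$age_band)
    pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
    age <- vapply(age_band, function(b) pick1(.age_ranges[[b]]), 1L)
    residence <- draw(cd$residence)
    edu_band <- draw(cd$education_band)
    education_years <- vapply(edu_band,
                              function(b) pick1(.edu_years[[b]]), 1L)
    co_residence <- draw(cd$co_residence)
    economic_status <- draw(cd$economic_status)

    lp <- eff$intercept +
      eff$female * (gender == "female") +
      eff$age_per_decade * (age / 10) +
      ifelse(edu_band == "0", 0, eff$education[edu_band]) +
      ifelse(residence == "city", 0, eff$residence[residence]) +
      ifelse(co_residence == "household", 0, eff$co_residence[co_residence]) +
      ifelse(economic_status == "very_poor", 0,
             eff$economic_status[economic_status])
    indicator <- rbinom(n, 1L, plogis(lp))

    # exact conditional draw from the enumerated pmf given the count stratum
    idx <- integer(n)
    for (z in c(0L, 1L)) {
      sel <- indicator == z
      stratum <- if (z == 1L) which(hi) else which(!hi)
      if (any(sel))
        idx[sel] <- stratum[sample.int(length(stratum), sum(sel),
                                       replace = TRUE,
                                       prob = pmf$probs[stratum])]
    }
    behaviors <- as_behavior_matrix(pmf$states[idx, , drop = FALSE])
    bcount <- rowSums(behaviors)

    score_from_latent <- function() {
      latent <- -config$outcome_link_strength * bcount + rnorm(n)
      z <- (latent - mean(latent)) / sd(latent)
      # equal-width cuts on the standardized latent; low latent -> score 1
      1L + findInterval(z, c(-1.5, -0.5, 0.5, 1.5))
    }
    qol_score <- score_from_latent()
    health_score <- score_from_latent()
    letter <- function(s) c("E", "D", "C", "B", "A")[s]

    pick <- function(risk, yes, no) {
      out <- character(n)
      out[risk == 1L] <- sample(yes, sum(risk == 1L), replace = TRUE)
      out[risk == 0L] <- sample(no, sum(risk == 0L), replace = TRUE)
      out
    }
    tab <- data.frame(
      id = seq_len(n),
      gender = gender, age = as.integer(age), residence = residence,
      education_years = as.integer(education_years),
      co_residence = co_residence, economic_status = economic_status,
      sleep_hours = as.numeric(pick(behaviors[, 7], as.character(seq(3, 5.5, 0.5)),
                                    as.character(seq(6, 10, 0.5)))),
      fruit_freq = pick(behaviors[, 1], c("C", "D"), c("A", "B")),
      veg_freq = pick(behaviors[, 2], c("C", "D"), c("A", "B")),
      flavor = pick(behaviors[, 3], "salty",
                    c("bland", "so-so", "sweet", "spicy")),
      smoking_now = ifelse(behaviors[, 4] == 1L, "yes", "no"),
      drinking_now = ifelse(behaviors[, 5] == 1L, "yes", "no"),
      regular_exercise = ifelse(behaviors[, 6] == 1L, "no", "yes"),
      qol_rating = letter(qol_score),
      health_rating = letter(health_score),
      stringsAsFactors = FALSE
    )
    if (config$mcar_rate > 0) {
      for (f in c("education_years", "co_residence", "economic_status"))
        tab[[f]][runif(n) < config$mcar_rate] <- NA
    }
    attr(tab, "behaviors") <- behaviors
    attr(tab, "indicator") <- indicator
    attr(tab, "behavior_count") <- bcount
    tab
  })
}

#' Write a survey table with a provenance sidecar
#'
#' Writes the table as UTF-8 CSV and, alongside it, a JSON sidecar recording
#' the generating Ising parameters, planted effects, and seed (when the
#' table came from [generate_survey_table()]).
#'
#' @param table Survey data.frame.
#' @param path Output CSV path; sidecar is `<path>.json`.
#' @param config Optional [synthetic_config()] used to generate the table.
#' @return Invisibly, the CSV path.
#' @export
write_survey <- function(table, path, config = NULL) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(config)) {
    side <- list(n_records = config$n_records,
                 tau = config$ising$tau, W = config$ising$W,
                 cooccurrence_log_odds = config$cooccurrence_log_odds,
                 outcome_link_strength = config$outcome_link_strength,
                 mcar_rate = config$mcar_rate, seed = config$seed)
    jsonlite::write_json(side, paste0(path, ".json"), digits = 12,
                         auto_unbox = TRUE)
  }
  invisible(path)
}
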