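# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Behavior prevalence with Wilson confidence intervals
#'
#' @param matrix Binary behavior matrix.
#' @param conf_level Confidence level for the Wilson score interval.
#' @return data.frame, one row per behavior: count, proportion, ci_low,
#'   ci_high, and rank (1 = most prevalent; ties share the smaller rank).
#' @export
prevalence <- function(matrix, conf_level = 0.95) {
  m <- as_behavior_matrix(matrix)
  n <- nrow(m)
  x <- colSums(m)
  ci <- t(vapply(x, wilson_ci, c(low = 0, high = 0), n = n,
                 conf_level = conf_level))
  out <- data.frame(behavior = colnames(m), count = as.integer(x),
                    proportion = x / n, ci_low = ci[, "low"],
                    ci_high = ci[, "high"],
                    rank = rank(-x, ties.method = "min"))
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with tie correction
#'
#' Computes rho as the Pearson correlation of midranks (average-rank tie
#' handling) and a two-sided p-value from the t approximation on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined correlation: constant input")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

# education years -> the banded factor used in the regression
education_band <- function(years) {
  band <- cut(years, breaks = c(-Inf, 0, 6, 9, 12, Inf),
              labels = c("0", "1-6", "7-9", "10-12", "13+"))
  factor(band, levels = c("0", "1-6", "7-9", "10-12", "13+"))
}

.mode_value <- function(x) {
  tx <- table(x)
  names(tx)[which.max(tx)]
}

#' Logistic regression of co-occurrence on demographics
#'
#' Fits, by maximum likelihood (IRLS), the binary logistic model of the
#' ">= 2 risk behaviors" indicator on gender (reference male), age per
#' decade (continuous, age / 10), education band (reference 0 years),
#' residence (reference city), co-residence (reference with household
#' members), and economic status (reference very poor, levels ordered
#' poor to rich). Reports odds ratios with Wald 95% confidence intervals
#' and Wald p-values, and the intercept on the odds scale.
#'
#' Records with missing regression covariates are deleted case-wise by
#' default; `mode_impute = TRUE` instead fills education years,
#' co-residence, and economic status with their modal values.
#'
#' @param covariates data.frame with columns gender, age, residence,
#'   education_years, co_residence, economic_status.
#' @param indicator 0/1 vector (co-occurrence flags), same length.
#' @param conf_level Confidence level for the Wald intervals.
#' @param mode_impute Impute the three imputable demographics by mode.
#' @return List of class `hrb_logistic`: `terms` (one row per level incl.
#'   references), `intercept_odds`, `iterations`, `converged`, `n_used`,
#'   `n_dropped`, and `coefficients` (raw scale).
#' @export
fit_cooccurrence_logistic <- function(covariates, indicator,
                                      conf_level = 0.95,
                                      mode_impute = FALSE) {
  stopifnot(nrow(covariates) == length(indicator))
  d <- data.frame(
    y = as.integer(indicator),
    gender = factor(covariates$gender, levels = c("male", "female")),
    age_decade = covariates$age / 10,
    education = education_band(covariates$education_years),
    residence = factor(covariates$residence,
                       levels = c("city", "town", "rural")),
    co_residence = factor(covariates$co_residence,
                          levels = c("household", "alone", "institution")),
    economic_status = factor(covariates$economic_status,
                             levels = c("very_poor", "poor", "so_so",
                                        "rich", "very_rich"))
  )
  if (mode_impute) {
    for (f in c("education", "co_residence", "economic_status")) {
      isna <- is.na(d[[f]])
      if (any(isna)) d[[f]][isna] <- .mode_value(d[[f]][!isna])
    }
  }
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (length(unique(d$y)) < 2)
    stop("need both outcome classes present after case deletion")
  fit <- glm(y ~ gender + age_decade + education + residence +
               co_residence + economic_status,
             family = binomial(), data = d)
  cf <- coef(fit)
  big <- which(abs(cf[-1]) > 15)
  if (length(big))
    stop("complete separation detected for term ", names(cf[-1])[big[1]])
  if (!fit$converged)
    stop("logistic regression did not converge; last deviance ",
         format(fit$deviance))
  se <- sqrt(diag(stats::vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  pvals <- 2 * pnorm(-abs(cf / se))

  lvl_rows <- function(var, labels, prefix) {
    ref <- labels[1]
    rows <- data.frame(variable = var, level = labels,
                       reference = labels == ref,
                       or = 1, ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_)
    for (i in seq_along(labels)[-1]) {
      nm <- paste0(prefix, labels[i])
      rows$or[i] <- exp(cf[nm])
      rows$ci_low[i] <- exp(cf[nm] - z * se[nm])
      rows$ci_high[i] <- exp(cf[nm] + z * se[nm])
      rows$p_value[i] <- pvals[nm]
    }
    rows
  }
  terms <- rbind(
    lvl_rows("gender", c("male", "female"), "gender"),
    data.frame(variable = "age", level = "per_decade", reference = FALSE,
               or = exp(cf["age_decade"]),
               ci_low = exp(cf["age_decade"] - z * se["age_decade"]),
               ci_high = exp(cf["age_decade"] + z * se["age_decade"]),
               p_value = pvals["age_decade"]),
    lvl_rows("education", c("0", "1-6", "7-9", "10-12", "13+"), "education"),
    lvl_rows("residence", c("city", "town", "rural"), "residence"),
    lvl_rows("co_residence", c("household", "alone", "institution"),
             "co_residence"),
    lvl_rows("economic_status",
             c("very_poor", "poor", "so_so", "rich", "very_rich"),
             "economic_status")
  )
  rownames(terms) <- NULL
  structure(list(terms = terms, intercept_odds = exp(cf["(Intercept)"]),
                 coefficients = cf, se = se,
                 iterations = fit$iter, converged = fit$converged,
                 n_used = nrow(d), n_dropped = n_dropped),
            class = "hrb_logistic")
}

#' @export
print.hrb_logistic <- function(x, ...) {
  cat("Co-occurrence logistic regression (n =", x$n_used, ")\n")
  cat("Intercept (odds):", format(x$intercept_odds, digits = 4), "\n")
  print(transform(x$terms, or = round(or, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3)), ...)
  invisible(x)
}
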