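# upper-triangle edge vector of a p x p weight matrix, fixed pair order
edge_vector <- function(W) W[upper.tri(W)]

edge_labels <- function(W) {
  nm <- colnames(W)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(W)))
  pairs <- combn(ncol(W), 2)
  paste0(nm[pairs[1, ]], "+", nm[pairs[2, ]])
}

#' Bootstrap confidence intervals for edge weights
#'
#' Draws B nonparametric resamples of the records, refits the eLasso
#' network on each at identical settings, and reports per-edge percentile
#' intervals across replicates. Resamples in which some behavior column is
#' constant cannot be refitted; they are skipped and counted, and more than
#' 10% skips is an error.
#'
#' @param matrix Binary behavior matrix with at least 50 records.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @param gamma,rule Passed to [elasso_fit()].
#' @return data.frame per edge: label, weight (full-sample point estimate),
#'   ci_low, ci_high, n_replicates. Attribute `n_skipped` counts failed
#'   resamples.
#' @export
bootstrap_edge_ci <- function(matrix, B = 1000, seed = 1L, conf_level = 0.95,
                              gamma = 0.25, rule = "AND") {
  X <- as_behavior_matrix(matrix)
  N <- nrow(X)
  if (N < 50) stop("need at least 50 records for the bootstrap")
  full <- elasso_fit(X, gamma = gamma, rule = rule)
  alpha <- 1 - conf_level
  n_edges <- ncol(X) * (ncol(X) - 1) / 2
  reps <- matrix(NA_real_, B, n_edges)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(N, N, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      cs <- colSums(Xb)
      if (any(cs == 0 | cs == N)) { skipped <- skipped + 1L; next }
      reps[b, ] <- edge_vector(elasso_fit(Xb, gamma = gamma, rule = rule)$W)
    }
  })
  if (skipped > 0.10 * B)
    stop("more than 10% of bootstrap replicates failed (", skipped, " of ",
         B, ")")
  ok <- !is.na(reps[, 1])
  ci <- apply(reps[ok, , drop = FALSE], 2, quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- data.frame(label = edge_labels(full$W),
                    weight = edge_vector(full$W),
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    n_replicates = sum(ok))
  attr(out, "n_skipped") <- skipped
  out
}

#' Case-dropping bootstrap stability of edge weights
#'
#' For each drop fraction f, refits the network on B random subsets of
#' round(N (1 - f)) records and records the Pearson correlation between the
#' subset and full-sample edge-weight vectors (all pair slots, including
#' zeros). The CS-coefficient is the largest f for which the correlation is
#' at least `cor_threshold` in at least `prop_threshold` of subsets (0 if
#' none). Subsets whose refit fails, or whose edge vector has fewer than two
#' nonzero entries (correlation undefined against a zero vector), are
#' logged and excluded from the correlation distribution.
#'
#' @param matrix Binary behavior matrix.
#' @param drop_fractions Fractions of cases to drop.
#' @param B_per_fraction Subsets per fraction.
#' @param seed Integer seed.
#' @param gamma,rule Passed to [elasso_fit()].
#' @param cor_threshold,prop_threshold CS-coefficient conventions
#'   (0.7 / 0.95).
#' @return Object of class `hrb_stability`: `correlations` (list of
#'   per-fraction correlation vectors), `summary` (per fraction: mean
#'   correlation, proportion >= threshold, n_valid, n_degenerate),
#'   `cs_coefficient`, and the full-sample fit.
#' @export
case_dropping_stability <- function(matrix,
                                    drop_fractions = seq(0.1, 0.7, by = 0.1),
                                    B_per_fraction = 100, seed = 1L,
                                    gamma = 0.25, rule = "AND",
                                    cor_threshold = 0.7,
                                    prop_threshold = 0.95) {
  X <- as_behavior_matrix(matrix)
  N <- nrow(X)
  if (N * (1 - max(drop_fractions)) <= ncol(X))
    stop("largest drop fraction leaves too few records")
  full <- elasso_fit(X, gamma = gamma, rule = rule)
  w_full <- edge_vector(full$W)
  if (sum(w_full != 0) < 2)
    warning("full-sample network has fewer than 2 edges; ",
            "stability correlations will mostly be undefined")
  cors <- vector("list", length(drop_fractions))
  names(cors) <- paste0("drop_", drop_fractions)
  degen <- integer(length(drop_fractions))
  with_seed(seed, {
    for (fi in seq_along(drop_fractions)) {
      f <- drop_fractions[fi]
      nsub <- round(N * (1 - f))
      vals <- rep(NA_real_, B_per_fraction)
      for (b in seq_len(B_per_fraction)) {
        idx <- sample.int(N, nsub)
        Xs <- X[idx, , drop = FALSE]
        cs <- colSums(Xs)
        if (any(cs == 0 | cs == nsub)) next
        w_sub <- edge_vector(elasso_fit(Xs, gamma = gamma, rule = rule)$W)
        if (sum(w_sub != 0) < 2 || sd(w_sub) == 0 || sd(w_full) == 0) next
        vals[b] <- cor(w_sub, w_full)
      }
      degen[fi] <- sum(is.na(vals))
      cors[[fi]] <- vals[!is.na(vals)]
    }
  })
  summary <- data.frame(
    drop_fraction = drop_fractions,
    mean_correlation = vapply(cors, function(v)
      if (length(v)) mean(v) else NA_real_, 0),
    prop_above = vapply(cors, function(v)
      if (length(v)) mean(v >= cor_threshold) else NA_real_, 0),
    n_valid = vapply(cors, length, 0L),
    n_degenerate = degen
  )
  ok <- !is.na(summary$prop_above) & summary$prop_above >= prop_threshold
  cs <- if (any(ok)) max(drop_fractions[ok]) else 0
  structure(list(correlations = cors, summary = summary,
                 cs_coefficient = cs, fit = full,
                 settings = list(B_per_fraction = B_per_fraction,
                                 seed = seed, gamma = gamma, rule = rule,
                                 cor_threshold = cor_threshold,
                                 prop_threshold = prop_threshold)),
            class = "hrb_stability")
}

#' @export
print.hrb_stability <- function(x, ...) {
  cat("Case-dropping stability; CS-coefficient =", x$cs_coefficient, "\n")
  print(x$summary, ...)
  invisible(x)
}
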