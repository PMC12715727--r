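#' Pairwise co-occurrence counts
#'
#' Exact marginal and joint counts for every unordered pair of behavior
#' columns.
#'
#' @param matrix Binary behavior matrix.
#' @return data.frame with one row per pair: i, j (column indices, i < j),
#'   label, N, n_i, n_j, n_ij.
#' @export
pairwise_counts <- function(matrix) {
  m <- as_behavior_matrix(matrix)
  p <- ncol(m)
  N <- nrow(m)
  marg <- colSums(m)
  joint <- crossprod(m)
  pairs <- combn(p, 2)
  out <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    label = paste0(colnames(m)[pairs[1, ]], "+", colnames(m)[pairs[2, ]]),
    N = N,
    n_i = as.integer(marg[pairs[1, ]]),
    n_j = as.integer(marg[pairs[2, ]]),
    n_ij = as.integer(joint[cbind(pairs[1, ], pairs[2, ])])
  )
  rownames(out) <- NULL
  out
}

#' Observed-to-expected ratio for one pair
#'
#' O/E = P(A and B) / (P(A) P(B)), computed from counts as
#' (n_ij / N) / ((n_i / N)(n_j / N)). Equals 1 under exact independence
#' (n_ij N = n_i n_j); values above 1 indicate clustering.
#'
#' @param pc One row of [pairwise_counts()] output (or any list with
#'   N, n_i, n_j, n_ij).
#' @return The sample O/E ratio.
#' @export
oe_ratio <- function(pc) {
  if (pc$n_i <= 0 || pc$n_j <= 0)
    stop("undefined statistic: zero marginal count in pair ",
         if (!is.null(pc$label)) pc$label else "")
  if (pc$n_ij * pc$N == pc$n_i * pc$n_j) return(1)  # exact independence
  (pc$n_ij / pc$N) / ((pc$n_i / pc$N) * (pc$n_j / pc$N))
}

#' Confidence interval for an O/E ratio
#'
#' Default method resamples the 2x2 cell counts of the pair (a multinomial
#' over \{neither, i only, j only, both\}) B times and takes percentile
#' bounds of the replicate O/E values; replicates with a zero marginal are
#' dropped (if all are, an error suggests the log-delta method). The
#' `log_delta` alternative is a normal interval on log(O/E) with variance
#' 1/n_ij - 1/n_i - 1/n_j + 1/N, exponentiated.
#'
#' @param pc One pair of counts as for [oe_ratio()].
#' @param conf_level Confidence level.
#' @param method "bootstrap" (percentile, default) or "log_delta".
#' @param B Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return Named vector c(ci_low, ci_high).
#' @export
oe_confidence_interval <- function(pc, conf_level = 0.95,
                                   method = c("bootstrap", "log_delta"),
                                   B = 1000, seed = 1L) {
  method <- match.arg(method)
  alpha <- 1 - conf_level
  N <- pc$N; n_i <- pc$n_i; n_j <- pc$n_j; n_ij <- pc$n_ij
  if (method == "log_delta") {
    if (n_ij < 1) stop("log-delta interval requires n_ij >= 1")
    v <- 1 / n_ij - 1 / n_i - 1 / n_j + 1 / N
    v <- max(v, 0)
    z <- qnorm(1 - alpha / 2)
    oe <- oe_ratio(pc)
    return(c(ci_low = oe * exp(-z * sqrt(v)), ci_high = oe * exp(z * sqrt(v))))
  }
  if (N < 2) stop("bootstrap interval requires N >= 2")
  cells <- c(N - n_i - n_j + n_ij, n_i - n_ij, n_j - n_ij, n_ij)
  reps <- with_seed(seed, stats::rmultinom(B, N, cells / N))
  bi <- reps[2, ] + reps[4, ]  # marginal of i
  bj <- reps[3, ] + reps[4, ]
  ok <- bi > 0 & bj > 0
  if (!any(ok))
    stop("all bootstrap replicates degenerate; try method = 'log_delta'")
  boot_oe <- (reps[4, ok] / N) / ((bi[ok] / N) * (bj[ok] / N))
  q <- quantile(boot_oe, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

#' O/E ratios for all pairs of a behavior matrix
#'
#' Convenience wrapper: counts, O/E, confidence interval, joint percentage,
#' and rank for every pair.
#'
#' @inheritParams oe_confidence_interval
#' @param matrix Binary behavior matrix.
#' @return data.frame, one row per pair, ranked (see [rank_combinations()]).
#' @export
oe_table <- function(matrix, conf_level = 0.95,
                     method = c("bootstrap", "log_delta"), B = 1000,
                     seed = 1L) {
  method <- match.arg(method)
  pc <- pairwise_counts(matrix)
  pc$oe <- NA_real_; pc$ci_low <- NA_real_; pc$ci_high <- NA_real_
  for (k in seq_len(nrow(pc))) {
    row <- pc[k, ]
    if (row$n_i == 0 || row$n_j == 0) next  # flagged undefined, left NA
    pc$oe[k] <- oe_ratio(row)
    ci <- tryCatch(oe_confidence_interval(row, conf_level, method, B,
                                          seed = seed + k),
                   error = function(e) c(NA_real_, NA_real_))
    pc$ci_low[k] <- ci[1]; pc$ci_high[k] <- ci[2]
  }
  rank_combinations(pc, top_k = nrow(pc))
}

#' Rank behavior combinations by O/E ratio
#'
#' Sorts pairs by descending O/E, breaking ties by larger joint count and
#' then lexicographic label. The joint percentage 100 n_ij / N is rounded
#' half-up to two decimals, as printed in epidemiological tables.
#'
#' @param results data.frame of pairs with at least oe, n_ij, N, label.
#' @param top_k Number of top pairs to keep (clamped to the total).
#' @return The top `top_k` rows with columns `joint_percent` and `rank`
#'   added (rank 1..k without gaps). Pairs with undefined O/E sort last.
#' @export
rank_combinations <- function(results, top_k = 10) {
  ord <- order(-results$oe, -results$n_ij, results$label, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  out$joint_percent <- round_half_up(100 * out$n_ij / out$N, 2)
  out$rank <- seq_len(nrow(out))
  out <- head(out, min(top_k, nrow(out)))
  rownames(out) <- NULL
  out
}

#' Stratified O/E ranking
#'
#' Runs the full pairwise O/E pipeline separately within each stratum
#' (e.g., male / female), with stratum-specific denominators. Pairs whose
#' marginal count is zero within a stratum are reported with NA O/E while
#' the remaining pairs are still ranked.
#'
#' @inheritParams oe_table
#' @param strata Per-record stratum labels (length N).
#' @param top_k Top pairs to keep per stratum.
#' @return Named list of ranked pair tables, one per stratum level.
#' @export
stratified_oe <- function(matrix, strata, conf_level = 0.95,
                          method = c("bootstrap", "log_delta"), B = 1000,
                          seed = 1L, top_k = 10) {
  m <- as_behavior_matrix(matrix)
  stopifnot(length(strata) == nrow(m))
  method <- match.arg(method)
  levs <- unique(as.character(strata))
  out <- lapply(seq_along(levs), function(s) {
    sub <- m[as.character(strata) == levs[s], , drop = FALSE]
    if (nrow(sub) == 0) stop("empty stratum: ", levs[s])
    tab <- oe_table(sub, conf_level, method, B, seed = seed + 1000L * s)
    rank_combinations(tab, top_k = top_k)
  })
  names(out) <- levs
  out
}
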