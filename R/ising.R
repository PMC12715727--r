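#' Ising model parameters
#'
#' Container for the parameters of a binary pairwise Markov random field
#' (Ising model in its 0/1 variant): a vector of node thresholds `tau` and a
#' symmetric coupling matrix `W` with zero diagonal. The unnormalized
#' probability of a state x in \{0,1\}^p is
#' exp( sum_i tau_i x_i + sum_{i<j} w_ij x_i x_j ).
#'
#' @param tau Numeric vector of node thresholds (length p >= 2).
#' @param W Symmetric p x p numeric matrix of pairwise couplings, zero
#'   diagonal.
#' @return An object of class `ising_parameters`.
#' @export
#' @examples
#' ising_parameters(tau = c(0, 0), W = matrix(c(0, log(2), log(2), 0), 2))
ising_parameters <- function(tau, W) {
  tau <- as.numeric(tau)
  W <- as.matrix(W)
  p <- length(tau)
  if (p < 2) stop("invalid parameters: need p >= 2 nodes")
  if (!is.numeric(W) || nrow(W) != p || ncol(W) != p)
    stop("invalid parameters: W must be a ", p, " x ", p, " numeric matrix")
  if (anyNA(tau) || anyNA(W)) stop("invalid parameters: NA in tau or W")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12)))
    stop("invalid parameters: W must be symmetric")
  if (any(diag(W) != 0))
    stop("invalid parameters: W must have zero diagonal")
  structure(list(tau = tau, W = (W + t(W)) / 2, p = p),
            class = "ising_parameters")
}

#' @export
print.ising_parameters <- function(x, ...) {
  cat("Ising parameters:", x$p, "nodes,",
      sum(x$W[upper.tri(x$W)] != 0), "nonzero couplings\n")
  invisible(x)
}

# all 2^p states as a 2^p x p 0/1 matrix, binary-counting order with
# node 1 in the least significant position (row k+1 encodes integer k)
ising_states <- function(p) {
  k <- 0:(2^p - 1)
  vapply(seq_len(p), function(i) bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L,
         integer(2^p))
}

#' Exact joint distribution of an Ising model
#'
#' Enumerates all 2^p binary states and computes their exact probabilities
#' under the model, normalizing by the enumerated partition sum. Feasible up
#' to p = 20; the package's standard use is p = 7 (128 states).
#'
#' @param params An [ising_parameters()] object.
#' @return Object of class `joint_pmf`: list with `states` (2^p x p 0/1
#'   matrix, binary counting order, node 1 least significant), `probs`
#'   (probabilities summing to 1), and `p`.
#' @export
#' @examples
#' pmf <- enumerate_joint_pmf(ising_parameters(rep(0, 3), matrix(0, 3, 3)))
#' all.equal(pmf$probs, rep(1 / 8, 8))
enumerate_joint_pmf <- function(params) {
  if (!inherits(params, "ising_parameters"))
    params <- ising_parameters(params$tau, params$W)
  p <- params$p
  if (p > 20) stop("capacity error: p > 20 states cannot be enumerated")
  states <- ising_states(p)
  # log weight: tau'x + x'Wx/2 (W symmetric, zero diagonal)
  lw <- states %*% params$tau + rowSums((states %*% params$W) * states) / 2
  lw <- lw - max(lw)
  w <- exp(lw)
  structure(list(states = states, probs = as.numeric(w / sum(w)), p = p),
            class = "joint_pmf")
}

# marginal P(x_i = 1) for every node
pmf_marginals <- function(pmf) {
  as.numeric(crossprod(pmf$states, pmf$probs))
}

#' Draw iid samples from an enumerated joint distribution
#'
#' @param pmf A `joint_pmf` from [enumerate_joint_pmf()].
#' @param n Number of records to draw.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An n x p integer 0/1 matrix (canonical behavior column names when
#'   p = 7).
#' @export
sample_behaviors <- function(pmf, n, seed) {
  stopifnot(inherits(pmf, "joint_pmf"), n >= 1)
  idx <- with_seed(seed, sample.int(nrow(pmf$states), n, replace = TRUE,
                                    prob = pmf$probs))
  as_behavior_matrix(pmf$states[idx, , drop = FALSE])
}

#' Exact pairwise O/E ratio under an Ising model
#'
#' Computes P(x_i = 1, x_j = 1) / (P(x_i = 1) P(x_j = 1)) from the
#' enumerated distribution. Serves as the population truth against which the
#' sample O/E estimator is tested; equals 1 for every pair when W = 0.
#'
#' @param pmf A `joint_pmf`.
#' @param i,j Distinct node indices.
#' @return The population O/E ratio.
#' @export
true_pairwise_oe <- function(pmf, i, j) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (i == j) stop("i and j must be distinct nodes")
  m <- pmf_marginals(pmf)
  if (m[i] <= 0 || m[j] <= 0)
    stop("undefined statistic: zero marginal for node ", if (m[i] <= 0) i else j)
  joint <- sum(pmf$probs[pmf$states[, i] == 1L & pmf$states[, j] == 1L])
  joint / (m[i] * m[j])
}

# run code with a temporary RNG state seeded by `seed`; restores the
# caller's RNG so simulation helpers do not perturb the global stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
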