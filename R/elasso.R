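#' Estimate an Ising network by eLasso (nodewise L1 logistic + EBIC)
#'
#' For each node, fits the L1-penalized logistic regression of that column
#' on the remaining columns over a 100-point log-spaced lambda path running
#' from lambda_max (the smallest penalty giving the empty model) down by a
#' factor of 1e-3, and selects the penalty minimizing the extended BIC
#' EBIC(lambda) = -2 loglik + k log N + 2 gamma k log(p - 1), where k is the
#' number of nonzero predictors. The two directed coefficient estimates per
#' pair are then symmetrized: under the AND rule an edge survives only if
#' both directions are nonzero (the conservative convention for Ising
#' estimation from binary data); under OR, if either is. Surviving edges get
#' the average of the two directed coefficients. Binary predictors enter
#' unstandardized.
#'
#' @param matrix Binary behavior matrix, every column varying, N > p.
#' @param gamma EBIC hyperparameter (0 = plain BIC; 0.25 default, the
#'   conventional choice for this estimator).
#' @param rule Edge symmetrization rule, "AND" (default) or "OR".
#' @param n_lambda Number of lambda path points.
#' @param lambda_min_ratio Ratio of smallest to largest lambda on the path.
#' @return Object of class `hrb_isingfit`: `W` (symmetric p x p weights,
#'   zero diagonal), `tau` (thresholds: nodewise intercepts at the selected
#'   penalty), `B` (directed coefficient matrix, row = response node),
#'   `lambda` and `ebic` (per-node selected values), `gamma`, `rule`, `n`.
#' @export
elasso_fit <- function(matrix, gamma = 0.25, rule = c("AND", "OR"),
                       n_lambda = 100, lambda_min_ratio = 1e-3) {
  rule <- match.arg(rule)
  X <- as_behavior_matrix(matrix)
  p <- ncol(X); N <- nrow(X)
  if (N <= p) stop("need more records than nodes")
  cs <- colSums(X)
  const <- which(cs == 0 | cs == N)
  if (length(const))
    stop("constant column: ", paste(colnames(X)[const], collapse = ", "))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

  B <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  tau <- numeric(p)
  sel_lambda <- numeric(p)
  sel_ebic <- numeric(p)
  for (j in seq_len(p)) {
    y <- X[, j]
    Z <- X[, -j, drop = FALSE]
    fit <- glmnet::glmnet(Z, y, family = "binomial", standardize = FALSE,
                          nlambda = n_lambda,
                          lambda.min.ratio = lambda_min_ratio,
                          thresh = 1e-10)
    beta <- as.matrix(fit$beta)
    mu <- predict(fit, newx = Z, type = "response")
    eps <- 1e-12
    ll <- colSums(y * log(pmax(mu, eps)) +
                    (1 - y) * log(pmax(1 - mu, eps)))
    k <- colSums(beta != 0)
    ebic <- -2 * ll + k * log(N) + 2 * gamma * k * log(p - 1)
    best <- which.min(ebic)  # ties: which.min takes the first = larger lambda
    B[j, -j] <- beta[, best]
    tau[j] <- fit$a0[best]
    sel_lambda[j] <- fit$lambda[best]
    sel_ebic[j] <- ebic[best]
  }
  keep <- if (rule == "AND") (B != 0) & (t(B) != 0) else (B != 0) | (t(B) != 0)
  W <- (B + t(B)) / 2 * keep
  diag(W) <- 0
  structure(list(W = W, tau = setNames(tau, colnames(X)), B = B,
                 lambda = sel_lambda, ebic = sel_ebic, gamma = gamma,
                 rule = rule, n = N),
            class = "hrb_isingfit")
}

#' @export
print.hrb_isingfit <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] != 0)
  cat("eLasso Ising fit:", ncol(x$W), "nodes,", ne, "edges (",
      x$rule, "rule, gamma =", x$gamma, ", n =", x$n, ")\n")
  invisible(x)
}

check_weight_matrix <- function(W) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W))
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
    stop("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  W
}

#' Network density
#'
#' Fraction of the p(p-1)/2 possible edges with strictly nonzero weight.
#'
#' @param W Symmetric weight matrix, zero diagonal.
#' @return Real in \[0, 1\].
#' @export
network_density <- function(W) {
  W <- check_weight_matrix(W)
  p <- ncol(W)
  sum(W[upper.tri(W)] != 0) / (p * (p - 1) / 2)
}

#' Node strength and mean strength
#'
#' Strength of node i is the sum of absolute weights of its incident edges.
#'
#' @param W Symmetric weight matrix, zero diagonal.
#' @return List with `strength` (per node) and `mean_strength`.
#' @export
node_strength <- function(W) {
  W <- check_weight_matrix(W)
  s <- rowSums(abs(W))
  list(strength = s, mean_strength = mean(s))
}

#' Average local clustering coefficient
#'
#' Default is the Watts-Strogatz average local clustering coefficient of
#' the graph binarized at nonzero weight: for each node, the fraction of
#' pairs of its neighbours that are themselves connected (0 for degree
#' < 2), averaged over all nodes. `weighted = TRUE` gives the Barrat
#' weighted variant (on absolute weights) for sensitivity analysis.
#'
#' @param W Symmetric weight matrix, zero diagonal.
#' @param weighted Use the Barrat weighted local coefficient.
#' @return Real in \[0, 1\].
#' @export
clustering_coefficient <- function(W, weighted = FALSE) {
  W <- check_weight_matrix(W)
  A <- (W != 0) * 1
  p <- ncol(A)
  deg <- rowSums(A)
  local <- numeric(p)
  for (i in seq_len(p)) {
    if (deg[i] < 2) next
    nb <- which(A[i, ] > 0)
    if (!weighted) {
      local[i] <- sum(A[nb, nb]) / (deg[i] * (deg[i] - 1))
    } else {
      aw <- abs(W)
      s <- sum(aw[i, ])
      num <- 0
      for (jx in seq_along(nb)) for (hx in seq_along(nb)) {
        j <- nb[jx]; h <- nb[hx]
        if (j != h && A[j, h] > 0)
          num <- num + (aw[i, j] + aw[i, h]) / 2
      }
      local[i] <- num / (s * (deg[i] - 1))
    }
  }
  mean(local)
}

#' All topology metrics of an estimated network
#'
#' @param W Symmetric weight matrix (or an `hrb_isingfit`).
#' @return List: density, mean_strength, clustering_coefficient, strength.
#' @export
network_metrics <- function(W) {
  if (inherits(W, "hrb_isingfit")) W <- W$W
  st <- node_strength(W)
  list(density = network_density(W),
       mean_strength = st$mean_strength,
       clustering_coefficient = clustering_coefficient(W),
       strength = st$strength)
}
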