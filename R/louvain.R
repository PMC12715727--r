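#' Modularity of a partition
#'
#' Newman-Girvan modularity on a symmetric nonnegative weight matrix:
#' Q = (1/2m) sum_ij (A_ij - r k_i k_j / 2m) delta(c_i, c_j), with m the
#' total edge weight, k the weighted degrees, and r the resolution.
#'
#' @param W Symmetric nonnegative weight matrix with at least one edge.
#' @param membership Community id per node.
#' @param resolution Resolution parameter r (1 = classical).
#' @return The modularity Q.
#' @export
modularity_q <- function(W, membership, resolution = 1) {
  W <- check_weight_matrix(W)
  if (any(W < 0)) stop("modularity requires nonnegative weights")
  m2 <- sum(W)  # 2m
  if (m2 <= 0) stop("undefined modularity: graph has no edges")
  stopifnot(length(membership) == ncol(W))
  k <- rowSums(W)
  same <- outer(membership, membership, `==`)
  sum((W - resolution * tcrossprod(k) / m2) * same) / m2
}

# one pass of Louvain local moving on aggregated graph A; returns membership
louvain_local_moving <- function(A, resolution) {
  p <- ncol(A)
  comm <- seq_len(p)
  m2 <- sum(A)
  k <- rowSums(A)
  # sum of degrees per community
  sigma_tot <- k
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(p)) {  # seeded shuffle via caller's RNG state
      ci <- comm[i]
      # weight from i to each community (excluding self-loop)
      w_to <- tapply(A[i, -i], comm[-i], sum)
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      base <- if (as.character(ci) %in% names(w_to))
        w_to[[as.character(ci)]] else 0
      gain_stay <- base - resolution * sigma_tot[ci] * k[i] / m2
      best_c <- ci; best_gain <- gain_stay
      for (cn in names(w_to)) {
        cc <- as.integer(cn)
        if (cc == ci) next
        g <- w_to[[cn]] - resolution * sigma_tot[cc] * k[i] / m2
        if (g > best_gain + 1e-12) { best_c <- cc; best_gain <- g }
      }
      comm[i] <- best_c
      sigma_tot[best_c] <- sigma_tot[best_c] + k[i]
      if (best_c != ci) { moved <- TRUE; improved_any <- TRUE }
    }
    if (!moved) break
  }
  attr(comm, "improved") <- improved_any
  comm
}

# one full multi-level Louvain run; node visit order taken from the
# caller's RNG state
louvain_single <- function(A, resolution) {
  p <- ncol(A)
  node_comm <- seq_len(p)  # membership of original nodes
  Acur <- A
  repeat {
    comm <- louvain_local_moving(Acur, resolution)
    ids <- match(comm, unique(comm))
    node_comm <- ids[node_comm]
    if (!attr(comm, "improved") || length(unique(ids)) == ncol(Acur)) break
    # aggregate: communities become super-nodes, weights summed
    agg <- matrix(0, max(ids), max(ids))
    for (a in seq_len(ncol(Acur))) for (b in seq_len(ncol(Acur)))
      agg[ids[a], ids[b]] <- agg[ids[a], ids[b]] + Acur[a, b]
    Acur <- agg
  }
  match(node_comm, unique(node_comm)) - 1L
}

#' Louvain community detection
#'
#' Greedy modularity maximization: repeated local node moves (visit order
#' shuffled from `seed`) followed by community aggregation, until no move
#' improves modularity. Because the greedy cycle can halt in a visit-order-
#' dependent local optimum, the search is restarted `n_restarts` times with
#' seed-derived visit orders and the best-modularity partition is returned;
#' the whole procedure is a deterministic function of (W, settings, seed).
#'
#' Estimated Ising networks can carry negative edge weights, which
#' modularity does not accept; the default transform takes absolute values
#' (treating any conditional dependence as connectivity), and `"positive"`
#' drops negative edges instead. Isolated nodes become singleton
#' communities.
#'
#' @param W Symmetric weight matrix (possibly signed).
#' @param weight_transform "abs" (default) or "positive".
#' @param resolution Resolution parameter (1 = classical Louvain).
#' @param seed Integer seed controlling the node visit orders.
#' @param n_restarts Number of seeded greedy runs; the best is kept.
#' @return Object of class `hrb_partition`: `membership` (0-based
#'   contiguous ids, named by node), `modularity_q`, `n_communities`,
#'   `resolution`, `seed`.
#' @export
louvain <- function(W, weight_transform = c("abs", "positive"),
                    resolution = 1, seed = 1L, n_restarts = 5L) {
  weight_transform <- match.arg(weight_transform)
  W <- check_weight_matrix(W)
  A <- if (weight_transform == "abs") abs(W) else pmax(W, 0)
  if (sum(A) <= 0)
    stop("transformed graph has no edges; community detection undefined")
  best_membership <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    rs <- (as.numeric(seed) * 131 + r) %% 2147480000
    memb <- with_seed(rs, louvain_single(A, resolution))
    q <- modularity_q(A, memb, resolution)
    if (q > best_q + 1e-15) { best_q <- q; best_membership <- memb }
  }
  names(best_membership) <- colnames(W)
  structure(list(membership = best_membership,
                 modularity_q = best_q,
                 n_communities = length(unique(best_membership)),
                 resolution = resolution, seed = as.integer(seed)),
            class = "hrb_partition")
}

#' @export
print.hrb_partition <- function(x, ...) {
  cat("Louvain partition:", x$n_communities, "communities, Q =",
      format(x$modularity_q, digits = 6), "\n")
  print(x$membership)
  invisible(x)
}

#' Compare two partitions
#'
#' Adjusted Rand index and (sum-)normalized mutual information between two
#' partitions of the same node set. ARI is 1 iff the partitions are
#' identical up to relabeling; NMI of two one-block (or two identical
#' trivial) partitions is defined as 1.
#'
#' @param p1,p2 `hrb_partition` objects or plain membership vectors of
#'   equal length.
#' @return List with `ari` and `nmi`.
#' @export
compare_partitions <- function(p1, p2) {
  m1 <- if (inherits(p1, "hrb_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "hrb_partition")) p2$membership else p2
  if (length(m1) != length(m2)) stop("partitions are over different node sets")
  n <- length(m1)
  tab <- table(m1, m2)
  # adjusted Rand via the pair-counting contingency formula
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  exp_idx <- si * sj / comb2(n)
  max_idx <- (si + sj) / 2
  ari <- if (max_idx == exp_idx) 1 else (sij - exp_idx) / (max_idx - exp_idx)
  # NMI, sum normalization
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (a in seq_along(pi_)) for (b in seq_along(pj_)) {
    if (pij[a, b] > 0)
      mi <- mi + pij[a, b] * log(pij[a, b] / (pi_[a] * pj_[b]))
  }
  denom <- h(pi_) + h(pj_)
  nmi <- if (denom == 0) 1 else 2 * mi / denom
  list(ari = as.numeric(ari), nmi = as.numeric(nmi))
}
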