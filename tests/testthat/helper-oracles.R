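# independent oracles and tiny fixtures shared across test files

# all set partitions of n labelled items as restricted-growth strings
all_set_partitions <- function(n) {
  parts <- list(1L)
  for (i in seq_len(n - 1)) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(c) c(p, c))
    }), recursive = FALSE)
  }
  parts
}

# exhaustive modularity optimum over every partition (feasible at p = 7)
exhaustive_best_modularity <- function(W, resolution = 1) {
  best <- -Inf
  for (p in all_set_partitions(ncol(W))) {
    q <- modularity_q(W, p, resolution)
    if (q > best) best <- q
  }
  best
}

# random symmetric nonnegative weighted graph with at least one edge
random_weight_graph <- function(p, edge_prob = 0.6, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, p, p)
    up <- upper.tri(A)
    on <- runif(sum(up)) < edge_prob
    w <- ifelse(on, runif(sum(up), 0.1, 1), 0)
    A[up] <- w
    A <- A + t(A)
    if (sum(A) > 0) return(A)
  }
}

# brute-force per-record pair counting (quadratic oracle)
brute_pair_counts <- function(X, i, j) {
  n_i <- 0L; n_j <- 0L; n_ij <- 0L
  for (r in seq_len(nrow(X))) {
    if (X[r, i] == 1) n_i <- n_i + 1L
    if (X[r, j] == 1) n_j <- n_j + 1L
    if (X[r, i] == 1 && X[r, j] == 1) n_ij <- n_ij + 1L
  }
  list(N = nrow(X), n_i = n_i, n_j = n_j, n_ij = n_ij)
}

# a small complete survey record used to build coding fixtures
base_record <- function(...) {
  rec <- data.frame(
    id = 1L, gender = "female", age = 80L, residence = "city",
    education_years = 4L, co_residence = "household",
    economic_status = "so_so", sleep_hours = 8, fruit_freq = "A",
    veg_freq = "B", flavor = "bland", smoking_now = "no",
    drinking_now = "no", regular_exercise = "yes", qol_rating = "B",
    health_rating = "C", stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

many_records <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    r <- base_record(...)
    r$id <- i
    r
  }))
}
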