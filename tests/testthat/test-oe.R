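test_that("pairwise counts equal the brute-force double loop", {
  set.seed(2)
  X <- matrix(rbinom(140, 1, 0.4), 20, 7)
  pc <- pairwise_counts(X)
  expect_equal(nrow(pc), 21)
  for (k in seq_len(21)) {
    ref <- brute_pair_counts(X, pc$i[k], pc$j[k])
    expect_equal(pc$N[k], ref$N)
    expect_equal(pc$n_i[k], ref$n_i)
    expect_equal(pc$n_j[k], ref$n_j)
    expect_equal(pc$n_ij[k], ref$n_ij)
  }
  # identical columns and disjoint columns
  Y <- cbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  pc2 <- pairwise_counts(Y)
  expect_equal(pc2$n_ij[pc2$label == "a+b"], 2L)
  expect_equal(pc2$n_ij[pc2$label == "a+c"], 0L)
})

test_that("O/E ratio arithmetic and the exact-independence identity", {
  expect_equal(oe_ratio(list(N = 100, n_i = 50, n_j = 40, n_ij = 20)), 1)
  expect_equal(oe_ratio(list(N = 100, n_i = 50, n_j = 40, n_ij = 30)), 1.5)
  expect_equal(oe_ratio(list(N = 100, n_i = 50, n_j = 40, n_ij = 0)), 0)
  expect_error(oe_ratio(list(N = 10, n_i = 0, n_j = 5, n_ij = 0,
                             label = "x+y")), "undefined statistic")
  # whenever n_ij * N == n_i * n_j the ratio is exactly 1
  for (s in 1:20) {
    set.seed(s)
    n_i <- sample(1:50, 1) * 2; n_j <- sample(1:50, 1) * 2
    N <- n_i * n_j / 2
    expect_identical(oe_ratio(list(N = N, n_i = n_i, n_j = n_j,
                                   n_ij = n_i * n_j / N)), 1)
  }
})

test_that("O/E is symmetric and unaffected by the other columns", {
  set.seed(4)
  X <- matrix(rbinom(700, 1, 0.5), 100, 7)
  pc <- pairwise_counts(X)
  oe12 <- oe_ratio(pc[pc$i == 1 & pc$j == 2, ])
  Xp <- X[, c(2, 1, sample(3:7))]  # swap the pair, permute the rest
  oe21 <- oe_ratio(pairwise_counts(Xp)[1, ])
  expect_equal(oe12, oe21)
})

test_that("confidence intervals behave at the boundaries", {
  allboth <- list(N = 40, n_i = 40, n_j = 40, n_ij = 40)
  ci <- oe_confidence_interval(allboth, B = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))  # zero-width at 1
  ld <- oe_confidence_interval(allboth, method = "log_delta")
  expect_equal(unname(ld), c(1, 1))
  expect_error(oe_confidence_interval(list(N = 10, n_i = 4, n_j = 4,
                                           n_ij = 0), method = "log_delta"),
               "n_ij >= 1")
})

test_that("log-delta interval matches its closed form", {
  pc <- list(N = 1000, n_i = 400, n_j = 300, n_ij = 180)
  ci <- oe_confidence_interval(pc, method = "log_delta")
  oe <- (180 / 1000) / (0.4 * 0.3)
  v <- 1 / 180 - 1 / 400 - 1 / 300 + 1 / 1000
  z <- qnorm(0.975)
  expect_equal(unname(ci), oe * exp(c(-z, z) * sqrt(v)))
})

test_that("bootstrap and log-delta intervals concord on a balanced fixture", {
  # the log-delta variance is the near-independence approximation, so the
  # concordance fixture sits at exact independence (O/E = 1)
  pc <- list(N = 5000, n_i = 2500, n_j = 2500, n_ij = 1250)
  b <- oe_confidence_interval(pc, B = 2000, seed = 7)
  d <- oe_confidence_interval(pc, method = "log_delta")
  expect_lt(abs(diff(b) - diff(d)) / diff(d), 0.10)
})

test_that("bootstrap CI is reproducible and contains the point estimate", {
  pc <- list(N = 500, n_i = 200, n_j = 150, n_ij = 80)
  ci1 <- oe_confidence_interval(pc, B = 500, seed = 3)
  expect_identical(ci1, oe_confidence_interval(pc, B = 500, seed = 3))
  oe <- oe_ratio(pc)
  expect_true(ci1[1] <= oe && oe <= ci1[2])
})

test_that("sample O/E converges to the enumerated truth", {
  ip <- two_block_ising()
  pmf <- enumerate_joint_pmf(ip)
  X <- sample_behaviors(pmf, 1e5, seed = 77)
  pc <- pairwise_counts(X)
  for (k in c(1, 11, 18)) {  # a cross-block, a lifestyle, an addictive pair
    truth <- true_pairwise_oe(pmf, pc$i[k], pc$j[k])
    est <- oe_ratio(pc[k, ])
    # 3 Monte-Carlo SDs via the log-delta variance
    sdlog <- sqrt(1 / pc$n_ij[k] - 1 / pc$n_i[k] - 1 / pc$n_j[k] +
                    1 / pc$N[k])
    expect_lt(abs(log(est) - log(truth)), 3 * sdlog)
  }
})

test_that("ranking is descending with the stated tie-breaks", {
  res <- data.frame(
    label = c("b+c", "a+b", "a+c"),
    N = 12766, n_ij = c(100, 1151, 100),
    oe = c(1.5, 1.5, 2.0))
  r <- rank_combinations(res, top_k = 10)
  expect_equal(r$label, c("a+c", "a+b", "b+c"))  # oe, then n_ij, then label
  expect_equal(r$rank, 1:3)
  expect_equal(r$joint_percent[r$label == "a+b"], 9.02)
  # all O/E equal: falls back to n_ij ordering
  res$oe <- 1
  r2 <- rank_combinations(res)
  expect_equal(r2$label[1], "a+b")
  # ties everywhere: lexicographic label order
  res$n_ij <- 100
  expect_equal(rank_combinations(res)$label, c("a+b", "a+c", "b+c"))
  expect_equal(nrow(rank_combinations(res, top_k = 99)), 3)
})

test_that("stratified O/E equals the unstratified run on the subset", {
  pmf <- enumerate_joint_pmf(two_block_ising())
  X <- sample_behaviors(pmf, 600, seed = 15)
  strata <- rep(c("male", "female"), 300)
  so <- stratified_oe(X, strata, B = 100, seed = 42, top_k = 21)
  sub <- X[strata == "male", ]
  direct <- oe_table(sub, B = 100, seed = 42 + 1000L)
  expect_equal(so$male$oe, direct$oe)
  expect_equal(so$male$n_ij, direct$n_ij)
  expect_equal(so$male$N[1], 300L)
  # identical strata give identical results
  so2 <- stratified_oe(rbind(sub, sub),
                       rep(c("a", "b"), each = nrow(sub)),
                       B = 50, seed = 9, top_k = 21)
  expect_equal(so2$a$oe, so2$b$oe)
})

test_that("degenerate strata are handled explicitly", {
  X <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L, 0L))
  tab <- oe_table(X, B = 50, seed = 1)
  defined <- !is.na(tab$oe)
  expect_true(all(tab$oe[defined] %in% c(0, 1)))  # N = 1 bounds
  # a zero-marginal behavior leaves its pairs NA, others reported
  Y <- matrix(rbinom(350, 1, 0.5), 50, 7)
  Y[, 3] <- 0L
  t2 <- oe_table(Y, B = 50, seed = 2)
  expect_true(all(is.na(t2$oe[t2$i == 3 | t2$j == 3])))
  expect_true(all(!is.na(t2$oe[t2$i != 3 & t2$j != 3])))
  expect_error(stratified_oe(Y, rep(c("m", "f"), length.out = 0)),
               "length")
})
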