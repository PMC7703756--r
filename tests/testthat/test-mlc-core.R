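test_that("pair partitions count p-p and p-n pairs", {
  p1 <- partition_pairs(c(1L, 1L, 0L))
  expect_equal(p1$n_pp, 1); expect_equal(p1$n_pn, 2)
  p2 <- partition_pairs(c(1L, 1L, 1L, 0L, 0L))
  expect_equal(p2$n_pp, 3); expect_equal(p2$n_pn, 6)
  set.seed(12)
  y <- rbinom(30, 1, 0.4)
  y[1:2] <- 1L  # ensure validity
  p3 <- partition_pairs(y)
  expect_equal(p3$n_pp, choose(sum(y), 2))
  expect_equal(p3$n_pn, sum(y) * sum(1 - y))
  expect_error(partition_pairs(c(1L, 0L, 0L)), "2 positive")
  expect_error(partition_pairs(c(1L, 1L)), "negative")
})

test_that("global partition classifies pairs by informative-term sharing", {
  Y <- rbind(g1 = c(1L, 1L, 1L), g2 = c(1L, 1L, 0L), g3 = c(0L, 0L, 1L),
             g4 = c(0L, 0L, 0L))
  # column 1 is annotated to all of g1,g2... add a root-like column
  Yr <- cbind(Y, root = 1L)
  part <- partition_pairs_global(Yr)
  # root column (all ones) must not create sharing: g2-g4 share nothing
  share_oracle <- function(i, j) any(Y[i, ] & Y[j, ])
  for (i in 1:3) for (j in (i + 1):4)
    expect_identical(unname(part$share[i, j]), share_oracle(i, j))
  expect_false("root" %in% part$terms)
  # identical and disjoint term sets
  expect_true(part$share["g1", "g2"])
  expect_false(part$share["g1", "g4"])
  # two unannotated genes form an excluded (n-n analogue) pair
  Y2 <- rbind(Y, g5 = c(0L, 0L, 0L))
  p2 <- partition_pairs_global(cbind(Y2, root = 1L))
  expect_true(is.na(p2$share["g4", "g5"]))
  expect_equal(p2$n_pp + p2$n_pn, choose(5, 2) - 1)
})

test_that("pair moments match hand-enumerated sums on a tiny instance", {
  # 3 genes (2 positive) x 2 samples: one p-p pair, two p-n pairs
  X <- rbind(c(1, -1), c(0.5, 0.5), c(-1, 2)) / 3  # arbitrary values
  part <- partition_pairs(c(1L, 1L, 0L))
  mo <- build_pair_moments(X, part)
  # U_m = x_1m * x_2m (single p-p pair)
  expect_equal(mo$U, X[1, ] * X[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  # V_m = (x_1m + x_2m) * x_3m
  expect_equal(mo$V, (X[1, ] + X[2, ]) * X[3, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # M_pp[m,n] = x_1m x_2m x_1n x_2n
  expect_equal(unclass(mo$M_pp), outer(X[1, ] * X[2, ], X[1, ] * X[2, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # M_pn[m,n] = sum over the two p-n pairs of products
  Mpn <- outer(X[1, ] * X[3, ], X[1, ] * X[3, ]) +
    outer(X[2, ] * X[3, ], X[2, ] * X[3, ])
  expect_equal(unclass(mo$M_pn), Mpn, tolerance = 1e-12, ignore_attr = TRUE)

  # all-zero expression gives vanishing moments
  mo0 <- build_pair_moments(matrix(0, 4, 3), partition_pairs(c(1L, 1L, 0L, 0L)))
  expect_true(all(mo0$U == 0) && all(mo0$V == 0) && all(mo0$M_pp == 0))
})

test_that("moment-based Welch t equals pair-enumeration on random instances", {
  set.seed(14)
  for (r in 1:25) {
    ng <- sample(6:12, 1); ns <- sample(3:6, 1)
    Xs <- random_scaled(ng, ns)
    npos <- sample(3:(ng - 2), 1)
    pos <- sample(ng, npos)
    y <- integer(ng); y[pos] <- 1L
    mo <- build_pair_moments(Xs, partition_pairs(y))
    for (k in 1:4) {
      w <- runif(ns)
      expect_equal(welch_t(w, mo), brute_welch_t(Xs, pos, w),
                   tolerance = 1e-9)
    }
  }
})

test_that("t is invariant to positive rescaling of the weights", {
  set.seed(15)
  Xs <- random_scaled(10, 6)
  y <- c(rep(1L, 4), rep(0L, 6))
  mo <- build_pair_moments(Xs, partition_pairs(y))
  w <- runif(6)
  t1 <- welch_t(w, mo)
  for (cc in c(0.1, 1, 10))
    expect_equal(welch_t(cc * w, mo), t1, tolerance = 1e-9)
})

test_that("objective and analytic gradient are consistent with finite differences", {
  set.seed(16)
  Xs <- random_scaled(14, 7)
  y <- c(rep(1L, 5), rep(0L, 9))
  mo <- build_pair_moments(Xs, partition_pairs(y))
  alpha <- 0.9
  # alpha -> 1 limit: objective approaches -t
  w <- runif(7) + 0.2
  expect_equal(mlc_objective(w, mo, 1 - 1e-12), -welch_t(w, mo),
               tolerance = 1e-6)
  for (r in 1:20) {
    w <- runif(7) + 0.1
    g <- unname(mlc_objective_grad(w, mo, alpha))
    h <- 1e-6
    for (m in sample(7, 3)) {
      e <- numeric(7); e[m] <- h
      fd <- (mlc_objective(w + e, mo, alpha) -
               mlc_objective(w - e, mo, alpha)) / (2 * h)
      expect_equal(g[m], fd, tolerance = 1e-5)
    }
  }
  expect_error(mlc_objective(w, mo, 1.2), "alpha")
  expect_error(mlc_objective(w, mo, 0), "alpha")
})

test_that("sampled-pair moments converge to the exact ones", {
  set.seed(17)
  Xs <- random_scaled(20, 5)
  y <- c(rep(1L, 8), rep(0L, 12))
  part <- partition_pairs(y)
  exact <- build_pair_moments(Xs, part)
  full <- build_pair_moments_sampled(Xs, part, n_pairs = 1e6)  # no subsampling
  w <- runif(5)
  expect_equal(welch_t(w, full), welch_t(w, exact), tolerance = 1e-9)
  # genuine subsample: close but not exact
  sub <- build_pair_moments_sampled(Xs, part, n_pairs = 60, seed = 3)
  expect_lt(abs(welch_t(w, sub) - welch_t(w, exact)), 1.5)
  # deterministic given the seed
  sub2 <- build_pair_moments_sampled(Xs, part, n_pairs = 60, seed = 3)
  expect_identical(sub$U, sub2$U)
})

test_that("t depends only on pairs inside the moment pair set (n-n exclusion)", {
  set.seed(18)
  Xs <- random_scaled(10, 5)
  pos <- 1:3
  # explicit pair lists: all p-p pairs, p-n pairs avoiding gene 10 entirely
  pp <- t(combn(pos, 2))
  pn <- as.matrix(expand.grid(pos, 4:9))
  mo <- mlcoex:::.moments_from_pairs(Xs, pp, pn)
  w <- runif(5)
  t0 <- welch_t(w, mo)
  # gene 10 participates in no tracked pair: perturbing it cannot move t
  Xp <- Xs; Xp[10, ] <- rnorm(5)
  expect_identical(welch_t(w, mlcoex:::.moments_from_pairs(Xp, pp, pn)), t0)
  # a tracked negative, by contrast, does move t
  Xq <- Xs; Xq[9, ] <- Xq[9, ] + 1
  expect_false(isTRUE(all.equal(
    welch_t(w, mlcoex:::.moments_from_pairs(Xq, pp, pn)), t0)))
})

test_that("fitting recovers informative samples and respects the L1 limit", {
  ds <- simulate_dataset(simulation_spec(n_genes = 120, n_samples = 60,
                                         n_terms = 1, positives_per_term = 25,
                                         informative_block_size = 15,
                                         within_block_correlation = 0.8,
                                         seed = 19))
  Xs <- center_scale(ds$expression)
  m <- fit_mlc(Xs, ds$labels[, 1], alpha = 0.99)
  B <- ds$blocks[[1]]
  expect_gt(mean(m$weights[B]), mean(m$weights[-B]))
  expect_true(all(m$weights >= 0))
  expect_identical(m$n_selected, length(selected_samples(m)))

  # objective at the solution does not exceed the all-ones start
  mo <- build_pair_moments(Xs, partition_pairs(ds$labels[, 1]))
  expect_lte(m$objective_value,
             mlc_objective(rep(1, ncol(Xs)), mo, 0.99) + 1e-9)

  # deterministic: same inputs, same fit
  m2 <- fit_mlc(Xs, ds$labels[, 1], alpha = 0.99)
  expect_identical(m$weights, m2$weights)

  # alpha near 0: the L1 term dominates and the weights collapse towards 0
  m0 <- fit_mlc(Xs, ds$labels[, 1], alpha = 1e-4)
  expect_lt(sum(m0$weights), 1e-3 * ncol(Xs))
})

test_that("selected_samples applies the relative zero threshold", {
  fake <- structure(list(weights = c(0, 1e-12, 0.3)), class = "mlc_model")
  expect_identical(unname(selected_samples(fake, eps = 1e-8)), 3L)
  expect_identical(length(selected_samples(structure(
    list(weights = rep(0, 4)), class = "mlc_model"))), 0L)
  # default threshold is relative to the largest weight
  fake2 <- structure(list(weights = c(1e-10, 1)), class = "mlc_model")
  expect_identical(unname(selected_samples(fake2)), 2L)
})

test_that("global fit equals term-specific behaviour on a single-term corpus", {
  ds <- simulate_dataset(simulation_spec(n_genes = 80, n_samples = 40,
                                         n_terms = 1, positives_per_term = 20,
                                         informative_block_size = 12,
                                         within_block_correlation = 0.8,
                                         seed = 23))
  Xs <- center_scale(ds$expression)
  Y <- ds$labels
  # with one term the share-a-term partition coincides with the term's P/Q
  m_term <- fit_mlc(Xs, Y[, 1], alpha = 0.95)
  m_glob <- fit_mlc_global(Xs, Y, alpha = 0.95, n_pairs = 1e6)
  expect_equal(unname(m_glob$weights), unname(m_term$weights),
               tolerance = 1e-6)

  # two disjoint informative blocks: both elevated under the global fit
  ds2 <- simulate_dataset(simulation_spec(n_genes = 150, n_samples = 60,
                                          n_terms = 2, positives_per_term = 30,
                                          informative_block_size = 15,
                                          within_block_correlation = 0.8,
                                          seed = 24))
  Xs2 <- center_scale(ds2$expression)
  mg <- fit_mlc_global(Xs2, ds2$labels, alpha = 0.99, n_pairs = 1e6)
  B1 <- ds2$blocks[[1]]; B2 <- ds2$blocks[[2]]
  out <- setdiff(seq_len(60), c(B1, B2))
  expect_gt(mean(mg$weights[B1]), mean(mg$weights[out]))
  expect_gt(mean(mg$weights[B2]), mean(mg$weights[out]))
})
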