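test_that("fractional occupancy matches counting oracles", {
  expect_equal(fractional_occupancy(rep(1, 10), K = 2), c(1, 0))
  expect_equal(fractional_occupancy(rep(c(1, 2), 10), K = 2), c(0.5, 0.5))
  withr::with_seed(1, path <- sample.int(4, 500, replace = TRUE))
  expect_equal(fractional_occupancy(path, K = 4),
               as.numeric(table(factor(path, 1:4))) / 500)
  # soft mode: column means of posteriors
  withr::with_seed(2, g <- matrix(runif(60), 20, 3))
  g <- g / rowSums(g)
  expect_equal(fractional_occupancy(g), colMeans(g))
})

test_that("transition probabilities count consecutive moves with uniform fallback", {
  tp <- transition_probability(c(1, 1, 1), K = 2)
  expect_equal(tp[1, ], c(1, 0))
  expect_equal(tp[2, ], c(0.5, 0.5))   # unvisited row fallback
  expect_equal(attr(tp, "unvisited"), 2L)

  expect_equal(unclass(transition_probability(c(1, 2, 1, 2, 1), K = 2)),
               matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)

  # law of large numbers against the generating chain
  P <- matrix(c(0.7, 0.2, 0.1,
                0.15, 0.8, 0.05,
                0.3, 0.3, 0.4), 3, 3, byrow = TRUE)
  m <- base_hmm(3, 2, seed = 3)
  sim <- simulate_subject(P, m, 300000, seed = 4)
  expect_lt(max(abs(transition_probability(sim$path, 3) - P)), 0.01)
  # fo matches the tp stationary distribution on long ergodic paths
  expect_lt(max(abs(fractional_occupancy(sim$path, 3) -
                      stationary_dist(P))), 0.02)
})

test_that("weighted state FC reduces to Pearson and separates planted regimes", {
  withr::with_seed(5, X <- matrix(rnorm(4000), 1000, 4))
  ones <- matrix(1, 1000, 1)
  fc <- subject_state_fc(X, ones)[[1]]
  expect_equal(fc, cor(X), tolerance = 1e-10)

  # interleaved regimes with opposite correlation, exact labels
  withr::with_seed(6, {
    n <- 4000
    z <- rnorm(n)
    e <- rnorm(n)
    lab <- rep(c(1, 2), n / 2)
    x1 <- z
    x2 <- ifelse(lab == 1, 0.8 * z + sqrt(1 - 0.64) * e,
                 -0.8 * z + sqrt(1 - 0.64) * e)
  })
  gamma <- cbind(lab == 1, lab == 2) * 1
  fcs <- subject_state_fc(cbind(x1, x2), gamma)
  expect_lt(abs(fcs[[1]][1, 2] - 0.8), 0.05)
  expect_lt(abs(fcs[[2]][1, 2] + 0.8), 0.05)

  # perfectly correlated pair
  fc2 <- subject_state_fc(cbind(z, 2 * z + 1), matrix(1, n, 1))[[1]]
  expect_equal(fc2[1, 2], 1, tolerance = 1e-10)

  # starved state flagged missing
  g0 <- cbind(rep(1, 1000), rep(0, 1000))
  fcs <- subject_state_fc(X, g0)
  expect_true(all(is.na(fcs[[2]])))
  expect_equal(attr(fcs, "missing_states"), 2L)
})

test_that("model-implied state FC normalizes covariances", {
  m <- gaussian_hmm(matrix(0, 2, 2),
                    list(matrix(c(1, 0.5, 0.5, 1), 2, 2), diag(2) * 3),
                    matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
                    c(0.5, 0.5))
  fcs <- state_fc_from_model(m)
  expect_equal(fcs[[1]][1, 2], 0.5)
  expect_equal(fcs[[2]], diag(2))
  withr::with_seed(7, {
    W <- matrix(rnorm(25), 5, 5)
    S <- crossprod(W) + diag(5)
  })
  C <- state_fc_from_model(gaussian_hmm(matrix(0, 1, 5), list(S),
                                        matrix(1), 1))[[1]]
  brute <- S / sqrt(outer(diag(S), diag(S)))
  expect_equal(C, brute, tolerance = 1e-12)
})

test_that("fixed-partition modularity matches closed forms and the double sum", {
  # two equal disconnected cliques: Q = 1/2
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  expect_equal(modularity_fixed_partition(A, rep(1:2, each = 3)), 0.5)
  # everything in one module: Q = 0
  expect_equal(modularity_fixed_partition(A, rep(1, 6)), 0)
  # random weighted graph vs direct double-sum evaluation
  withr::with_seed(8, {
    W <- matrix(runif(64), 8, 8)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    part <- sample(1:2, 8, replace = TRUE)
  })
  deg <- rowSums(W)
  two_m <- sum(deg)
  oracle <- 0
  for (i in 1:8) for (j in 1:8) {
    if (part[i] == part[j]) {
      oracle <- oracle + (W[i, j] - deg[i] * deg[j] / two_m) / two_m
    }
  }
  expect_equal(modularity_fixed_partition(W, part), oracle, tolerance = 1e-12)
  # igraph cross-check on the same graph/partition
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(modularity_fixed_partition(W, part),
               igraph::modularity(g, part, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("cluster_fc averages masked off-diagonal edges", {
  fcs <- list(matrix(c(1, 0.2, 0.2, 1), 2, 2),
              matrix(c(1, -0.4, -0.4, 1), 2, 2))
  mask <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(cluster_fc(fcs, mask), c(0.2, -0.4))
  # identity FC, all edges: off-diagonal mean is 0
  expect_equal(cluster_fc(list(diag(3)), matrix(1, 3, 3)), 0)
  # random mask equals brute-force masked mean
  withr::with_seed(9, {
    F1 <- cov2cor(crossprod(matrix(rnorm(36), 6, 6)) + diag(6))
    M <- matrix(0, 6, 6)
    picks <- cbind(c(1, 2, 4), c(3, 5, 6))
    M[picks] <- 1
    M <- M + t(M)
  })
  expect_equal(cluster_fc(list(F1), M), mean(F1[picks]))
})

test_that("ICN-pair FC produces all block means, order-invariantly", {
  # two networks of two regions, hand-computed 4x4 case
  fc <- matrix(c(1, .5, .1, .2,
                 .5, 1, .3, .4,
                 .1, .3, 1, .6,
                 .2, .4, .6, 1), 4, 4, byrow = TRUE)
  part <- c("A", "A", "B", "B")
  out <- icn_pair_fc(list(fc), part)
  expect_equal(unname(out["A-A", 1]), 0.5)
  expect_equal(unname(out["B-B", 1]), 0.6)
  expect_equal(unname(out["A-B", 1]), mean(c(.1, .2, .3, .4)))

  # region permutation with consistently permuted partition
  perm <- c(3, 1, 4, 2)
  out_p <- icn_pair_fc(list(fc[perm, perm]), part[perm])
  expect_equal(out_p, out)

  # 7 networks: exactly 28 entries (21 between + 7 within)
  withr::with_seed(10, {
    S <- cov2cor(crossprod(matrix(rnorm(14 * 14), 14, 14)) + diag(14))
  })
  p7 <- default_partition(14)
  out7 <- icn_pair_fc(list(S), p7)
  expect_equal(nrow(out7), 28)
  expect_equal(sum(grepl("^(.+)-\\1$", rownames(out7))), 7)
})

test_that("features are invariant to state relabeling after canonical ordering", {
  coh <- tiny_cohort(seed = 55, duration_s = 40, K = 3, R = 4)
  st <- standardize_concatenate(coh$envelopes$alpha)
  f1 <- fit_hmm(st, K = 3, n_restarts = 2, seed = 1, tol = 1e-4,
                max_iter = 50)
  f2 <- fit_hmm(st, K = 3, n_restarts = 2, seed = 99, tol = 1e-4,
                max_iter = 50)
  fo1 <- t(sapply(f1$courses, function(x) fractional_occupancy(x$path, 3)))
  fo2 <- t(sapply(f2$courses, function(x) fractional_occupancy(x$path, 3)))
  expect_lt(max(abs(fo1 - fo2)), 0.02)
})
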