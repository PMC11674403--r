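# build a subject-state FC list with optional per-state mean shifts on
# selected edges; each planted edge gets its own state profile so that edge
# effects are not artificially synchronized
make_fc_data <- function(n, K, R, shift_edges = NULL, shift_size = 0,
                         seed = 1, noise = 0.1) {
  withr::with_seed(seed, {
    profiles <- if (!is.null(shift_edges)) {
      t(vapply(seq_len(nrow(shift_edges)), function(e) sample(seq_len(K)),
               integer(K)))
    }
    lapply(seq_len(n), function(s) {
      lapply(seq_len(K), function(k) {
        M <- matrix(rnorm(R * R, sd = noise), R, R)
        M <- (M + t(M)) / 2
        if (!is.null(shift_edges)) {
          delta <- shift_size * profiles[, k]
          idx <- cbind(shift_edges[, 1], shift_edges[, 2])
          M[idx] <- M[idx] + delta
          M[idx[, c(2, 1), drop = FALSE]] <-
            M[idx[, c(2, 1), drop = FALSE]] + delta
        }
        diag(M) <- 1
        M
      })
    })
  })
}

covars <- function(n, seed = 2) {
  withr::with_seed(seed, list(age = runif(n, 23, 40),
                              sex = sample(c("F", "M"), n, replace = TRUE)))
}

test_that("edgewise state ANCOVA matches a normal-equations oracle", {
  n <- 6; K <- 2; R <- 3
  fcs <- make_fc_data(n, K, R, seed = 3)
  cv <- covars(n, seed = 4)
  stats <- edgewise_state_ancova(fcs, cv$age, cv$sex)
  expect_equal(stats$df, c(1, 12 - 4))
  expect_equal(stats$f_values, t(stats$f_values))
  expect_equal(diag(stats$f_values), rep(0, R))

  # brute-force projection-matrix oracle for edge (1, 2)
  y <- unlist(lapply(fcs, function(x) sapply(x, function(m) m[1, 2])))
  subj <- rep(1:n, each = K)
  state <- rep(1:K, times = n)
  X0 <- cbind(1, (cv$age - mean(cv$age))[subj],
              (as.numeric(factor(cv$sex)) - 1)[subj])
  X1 <- cbind(X0, as.numeric(state == 2))
  rss <- function(X) {
    H <- X %*% solve(crossprod(X)) %*% t(X)
    sum(((diag(length(y)) - H) %*% y)^2)
  }
  f_oracle <- ((rss(X0) - rss(X1)) / 1) / (rss(X1) / (n * K - ncol(X1)))
  expect_equal(stats$f_values[1, 2], f_oracle, tolerance = 1e-10)
})

test_that("edge with no state effect gives F ~ 0 and planted effects exceed the null", {
  n <- 50; K <- 3; R <- 4
  fcs <- make_fc_data(n, K, R, seed = 5)
  cv <- covars(n, seed = 6)
  # constant edge across states within subject
  for (s in seq_len(n)) {
    v <- fcs[[s]][[1]][1, 2]
    for (k in 1:K) fcs[[s]][[k]][1, 2] <- fcs[[s]][[k]][2, 1] <- v
  }
  stats <- edgewise_state_ancova(fcs, cv$age, cv$sex)
  expect_lt(stats$f_values[1, 2], 1e-6)

  # planted 2-SD state shift on edge (3, 4)
  fcs2 <- make_fc_data(n, K, R, shift_edges = cbind(3, 4),
                       shift_size = 0.2, seed = 7)
  stats2 <- edgewise_state_ancova(fcs2, cv$age, cv$sex)
  expect_gt(stats2$f_values[3, 4], qf(0.999, stats2$df[1], stats2$df[2]))
})

test_that("density thresholding keeps the exact edge count with a stable tie rule", {
  withr::with_seed(8, {
    F54 <- matrix(rexp(54 * 54), 54, 54)
    F54 <- (F54 + t(F54)) / 2
    diag(F54) <- 0
  })
  A <- threshold_by_density(F54, 0.05)
  expect_equal(sum(A) / 2, round(0.05 * 54 * 53 / 2))  # 72 of 1,431
  expect_equal(sum(threshold_by_density(F54, 1)) / 2, 1431)
  # all-equal F: first edges in upper-triangle order are kept
  Feq <- matrix(1, 5, 5); diag(Feq) <- 0
  A_eq <- threshold_by_density(Feq, 0.3)
  ut <- which(upper.tri(Feq))
  expect_equal(which(A_eq[upper.tri(A_eq)] == 1), seq_len(round(0.3 * 10)))
})

test_that("NBS is deterministic and recovers a planted connected cluster", {
  n <- 40; K <- 3; R <- 40
  # planted 10-edge path cluster through nodes 1..11; the kept-edge count
  # stays subcritical on 40 nodes, so null components are small
  planted <- cbind(1:10, 2:11)
  fcs <- make_fc_data(n, K, R, shift_edges = planted, shift_size = 0.1,
                      seed = 9)
  cv <- covars(n, seed = 10)
  res <- nbs(fcs, cv$age, cv$sex, density = 0.015, n_perm = 200, seed = 11)
  res2 <- nbs(fcs, cv$age, cv$sex, density = 0.015, n_perm = 200, seed = 11)
  expect_identical(res$fwer_p, res2$fwer_p)

  sig <- which(res$fwer_p < 0.05)
  expect_gte(length(sig), 1)
  got <- do.call(rbind, res$clusters[sig])
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_gte(sum(key(planted) %in% key(got)), 8)
})

test_that("scalar state ANCOVA reproduces a hand-worked two-group case", {
  vals <- rbind(c(1.0, 2.0), c(1.2, 2.4), c(0.8, 1.9),
                c(1.1, 2.2), c(0.9, 2.1), c(1.0, 2.0))
  cv <- covars(6, seed = 12)
  out <- state_feature_ancova(vals, cv$age, cv$sex)
  # oracle via explicit projections
  y <- as.vector(t(vals))
  subj <- rep(1:6, each = 2)
  X0 <- cbind(1, (cv$age - mean(cv$age))[subj],
              (as.numeric(factor(cv$sex)) - 1)[subj])
  X1 <- cbind(X0, rep(c(0, 1), 6))
  rss <- function(X) sum(resid(lm.fit(X, y))^2)
  f_oracle <- (rss(X0) - rss(X1)) / (rss(X1) / (12 - 4))
  expect_equal(out$F, f_oracle, tolerance = 1e-10)
  # partial eta squared identity
  expect_equal(out$eta_p2, out$ss_state / (out$ss_state + out$ss_error))
  expect_equal(out$df, c(1, 8))

  # state-independent values
  flat <- matrix(rep(c(1, 1.1, 0.9, 1.2, 1, 1.05), 2), 6, 2)
  expect_lt(state_feature_ancova(flat, cv$age, cv$sex)$F, 1e-6)
})

test_that("edge stats are invariant to subject ordering", {
  n <- 12; K <- 2; R <- 4
  fcs <- make_fc_data(n, K, R, seed = 13)
  cv <- covars(n, seed = 14)
  a <- edgewise_state_ancova(fcs, cv$age, cv$sex)
  perm <- rev(seq_len(n))
  b <- edgewise_state_ancova(fcs[perm], cv$age[perm], cv$sex[perm])
  expect_equal(a$f_values, b$f_values, tolerance = 1e-10)
})
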