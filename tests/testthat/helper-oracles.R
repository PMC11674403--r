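# Independent oracles used across tests. These deliberately use brute-force
# or closed-form routes that share no code with the package internals.

# multivariate normal log-density, direct formula
mvn_logdens <- function(x, mu, sigma) {
  k <- length(mu)
  d <- x - mu
  as.numeric(-0.5 * (k * log(2 * pi) +
                       determinant(sigma, logarithm = TRUE)$modulus +
                       drop(t(d) %*% solve(sigma) %*% d)))
}

# exhaustive-path log-likelihood of a Gaussian HMM (K^T enumeration)
enum_loglik <- function(model, X) {
  K <- model$K
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  ll <- apply(paths, 1, function(p) {
    lp <- log(model$initial[p[1]])
    if (T_ > 1) {
      for (t in 2:T_) lp <- lp + log(model$transition[p[t - 1], p[t]])
    }
    for (t in seq_len(T_)) {
      lp <- lp + mvn_logdens(X[t, ], model$means[p[t], ],
                             model$covariances[[p[t]]])
    }
    lp
  })
  m <- max(ll)
  m + log(sum(exp(ll - m)))
}

# exhaustive-path MAP state sequence
enum_viterbi <- function(model, X) {
  K <- model$K
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  ll <- apply(paths, 1, function(p) {
    lp <- log(model$initial[p[1]])
    if (T_ > 1) {
      for (t in 2:T_) lp <- lp + log(model$transition[p[t - 1], p[t]])
    }
    for (t in seq_len(T_)) {
      lp <- lp + mvn_logdens(X[t, ], model$means[p[t], ],
                             model$covariances[[p[t]]])
    }
    lp
  })
  as.integer(paths[which.max(ll), ])
}

# best label-permutation agreement between two state paths
best_path_agreement <- function(path_hat, path_true, K) {
  perms <- combinat_perms(K)
  max(vapply(seq_len(nrow(perms)), function(i) {
    mean(perms[i, path_hat] == path_true)
  }, numeric(1)))
}

combinat_perms <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(K - 1)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    t(vapply(seq_len(nrow(sub)), function(i) {
      as.integer(append(sub[i, ], K, after = pos - 1))
    }, integer(K)))
  }))
}

# stationary distribution of a row-stochastic matrix by eigen-decomposition
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# order-dependent sequential orthogonalization (Gram-Schmidt with magnitude
# refit), the classical alternative the symmetric method should beat
sequential_orthogonalize <- function(X) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  d <- colSums(X * Q)
  sweep(Q, 2, d, `*`)
}

# small twin-pair phenotype simulator with exact within-pair correlations
simulate_pairs <- function(n_mz, n_dz, n_ur, r_mz, r_dz, seed) {
  withr::with_seed(seed, {
    draw <- function(n, r) {
      z1 <- rnorm(n); z2 <- rnorm(n)
      cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
    }
    y <- rbind(draw(n_mz, r_mz), draw(n_dz, r_dz), draw(n_ur, 0))
    list(y_a = y[, 1], y_b = y[, 2],
         zygosity = rep(c("MZ", "DZ", "UR"), c(n_mz, n_dz, n_ur)))
  })
}

# standard pair covariate frame for ANCOVA tests
fake_pairs <- function(zygosity, seed = 1) {
  withr::with_seed(seed, {
    n <- length(zygosity)
    data.frame(zygosity = zygosity,
               pair_sex = sample(c("F", "M"), n, replace = TRUE),
               age_diff = abs(rnorm(n, 0, 0.3)))
  })
}

# tiny ready-made state-structured cohort for feature/HMM tests
tiny_cohort <- function(seed = 42, n_mz = 4, n_dz = 2, n_ur = 2,
                        duration_s = 30, K = 3, R = 5, effect_scale = 1,
                        a2 = 0.6) {
  cfg <- cohort_config(n_mz, n_dz, n_ur, n_regions = R, n_states = K,
                       duration_s = duration_s, seed = seed)
  generate_cohort(cfg, ace_spec(a2 = a2, e2 = 1 - a2),
                  effect_scale = effect_scale)
}
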