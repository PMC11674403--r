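hand_model_2 <- function() {
  gaussian_hmm(means = matrix(c(-1, 2), 2, 1),
               covariances = list(matrix(0.5), matrix(1.2)),
               transition = matrix(c(0.85, 0.15, 0.3, 0.7), 2, 2,
                                   byrow = TRUE),
               initial = c(0.6, 0.4))
}

test_that("standardize_concatenate z-scores per subject and tracks boundaries", {
  withr::with_seed(2, {
    a <- matrix(rnorm(300, mean = 5, sd = 2), 100, 3)
    b <- matrix(rnorm(150, mean = -1, sd = 0.5), 50, 3)
  })
  st <- standardize_concatenate(list(s1 = a, s2 = b))
  expect_equal(st$boundaries, c(0, 100, 150))
  expect_lt(max(abs(colMeans(st$data[1:100, ]))), 1e-10)
  expect_lt(max(abs(apply(st$data[101:150, ], 2, sd) - 1)), 1e-10)
  expect_error(standardize_concatenate(list(cbind(a[, 1], 3))),
               "zero-variance")
})

test_that("forward_backward matches the exhaustive-path oracle", {
  m <- hand_model_2()
  withr::with_seed(4, X <- matrix(rnorm(3, sd = 2), 3, 1))
  stc <- forward_backward(m, X)
  expect_equal(stc$loglik, enum_loglik(m, X), tolerance = 1e-10)
  expect_equal(rowSums(stc$posteriors), rep(1, 3), tolerance = 1e-8)

  # longer series, K = 3
  m3 <- base_hmm(3, 2, seed = 8)
  withr::with_seed(5, X3 <- matrix(rnorm(12), 6, 2))
  expect_equal(forward_backward(m3, X3)$loglik, enum_loglik(m3, X3),
               tolerance = 1e-8)
})

test_that("identical emissions give stationary posteriors; forced chains give one-hot", {
  P <- matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2, byrow = TRUE)
  pi_st <- stationary_dist(P)
  m <- gaussian_hmm(matrix(0, 2, 1), list(matrix(1), matrix(1)), P, pi_st)
  withr::with_seed(6, X <- matrix(rnorm(50), 50, 1))
  stc <- forward_backward(m, X)
  expect_equal(stc$posteriors,
               matrix(pi_st, 50, 2, byrow = TRUE), tolerance = 1e-8)

  # deterministic cycle with certain start forces the path
  m_det <- gaussian_hmm(matrix(0, 2, 1), list(matrix(1), matrix(1)),
                        matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE), c(1, 0))
  stc <- forward_backward(m_det, X[1:6, , drop = FALSE])
  expect_equal(stc$posteriors[, 1], rep(c(1, 0), 3), tolerance = 1e-10)
})

test_that("viterbi_path matches exhaustive argmax decoding", {
  m <- hand_model_2()
  withr::with_seed(7, X <- matrix(rnorm(4, sd = 2), 4, 1))
  expect_equal(viterbi_path(m, X), enum_viterbi(m, X))

  # emission-free limit follows the most probable chain
  m_flat <- gaussian_hmm(matrix(0, 2, 1), list(matrix(1), matrix(1)),
                         matrix(c(0.95, 0.05, 0.5, 0.5), 2, 2, byrow = TRUE),
                         c(0.99, 0.01))
  expect_true(all(viterbi_path(m_flat, matrix(0, 20, 1)) == 1))
})

test_that("EM recovers a planted well-separated model deterministically", {
  truth <- gaussian_hmm(
    means = matrix(c(-3, -3, 3, 3), 2, 2, byrow = TRUE),
    covariances = list(diag(2), diag(2) * 1.5),
    transition = matrix(c(0.92, 0.08, 0.1, 0.9), 2, 2, byrow = TRUE),
    initial = c(0.5, 0.5))
  sim <- simulate_subject(truth$transition, truth, 6000, seed = 10, shift = 0)
  fit <- fit_hmm(sim$data, K = 2, n_restarts = 2, seed = 20, tol = 1e-6,
                 max_iter = 200)
  expect_gte(best_path_agreement(fit$courses[[1]]$path, sim$path, 2), 0.98)
  # monotone log-likelihood trace
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik)))
  # determinism
  fit2 <- fit_hmm(sim$data, K = 2, n_restarts = 2, seed = 20, tol = 1e-6,
                  max_iter = 200)
  expect_equal(fit$model$transition, fit2$model$transition, tolerance = 1e-12)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-12)
  # recovered transition close to truth (states are FO-ordered both ways)
  perm <- order(-fractional_occupancy(sim$path, 2))
  expect_lt(max(abs(fit$model$transition -
                      truth$transition[perm, perm])), 0.05)
})

test_that("K = 1 degenerates to a single always-on state", {
  withr::with_seed(11, X <- matrix(rnorm(200), 100, 2))
  fit <- fit_hmm(X, K = 1)
  expect_equal(fit$model$transition, matrix(1, 1, 1))
  expect_true(all(fit$courses[[1]]$posteriors == 1))
  expect_true(all(fit$courses[[1]]$path == 1))
})

test_that("order_states sorts by occupancy and is idempotent", {
  m <- base_hmm(3, 2, seed = 12)
  withr::with_seed(13, gamma <- matrix(runif(300), 100, 3))
  gamma <- gamma / rowSums(gamma)
  ord <- order_states(m, gamma)
  fo <- colMeans(ord$posteriors)
  expect_equal(fo, sort(fo, decreasing = TRUE))
  # applying again is a no-op
  ord2 <- order_states(ord$model, ord$posteriors)
  expect_equal(ord2$perm, 1:3)
  expect_equal(ord2$model$means, ord$model$means)
  # a random permutation is undone
  perm <- c(3, 1, 2)
  m_perm <- m
  m_perm$means <- m$means[perm, ]
  m_perm$covariances <- m$covariances[perm]
  m_perm$transition <- m$transition[perm, perm]
  m_perm$initial <- m$initial[perm]
  back <- order_states(m_perm, gamma[, perm])
  expect_equal(colMeans(back$posteriors), fo)
})

test_that("dwell_times converts run lengths to milliseconds", {
  expect_equal(dwell_times(c(1, 1, 2, 2), fs = 40, K = 2), c(50, 50))
  expect_equal(dwell_times(rep(1, 120), fs = 40, K = 2)[1], 3000)
  expect_true(is.na(dwell_times(rep(1, 120), fs = 40, K = 2)[2]))
  # P_kk = 0.9 at 40 Hz gives ~250 ms mean dwell
  m <- base_hmm(2, 2, stay = 0.9, seed = 14)
  sim <- simulate_subject(m$transition, m, 50000, seed = 15)
  dw <- dwell_times(sim$path, fs = 40, K = 2)
  expect_lt(max(abs(dw - 250) / 250), 0.1)
})
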