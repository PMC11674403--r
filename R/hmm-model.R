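#' Gaussian-observation hidden Markov model
#'
#' Container for a K-state HMM whose states are multivariate Gaussians over R
#' regions: each state has a mean activation vector and an amplitude-coupling
#' covariance, together with a row-stochastic transition matrix and an initial
#' state distribution.
#'
#' @param means K x R matrix of state mean activations.
#' @param covariances list of K symmetric positive-definite R x R covariances
#'   (amplitude-coupling FC of each state).
#' @param transition K x K row-stochastic transition matrix.
#' @param initial length-K initial state probability vector.
#' @return An object of class `gaussian_hmm` with elements `K`, `R`, `means`,
#'   `covariances`, `transition`, `initial`.
#' @export
gaussian_hmm <- function(means, covariances, transition, initial) {
  means <- as.matrix(means)
  K <- nrow(means)
  R <- ncol(means)
  if (!is.list(covariances) || length(covariances) != K) {
    stop("`covariances` must be a list of K matrices", call. = FALSE)
  }
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      stop("state covariance not symmetric", call. = FALSE)
    }
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("state covariance not positive-definite",
                           call. = FALSE)
    (S + t(S)) / 2
  })
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(K, K))) {
    stop("transition must be K x K", call. = FALSE)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-10)) {
    stop("transition rows must be non-negative and sum to 1", call. = FALSE)
  }
  initial <- as.numeric(initial)
  if (length(initial) != K || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-10) {
    stop("initial must be a length-K probability vector", call. = FALSE)
  }
  structure(list(K = K, R = R, means = means, covariances = covariances,
                 transition = transition, initial = initial),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM: K = %d states, R = %d regions\n", x$K, x$R))
  cat("transition matrix:\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' Construct a generic ground-truth HMM for simulation
#'
#' Builds a K-state model with well-separated mean activations and distinct
#' amplitude-coupling covariances, plus a diagonally dominant transition matrix
#' whose self-transition probability sets the expected dwell time
#' (`1/(1 - stay)` samples). Deterministic given the seed; used as the base
#' model of the synthetic twin cohort.
#'
#' @param n_states number of states K.
#' @param n_regions number of regions R.
#' @param stay self-transition probability (default 0.9, i.e. mean dwell of 10
#'   samples, 250 ms at 40 Hz).
#' @param separation scale of between-state mean differences in SD units
#'   (default 2).
#' @param seed integer seed for the randomly oriented covariance structure.
#' @return A [gaussian_hmm()].
#' @export
#' @examples
#' m <- base_hmm(3, 5, seed = 1)
#' rowSums(m$transition)
base_hmm <- function(n_states, n_regions, stay = 0.9, separation = 2,
                     seed = 1L) {
  K <- stopifnot_scalar_count(n_states, "n_states", 1L)
  R <- stopifnot_scalar_count(n_regions, "n_regions", 1L)
  if (stay < 0 || stay >= 1) stop("`stay` must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    means <- matrix(rnorm(K * R, sd = separation / 2), K, R)
    covariances <- lapply(seq_len(K), function(k) {
      W <- matrix(rnorm(R * R, sd = 0.4), R, R)
      S <- crossprod(W) / R + diag(R)
      (S + t(S)) / 2
    })
    transition <- matrix((1 - stay) / max(1, K - 1), K, K)
    diag(transition) <- if (K == 1) 1 else stay
    gaussian_hmm(means, covariances, transition, rep(1 / K, K))
  })
}
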