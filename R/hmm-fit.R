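#' Standardize and concatenate subject envelopes
#'
#' Z-scores every region of every subject (mean 0, SD 1 within subject) and
#' stacks subjects row-wise, returning the boundary offsets that keep the
#' Markov chain from crossing subjects during inference.
#'
#' @param envelopes list of [envelope_ts()] objects or T x R matrices sharing
#'   the same region count.
#' @return A list with `data` (stacked matrix), `boundaries` (0-based offsets,
#'   length `n_subjects + 1`) and `subject_ids`.
#' @export
standardize_concatenate <- function(envelopes) {
  stopifnot(is.list(envelopes), length(envelopes) >= 1L)
  mats <- lapply(envelopes, ts_matrix)
  R <- ncol(mats[[1]])
  if (!all(vapply(mats, ncol, 0L) == R)) {
    stop("all subjects must share the same number of regions", call. = FALSE)
  }
  mats <- lapply(seq_along(mats), function(i) {
    X <- mats[[i]]
    sds <- apply(X, 2, sd)
    if (any(sds < 1e-12)) {
      stop(sprintf("subject %d has a zero-variance region; cannot standardize", i),
           call. = FALSE)
    }
    scale(X)
  })
  ids <- names(envelopes) %||% as.character(seq_along(envelopes))
  lens <- vapply(mats, nrow, 0L)
  list(data = do.call(rbind, mats),
       boundaries = c(0L, cumsum(lens)),
       subject_ids = ids)
}

# T x K matrix of per-sample state log-densities under the model's Gaussians.
state_logdens <- function(model, X) {
  T_ <- nrow(X)
  out <- matrix(0, T_, model$K)
  const <- model$R * log(2 * pi)
  for (k in seq_len(model$K)) {
    U <- chol(model$covariances[[k]])
    Z <- sweep(X, 2, model$means[k, ]) %*% backsolve(U, diag(model$R))
    out[, k] <- -0.5 * (const + 2 * sum(log(diag(U))) + rowSums(Z^2))
  }
  out
}

#' Exact posterior state inference (forward-backward)
#'
#' Scaled forward-backward recursions giving the posterior probability of each
#' state at each sample, the exact log-likelihood, and the Viterbi-decoded
#' path.
#'
#' @param model a [gaussian_hmm()].
#' @param series T x R matrix or [envelope_ts()] (standardized to match the
#'   model's training scale).
#' @return A `state_time_course`: list with `posteriors` (T x K), `path`
#'   (length T) and `loglik`.
#' @export
forward_backward <- function(model, series) {
  X <- ts_matrix(series)
  stopifnot(ncol(X) == model$R)
  ld <- state_logdens(model, X)
  fb <- forward_backward_cpp(ld, model$transition, model$initial,
                             c(0L, nrow(X)))
  path <- viterbi_cpp(ld, log(pmax(model$transition, 1e-300)),
                      log(pmax(model$initial, 1e-300)), c(0L, nrow(X)))
  structure(list(posteriors = fb$gamma, path = as.integer(path),
                 loglik = fb$loglik),
            class = "state_time_course")
}

#' Viterbi maximum a posteriori state path
#'
#' @inheritParams forward_backward
#' @return Integer state sequence of length T.
#' @export
viterbi_path <- function(model, series) {
  X <- ts_matrix(series)
  stopifnot(ncol(X) == model$R)
  ld <- state_logdens(model, X)
  as.integer(viterbi_cpp(ld, log(pmax(model$transition, 1e-300)),
                         log(pmax(model$initial, 1e-300)), c(0L, nrow(X))))
}

init_hmm <- function(X, K, seed) {
  with_seed(seed, {
    n <- nrow(X)
    idx <- if (n > 5000L) sample.int(n, 5000L) else seq_len(n)
    km <- suppressWarnings(kmeans(X[idx, , drop = FALSE], centers = K,
                                  nstart = 3, iter.max = 50))
    R <- ncol(X)
    covs <- lapply(seq_len(K), function(k) {
      rows <- idx[km$cluster == k]
      S <- if (length(rows) > R + 2) cov(X[rows, , drop = FALSE]) else cov(X)
      regularize_cov(S)
    })
    P <- matrix(0.1 / max(1, K - 1), K, K)
    diag(P) <- if (K == 1) 1 else 0.9
    gaussian_hmm(km$centers, covs, P, rep(1 / K, K))
  })
}

regularize_cov <- function(S, ridge_base = 1e-6) {
  S <- (S + t(S)) / 2
  ridge <- ridge_base * sum(diag(S)) / nrow(S)
  for (i in 0:8) {
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) return(S)
    S <- S + ridge * 10^i * diag(nrow(S))
  }
  stop("covariance remains singular after ridge regularization", call. = FALSE)
}

em_once <- function(X, boundaries, model, tol, max_iter) {
  n_seg <- length(boundaries) - 1L
  trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    ld <- state_logdens(model, X)
    fb <- forward_backward_cpp(ld, model$transition, model$initial, boundaries)
    ll <- fb$loglik
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
    gamma <- fb$gamma
    G <- colSums(gamma)
    K <- model$K
    model$initial <- pmax(fb$start_gamma / n_seg, 1e-12)
    model$initial <- model$initial / sum(model$initial)
    P <- fb$xi
    rs <- rowSums(P)
    for (k in seq_len(K)) {
      P[k, ] <- if (rs[k] > 0) P[k, ] / rs[k] else rep(1 / K, K)
    }
    model$transition <- P
    means <- crossprod(gamma, X) / G
    covs <- vector("list", K)
    for (k in seq_len(K)) {
      Xg <- X * gamma[, k]
      S <- crossprod(Xg, X) / G[k] - tcrossprod(means[k, ])
      covs[[k]] <- regularize_cov(S)
    }
    model$means <- means
    model$covariances <- covs
  }
  list(model = model, loglik = trace[length(trace)], trace = trace,
       gamma = fb$gamma)
}

#' Fit a Gaussian-observation HMM by expectation-maximization
#'
#' Baum-Welch EM with per-subject forward-backward (chains restart at subject
#' boundaries), k-means initialization and multiple restarts; the restart with
#' the highest final log-likelihood wins. States are then re-ordered
#' canonically by descending group fractional occupancy (see
#' [order_states()]), and each subject's posterior state probabilities and
#' Viterbi path are decoded under the final model.
#'
#' @param stacked output of [standardize_concatenate()], or a T x R matrix
#'   (then `boundaries` must be given).
#' @param boundaries 0-based subject boundary offsets (ignored when `stacked`
#'   is a [standardize_concatenate()] result).
#' @param K number of states (>= 1).
#' @param n_restarts number of EM restarts from distinct k-means seeds.
#' @param seed integer seed controlling initialization.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @return An `hmm_fit`: list with `model` ([gaussian_hmm()]), `courses`
#'   (per-subject `state_time_course`s), `loglik`, `loglik_trace`
#'   (per-iteration, winning restart) and `subject_ids`.
#' @export
fit_hmm <- function(stacked, boundaries = NULL, K = 6L, n_restarts = 5L,
                    seed = 1L, tol = 1e-5, max_iter = 500L) {
  if (is.list(stacked) && !is.null(stacked$data)) {
    boundaries <- stacked$boundaries
    subject_ids <- stacked$subject_ids
    X <- stacked$data
  } else {
    X <- as.matrix(stacked)
    if (is.null(boundaries)) boundaries <- c(0L, nrow(X))
    subject_ids <- as.character(seq_len(length(boundaries) - 1L))
  }
  K <- stopifnot_scalar_count(K, "K")
  if (!all(is.finite(X))) stop("data must be finite", call. = FALSE)
  boundaries <- as.integer(boundaries)

  if (K == 1L) {
    model <- gaussian_hmm(matrix(colMeans(X), 1), list(regularize_cov(cov(X))),
                          matrix(1, 1, 1), 1)
    fitted <- list(model = model, loglik = NA_real_, trace = numeric(0),
                   gamma = matrix(1, nrow(X), 1))
    ld <- state_logdens(model, X)
    fb <- forward_backward_cpp(ld, model$transition, model$initial, boundaries)
    fitted$loglik <- fb$loglik
    fitted$trace <- fb$loglik
  } else {
    fits <- lapply(seq_len(n_restarts), function(r) {
      model0 <- init_hmm(X, K, seed = substream_seed(seed, paste0("restart", r)))
      em_once(X, boundaries, model0, tol, max_iter)
    })
    fitted <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  }

  ord <- order_states(fitted$model, fitted$gamma)
  model <- ord$model
  gamma <- ord$posteriors

  ld <- state_logdens(model, X)
  path <- as.integer(viterbi_cpp(ld, log(pmax(model$transition, 1e-300)),
                                 log(pmax(model$initial, 1e-300)), boundaries))
  courses <- lapply(seq_len(length(boundaries) - 1L), function(s) {
    rows <- (boundaries[s] + 1L):boundaries[s + 1L]
    structure(list(posteriors = gamma[rows, , drop = FALSE],
                   path = path[rows], loglik = NA_real_),
              class = "state_time_course")
  })
  names(courses) <- subject_ids
  structure(list(model = model, courses = courses, loglik = fitted$loglik,
                 loglik_trace = fitted$trace, subject_ids = subject_ids,
                 boundaries = boundaries),
            class = "hmm_fit")
}

#' Canonically order HMM states
#'
#' HMM state labels are arbitrary; for cross-run comparability states are
#' relabeled by descending group fractional occupancy (mean posterior
#' probability), with ties broken by earliest first activation.
#'
#' @param model a [gaussian_hmm()].
#' @param posteriors T x K posterior matrix used to compute group occupancy.
#' @return A list with the relabeled `model`, `posteriors` and the applied
#'   `perm` (new index `k` was old index `perm[k]`).
#' @export
order_states <- function(model, posteriors) {
  K <- model$K
  fo <- colMeans(posteriors)
  first_hit <- vapply(seq_len(K), function(k) {
    w <- which(max.col(posteriors, ties.method = "first") == k)
    if (length(w)) w[1] else nrow(posteriors) + 1L
  }, 0L)
  perm <- order(-fo, first_hit)
  model$means <- model$means[perm, , drop = FALSE]
  model$covariances <- model$covariances[perm]
  model$transition <- model$transition[perm, perm, drop = FALSE]
  model$initial <- model$initial[perm]
  list(model = model, posteriors = posteriors[, perm, drop = FALSE],
       perm = perm)
}

#' Mean dwell time per state
#'
#' Mean length of maximal constant runs of each state in a decoded path,
#' converted to milliseconds.
#'
#' @param path integer state sequence.
#' @param fs sampling rate in samples/s.
#' @param K number of states.
#' @return Length-K vector of mean dwell times in ms (`NA` for unvisited
#'   states).
#' @export
#' @examples
#' dwell_times(c(1, 1, 2, 2), fs = 40, K = 2)  # 50 ms each
dwell_times <- function(path, fs, K) {
  r <- rle(as.integer(path))
  vapply(seq_len(K), function(k) {
    runs <- r$lengths[r$values == k]
    if (!length(runs)) return(NA_real_)
    mean(runs) * 1000 / fs
  }, numeric(1))
}
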