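#' Fractional occupancy
#'
#' Proportion of total time spent in each state. With a hard path this is the
#' state histogram divided by T; with a posterior matrix it is the column mean
#' of the posteriors ("soft" occupancy).
#'
#' @param x integer state path, or T x K posterior matrix.
#' @param K number of states (required for a path).
#' @return Length-K vector summing to 1.
#' @export
#' @examples
#' fractional_occupancy(c(1, 2, 1, 1), K = 2)
fractional_occupancy <- function(x, K = NULL) {
  if (is.matrix(x)) return(colMeans(x))
  K <- stopifnot_scalar_count(K, "K")
  tabulate(as.integer(x), nbins = K) / length(x)
}

#' Empirical transition probability matrix
#'
#' `tp[i, j]` is the number of observed i -> j transitions at consecutive
#' samples divided by the number of departures from state i (diagonal
#' included). Rows for states never visited before the final sample fall back
#' to the uniform distribution `1/K` so that the matrix stays row-stochastic;
#' such rows are flagged in the `"unvisited"` attribute.
#'
#' @param path integer state sequence.
#' @param K number of states.
#' @return K x K row-stochastic matrix with attribute `unvisited`.
#' @export
transition_probability <- function(path, K) {
  K <- stopifnot_scalar_count(K, "K")
  path <- as.integer(path)
  n <- length(path)
  counts <- matrix(0, K, K)
  if (n >= 2) {
    from <- path[-n]
    to <- path[-1]
    for (idx in seq_along(from)) counts[from[idx], to[idx]] <-
        counts[from[idx], to[idx]] + 1
  }
  rs <- rowSums(counts)
  unvisited <- rs == 0
  tp <- counts / ifelse(rs > 0, rs, 1)
  tp[unvisited, ] <- 1 / K
  attr(tp, "unvisited") <- which(unvisited)
  tp
}

weighted_corr <- function(X, w) {
  sw <- sum(w)
  m <- colSums(X * w) / sw
  Xc <- sweep(X, 2, m)
  S <- crossprod(Xc * w, Xc) / sw
  d <- sqrt(pmax(diag(S), 1e-300))
  C <- S / tcrossprod(d)
  diag(C) <- 1
  (C + t(C)) / 2
}

#' Per-state functional connectivity of one subject
#'
#' Posterior-weighted Pearson correlation of the envelope across regions, one
#' R x R matrix per state (weights are the state's posterior probabilities).
#' States whose effective sample size (sum of weights) is below `min_weight`
#' are returned as `NA` matrices and listed in the `"missing_states"`
#' attribute.
#'
#' @param envelope [envelope_ts()] or T x R matrix.
#' @param posteriors T x K posterior matrix (columns used as weights).
#' @param min_weight minimum summed weight for a state to be estimated
#'   (default 10 samples).
#' @return List of K symmetric correlation matrices with unit diagonal.
#' @export
subject_state_fc <- function(envelope, posteriors, min_weight = 10) {
  X <- ts_matrix(envelope)
  stopifnot(nrow(X) == nrow(posteriors))
  K <- ncol(posteriors)
  missing_states <- integer(0)
  out <- lapply(seq_len(K), function(k) {
    w <- posteriors[, k]
    if (sum(w) < min_weight) {
      missing_states <<- c(missing_states, k)
      return(matrix(NA_real_, ncol(X), ncol(X)))
    }
    weighted_corr(X, w)
  })
  attr(out, "missing_states") <- missing_states
  out
}

#' State FC matrices implied by a fitted model
#'
#' Normalizes each state's amplitude-coupling covariance to a correlation
#' matrix.
#'
#' @param model a [gaussian_hmm()].
#' @return List of K correlation matrices.
#' @export
state_fc_from_model <- function(model) {
  lapply(model$covariances, function(S) {
    d <- sqrt(diag(S))
    C <- S / tcrossprod(d)
    diag(C) <- 1
    C
  })
}

#' Newman modularity of a weighted graph under a fixed partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)` on the
#' non-negative weighted graph (self-loops excluded). Negative edge weights
#' are zeroed by default, matching the classic formulation; `signed = TRUE`
#' instead evaluates the signed variant
#' `Q+ - (w- / (w+ + w-)) Q-` that weighs the positive and negative subgraphs
#' asymmetrically.
#'
#' @param fc symmetric R x R weight matrix (e.g. a state FC matrix).
#' @param partition integer or character module label per region.
#' @param signed use the signed-graph variant.
#' @return Scalar modularity Q.
#' @export
modularity_fixed_partition <- function(fc, partition, signed = FALSE) {
  A <- as.matrix(fc)
  stopifnot(nrow(A) == ncol(A), length(partition) == nrow(A))
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8))) {
    stop("`fc` must be symmetric", call. = FALSE)
  }
  diag(A) <- 0
  same <- outer(partition, partition, `==`)
  q_part <- function(W) {
    deg <- rowSums(W)
    two_m <- sum(deg)
    if (two_m == 0) return(c(q = 0, w = 0))
    q <- sum((W - tcrossprod(deg) / two_m) * same) / two_m
    c(q = q, w = two_m / 2)
  }
  pos <- q_part(pmax(A, 0))
  if (!signed) return(unname(pos["q"]))
  neg <- q_part(pmax(-A, 0))
  unname(pos["q"] - neg["w"] / (pos["w"] + neg["w"]) * neg["q"])
}

#' Mean FC over a cluster of connections, per state
#'
#' Averages the off-diagonal FC values inside a binary edge mask separately
#' for each state, giving the 1 x K time-varying cluster-FC feature.
#'
#' @param state_fcs list of K R x R FC matrices.
#' @param cluster_mask symmetric binary R x R matrix marking the edges.
#' @return Length-K vector of masked edge means.
#' @export
cluster_fc <- function(state_fcs, cluster_mask) {
  M <- as.matrix(cluster_mask) != 0
  diag(M) <- FALSE
  if (!any(M)) stop("cluster mask selects no edges", call. = FALSE)
  vapply(state_fcs, function(fc) mean(fc[M]), numeric(1))
}

#' Mean FC between and within canonical networks, per state
#'
#' Block means of each state's FC over every pair of intrinsic connectivity
#' networks: all between-network edges for distinct networks, off-diagonal
#' within-network edges otherwise. With 7 networks this yields the 21 between
#' plus 7 within entries.
#'
#' @param state_fcs list of K R x R FC matrices.
#' @param partition network label per region.
#' @return Matrix with one row per network pair (rownames `"A-B"` / `"A-A"`)
#'   and K columns.
#' @export
icn_pair_fc <- function(state_fcs, partition) {
  partition <- as.character(partition)
  nets <- sort(unique(partition))
  # enumerate unordered pairs incl. self-pairs in a stable order
  pair_idx <- which(upper.tri(matrix(0, length(nets), length(nets)),
                              diag = TRUE), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(pair_idx), length(state_fcs))
  rn <- character(nrow(pair_idx))
  for (p in seq_len(nrow(pair_idx))) {
    a <- nets[pair_idx[p, 1]]
    b <- nets[pair_idx[p, 2]]
    ia <- which(partition == a)
    ib <- which(partition == b)
    mask <- matrix(FALSE, length(partition), length(partition))
    mask[ia, ib] <- TRUE
    mask[ib, ia] <- TRUE
    diag(mask) <- FALSE
    rn[p] <- paste(a, b, sep = "-")
    out[p, ] <- vapply(state_fcs, function(fc) mean(fc[mask]), numeric(1))
  }
  rownames(out) <- rn
  out
}

#' Assemble per-subject multivariate dynamic-connectome features
#'
#' Computes the four multivariate phenotypes for every subject of a fitted
#' HMM: fractional occupancy (1 x K), the full transition-probability matrix
#' flattened row-wise (1 x K^2), time-varying modularity of the subject's
#' per-state FC under the network partition (1 x K) and cluster-averaged
#' time-varying FC (1 x K).
#'
#' @param fit an `hmm_fit` from [fit_hmm()].
#' @param envelopes the subject envelope list the fit was computed from
#'   (same order), used for subject-level state FC.
#' @param partition network label per region (for modularity).
#' @param cluster_mask binary R x R edge mask (for cluster FC), e.g. from
#'   [nbs()] or [threshold_by_density()].
#' @param mode `"hard"` (Viterbi path, default) or `"soft"` (posterior
#'   weighted) for the temporal features.
#' @return A list of per-subject rows: `fo` (n x K), `tp` (n x K^2),
#'   `modularity` (n x K), `cluster_fc` (n x K), `dwell_ms` (n x K), plus
#'   `subject_ids`.
#' @export
dynamic_features <- function(fit, envelopes, partition = NULL,
                             cluster_mask = NULL, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "hmm_fit"))
  K <- fit$model$K
  n <- length(fit$courses)
  fo <- matrix(NA_real_, n, K)
  tp <- matrix(NA_real_, n, K * K)
  qv <- matrix(NA_real_, n, K)
  cfc <- matrix(NA_real_, n, K)
  dw <- matrix(NA_real_, n, K)
  fs_guess <- if (inherits(envelopes[[1]], "envelope_ts")) envelopes[[1]]$fs else NA
  for (s in seq_len(n)) {
    crs <- fit$courses[[s]]
    fo[s, ] <- if (mode == "hard") {
      fractional_occupancy(crs$path, K)
    } else fractional_occupancy(crs$posteriors)
    tps <- transition_probability(crs$path, K)
    tp[s, ] <- as.vector(t(tps))
    if (!is.na(fs_guess)) dw[s, ] <- dwell_times(crs$path, fs_guess, K)
    if (!is.null(partition) || !is.null(cluster_mask)) {
      fcs <- subject_state_fc(envelopes[[s]], crs$posteriors)
      if (!is.null(partition)) {
        qv[s, ] <- vapply(fcs, function(fc) {
          if (anyNA(fc)) NA_real_ else modularity_fixed_partition(fc, partition)
        }, numeric(1))
      }
      if (!is.null(cluster_mask)) {
        cfc[s, ] <- vapply(seq_len(K), function(k) {
          if (anyNA(fcs[[k]])) NA_real_ else cluster_fc(fcs[k], cluster_mask)
        }, numeric(1))
      }
    }
  }
  list(fo = fo, tp = tp, modularity = qv, cluster_fc = cfc, dwell_ms = dw,
       subject_ids = fit$subject_ids)
}
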