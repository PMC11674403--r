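#' Generate dynamics-free surrogate envelopes
#'
#' For each subject, draws i.i.d. Gaussian samples with that subject's static
#' (time-averaged) mean and covariance and the same length as the original
#' series: the static covariance structure is preserved while all temporal
#' ordering of states is destroyed.
#'
#' @param envelopes list of [envelope_ts()] or T x R matrices, one per
#'   subject.
#' @param seed integer seed.
#' @return A list of surrogate matrices with the same names and dimensions.
#' @export
generate_surrogate <- function(envelopes, seed = 1L) {
  with_seed(seed, {
    out <- lapply(envelopes, function(e) {
      X <- ts_matrix(e)
      mu <- colMeans(X)
      U <- chol(regularize_cov(cov(X)))
      Z <- matrix(rnorm(nrow(X) * ncol(X)), nrow(X), ncol(X)) %*% U
      sweep(Z, 2, mu, `+`)
    })
    names(out) <- names(envelopes)
    out
  })
}

#' Null-model origin of each multivariate feature space
#'
#' Repeats the full state inference on surrogate data: for each of
#' `n_surrogates` dynamics-free surrogate datasets, an HMM with the same K is
#' fitted (states canonically ordered) and the multivariate features are
#' extracted; the origin of each feature space is the mean feature vector over
#' surrogates. Surrogates whose HMM fit fails are dropped with a warning.
#'
#' @param envelopes list of subject envelopes (matrices or [envelope_ts()]).
#' @param K number of states for the surrogate HMM fits.
#' @param partition optional network labels (enables the modularity origin).
#' @param cluster_mask optional binary edge mask (enables the cluster-FC
#'   origin).
#' @param n_surrogates number of surrogate datasets (default 50).
#' @param seed integer seed; surrogate `i` uses a substream derived from it.
#' @param level `"group"` (default): origin is the mean of the
#'   subject-averaged feature vector; `"subject"`: per-subject origins.
#' @param n_restarts,max_iter,tol HMM fitting controls for the surrogate fits.
#' @param mode temporal feature mode passed to [dynamic_features()].
#' @return A `null_origin` list: `origins` (named list with `fo`, `tp` and,
#'   when enabled, `modularity` and `cluster_fc`), `n_used`, `n_surrogates`,
#'   `level`, `K`.
#' @export
compute_null_origin <- function(envelopes, K, partition = NULL,
                                cluster_mask = NULL, n_surrogates = 50L,
                                seed = 1L, level = c("group", "subject"),
                                n_restarts = 2L, max_iter = 100L, tol = 1e-4,
                                mode = "hard") {
  level <- match.arg(level)
  n_surrogates <- stopifnot_scalar_count(n_surrogates, "n_surrogates")
  acc <- list()
  n_used <- 0L
  for (i in seq_len(n_surrogates)) {
    feats <- tryCatch({
      surr <- generate_surrogate(envelopes,
                                 seed = substream_seed(seed,
                                                       paste0("surrogate", i)))
      stacked <- standardize_concatenate(surr)
      fit <- fit_hmm(stacked, K = K, n_restarts = n_restarts, seed =
                       substream_seed(seed, paste0("fit", i)),
                     tol = tol, max_iter = max_iter)
      dynamic_features(fit, surr, partition = partition,
                       cluster_mask = cluster_mask, mode = mode)
    }, error = function(e) {
      warning(sprintf("surrogate %d dropped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(feats)) next
    n_used <- n_used + 1L
    take <- c("fo", "tp",
              if (!is.null(partition)) "modularity",
              if (!is.null(cluster_mask)) "cluster_fc")
    for (nm in take) {
      # subjects with a missing (starved) state are excluded from the group
      # average rather than poisoning the origin with NA
      v <- if (level == "group") colMeans(feats[[nm]], na.rm = TRUE) else feats[[nm]]
      acc[[nm]] <- if (is.null(acc[[nm]])) list(v) else c(acc[[nm]], list(v))
    }
  }
  if (n_used == 0L) stop("all surrogate fits failed", call. = FALSE)
  origins <- lapply(acc, function(lst) Reduce(`+`, lst) / length(lst))
  structure(list(origins = origins, n_used = n_used,
                 n_surrogates = n_surrogates, level = level, K = K),
            class = "null_origin")
}
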