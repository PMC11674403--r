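# Pooled fixed-effects ANCOVA machinery shared by the edgewise and scalar
# state contrasts: factor state (K levels) + covariates age (centered) and
# sex, F for the state factor by extra sum of squares.
ancova_design <- function(subject, state, ages, sexes) {
  age_c <- ages - mean(ages)
  sex01 <- as.numeric(factor(sexes)) - 1
  X0 <- cbind(1, age_c[subject], sex01[subject])
  state_f <- factor(state)
  K <- nlevels(state_f)
  D <- model.matrix(~ state_f)[, -1, drop = FALSE]
  X1 <- cbind(X0, D)
  list(qr0 = qr(X0), qr1 = qr(X1), df1 = K - 1L,
       df2 = nrow(X1) - ncol(X1), n = nrow(X1))
}

ancova_f <- function(design, Y) {
  Y <- as.matrix(Y)
  rss0 <- colSums(qr.resid(design$qr0, Y)^2)
  rss1 <- colSums(qr.resid(design$qr1, Y)^2)
  f <- ((rss0 - rss1) / design$df1) / (rss1 / design$df2)
  list(f = pmax(f, 0), rss0 = rss0, rss1 = rss1)
}

# Stack per-subject per-state FC into a (n_subj * K) x E edge-value matrix.
# Subjects with any missing (all-NA) state matrix are dropped so that the
# within-subject permutation scheme of the NBS stays exchangeable.
stack_edge_values <- function(subject_state_fc) {
  complete <- vapply(subject_state_fc, function(fcs) {
    !any(vapply(fcs, anyNA, TRUE))
  }, TRUE)
  if (!all(complete)) {
    warning(sprintf("%d subject(s) dropped from edgewise contrasts (missing state FC)",
                    sum(!complete)))
    subject_state_fc <- subject_state_fc[complete]
  }
  n <- length(subject_state_fc)
  K <- length(subject_state_fc[[1]])
  R <- nrow(subject_state_fc[[1]][[1]])
  ut <- upper.tri(matrix(0, R, R))
  Y <- matrix(NA_real_, n * K, sum(ut))
  subject <- integer(n * K)
  state <- integer(n * K)
  row <- 0L
  for (s in seq_len(n)) {
    for (k in seq_len(K)) {
      row <- row + 1L
      Y[row, ] <- subject_state_fc[[s]][[k]][ut]
      subject[row] <- s
      state[row] <- k
    }
  }
  list(Y = Y, subject = subject, state = state, R = R, K = K, ut = ut,
       kept = which(complete))
}

#' Edgewise state ANCOVA
#'
#' For every connection, a pooled linear-model ANCOVA of the factor state
#' (K levels) with covariates age and sex on the subject-by-state FC values;
#' the F statistic for the state factor comes from the extra sum of squares.
#'
#' @param subject_state_fc list over subjects of K-length lists of R x R FC
#'   matrices (see [subject_state_fc()]).
#' @param ages,sexes per-subject covariates.
#' @return An `edge_stats` list: `f_values` (symmetric R x R, zero diagonal)
#'   and `df` (numerator, denominator).
#' @export
edgewise_state_ancova <- function(subject_state_fc, ages, sexes) {
  st <- stack_edge_values(subject_state_fc)
  design <- ancova_design(st$subject, st$state, ages[st$kept], sexes[st$kept])
  f <- ancova_f(design, st$Y)$f
  F_mat <- matrix(0, st$R, st$R)
  F_mat[st$ut] <- f
  F_mat <- F_mat + t(F_mat)
  structure(list(f_values = F_mat, df = c(design$df1, design$df2)),
            class = "edge_stats")
}

#' Threshold an F matrix at a connection density
#'
#' Keeps the top `round(density * E)` edges by F value, where
#' `E = R(R-1)/2`; ties are broken by edge index (upper-triangle order), so
#' the result is deterministic.
#'
#' @param f_values symmetric R x R matrix (e.g. from
#'   [edgewise_state_ancova()]).
#' @param density fraction of edges to keep, in (0, 1].
#' @return Binary symmetric R x R adjacency matrix.
#' @export
threshold_by_density <- function(f_values, density) {
  F_mat <- as.matrix(f_values)
  R <- nrow(F_mat)
  stopifnot(density > 0, density <= 1)
  ut <- which(upper.tri(F_mat))
  E <- length(ut)
  n_keep <- round(density * E)
  ord <- order(-F_mat[ut], seq_along(ut))
  keep <- ut[ord[seq_len(n_keep)]]
  A <- matrix(0L, R, R)
  A[keep] <- 1L
  A + t(A)
}

component_clusters <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- list()
  for (c_id in seq_len(comp$no)) {
    members <- which(comp$membership == c_id)
    sub <- adjacency[members, members, drop = FALSE]
    n_edges <- sum(sub) / 2
    if (n_edges == 0) next
    ij <- which(upper.tri(sub) & sub == 1, arr.ind = TRUE)
    clusters[[length(clusters) + 1L]] <-
      cbind(region_i = members[ij[, 1]], region_j = members[ij[, 2]])
  }
  clusters
}

#' Network-based statistic for cross-state FC differences
#'
#' Observed clusters are the connected components of the density-thresholded
#' suprathreshold graph of edgewise state-ANCOVA F values. The null
#' distribution of the maximum component size (in edges) comes from
#' permutations of the state labels within each subject (covariates
#' untouched); family-wise-error-corrected p values use the +1 correction.
#'
#' @inheritParams edgewise_state_ancova
#' @param density connection density for thresholding.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return An `nbs_result` list: `clusters` (edge lists), `sizes`,
#'   `fwer_p`, `n_perm`, `density`, `f_values`, `adjacency`, `df`,
#'   `null_max_size`.
#' @export
nbs <- function(subject_state_fc, ages, sexes, density = 0.05,
                n_perm = 1000L, seed = 1L) {
  n_perm <- stopifnot_scalar_count(n_perm, "n_perm", min = 100L)
  st <- stack_edge_values(subject_state_fc)
  design <- ancova_design(st$subject, st$state, ages[st$kept], sexes[st$kept])
  obs <- ancova_f(design, st$Y)
  F_mat <- matrix(0, st$R, st$R)
  ut_idx <- which(st$ut)
  F_mat[ut_idx] <- obs$f
  F_mat <- F_mat + t(F_mat)
  A <- threshold_by_density(F_mat, density)
  clusters <- component_clusters(A)
  sizes <- vapply(clusters, nrow, 0L)

  n_subj <- length(st$kept)
  K <- st$K
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm_rows <- unlist(lapply(seq_len(n_subj), function(s) {
        (s - 1L) * K + sample.int(K)
      }))
      # permuting responses within subject: RSS0 is invariant because the
      # covariate rows are identical within a subject block
      rss1 <- colSums(qr.resid(design$qr1, st$Y[perm_rows, , drop = FALSE])^2)
      f <- pmax(((obs$rss0 - rss1) / design$df1) / (rss1 / design$df2), 0)
      Fp <- matrix(0, st$R, st$R)
      Fp[ut_idx] <- f
      Fp <- Fp + t(Fp)
      cl <- component_clusters(threshold_by_density(Fp, density))
      if (length(cl)) max(vapply(cl, nrow, 0L)) else 0L
    }, 0L)
  })
  fwer_p <- vapply(sizes, function(sz) {
    (1 + sum(null_max >= sz)) / (1 + n_perm)
  }, numeric(1))
  structure(list(clusters = clusters, sizes = sizes, fwer_p = fwer_p,
                 n_perm = n_perm, density = density, f_values = F_mat,
                 adjacency = A, df = c(design$df1, design$df2),
                 null_max_size = null_max),
            class = "nbs_result")
}

#' One-way state ANCOVA for a scalar state feature
#'
#' The same pooled linear-model machinery as the edgewise contrast, applied
#' to one subject-by-state scalar (e.g. per-state modularity or fractional
#' occupancy): factor state, covariates age and sex.
#'
#' @param values n_subjects x K matrix of the feature.
#' @param ages,sexes per-subject covariates.
#' @return List with `F`, `df`, `p`, `eta_p2`, `ss_state`, `ss_error`.
#' @export
state_feature_ancova <- function(values, ages, sexes) {
  values <- as.matrix(values)
  n <- nrow(values)
  K <- ncol(values)
  subject <- rep(seq_len(n), each = K)
  state <- rep(seq_len(K), times = n)
  y <- as.vector(t(values))
  keep <- is.finite(y)
  design <- ancova_design(subject[keep], state[keep], ages, sexes)
  res <- ancova_f(design, y[keep])
  ss_state <- res$rss0 - res$rss1
  f <- unname(res$f)
  list(F = f, df = c(design$df1, design$df2),
       p = pf(f, design$df1, design$df2, lower.tail = FALSE),
       eta_p2 = unname(ss_state / (ss_state + res$rss1)),
       ss_state = unname(ss_state), ss_error = unname(res$rss1))
}
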