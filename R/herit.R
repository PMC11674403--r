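#' Euclidean distance between two feature vectors
#'
#' Pairwise similarity of a multivariate phenotype: the Euclidean norm of the
#' difference, independent of any origin.
#'
#' @param x_a,x_b numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
pair_distance <- function(x_a, x_b) {
  stopifnot(length(x_a) == length(x_b))
  sqrt(sum((x_a - x_b)^2))
}

#' Distance of a subject's feature vector from the null origin
#'
#' The scalar phenotype entering variance-component modeling: the Euclidean
#' distance of the subject's multivariate feature from the surrogate-derived
#' origin point.
#'
#' @param x subject feature vector.
#' @param origin origin vector of the same dimension (e.g. one entry of
#'   [compute_null_origin()]'s `origins`).
#' @return Non-negative scalar.
#' @export
subject_origin_distance <- function(x, origin) {
  origin <- as.numeric(origin)
  stopifnot(length(x) == length(origin))
  sqrt(sum((x - origin)^2))
}

pair_frame <- function(distances, pairs) {
  stopifnot(length(distances) == nrow(pairs))
  d <- data.frame(dist = as.numeric(distances),
                  zygosity = factor(pairs$zygosity,
                                    levels = c("MZ", "DZ", "UR")),
                  age_diff = pairs$age_diff,
                  pair_sex = factor(pairs$pair_sex))
  d <- droplevels(d[is.finite(d$dist), , drop = FALSE])
  if (nlevels(d$zygosity) < 2) {
    stop("need at least two zygosity groups with finite distances",
         call. = FALSE)
  }
  d
}

# covariate part of the pair-model formula; a sex factor that collapses to
# one level (e.g. after dropping missing distances) is omitted
pair_covariate_terms <- function(d) {
  if (nlevels(d$pair_sex) >= 2) "age_diff + pair_sex" else "age_diff"
}

#' Sibling-status ANCOVA on pairwise feature distances
#'
#' One-way ANCOVA of the factor sibling status (MZ, DZ, UR) on the pairwise
#' Euclidean distance of a multivariate feature, adjusting for the pair's age
#' difference and sex. A genetically graded ordering of the group means
#' (MZ < DZ < UR distances) is the signature of heritability.
#'
#' @param distances per-pair distance values (see [pair_distance()]).
#' @param pairs data.frame with columns `zygosity` (`"MZ"/"DZ"/"UR"`),
#'   `pair_sex`, `age_diff`.
#' @param n_tests size of the Bonferroni family (default 20: four features by
#'   five bands).
#' @return An `ancova_result` list: `F`, `df`, `p`, `p_bonf`, `eta_p2`,
#'   `bf01`, `group_means`.
#' @export
sibling_ancova <- function(distances, pairs, n_tests = 20L) {
  d <- pair_frame(distances, pairs)
  cov_terms <- pair_covariate_terms(d)
  full <- lm(as.formula(paste("dist ~", cov_terms, "+ zygosity")), data = d)
  null <- lm(as.formula(paste("dist ~", cov_terms)), data = d)
  a <- anova(null, full)
  ss_z <- a[["Sum of Sq"]][2]
  ss_e <- a$RSS[2]
  f <- a$F[2]
  p <- a[["Pr(>F)"]][2]
  structure(list(
    F = f,
    df = c(a$Df[2], a$Res.Df[2]),
    p = p,
    p_bonf = min(1, n_tests * p),
    eta_p2 = ss_z / (ss_z + ss_e),
    bf01 = bf01_bic(distances, pairs),
    group_means = tapply(d$dist, d$zygosity, mean, na.rm = TRUE)
  ), class = "ancova_result")
}

#' Two-way ANCOVA of sibling status by feature component
#'
#' Componentwise follow-up of [sibling_ancova()]: the dependent variable is
#' the absolute within-pair difference of each scalar component of a
#' multivariate feature (states for occupancy-type features, off-diagonal
#' state pairs for transition probabilities); factors are sibling status and
#' component with their interaction, covariates are pair age difference and
#' pair sex. F tests are type II (each term against the model without it, on
#' top of all other terms).
#'
#' @param comp_a,comp_b n_pairs x m matrices of the component values of the
#'   two pair members.
#' @param pairs pair data.frame as in [sibling_ancova()].
#' @param component_labels optional length-m labels.
#' @return A data.frame with one row per effect (`sibling`, `component`,
#'   `sibling:component`) giving F, df and p.
#' @export
componentwise_twoway_ancova <- function(comp_a, comp_b, pairs,
                                        component_labels = NULL) {
  comp_a <- as.matrix(comp_a)
  comp_b <- as.matrix(comp_b)
  stopifnot(all(dim(comp_a) == dim(comp_b)), nrow(comp_a) == nrow(pairs))
  m <- ncol(comp_a)
  labels <- component_labels %||% paste0("c", seq_len(m))
  n <- nrow(pairs)
  d <- data.frame(
    y = as.vector(abs(comp_a - comp_b)),
    zygosity = factor(rep(pairs$zygosity, times = m),
                      levels = c("MZ", "DZ", "UR")),
    component = factor(rep(labels, each = n), levels = labels),
    age_diff = rep(pairs$age_diff, times = m),
    pair_sex = factor(rep(pairs$pair_sex, times = m))
  )
  full <- lm(y ~ age_diff + pair_sex + zygosity * component, data = d)
  no_int <- lm(y ~ age_diff + pair_sex + zygosity + component, data = d)
  no_z <- lm(y ~ age_diff + pair_sex + component, data = d)
  no_c <- lm(y ~ age_diff + pair_sex + zygosity, data = d)
  row_of <- function(reduced, base, label) {
    a <- anova(reduced, base)
    data.frame(effect = label, F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
               p = a[["Pr(>F)"]][2])
  }
  rbind(row_of(no_z, no_int, "sibling"),
        row_of(no_c, no_int, "component"),
        row_of(no_int, full, "sibling:component"))
}

#' BIC-approximate Bayes factor for the sibling-status effect
#'
#' `BF01 = exp((BIC_H1 - BIC_H0) / 2)` comparing the covariates-only linear
#' model (H0) against covariates plus sibling status (H1); values above 1
#' favor the null of no heritability.
#'
#' @inheritParams sibling_ancova
#' @return Scalar BF01 (`1 / BF10`).
#' @export
bf01_bic <- function(distances, pairs) {
  d <- pair_frame(distances, pairs)
  cov_terms <- pair_covariate_terms(d)
  h0 <- lm(as.formula(paste("dist ~", cov_terms)), data = d)
  h1 <- lm(as.formula(paste("dist ~", cov_terms, "+ zygosity")), data = d)
  exp((BIC(h1) - BIC(h0)) / 2)
}

#' Convert eta-squared to Cohen's f
#'
#' `f = sqrt(eta2 / (1 - eta2))`.
#'
#' @param eta2 (partial) eta-squared effect size.
#' @return Cohen's f.
#' @export
eta2_to_f <- function(eta2) sqrt(eta2 / (1 - eta2))

#' Power of the sibling-status ANCOVA at a given effect size
#'
#' Noncentral-F power of a one-way ANCOVA with `k_groups` levels and
#' `n_covariates` covariates, noncentrality `f^2 * n_total`.
#'
#' @param f Cohen's f effect size.
#' @param n_total total number of observations.
#' @param k_groups number of factor levels.
#' @param n_covariates number of covariates.
#' @param alpha significance level.
#' @return Power in `[0, 1]`.
#' @export
ancova_power <- function(f, n_total, k_groups = 3L, n_covariates = 2L,
                         alpha = 0.05) {
  df1 <- k_groups - 1
  df2 <- n_total - k_groups - n_covariates
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = f^2 * n_total, lower.tail = FALSE)
}

#' Minimum detectable effect size of the sibling-status ANCOVA
#'
#' Smallest Cohen's f for which a one-way ANCOVA with `k_groups` groups and
#' `n_covariates` covariates on `n_total` observations reaches the target
#' power at level `alpha` (noncentral-F power with noncentrality
#' `f^2 * n_total`, found by bisection).
#'
#' @param n_total total number of observations (pairs).
#' @param k_groups number of factor levels (default 3: MZ, DZ, UR).
#' @param n_covariates number of covariates (default 2: age, sex).
#' @param alpha significance level.
#' @param power target power.
#' @return Cohen's f (scalar).
#' @export
#' @examples
#' min_detectable_f(463)  # about 0.145
min_detectable_f <- function(n_total, k_groups = 3L, n_covariates = 2L,
                             alpha = 0.05, power = 0.80) {
  lo <- 1e-6
  hi <- 2
  while (ancova_power(hi, n_total, k_groups, n_covariates, alpha) < power) {
    hi <- hi * 2
    if (hi > 100) stop("power target unreachable", call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (ancova_power(mid, n_total, k_groups, n_covariates, alpha) < power) {
      lo <- mid
    } else hi <- mid
  }
  (lo + hi) / 2
}
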