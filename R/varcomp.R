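#' Residualize a phenotype for age and sex
#'
#' Returns the residuals of a linear regression of the phenotype on age and
#' sex, standardized to unit variance, so downstream variance components are
#' fractions of the adjusted phenotypic variance.
#'
#' @param phenotype per-subject scalar phenotype.
#' @param age,sex per-subject covariates.
#' @return Numeric vector of standardized residuals (mean 0, SD 1).
#' @export
residualize <- function(phenotype, age, sex) {
  if (sum(is.finite(phenotype)) < 3) {
    stop("too few finite phenotype values to residualize", call. = FALSE)
  }
  r <- resid(lm(phenotype ~ age + factor(sex), na.action = na.exclude))
  s <- sd(r, na.rm = TRUE)
  if (is.na(s) || s < 1e-10) return(as.numeric(r))  # fully explained
  as.numeric(r / s)
}

twin_structures <- list(
  ACE = c("a", "c", "e"), ADE = c("a", "d", "e"), AE = c("a", "e"),
  CE = c("c", "e"), DE = c("d", "e"), E = "e"
)

# expected within-pair correlations of the A, C, D components
twin_r_table <- rbind(MZ = c(a = 1, c = 1, d = 1),
                      DZ = c(a = 0.5, c = 1, d = 0.25),
                      UR = c(a = 0, c = 0, d = 0))

# -2 log-likelihood of the bivariate-normal pair model from per-zygosity
# sufficient statistics (pair scatter matrices); theta are SD-scale params.
twin_m2ll <- function(theta, comps, stats) {
  v <- c(a = 0, c = 0, d = 0, e = 0)
  v[comps] <- theta^2
  total <- sum(v)
  m2ll <- 0
  for (g in names(stats)) {
    st <- stats[[g]]
    if (st$n == 0) next
    cv <- sum(twin_r_table[g, ] * v[c("a", "c", "d")])
    det_s <- total^2 - cv^2
    if (det_s <= 0 || total <= 0) return(1e10)
    # trace(solve(Sigma) %*% S) with Sigma = [[total, cv], [cv, total]]
    tr <- (total * (st$s11 + st$s22) - 2 * cv * st$s12) / det_s
    m2ll <- m2ll + st$n * (log(det_s) + 2 * log(2 * pi)) + tr
  }
  m2ll
}

twin_suffstats <- function(y_a, y_b, zygosity) {
  stats <- list()
  for (g in c("MZ", "DZ", "UR")) {
    idx <- which(zygosity == g)
    stats[[g]] <- list(n = length(idx),
                       s11 = sum(y_a[idx]^2), s22 = sum(y_b[idx]^2),
                       s12 = sum(y_a[idx] * y_b[idx]))
  }
  stats
}

#' Fit a twin variance-component model by maximum likelihood
#'
#' Bivariate-normal pair likelihood with expected within-pair covariance
#' `a^2 rA + c^2 rC + d^2 rD`, where `(rA, rC, rD)` is `(1, 1, 1)` for MZ,
#' `(0.5, 1, 0.25)` for DZ and `(0, 0, 0)` for unrelated pairs. Parameters
#' are SD-scale path coefficients constrained non-negative, optimized by
#' multi-start bounded quasi-Newton. The phenotype is assumed already
#' residualized and centered (see [residualize()]); only variance parameters
#' are estimated. Confidence intervals come from the delta method on the
#' unconstrained parameterization and may cross zero.
#'
#' @param y_a,y_b phenotype of the first and second pair member.
#' @param zygosity per-pair labels among `"MZ"`, `"DZ"`, `"UR"`.
#' @param structure model family: `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"DE"`
#'   or `"E"`.
#' @param n_restarts number of optimizer starts.
#' @param seed seed for start-point jitter.
#' @return A `varcomp_fit` list: `structure`, `fractions` (a2/c2/d2/e2 of
#'   total), `h2`, `H2`, `ci` (per fraction and for h2/H2), `minus2ll`,
#'   `aic`, `n_params`, `total_var`, `convergence`.
#' @export
fit_twin_model <- function(y_a, y_b, zygosity, structure = "ACE",
                           n_restarts = 10L, seed = 1L) {
  structure_name <- match.arg(structure, names(twin_structures))
  comps <- twin_structures[[structure_name]]
  zygosity <- as.character(zygosity)
  keep <- is.finite(y_a) & is.finite(y_b)
  if (!all(keep)) {
    y_a <- y_a[keep]
    y_b <- y_b[keep]
    zygosity <- zygosity[keep]
  }
  if (length(y_a) < 3) stop("too few complete pairs", call. = FALSE)
  ok <- zygosity %in% rownames(twin_r_table)
  if (!all(ok)) stop("unknown zygosity label(s): ",
                     paste(unique(zygosity[!ok]), collapse = ", "),
                     call. = FALSE)
  has_mz <- any(zygosity == "MZ")
  if (!has_mz || !any(zygosity %in% c("DZ", "UR"))) {
    if (length(comps) > 1) {
      stop("need MZ pairs plus DZ or UR pairs for an informative fit",
           call. = FALSE)
    }
  }
  stats <- twin_suffstats(y_a, y_b, zygosity)
  obj <- function(theta) twin_m2ll(theta, comps, stats)
  sd0 <- sd(c(y_a, y_b))
  p <- length(comps)
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      init <- if (r == 1) rep(sd0 / sqrt(p), p) else runif(p, 0.05, 1.5 * sd0)
      tryCatch(
        optim(init, obj, method = "L-BFGS-B", lower = rep(0, p),
              upper = rep(10 * sd0 + 1, p),
              control = list(factr = 1e4, maxit = 500)),
        error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("twin model optimization failed in all restarts",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  theta <- best$par
  m2ll <- best$value

  v <- c(a = 0, c = 0, d = 0, e = 0)
  v[comps] <- theta^2
  total <- sum(v)
  fractions <- v / total
  h2 <- unname(if ("d" %in% comps) fractions["a"] else
    fractions["a"] / (fractions["a"] + fractions["c"] + fractions["e"]))
  H2 <- unname((fractions["a"] + fractions["d"]) /
                 (fractions["a"] + fractions["d"] + fractions["e"]))

  ci <- twin_delta_ci(theta, comps, stats, obj)

  structure(list(structure = structure_name, fractions = fractions,
                 h2 = h2, H2 = H2, ci = ci, minus2ll = m2ll,
                 aic = m2ll + 2 * p, n_params = p, total_var = total,
                 convergence = best$convergence),
            class = "varcomp_fit")
}

# Delta-method CIs for the variance fractions and h2/H2, from the numerical
# Hessian of -2LL at the (possibly boundary) MLE.
twin_delta_ci <- function(theta, comps, stats, obj) {
  p <- length(theta)
  H <- tryCatch(optimHess(theta, obj), error = function(e) NULL)
  cov_theta <- if (is.null(H)) matrix(NA_real_, p, p) else {
    tryCatch(2 * MASS::ginv(H), error = function(e) matrix(NA_real_, p, p))
  }
  frac_fun <- function(th) {
    v <- c(a = 0, c = 0, d = 0, e = 0)
    v[comps] <- th^2
    fr <- v / sum(v)
    h2 <- unname(if ("d" %in% comps) fr["a"] else
      fr["a"] / (fr["a"] + fr["c"] + fr["e"]))
    H2 <- unname((fr["a"] + fr["d"]) / (fr["a"] + fr["d"] + fr["e"]))
    c(fr, h2 = h2, H2 = H2)
  }
  est <- frac_fun(theta)
  grad <- matrix(0, length(est), p)
  eps <- 1e-5
  for (j in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + eps
    tm[j] <- max(tm[j] - eps, 0)
    grad[, j] <- (frac_fun(tp) - frac_fun(tm)) / (tp[j] - tm[j])
  }
  se <- sqrt(pmax(diag(grad %*% cov_theta %*% t(grad)), 0))
  out <- cbind(estimate = est, lower = est - 1.96 * se,
               upper = est + 1.96 * se)
  rownames(out) <- names(est)
  out
}

#' Likelihood-ratio test between nested twin models
#'
#' `chi` is the increase in -2 log-likelihood from full to nested; the p
#' value uses the plain chi-squared reference with the difference in
#' parameter count (the conventional 3.84 criterion at one df), without a
#' boundary mixture correction.
#'
#' @param full,nested `varcomp_fit` objects (nested within full).
#' @return An `lrt_result` list: `chi`, `delta_df`, `p`.
#' @export
lrt <- function(full, nested) {
  chi <- nested$minus2ll - full$minus2ll
  if (chi < -1e-6) {
    warning("nested model has higher likelihood than full model; chi clamped to 0")
  }
  chi <- max(chi, 0)
  delta_df <- full$n_params - nested$n_params
  structure(list(chi = chi, delta_df = delta_df,
                 p = pchisq(chi, delta_df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Full ACE/ADE model selection for one phenotype
#'
#' Chooses the full family by the classical twin-correlation heuristic
#' (`rDZ < rMZ / 2` implies dominance, hence ADE; otherwise ACE), fits the
#' full model and its nested submodels (AE plus CE or DE), and reports LRTs
#' and AIC for each. The full model is retained unless a nested model fits
#' significantly better; since dropping a parameter can never raise the
#' likelihood, in practice the full family model is the selected one, which
#' matches the reporting convention of classical twin tables.
#'
#' @inheritParams fit_twin_model
#' @return A list: `family`, `r_mz`, `r_dz`, `fits` (named list of
#'   `varcomp_fit`s), `lrt` (data.frame of nested-model tests), `chosen`.
#' @export
twin_model_selection <- function(y_a, y_b, zygosity, n_restarts = 10L,
                                 seed = 1L) {
  zygosity <- as.character(zygosity)
  de_cor <- function(g) {
    idx <- which(zygosity == g & is.finite(y_a) & is.finite(y_b))
    if (length(idx) < 3) return(NA_real_)
    cor(c(y_a[idx], y_b[idx]), c(y_b[idx], y_a[idx]))  # double entry
  }
  r_mz <- de_cor("MZ")
  r_dz <- de_cor("DZ")
  family <- if (!is.na(r_mz) && !is.na(r_dz) && r_dz < r_mz / 2) "ADE" else "ACE"
  nested_names <- c("AE", if (family == "ACE") "CE" else "DE")
  fits <- lapply(c(family, nested_names), function(s) {
    fit_twin_model(y_a, y_b, zygosity, structure = s,
                   n_restarts = n_restarts, seed = seed)
  })
  names(fits) <- c(family, nested_names)
  full <- fits[[family]]
  lrt_rows <- do.call(rbind, lapply(nested_names, function(s) {
    res <- lrt(full, fits[[s]])
    data.frame(nested = s, chi = res$chi, delta_df = res$delta_df, p = res$p,
               aic = fits[[s]]$aic)
  }))
  chosen <- family
  better <- lrt_rows$p < 0.05 & lrt_rows$aic < full$aic
  if (any(better)) chosen <- lrt_rows$nested[which(better)[1]]
  list(family = family, r_mz = r_mz, r_dz = r_dz, fits = fits,
       lrt = lrt_rows, chosen = fits[[chosen]])
}
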