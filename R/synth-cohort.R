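#' Configuration of a synthetic twin cohort
#'
#' Defaults reproduce the study conditions of a full-scale twin EEG design:
#' 206 monozygotic (MZ) pairs, 112 sex-matched dizygotic (DZ) pairs and 145
#' sex-matched unrelated (UR) pairs (463 pairs, 926 subjects), 54 cortical
#' regions, six connectome states, 40 Hz envelope sampling and six minutes of
#' recording per subject, ages drawn uniformly on 23-40 years.
#'
#' @param n_mz_pairs,n_dz_pairs,n_ur_pairs pair counts per zygosity group.
#' @param n_regions number of regions R.
#' @param n_states number of states K.
#' @param fs envelope sampling rate, samples/s.
#' @param duration_s recording length per subject in seconds; must satisfy
#'   `duration_s * fs >= 10 * n_states`.
#' @param bands character vector of band names (see [canonical_bands()]);
#'   each band is simulated as an independent realization.
#' @param age_mismatch_frac fraction of pairs whose members are not age-matched
#'   within one year (realistic cohorts contain a few non-matched unrelated
#'   pairs).
#' @param seed global integer seed; fans out to per-subject substreams.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_mz_pairs = 206L, n_dz_pairs = 112L,
                          n_ur_pairs = 145L, n_regions = 54L, n_states = 6L,
                          fs = 40, duration_s = 360, bands = "alpha",
                          age_mismatch_frac = 0.01, seed = 1L) {
  for (nm in c("n_mz_pairs", "n_dz_pairs", "n_ur_pairs", "n_regions",
               "n_states")) {
    stopifnot_scalar_count(get(nm), nm)
  }
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (duration_s * fs < 10 * n_states) {
    stop("`duration_s * fs` must be at least 10 * n_states", call. = FALSE)
  }
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_ur_pairs = as.integer(n_ur_pairs),
                 n_regions = as.integer(n_regions),
                 n_states = as.integer(n_states),
                 fs = fs, duration_s = duration_s, bands = bands,
                 age_mismatch_frac = age_mismatch_frac,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Specify the variance decomposition of a heritable latent trait
#'
#' Fractions of phenotypic variance attributed to additive genetic (A), common
#' environmental (C), dominance genetic (D) and unique environmental (E)
#' sources. ACE and ADE are mutually exclusive (`c2 * d2 == 0`), matching the
#' classical twin model families.
#'
#' @param a2,c2,d2,e2 variance fractions in `[0, 1]` summing to 1.
#' @return An `ace_spec` list.
#' @export
#' @examples
#' ace_spec(a2 = 0.4, c2 = 0.2, e2 = 0.4)
ace_spec <- function(a2 = 0, c2 = 0, d2 = 0, e2 = 1) {
  v <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(v < 0) || any(v > 1)) {
    stop("variance fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(v) - 1) > 1e-8) {
    stop("variance fractions must sum to 1 (got ", sum(v), ")", call. = FALSE)
  }
  if (c2 * d2 > 0) {
    stop("C and D cannot both be non-zero (choose ACE or ADE)", call. = FALSE)
  }
  structure(as.list(v), class = "ace_spec")
}

zygosity_correlations <- function(zygosity) {
  # (rA, rC, rD) per classical twin theory
  switch(zygosity,
         MZ = c(1, 1, 1),
         DZ = c(0.5, 1, 0.25),
         UR = c(0, 0, 0),
         stop("unknown zygosity: ", zygosity, call. = FALSE))
}

#' Sample heritable latent traits for twin pairs
#'
#' Draws unit-variance latent phenotypes whose within-pair correlation follows
#' the classical twin decomposition: `rMZ = a2 + c2 + d2`,
#' `rDZ = 0.5 a2 + c2 + 0.25 d2`, `rUR = 0`. Each latent dimension is sampled
#' independently; pair members appear in consecutive rows.
#'
#' @param spec an [ace_spec()].
#' @param pair_counts integer vector `c(mz, dz, ur)` of pair counts.
#' @param n_latents number of independent latent dimensions per subject.
#' @param seed integer seed.
#' @return A list with `latents` (2*sum(pair_counts) x n_latents matrix),
#'   `zygosity` (per subject) and `pair` (pair index per subject).
#' @export
sample_ace_latents <- function(spec, pair_counts, n_latents, seed = 1L) {
  if (!inherits(spec, "ace_spec")) spec <- do.call(ace_spec, as.list(spec))
  stopifnot(length(pair_counts) == 3L, all(pair_counts >= 0))
  n_latents <- stopifnot_scalar_count(n_latents, "n_latents")
  zyg <- rep(c("MZ", "DZ", "UR"), times = pair_counts)
  n_pairs <- length(zyg)
  with_seed(seed, {
    lat <- matrix(0, 2L * n_pairs, n_latents)
    load <- sqrt(c(spec$a2, spec$c2, spec$d2, spec$e2))
    for (g in c("MZ", "DZ", "UR")) {
      idx <- which(zyg == g)
      if (!length(idx)) next
      n <- length(idx)
      r <- zygosity_correlations(g)
      pair_block <- matrix(0, 2L * n, n_latents)
      for (j in seq_along(r)) {        # A, C, D components
        if (load[j] == 0) next
        z1 <- matrix(rnorm(n * n_latents), n, n_latents)
        z2 <- matrix(rnorm(n * n_latents), n, n_latents)
        x1 <- z1
        x2 <- r[j] * z1 + sqrt(1 - r[j]^2) * z2
        pair_block[seq(1, 2 * n, 2), ] <-
          pair_block[seq(1, 2 * n, 2), ] + load[j] * x1
        pair_block[seq(2, 2 * n, 2), ] <-
          pair_block[seq(2, 2 * n, 2), ] + load[j] * x2
      }
      if (load[4] > 0) {               # E: independent per member
        pair_block <- pair_block +
          load[4] * matrix(rnorm(2 * n * n_latents), 2 * n, n_latents)
      }
      rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
      lat[rows, ] <- pair_block
    }
    list(latents = lat,
         zygosity = rep(zyg, each = 2L),
         pair = rep(seq_len(n_pairs), each = 2L))
  })
}

#' Map a latent phenotype onto a subject-specific transition matrix
#'
#' Perturbs the base model's transition logits: row `i` receives
#' `effect_scale * latent[i]` times a fixed unit-norm linear contrast across
#' destination states, then each row is renormalized by softmax. With
#' `effect_scale = 0` the base transition matrix is returned exactly, so the
#' injected heritable signal is fully controlled by `effect_scale`.
#'
#' @param latent numeric vector of length K (one latent per transition row).
#' @param base_model a [gaussian_hmm()].
#' @param effect_scale non-negative perturbation magnitude.
#' @return A K x K row-stochastic transition matrix.
#' @export
phenotype_to_dynamics <- function(latent, base_model, effect_scale) {
  K <- base_model$K
  stopifnot(length(latent) == K, effect_scale >= 0)
  if (effect_scale == 0) return(base_model$transition)
  v <- seq_len(K) - (K + 1) / 2
  nv <- sqrt(sum(v^2))
  v <- if (nv > 0) v / nv else v
  logits <- log(pmax(base_model$transition, 1e-300))
  out <- t(vapply(seq_len(K), function(i) {
    softmax(logits[i, ] + effect_scale * latent[i] * v)
  }, numeric(K)))
  out
}

#' Simulate one subject's state path and envelope time series
#'
#' Realizes a Markov chain under the given transition matrix and draws
#' state-conditional Gaussian observations from the model's emission
#' distributions. Observations are shifted by a constant offset (six SDs above
#' the largest state mean) and floored at zero so that the output is a valid
#' non-negative amplitude-envelope matrix.
#'
#' @param transition K x K row-stochastic matrix (e.g. from
#'   [phenotype_to_dynamics()]).
#' @param model a [gaussian_hmm()] providing emissions and the initial
#'   distribution.
#' @param n_samples number of time points T.
#' @param seed integer seed.
#' @param shift constant added to all observations (default places the data
#'   comfortably above zero); use `0` to keep raw Gaussian observations.
#' @return A list with `data` (T x R matrix) and `path` (length-T integer
#'   state sequence).
#' @export
simulate_subject <- function(transition, model, n_samples, seed = 1L,
                             shift = NULL) {
  transition <- as.matrix(transition)
  K <- model$K
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition rows must be non-negative and sum to 1", call. = FALSE)
  }
  n_samples <- stopifnot_scalar_count(n_samples, "n_samples")
  if (is.null(shift)) {
    max_sd <- sqrt(max(vapply(model$covariances,
                              function(S) max(diag(S)), numeric(1))))
    shift <- max(abs(model$means)) + 6 * max_sd
  }
  with_seed(seed, {
    path <- integer(n_samples)
    path[1] <- sample.int(K, 1L, prob = model$initial)
    if (n_samples > 1) {
      u <- runif(n_samples - 1L)
      cum <- lapply(seq_len(K), function(i) cumsum(transition[i, ]))
      for (t in 2:n_samples) {
        path[t] <- findInterval(u[t - 1L], cum[[path[t - 1L]]],
                                left.open = TRUE) + 1L
      }
    }
    chol_list <- lapply(model$covariances, chol)
    data <- matrix(rnorm(n_samples * model$R), n_samples, model$R)
    for (k in seq_len(K)) {
      rows <- which(path == k)
      if (!length(rows)) next
      data[rows, ] <- data[rows, , drop = FALSE] %*% chol_list[[k]] +
        matrix(model$means[k, ], length(rows), model$R, byrow = TRUE)
    }
    data <- data + shift
    if (shift > 0) data <- pmax(data, 0)  # raw Gaussian mode stays unclamped
    list(data = data, path = path)
  })
}

#' Generate a complete synthetic twin cohort
#'
#' Produces a manifest, per-subject per-band envelope matrices and a ground
#' truth record. Dynamics (the transition matrix) are heritable through
#' latent traits sampled under `spec`; emission means and covariances are
#' shared across subjects by default, so spatial state features carry no
#' heritable signal. All randomness fans out from `config$seed` through
#' per-subject substreams keyed by subject id, so output is reproducible
#' independently of iteration order.
#'
#' @param config a [cohort_config()].
#' @param spec an [ace_spec()] for the dynamics latents.
#' @param base_model optional [gaussian_hmm()]; defaults to
#'   `base_hmm(config$n_states, config$n_regions)`.
#' @param effect_scale magnitude of the heritable logit perturbation
#'   (see [phenotype_to_dynamics()]); `0` yields a non-heritable cohort.
#' @param heritable_emissions if `TRUE`, state mean activations also receive a
#'   latent-driven subject offset, making spatial features heritable (used to
#'   probe the spatial-feature null).
#' @return A list with elements `manifest` (data.frame: subject_id, pair_id,
#'   zygosity, sex, age), `pairs` (data.frame: pair_id, subject_a, subject_b,
#'   zygosity, pair_sex, age_diff), `envelopes` (list by band of lists of
#'   T x R matrices keyed by subject id), `fs`, and `truth` (base model,
#'   subject transition matrices, latents, true state paths by band).
#' @export
generate_cohort <- function(config, spec, base_model = NULL,
                            effect_scale = 1, heritable_emissions = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!inherits(spec, "ace_spec")) spec <- do.call(ace_spec, as.list(spec))
  K <- config$n_states
  if (is.null(base_model)) {
    base_model <- base_hmm(K, config$n_regions, seed = config$seed)
  }
  stopifnot(base_model$K == K, base_model$R == config$n_regions)
  counts <- c(config$n_mz_pairs, config$n_dz_pairs, config$n_ur_pairs)
  lat <- sample_ace_latents(spec, counts, n_latents = K,
                            seed = substream_seed(config$seed, "latents"))
  n_pairs <- sum(counts)
  n_subj <- 2L * n_pairs
  zyg_pair <- rep(c("MZ", "DZ", "UR"), times = counts)
  pair_id <- sprintf("%s%03d", zyg_pair, unlist(lapply(counts, seq_len)))
  subject_id <- paste0(rep(pair_id, each = 2L), c("a", "b"))

  demo <- with_seed(substream_seed(config$seed, "demographics"), {
    pair_sex <- sample(rep(c("F", "M"), length.out = n_pairs))
    pair_age <- runif(n_pairs, 23, 40)
    mism <- runif(n_pairs) < config$age_mismatch_frac
    age_b <- ifelse(zyg_pair == "UR",
                    pair_age + runif(n_pairs, -0.5, 0.5),
                    pair_age)
    age_b[mism] <- runif(sum(mism), 23, 40)
    list(pair_sex = pair_sex, age_a = pair_age, age_b = age_b)
  })

  manifest <- data.frame(
    subject_id = subject_id,
    pair_id = rep(pair_id, each = 2L),
    zygosity = rep(zyg_pair, each = 2L),
    sex = rep(demo$pair_sex, each = 2L),
    age = as.vector(rbind(demo$age_a, demo$age_b)),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    pair_id = pair_id,
    subject_a = subject_id[seq(1, n_subj, 2)],
    subject_b = subject_id[seq(2, n_subj, 2)],
    zygosity = zyg_pair,
    pair_sex = demo$pair_sex,
    age_diff = abs(demo$age_a - demo$age_b),
    stringsAsFactors = FALSE
  )

  transitions <- lapply(seq_len(n_subj), function(s) {
    phenotype_to_dynamics(lat$latents[s, ], base_model, effect_scale)
  })
  names(transitions) <- subject_id

  emission_models <- if (heritable_emissions) {
    lapply(seq_len(n_subj), function(s) {
      m <- base_model
      m$means <- m$means + 0.5 * effect_scale *
        matrix(lat$latents[s, ], K, base_model$R)
      m
    })
  } else NULL

  n_samples <- round(config$duration_s * config$fs)
  envelopes <- list()
  true_paths <- list()
  for (band in config$bands) {
    env_b <- vector("list", n_subj)
    path_b <- vector("list", n_subj)
    names(env_b) <- names(path_b) <- subject_id
    for (s in seq_len(n_subj)) {
      mdl <- if (heritable_emissions) emission_models[[s]] else base_model
      sim <- simulate_subject(
        transitions[[s]], mdl, n_samples,
        seed = substream_seed(config$seed, paste0(band, "/", subject_id[s]))
      )
      env_b[[s]] <- sim$data
      path_b[[s]] <- sim$path
    }
    envelopes[[band]] <- env_b
    true_paths[[band]] <- path_b
  }

  list(manifest = manifest, pairs = pairs, envelopes = envelopes,
       fs = config$fs,
       truth = list(base_model = base_model, transitions = transitions,
                    latents = lat$latents, true_paths = true_paths,
                    effect_scale = effect_scale))
}
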