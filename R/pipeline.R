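#' Configuration of a full analysis run
#'
#' Collects every tunable of the pipeline with the study defaults: K = 6
#' states, 5 EM restarts, 50 surrogates, NBS at 5% density with 1,000
#' permutations, hard (Viterbi) temporal features, delta-method CIs, and a
#' single top-level seed that fans out to every stochastic stage.
#'
#' @param out_dir output directory for result tables (`NULL` disables
#'   writing).
#' @param K number of HMM states (use 4 for the replication preset).
#' @param n_restarts EM restarts per band.
#' @param n_surrogates surrogate datasets for the null origin.
#' @param nbs_density,nbs_perm NBS threshold density and permutation count.
#' @param mode `"hard"` or `"soft"` temporal features.
#' @param seed top-level integer seed.
#' @param hmm_tol,hmm_max_iter EM convergence controls.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = NULL, K = 6L, n_restarts = 5L,
                       n_surrogates = 50L, nbs_density = 0.05,
                       nbs_perm = 1000L, mode = "hard", seed = 1L,
                       hmm_tol = 1e-5, hmm_max_iter = 500L) {
  structure(list(out_dir = out_dir, K = as.integer(K),
                 n_restarts = as.integer(n_restarts),
                 n_surrogates = as.integer(n_surrogates),
                 nbs_density = nbs_density, nbs_perm = as.integer(nbs_perm),
                 mode = mode, seed = as.integer(seed), hmm_tol = hmm_tol,
                 hmm_max_iter = as.integer(hmm_max_iter)),
            class = "run_config")
}

log_stage <- function(log, stage, t0, seed = NA) {
  entry <- data.frame(stage = stage,
                      seconds = round(as.numeric(Sys.time()) - t0, 2),
                      seed = seed)
  rbind(log, entry)
}

#' Run the full dynamics-heritability pipeline on one cohort
#'
#' Executes, per band: standardize + concatenate -> HMM fit -> per-subject
#' dynamic features -> edgewise state contrasts with NBS (the significant
#' cluster defines the cluster-FC feature mask) -> surrogate null origin ->
#' sibling-status ANCOVA on pair distances of the four multivariate features
#' -> ACE/ADE variance-component models on origin-referenced distances.
#' Deterministic given the cohort and `config$seed`.
#'
#' @param cohort a cohort as returned by [generate_cohort()], or a list with
#'   `manifest`, `pairs`, `envelopes` (by band), `fs` read from disk.
#' @param partition region-to-network labels (default
#'   [default_partition()] of R).
#' @param config a [run_config()].
#' @return A `pipeline_result`: per-band list with `fit` (model summary),
#'   `features`, `nbs`, `origin`, `herit` (ANCOVA table), `varcomp`
#'   (variance-component table), plus `log`.
#' @export
run_pipeline <- function(cohort, partition = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  for (field in c("manifest", "envelopes")) {
    if (is.null(cohort[[field]])) {
      stop("cohort is missing required field `", field, "`", call. = FALSE)
    }
  }
  manifest <- cohort$manifest
  pairs <- cohort$pairs %||% pairs_from_manifest(manifest)
  R <- ncol(ts_matrix(cohort$envelopes[[1]][[1]]))
  partition <- partition %||% default_partition(R)
  if (length(partition) != R) {
    stop("partition must label each of the ", R, " regions", call. = FALSE)
  }
  log <- data.frame()
  results <- list()
  for (band in names(cohort$envelopes)) {
    env_b <- cohort$envelopes[[band]]
    # subjects in manifest order
    env_b <- env_b[manifest$subject_id]
    t0 <- as.numeric(Sys.time())
    stacked <- standardize_concatenate(env_b)
    fit <- fit_hmm(stacked, K = config$K, n_restarts = config$n_restarts,
                   seed = substream_seed(config$seed, paste0("hmm/", band)),
                   tol = config$hmm_tol, max_iter = config$hmm_max_iter)
    log <- log_stage(log, paste0(band, "/fit_hmm"), t0, config$seed)

    t0 <- as.numeric(Sys.time())
    fcs <- lapply(seq_along(env_b), function(s) {
      subject_state_fc(env_b[[s]], fit$courses[[s]]$posteriors)
    })
    nbs_res <- nbs(fcs, manifest$age, manifest$sex,
                   density = config$nbs_density, n_perm = config$nbs_perm,
                   seed = substream_seed(config$seed, paste0("nbs/", band)))
    sig <- which(nbs_res$fwer_p < 0.05)
    mask <- if (length(sig)) {
      A <- matrix(0L, R, R)
      for (cl in nbs_res$clusters[sig]) {
        A[cl] <- 1L
        A[cl[, c(2, 1), drop = FALSE]] <- 1L
      }
      A
    } else nbs_res$adjacency  # fall back to the thresholded graph
    feats <- dynamic_features(fit, env_b, partition = partition,
                              cluster_mask = mask, mode = config$mode)
    log <- log_stage(log, paste0(band, "/features+nbs"), t0, config$seed)

    t0 <- as.numeric(Sys.time())
    # surrogate refits feed an average over surrogates, so looser EM
    # convergence suffices and keeps the null stage tractable
    origin <- compute_null_origin(
      env_b, K = config$K, partition = partition, cluster_mask = mask,
      n_surrogates = config$n_surrogates,
      seed = substream_seed(config$seed, paste0("null/", band)),
      n_restarts = max(1L, config$n_restarts %/% 2L),
      max_iter = min(config$hmm_max_iter, 100L),
      tol = max(config$hmm_tol, 1e-4),
      mode = config$mode)
    log <- log_stage(log, paste0(band, "/null_origin"), t0, config$seed)

    t0 <- as.numeric(Sys.time())
    idx_a <- match(pairs$subject_a, manifest$subject_id)
    idx_b <- match(pairs$subject_b, manifest$subject_id)
    feature_names <- c("fo", "tp", "modularity", "cluster_fc")
    herit <- do.call(rbind, lapply(feature_names, function(nm) {
      M <- feats[[nm]]
      dist_pair <- vapply(seq_len(nrow(pairs)), function(i) {
        pair_distance(M[idx_a[i], ], M[idx_b[i], ])
      }, numeric(1))
      res <- sibling_ancova(dist_pair, pairs)
      data.frame(band = band, feature = nm, F = res$F, df1 = res$df[1],
                 df2 = res$df[2], p = res$p, p_bonf = res$p_bonf,
                 eta_p2 = res$eta_p2, bf01 = res$bf01,
                 mean_mz = res$group_means["MZ"],
                 mean_dz = res$group_means["DZ"],
                 mean_ur = res$group_means["UR"])
    }))
    rownames(herit) <- NULL

    varcomp <- do.call(rbind, lapply(feature_names, function(nm) {
      M <- feats[[nm]]
      orig <- origin$origins[[nm]]
      if (is.null(orig)) return(NULL)
      tryCatch({
        dist_subj <- vapply(seq_len(nrow(M)), function(s) {
          subject_origin_distance(M[s, ], orig)
        }, numeric(1))
        pheno <- residualize(dist_subj, manifest$age, manifest$sex)
        sel <- twin_model_selection(pheno[idx_a], pheno[idx_b], pairs$zygosity,
                                    seed = substream_seed(config$seed,
                                                          paste0("vc/", band, nm)))
        fit_c <- sel$chosen
        data.frame(band = band, feature = nm, model = fit_c$structure,
                   h2 = fit_c$h2, H2 = fit_c$H2,
                   a2 = fit_c$fractions["a"], c2 = fit_c$fractions["c"],
                   d2 = fit_c$fractions["d"], e2 = fit_c$fractions["e"],
                   minus2ll = fit_c$minus2ll, aic = fit_c$aic,
                   r_mz = sel$r_mz, r_dz = sel$r_dz)
      }, error = function(e) {
        warning(sprintf("variance-component fit skipped for %s/%s: %s",
                        band, nm, conditionMessage(e)))
        NULL
      })
    }))
    rownames(varcomp) <- NULL
    log <- log_stage(log, paste0(band, "/heritability"), t0, config$seed)

    results[[band]] <- list(
      fit = list(K = fit$model$K, loglik = fit$loglik,
                 transition = fit$model$transition),
      features = feats, nbs = nbs_res, origin = origin,
      herit = herit, varcomp = varcomp)
  }
  out <- structure(list(bands = results, log = log, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    herit_all <- do.call(rbind, lapply(results, `[[`, "herit"))
    vc_all <- do.call(rbind, lapply(results, `[[`, "varcomp"))
    data.table::fwrite(herit_all, file.path(config$out_dir, "heritability_ancova.tsv"),
                       sep = "\t")
    if (!is.null(vc_all)) {
      data.table::fwrite(vc_all, file.path(config$out_dir, "variance_components.tsv"),
                         sep = "\t")
    }
    data.table::fwrite(log, file.path(config$out_dir, "run_log.tsv"), sep = "\t")
    jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  out
}
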