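test_that("ace_spec rejects invalid variance decompositions", {
  expect_error(ace_spec(a2 = 0.5, e2 = 0.4), "sum to 1")
  expect_error(ace_spec(a2 = 0.2, c2 = 0.2, d2 = 0.2, e2 = 0.4), "ACE or ADE")
  expect_error(ace_spec(a2 = -0.1, e2 = 1.1), "\\[0, 1\\]")
  expect_s3_class(ace_spec(a2 = 0.4, c2 = 0.2, e2 = 0.4), "ace_spec")
})

test_that("latent within-pair correlations follow the twin decomposition", {
  # E-only null: MZ correlation ~ 0
  lat <- sample_ace_latents(ace_spec(e2 = 1), c(2000, 0, 0), 1, seed = 11)
  a <- lat$latents[seq(1, 4000, 2), 1]
  b <- lat$latents[seq(2, 4000, 2), 1]
  expect_lt(abs(cor(a, b)), 0.05)

  # perfect heritability: MZ identical, DZ correlation ~ 0.5
  lat <- sample_ace_latents(ace_spec(a2 = 1, e2 = 0), c(500, 2000, 0), 1,
                            seed = 12)
  mz <- lat$zygosity == "MZ"
  expect_equal(lat$latents[mz, 1][seq(1, sum(mz), 2)],
               lat$latents[mz, 1][seq(2, sum(mz), 2)], tolerance = 1e-12)
  dz_a <- lat$latents[lat$zygosity == "DZ", 1][seq(1, 4000, 2)]
  dz_b <- lat$latents[lat$zygosity == "DZ", 1][seq(2, 4000, 2)]
  expect_lt(abs(cor(dz_a, dz_b) - 0.5), 0.05)

  # ACE mixture: rMZ = a2 + c2 = 0.6, rDZ = a2/2 + c2 = 0.4
  lat <- sample_ace_latents(ace_spec(a2 = 0.4, c2 = 0.2, e2 = 0.4),
                            c(5000, 5000, 0), 1, seed = 13)
  for (g in c("MZ", "DZ")) {
    idx <- which(lat$zygosity == g)
    r <- cor(lat$latents[idx[seq(1, length(idx), 2)], 1],
             lat$latents[idx[seq(2, length(idx), 2)], 1])
    expect_lt(abs(r - if (g == "MZ") 0.6 else 0.4), 0.03)
  }
})

test_that("dominance latents hit rMZ = 1 and rDZ = 0.25 correlations", {
  lat <- sample_ace_latents(ace_spec(a2 = 0, d2 = 0.8, e2 = 0.2),
                            c(4000, 4000, 1000), 2, seed = 21)
  for (g in c("MZ", "DZ", "UR")) {
    idx <- which(lat$zygosity == g)
    r <- cor(lat$latents[idx[seq(1, length(idx), 2)], 1],
             lat$latents[idx[seq(2, length(idx), 2)], 1])
    expected <- c(MZ = 0.8, DZ = 0.25 * 0.8, UR = 0)[g]
    expect_lt(abs(r - expected), 0.04)
  }
  expect_equal(sd(lat$latents[, 2]), 1, tolerance = 0.05)
})

test_that("phenotype_to_dynamics perturbs logits and preserves stochasticity", {
  m <- base_hmm(4, 6, seed = 3)
  lat <- c(0.5, -1, 2, 0)
  expect_equal(phenotype_to_dynamics(lat, m, 0), m$transition,
               tolerance = 1e-12)
  P <- phenotype_to_dynamics(lat, m, 1.5)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_identical(P, phenotype_to_dynamics(lat, m, 1.5))
  expect_false(isTRUE(all.equal(P, m$transition)))
})

test_that("simulate_subject realizes the requested Markov chain", {
  m2 <- base_hmm(2, 3, seed = 5)
  # absorbing chain stays in its start state
  m_abs <- m2
  m_abs$initial <- c(1, 0)
  sim <- simulate_subject(diag(2), m_abs, 500, seed = 1)
  expect_true(all(sim$path == 1))
  # deterministic cycle alternates
  sim <- simulate_subject(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE),
                          m_abs, 100, seed = 2)
  expect_true(all(abs(diff(sim$path)) == 1))
  # generic chain matches its stationary distribution (eigen oracle)
  P <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.7, 0.2,
                0.25, 0.25, 0.5), 3, 3, byrow = TRUE)
  m3 <- base_hmm(3, 3, seed = 6)
  sim <- simulate_subject(P, m3, 100000, seed = 3)
  freq <- tabulate(sim$path, 3) / length(sim$path)
  expect_lt(max(abs(freq - stationary_dist(P))), 0.01)
  # rejection of non-stochastic transitions
  expect_error(simulate_subject(matrix(0.3, 2, 2), m2, 10), "sum to 1")
})

test_that("simulated dwell times are geometric", {
  m <- base_hmm(2, 3, stay = 0.9, seed = 9)
  sim <- simulate_subject(m$transition, m, 120000, seed = 4)
  runs <- rle(sim$path)$lengths
  runs <- runs[seq_len(min(length(runs), 10000))]
  # geometric with success prob 1 - P_kk = 0.1, support 1, 2, ...
  cutoffs <- c(1:29, Inf)
  obs <- table(cut(runs, breaks = c(0, cutoffs)))
  probs <- diff(c(0, pgeom(cutoffs - 1, prob = 0.1)))
  keep <- probs * length(runs) >= 5
  gof <- suppressWarnings(
    chisq.test(as.numeric(obs[keep]), p = probs[keep] / sum(probs[keep])))
  expect_gt(gof$p.value, 0.01)
  expect_lt(abs(mean(runs) - 10), 1)
})

test_that("generate_cohort bookkeeping, matching and determinism hold", {
  cfg <- cohort_config(2, 2, 2, n_regions = 4, n_states = 2,
                       duration_s = 2, seed = 31)
  coh <- generate_cohort(cfg, ace_spec(a2 = 0.5, e2 = 0.5))
  expect_equal(nrow(coh$manifest), 12)
  expect_equal(nrow(coh$pairs), 6)
  sex_by_pair <- tapply(coh$manifest$sex, coh$manifest$pair_id,
                        function(s) length(unique(s)))
  expect_true(all(sex_by_pair == 1))
  expect_true(all(coh$manifest$age >= 23 & coh$manifest$age <= 40.5))

  coh2 <- generate_cohort(cfg, ace_spec(a2 = 0.5, e2 = 0.5))
  expect_identical(coh$envelopes, coh2$envelopes)
  expect_identical(coh$manifest, coh2$manifest)

  # study-sized default: 463 pairs, 926 subjects
  cfg_full <- cohort_config(n_regions = 3, n_states = 2, duration_s = 1,
                            seed = 1)
  coh_full <- generate_cohort(cfg_full, ace_spec(e2 = 1), effect_scale = 0)
  expect_equal(nrow(coh_full$pairs), 463)
  expect_equal(nrow(coh_full$manifest), 926)
})

test_that("envelopes are non-negative and reproducible per subject", {
  coh <- tiny_cohort(seed = 77, duration_s = 5)
  env <- coh$envelopes$alpha
  expect_true(all(vapply(env, function(e) all(e >= 0), TRUE)))
  expect_equal(vapply(env, nrow, 0L), rep(200L, length(env)),
               ignore_attr = TRUE)
})
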