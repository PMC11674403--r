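# twindyn

Heritability of rapid connectome-state dynamics from band-limited amplitude
envelopes, in the classical twin design.

Resting-state electrophysiological connectivity is not static: band-limited
envelope correlations switch among a small set of recurrent **connectome
states** every few hundred milliseconds. `twindyn` asks whether the
*dynamics* of that switching are genetically influenced. It is written for
researchers running EEG/MEG twin (or family) studies who have parcellated
source time series and a cohort manifest, and for methodologists who want a
fully testable reference implementation of this analysis chain.

## What it computes

For each frequency band (delta 1–3, theta 4–7, alpha 8–12, beta 13–25,
gamma 30–45 Hz):

1. **Envelopes** — collinearity screening (column-pivoted QR), detrending,
   zero-phase Butterworth band-pass, symmetric orthogonalization (removes
   all shared zero-lag signal), Hilbert amplitude envelopes, anti-aliased
   downsampling to 40 Hz.
2. **States** — a K-state Gaussian-observation hidden Markov model fitted by
   EM to standardized envelopes concatenated over subjects. Each state k has
   a mean activation μₖ and an amplitude-coupling covariance Σₖ; subjects
   get posterior state probabilities γₜₖ and a Viterbi path.
3. **Dynamic features per subject** — Fractional Occupancy
   (FOₖ = #{t: sₜ = k}/T, 1 × K), Transition Probabilities
   (TPᵢⱼ = #{i→j}/#{i→·}, K × K), Newman modularity
   Q = (1/2m) Σᵢⱼ (Aᵢⱼ − kᵢkⱼ/2m) δ(cᵢ, cⱼ) of each state's FC under the
   seven canonical intrinsic connectivity networks, and the mean FC of the
   data-driven cluster of state-dissociating connections (edgewise state
   ANCOVA → density threshold → network-based-statistic permutation test).
4. **Null origin** — features recomputed on 50 surrogate datasets that keep
   each subject's static covariance but destroy temporal ordering; their
   mean is the origin of each feature space.
5. **Heritability** — one-way ANCOVA of sibling status (MZ / DZ / unrelated)
   on pairwise Euclidean feature distances, adjusted for pair age difference
   and sex, with partial η², a 20-test Bonferroni family and BIC Bayes
   factors; then maximum-likelihood ACE/ADE variance-component models on
   each subject's origin distance, with nested AE/CE/DE fits,
   likelihood-ratio tests, AIC, and h² = σ²A/(σ²A+σ²C+σ²E) or
   H² = (σ²A+σ²D)/(σ²A+σ²D+σ²E).

A synthetic twin-cohort generator (`generate_cohort()`) produces envelope
data with known HMM structure and a chosen A/C/D/E decomposition of the
dynamics, so the entire chain is validated against ground truth.

## Worked example

A cohort of 80 twin pairs with strongly heritable transition dynamics
(`a2 = 0.9`) and emission (spatial) parameters shared across subjects; the
whole run takes about five minutes on one CPU:

```r
library(twindyn)

cfg <- cohort_config(n_mz_pairs = 40, n_dz_pairs = 20, n_ur_pairs = 20,
                     n_regions = 8, n_states = 4, duration_s = 120, seed = 7)
bm  <- base_hmm(4, 8, stay = 0.9, separation = 4, seed = 7)
coh <- generate_cohort(cfg, ace_spec(a2 = 0.9, e2 = 0.1), base_model = bm,
                       effect_scale = 0.8)
res <- run_pipeline(coh, config = run_config(K = 4, n_restarts = 2,
                                             n_surrogates = 10, seed = 7))
res$bands$alpha$herit[, c("feature", "F", "df1", "df2", "p_bonf", "eta_p2")]
#>      feature         F df1 df2       p_bonf     eta_p2
#> 1         fo 11.835520   2  75 0.0006818883 0.23989856
#> 2         tp 11.983019   2  75 0.0006096708 0.24216427
#> 3 modularity  1.980031   2  75 1.0000000000 0.05015272
#> 4 cluster_fc  1.762078   2  75 1.0000000000 0.04487990

res$bands$alpha$varcomp[, c("feature", "model", "h2", "H2")]
#>      feature model        h2        H2
#> 1         fo   ACE 0.6827900 0.6827900
#> 2         tp   ADE 0.4867577 0.8367617
#> 3 modularity   ACE 0.0000000 0.0000000
#> 4 cluster_fc   ACE 0.0000000 0.0000000
```

Read: the temporal features (FO, TP) show a strong sibling-status effect —
genetically closer pairs have more similar state dynamics (Bonferroni p†
≈ 7e-4 and 6e-4, partial η² ≈ 0.24) — and substantial genetic variance in
the origin-referenced distance phenotypes, while the spatial features
(modularity, cluster FC) show neither: exactly the dissociation the
generator builds in (heritable transition dynamics, shared spatial
patterns).

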