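---
title: "Methods: state dynamics of the EEG connectome and their heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state dynamics of the EEG connectome and their heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindyn)
```

## The scientific problem

Whole-brain functional connectivity is not static: band-limited
electrophysiological recordings switch among a small set of recurrent
connectome states on subsecond timescales. `twindyn` implements a complete
analysis chain for asking whether the *dynamics* of this switching — how long
each state is occupied and how states follow one another — are heritable
traits, using the classical twin design (monozygotic pairs, dizygotic pairs
and unrelated pairs).

The chain has five stages:

1. **Envelope preprocessing** — parcellated source signals are screened for
   collinear regions, detrended, band-pass filtered, symmetrically
   orthogonalized, converted to Hilbert amplitude envelopes and downsampled
   to 40 Hz.
2. **State inference** — a K-state Gaussian-observation hidden Markov model
   on standardized envelopes concatenated over subjects. Each state is a
   mean-activation vector plus an amplitude-coupling covariance; decoding
   gives each subject a state time course.
3. **Feature extraction** — four multivariate phenotypes per subject:
   fractional occupancy (FO, 1 × K), the transition-probability matrix (TP,
   K × K), Newman modularity of the per-state connectivity under the
   canonical intrinsic-connectivity-network partition (1 × K), and the mean
   connectivity of the data-driven cluster of state-dissociating edges
   (1 × K). The cluster is found by edgewise state ANCOVA, density
   thresholding and network-based-statistic (NBS) permutation inference.
4. **Null origin** — surrogate datasets that keep each subject's static mean
   and covariance but destroy temporal ordering; refitting the HMM on
   surrogates and averaging features over surrogates gives the origin point
   of each feature space.
5. **Heritability** — a one-way ANCOVA of sibling status on pairwise
   Euclidean feature distances (with pair age difference and pair sex as
   covariates), and maximum-likelihood ACE/ADE variance-component models on
   each subject's distance from the null origin, residualized for age and
   sex.

Since no public EEG twin cohort accompanies this problem, the package is
validated end to end on a synthetic cohort generator with known ground
truth.

## The synthetic cohort generator

`generate_cohort()` is a forward model of the whole design:

* **Latent traits.** `sample_ace_latents()` draws unit-variance latents with
  within-pair correlations `rMZ = a² + c² + d²`, `rDZ = a²/2 + c² + d²/4`,
  `rUR = 0` — the same decomposition the variance-component model estimates.
* **Latent → dynamics.** Each subject's K latents perturb the K rows of the
  base transition-matrix logits along a fixed unit-norm linear contrast
  (`phenotype_to_dynamics()`); softmax renormalizes rows. This makes TP — and
  through the stationary distribution, FO — heritable while leaving emission
  means and covariances identical across subjects, so spatial features carry
  no heritable signal by construction. `effect_scale = 0` switches
  heritability off exactly. The logit-perturbation link is a modeling choice
  of this package, not a biological claim; nothing in the twin literature
  pins down how genotype should enter a transition matrix, and any smooth
  monotone link would serve the same validation purpose.
* **Emissions.** Envelopes are generated directly in envelope space:
  state-conditional Gaussian draws shifted by a constant (six SDs above the
  largest state mean) so values are non-negative. This skips the
  oscillation–Hilbert route for speed; the filtering/Hilbert path is
  exercised separately by its own deterministic tests with analytic tones.
  A flag (`heritable_emissions`) can make spatial patterns heritable for
  probing the spatial-feature null.
* **Demographics.** Pairs are sex-matched (50/50 at pair level) with ages
  uniform on 23–40 years; twins share an age, unrelated pairs are matched
  within a year except for a small configurable fraction — mirroring the
  occasional non-matched unrelated pairs of real cohorts.
* **Defaults.** 206 MZ + 112 DZ + 145 UR pairs (463 pairs, 926 subjects),
  54 regions, 6 states, 40 Hz, 6 minutes per subject — full study-scale
  conditions. One top-level seed fans out to per-subject substreams via a
  stable string hash, so results do not depend on iteration order.

What the generator does **not** emulate: source leakage (synthetic regions
are generated leakage-free), 1/f spectra, non-Gaussian envelope marginals,
artifacts, or genetic effects on spatial patterns (unless enabled). Passing
tests on synthetic cohorts therefore validates the *inference machinery*,
not the biology of any particular dataset.

## Numerical and design choices

**Envelope preprocessing.** The band-pass filter is a 4th-order Butterworth
run forward and backward (zero phase, effective order 8); the band-splitting
filter family is otherwise unconstrained by the problem, and zero-phase
filtering preserves envelope timing. Symmetric orthogonalization alternates
a polar decomposition with a per-column magnitude fit on mean-centered data;
centering makes orthogonality equivalent to zero correlation, and the
procedure stops when the relative change of the reconstruction error falls
below `tol` (default 1e-10). Collinearity screening uses column-pivoted QR
and drops the last `n_exclude` pivots; `n_exclude = 14` reproduces the
68 → 54 Desikan-Killiany reduction, and the threshold is an explicit
parameter because no principled rule for "how many" exists. Downsampling
low-passes at 0.4× the target rate before resampling onto the target grid.

**HMM.** Inference is expectation-maximization with scaled per-subject
forward–backward recursions (chains restart at subject boundaries),
k-means initialization on a subsample, and `n_restarts` independent starts
(default 5); the best final log-likelihood wins. Covariance updates receive
an escalating ridge (`1e-6 · trace/R` upward) only when Cholesky
factorization fails. Variational-Bayes inference is common in this
literature; EM with the same full-covariance Gaussian observation model was
chosen for exact testability (the forward–backward and Viterbi recursions
are verified against exhaustive path enumeration). State labels are
arbitrary, so models are canonically re-ordered by descending group
fractional occupancy, ties broken by first activation. Temporal features
default to the hard Viterbi path — transition *counts* are well-defined
there — with a soft (posterior-weighted) FO variant available; with
well-separated states the two agree closely.

**Features.** TP rows for states never visited fall back to uniform 1/K
(the multivariate distance needs a complete row-stochastic matrix) and are
flagged. Modularity zeroes negative edge weights, the classic Newman
convention; a signed variant is available behind a flag. The full K² TP
vector (diagonal included) enters the multivariate phenotype; componentwise
follow-ups use off-diagonal entries. Subject-level state FC uses
posterior-weighted Pearson correlation; a state with summed weight below 10
samples is flagged missing, and subjects with missing states are dropped
from edgewise contrasts so the NBS permutation unit stays exchangeable.

**NBS.** The pooled subject × state ANCOVA (factor state, covariates age and
sex, no repeated-measures error term) yields an F per edge; the top
`round(density · E)` edges (ties by edge index) form the suprathreshold
graph, and clusters are its connected components measured in edges. The null
distribution of the maximum component size comes from permuting state labels
within subject; because covariate rows are identical within a subject, the
reduced-model residual sum is permutation-invariant and only the full-model
fit is recomputed, which makes the permutation loop a single matrix
operation. p values use the +1 correction. A practical note from the
package's own calibration experiments: the extent statistic discriminates
only while the thresholded graph is subcritical (kept edges well below the
region count); at higher densities null components percolate and power
collapses. Test geometries are chosen accordingly.

**Null origin.** Surrogates are i.i.d. Gaussian draws with each subject's
static mean and covariance — the minimal construction that preserves static
covariance while destroying temporal ordering. The origin is the mean of the
subject-averaged feature vector over 50 surrogates by default (configurable
down to a handful for speed); a subject-level origin variant is exposed by
flag since either level is defensible.

**Heritability screening.** The pairwise ANCOVA uses the pair's age
*difference* and the pair's (matched) sex; distances enter raw, without
variance standardization. The Bonferroni family is fixed at 20 (four
features × five bands) regardless of extra exploratory features. Bayes
factors use the BIC approximation `BF01 = exp((BIC₁ − BIC₀)/2)`; this is an
approximation to a default Bayes factor, adequate for direction-of-evidence
summaries. The power analysis treats the quoted small effect 0.021 as an
eta-squared when converting to Cohen's f via `f = √(η²/(1−η²))`, since that
is the conversion under which 0.021 ↔ 0.145.

**Variance components.** The pair phenotype is the origin-referenced
distance, residualized for age and sex and standardized, so fitted
components are fractions of adjusted phenotypic variance. The likelihood is
the bivariate normal over pairs with expected within-pair covariance
`a²·rA + c²·rC + d²·rD`; unrelated pairs carry zero A, C and D correlations
(members come from different families). The mean is fixed at zero after
residualization, so only variance parameters (SD-scale, bounded at zero) are
estimated by multi-start L-BFGS-B; sufficient statistics per zygosity group
make each likelihood evaluation O(1). Confidence intervals use the delta
method on the unconstrained parameterization and may extend below zero —
the convention that produces the familiar negative lower bounds of twin
tables. Likelihood-ratio tests use the plain χ² reference (3.84 at one df)
despite the boundary non-regularity; at the boundary this is conservative
for rejecting the nested model. The ACE-vs-ADE family choice follows the
twin-correlation heuristic (`rDZ < rMZ/2 ⇒ ADE`), and the full-family model
is retained unless a nested model fits significantly better — which, since
dropping a parameter cannot raise the likelihood, effectively retains the
full model, matching the reporting convention of classical twin tables.

## Problem sizes used in validation

The test suite validates each stage at the smallest size where the property
is meaningful: exact HMM oracles at T ≤ 8, parameter recovery at
T = 20,000, distributional claims (FWER calibration, CI coverage, LRT null)
at 100–200 replicates, and the end-to-end temporal-vs-spatial dissociation
on twenty replicate mini-cohorts of 80 pairs (8 regions, 4 states, two
minutes of recording at 40 Hz). At 80 pairs, Bonferroni-corrected detection
(α = 0.0025) requires a Cohen's f near 0.55, so mini-cohorts inject a strong
heritable dynamics signal (`a² = 0.95`, `effect_scale = 0.8`) — the
dissociation being tested is qualitative (temporal heritable, spatial not),
and the generator keeps emissions identical across subjects so any spatial
"signal" would be a pipeline artifact.

One such artifact deserves record: when states are poorly separated or
recordings short, heritable occupancy couples into *estimates* of spatial
features (shared time-in-state means correlated estimation noise within MZ
pairs), which can mimic spatial heritability. Well-separated states and
recordings long enough that per-state FC estimates stabilize keep this
channel negligible; analysts of real data should treat a spatial-feature
heritability signal with suspicion when it co-occurs with strong temporal
heritability and short recordings.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_mz_pairs = 40, n_dz_pairs = 20, n_ur_pairs = 20,
                     n_regions = 8, n_states = 4, duration_s = 120,
                     seed = 7)
bm <- base_hmm(4, 8, stay = 0.9, separation = 4, seed = 7)
coh <- generate_cohort(cfg, ace_spec(a2 = 0.9, e2 = 0.1), base_model = bm,
                       effect_scale = 0.8)
res <- run_pipeline(coh, config = run_config(K = 4, n_restarts = 2,
                                             n_surrogates = 10, seed = 7))
res$bands$alpha$herit      # sibling-status ANCOVA per feature
res$bands$alpha$varcomp    # ACE/ADE fits on origin distances
```

The README shows the output of this exact run: both temporal features carry
a Bonferroni-significant sibling effect and substantial genetic variance
fractions, while both spatial features are null on both analyses.

## Known limitations

* The generator's envelope-space shortcut means the filtering/Hilbert path
  is validated on analytic signals, not on full synthetic oscillations, by
  default; `prepare_envelopes()` accepts real parcellated recordings
  unchanged.
* The EM fit, like all local optimizers, can hit poor optima for strongly
  overlapping states; restarts mitigate but do not guarantee recovery.
* The delta-method CIs degrade at boundary estimates (a component exactly
  zero); a pair-resampling bootstrap is the robust alternative when boundary
  solutions matter.
* The BIC Bayes factor is a large-sample approximation and should not be
  quoted beyond order-of-magnitude evidence.
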