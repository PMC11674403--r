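Package: twindyn
Title: Twin Heritability of Rapid Connectome-State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying rapid brain connectome-state dynamics and their
    heritability in classical twin designs. Parcellated electrophysiological
    source signals are turned into leakage-corrected band-limited amplitude
    envelopes (column-pivoted QR collinearity screening, zero-phase band-pass
    filtering, symmetric orthogonalization, Hilbert envelopes, anti-aliased
    downsampling); a K-state Gaussian-observation hidden Markov model is fitted
    to concatenated standardized envelopes by expectation-maximization;
    multivariate dynamic features (fractional occupancy, transition
    probabilities, Newman modularity over canonical intrinsic connectivity
    networks, and cluster-averaged state connectivity) are extracted per
    subject; state contrasts use edgewise ANCOVA with network-based statistic
    permutation inference; dynamics-free surrogate data define a null origin
    for multivariate phenotypes; and heritability is assessed by sibling-status
    ANCOVA on pairwise distances plus maximum-likelihood ACE/ADE
    variance-component models on origin-referenced distances. A synthetic
    twin-cohort generator with known ground-truth state structure and
    heritability supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    MASS,
    igraph,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
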