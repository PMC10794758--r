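Package: lncsig
Title: Discriminating Long Non-Coding RNA from mRNA by Sequence-Intrinsic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies transcript sequences as long non-coding RNA (lncRNA)
    or messenger RNA (mRNA) from sequence-intrinsic signals alone: the
    period-3 peak and signal-to-noise ratio of the base-indicator power
    spectrum, frequency-weighted dinucleotide and trinucleotide
    physicochemical energies (solvation, stacking, hydrogen bonding), and
    PCA-reduced k-mer composition. Provides a registry of sixteen named
    feature combinations, class balancing by random undersampling or SMOTE,
    a small feed-forward neural classifier trained with binary
    cross-entropy, six classification metrics, maximum-likelihood fitting
    of lognormal, gamma and exponential distributions with AIC model
    selection, and a seeded generator of codon-biased coding-like and
    Markov non-coding-like synthetic sequences for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fitdistrplus,
    MASS
Config/testthat/edition: 3
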