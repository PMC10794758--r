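---
title: "Methods: sequence-intrinsic discrimination of lncRNA and mRNA"
author: "lncsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-intrinsic discrimination of lncRNA and mRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lncsig` classifies transcript sequences as long non-coding RNA (label 0)
or mRNA (label 1, the positive class throughout) from three families of
sequence-intrinsic features. This vignette is the package's own account of
the model: what is computed, which choices were open and how they were
settled, and what the bundled synthetic benchmark does and does not show.

## Base periodicity

Codon structure imprints a period-3 signal on coding sequence. For each
base $b$ the indicator vector $u_b[n] = \mathbf{1}[s_n = b]$ is
transformed with an unnormalized DFT of length $N$ (no zero-padding), and
the four squared magnitudes are summed into one power spectrum $S[k]$.
Two scalars summarize it:

* `bp_peak` $= S[\mathrm{round}(N/3)]$ — the DFT bin nearest the 1/3
  frequency. Rounding is the natural choice when $3 \nmid N$; with no
  zero-padding the bin interpretation and the Parseval identity
  $\sum_k S[k] = N \times \#\{\text{non-N positions}\}$ stay exact, and
  both are asserted in the test suite.
* `bp_snr` — the peak divided by the mean of $S$ over all $N-1$ non-DC
  bins. The DC bin encodes base composition, not periodicity, so it is
  excluded; the full non-DC range (rather than the symmetric half) is
  used, which differs only by bookkeeping since $S$ is symmetric. Under
  this convention an i.i.d. uniform sequence has expected SNR close to 1,
  a convenient null reference, while strongly codon-biased sequence
  reaches SNR in the tens to hundreds (a pure `ATG` repeat of length 300
  gives peak $3\times100^2 = 30000$ and SNR $\approx 149.5$).

"Signal-to-noise" is implemented as signal over noise: discrimination
claims of the form "SNR is higher in coding sequence" are only coherent
in that orientation.

Positions holding `N` are zero in all four indicators, so ambiguity
contributes neither signal nor noise. A homopolymer has zero off-DC
power; its SNR is defined as 0 (the 0/0 case is guarded by a threshold
relative to total power, which is at the $N^2$ scale by Parseval).
Sequences shorter than 9 nt are rejected so the period-3 bin is distinct
from DC.

## Physicochemical energies

Each k-mer $m$ carries three energies $E(m)$ — solvation, stacking,
hydrogen bonding, in kcal/mol — from a user-supplied table. A sequence's
three features per order are the frequency-weighted means
$\sum_m f(m) E(m)$, where $f$ is the empirical overlapping k-mer
frequency over N-free windows, normalized to sum to one.

Two design points were genuinely open:

* **Weighting.** The alternative to empirical frequencies is the
  stationary distribution of the fitted first-order k-mer transition
  matrix. The two agree up to end effects on any reasonably long
  sequence (a test asserts agreement within 5% on 20 knt chains), but
  empirical weights are deterministic and well-defined on short
  sequences, so they are the default; `weighting = "stationary"`
  switches to power iteration on the transition matrix, which is built
  and exportable in any case.
* **Order reduction.** Tables can be averaged down one order:
  the energy of a (k−1)-mer is the unweighted arithmetic mean over all
  order-k k-mers containing it, one term per occurrence position (so
  `AAA` contributes twice to `AA`). Weighting positions by genomic
  frequency would be an alternative; the unweighted positional mean is
  the simplest well-posed reading and is cross-checked against a
  brute-force substring enumeration in the tests.

The shipped tables (`inst/extdata/synthetic_*_energies.tsv`) are
**synthetic illustrative stand-ins**: hydrogen-bond energy scales with
the number of hydrogen bonds of the constituent bases (2 for A/T, 3 for
G/C), stacking and solvation vary smoothly with G+C content, and small
seeded noise breaks ties. Magnitudes are plausible, values are not
measurements; real analyses must supply a measured table via
`load_energy_table()`. The dinucleotide table is exactly the positional
average of the trinucleotide one, so the pair is self-consistent with
the reduction operation. Sequences are handled in the DNA alphabet
(U→T at load), matching how such tables are parameterized.

## Composition PCA

Overlapping dinucleotide (16-D) and trinucleotide (64-D) frequency
vectors enter PCA. Frequencies, not raw counts, are used: transcript
lengths span 200 nt to >10 knt and counts would make length the dominant
axis. PCA is computed by SVD of the centered matrix; components are
sorted by decreasing explained variance and signs are fixed by making
each component's largest-magnitude loading positive, so fits are
reproducible across platforms and row orders. The default keeps 15
components per family; a warning is raised when they retain less than
95% of the variance (on short synthetic sequences the trinucleotide
family sits slightly below that figure — sampling noise spreads variance
across all 64 axes).

PCA is always fit on training rows only, pooled across classes, and test
rows are projected with the frozen model. A sentinel test poisons the
held-out rows and asserts the fitted model is unchanged.

## Feature combinations

Sixteen named combinations concatenate family subsets, capping the model
input at 15 columns: DP, TP, DPTP, DC, TC, BP, BPDP, BPTP, BPDPTP,
BPDC (2+13), BPTC (2+13), BPDCTC (2+7+6), DPDC (3+12), TPTC (3+12),
DCTC (8+7), DPTPDCTC (3+3+5+4 over DP, TP, DC, TC). When a composition
family is truncated, the top-variance components are kept — the
canonical choice given that PCs arrive variance-ranked. Column
provenance is attached to every assembled matrix.

All assembled columns are z-scored with training-set statistics before
they reach the classifier: `bp_peak` spans orders of magnitude while
energies sit in single-digit kcal/mol, and unscaled training would be
dominated by the former.

## Balancing

Real lncRNA/mRNA collections are heavily imbalanced in both directions
depending on the organism, so two seeded remedies are provided:
random undersampling of the majority class, and SMOTE — each synthetic
minority point is $x + u(z - x)$ with $z$ one of the $k=5$ nearest
minority neighbors (the canonical neighborhood size) and
$u \sim U(0,1)$. SMOTE runs in the assembled, z-scored space so
Euclidean neighborhoods are scale-meaningful, and only training rows are
ever balanced; the held-out split keeps its natural ratio. SMOTE can
overfit the minority manifold; both methods are exposed so results can
be reported side by side.

## Classifier and training

A single hidden layer of width $\max(8, 2d)$ (input width $d$ ranges 2
to 15 across combinations), ReLU activation and a sigmoid output unit,
trained on binary cross-entropy
$\mathrm{Loss}(y,\hat y) = -y\log\hat y - (1-y)\log(1-\hat y)$
(predictions clipped to $[10^{-12}, 1-10^{-12}]$) with plain mini-batch
gradient descent: learning rate 0.01, 200 epochs, batch 32, seeded
Glorot-uniform initialization. These are deliberately unremarkable
defaults for a problem this size, all exposed in `mlp_config()`.
Analytic gradients are verified against central finite differences in
the tests. Evaluation uses a seeded stratified 80/20 split.

## Metrics and distribution fitting

Accuracy, precision, recall and F1 come from the confusion table at
threshold 0.5 (predicted positive when the probability exceeds it;
precision on an empty positive set is recorded as 0 with a warning
flag). ROC-AUC is trapezoidal integration over all score thresholds,
which equals the Mann-Whitney statistic with ties counting one half — a
brute-force $O(n^2)$ oracle asserts exact agreement. PRC-AUC uses
step-interpolated average precision, avoiding the optimistic trapezoid
in precision–recall space.

Spectral features (peak, SNR) are positively skewed, and lognormal,
gamma and exponential candidates are fit by maximum likelihood:
closed forms for exponential and lognormal, Newton iteration on
$\log\alpha - \psi(\alpha) = \log\bar x - \overline{\log x}$ (tolerance
$10^{-10}$, cap 200 iterations) for the gamma shape. Model selection is
by AIC, ties broken toward fewer parameters; likelihood-only or visual
selection would be alternatives, but AIC is the defensible default when
the families differ in parameter count. Zero values (homopolymer SNR)
are excluded with a logged count since all three families have positive
support; samples with zero log-variance are an error for the two-
parameter families rather than a silent degenerate fit.

## The synthetic benchmark

`generator_config()` defines the study conditions: 500 sequences per
class, lengths uniform on 200–1000 nt (the lncRNA length floor up to
typical transcript scale), coding-like sequences as i.i.d. codons from a
skewed usage table (mass on a random 20-codon subset per seed,
exponential weights) sharpened by a temperature exponent
(`codon_bias_strength`, default 2; 0 erases all bias), non-coding-like
sequences as a first-order nucleotide Markov chain with a mildly
structured default matrix (slight CG-step depletion). mRNA-like lengths
are floored to codon multiples.

This emulates exactly the statistical contrast the features target:
frame structure versus none, and divergent k-mer composition. It does
**not** emulate ORF grammar (no start/stop structure), splicing,
UTR/CDS mosaic structure, GC heterogeneity along the transcript, or any
organism's real codon usage. Passing the end-to-end tests therefore
demonstrates that the machinery is correct and that the features carry
the intended signal — not that the shipped defaults reach any particular
accuracy on real NONCODE/NCBI data, for which users supply their own
FASTA files and measured energy tables. A negative control (bias 0,
uniform composition on both sides) confirms the pipeline finds nothing
when nothing is there (held-out AUC near 0.5).

## Problem sizes and numerical choices

The test suite runs the spectral oracle on 50 random sequences of length
9–512 against a naive DFT (tolerance $10^{-8}$ relative), the SNR null
on 1000 sequences of length 300, energy-feature convergence at 30 knt
with a 3-standard-error band computed from the exact lag-1 covariance of
overlapping windows, SMOTE convexity on 500 minority points, lognormal
recovery at $n = 5000$ with AIC selection over 100 seeds, and the
end-to-end benchmark at 500 sequences per class. `scripts/acceptance.R`
reruns the main quantities at the same sizes from a single command-line
seed.

Tolerances follow the quantity being checked: $10^{-12}$ for algebraic
identities (row-stochasticity, weight normalization), $10^{-8}$–$10^{-9}$
for floating-point linear algebra (FFT vs DFT, PCA vs eigendecomposition,
Parseval), Monte-Carlo bands (3 SE) for stochastic checks. Ties in AIC
go to fewer parameters; ties in nearest-neighbor distance resolve by
index order; the RNG state is always restored after seeded operations.

## Known limitations

* The classifier is intentionally small; no regularization, early
  stopping or architecture search is provided.
* Energy features inherit whatever biases the supplied table carries;
  the bundled tables are illustrative only.
* Markov order 1 for the non-coding generator understates long-range
  structure in real lncRNA.
* PCA truncation for partial combinations is variance-ranked, which need
  not be discrimination-ranked; a supervised selection is out of scope.
* Metrics are point estimates on a single split; no cross-validation or
  bootstrap intervals.
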