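# lncsig

Discriminating long non-coding RNA (lncRNA) from messenger RNA (mRNA) using
only sequence-intrinsic signals. Annotating transcripts without relying on
homology or ORF heuristics matters wherever experimental annotation is thin;
`lncsig` is aimed at bioinformaticians who want a transparent, fully
inspectable classifier built from three interpretable feature families
rather than a black box.

## The signals

**Base periodicity (BP, 2 features).** Coding sequence carries a period-3
signal from codon structure. For a sequence of length *N*, each base
*b ∈ {A,C,G,T}* defines a binary indicator vector *u_b*, and the summed
power spectrum is

    S[k] = Σ_b | Σ_n u_b[n] · e^(−2πikn/N) |²,   k = 0, …, N−1.

The two features are the period-3 peak `S[round(N/3)]` and its
signal-to-noise ratio, SNR = peak / mean(S[1..N−1]) (DC excluded). In
mRNA the peak stands well above the noise floor; in lncRNA it does not.

**Physicochemical energies (DP/TP, 3 + 3 features).** Solvation, stacking
and hydrogen-bonding energies per dinucleotide and trinucleotide
(kcal/mol), combined as the k-mer-frequency-weighted mean
Σ_m f(m)·E(m). Energy tables are supplied by the user as TSV
(`kmer  solvation  stacking  hbond`); the package ships clearly labelled
*synthetic illustrative* tables and can average an order-k table down to
order k−1 by positional means. The overlapping k-mer Markov transition
matrix P[i,j] = p(s_j | s_i) is also built and exportable.

**k-mer composition (DC/TC, up to 15 + 15 features).** Overlapping
dinucleotide (16-D) and trinucleotide (64-D) frequency vectors reduced by
PCA (fit on training rows only; deterministic sign convention).

Sixteen named combinations of these families (DP, TP, DPTP, DC, TC, BP,
BPDP, BPTP, BPDPTP, BPDC, BPTC, BPDCTC, DPDC, TPTC, DCTC, DPTPDCTC) cap
the model input at 15 columns, truncated families keeping their
top-variance components. Class imbalance is removed by seeded random
undersampling or SMOTE; the classifier is a small feed-forward network
(one hidden layer, ReLU, sigmoid output) trained with binary
cross-entropy, Loss(y, ŷ) = −y·log ŷ − (1−y)·log(1−ŷ), by mini-batch
gradient descent. Evaluation reports accuracy, precision, recall,
ROC-AUC, PRC-AUC and F1 on a stratified held-out split, and the
distributions of the spectral features can be fit by lognormal, gamma and
exponential MLE with AIC model selection.

A seeded synthetic-sequence generator (codon-biased coding-like sequences
vs first-order Markov non-coding-like sequences) makes the whole pipeline
testable without any downloads.

## Worked example

```r
library(lncsig)
ds  <- simulate_dataset(generator_config(n_per_class = 200, seed = 7))
fit <- lnc_classifier(ds$lnc, ds$mrna, combo = "BPDC",
                      balance = "undersample", seed = 7)
print(fit)
```

```
lncRNA/mRNA classifier
  combination : BPDC ( 15 features )
  balancing   : undersample 
  split       : 320 train / 80 test
  held-out    : accuracy 1.0000, ROC-AUC 1.0000, F1 1.0000
```

With 200 sequences per class and codon-bias strength 2, the combination
of base periodicity and dinucleotide composition separates the two
synthetic classes perfectly on the 80-sequence held-out split. The
period-3 machinery is exact — a pure codon repeat concentrates its power
in one bin:

```r
print(power_spectrum(strrep("ATG", 100)))
```

```
Base-indicator power spectrum
  length N     : 300 
  period-3 bin : 100 (k = round(N/3))
  peak power   : 30000 
  SNR          : 149.5 
```

Each of the three nonzero indicators contributes magnitude 100 at bin
N/3, giving 3 × 100² = 30000. The SNR distribution of the coding-like
class is positively skewed, and its best-fitting family can be checked
directly:

```r
bp <- bp_features(ds$mrna)
print(select_best_fit(bp$bp_snr))
```

```
Distribution fits (AIC model selection):
  lognormal    AIC = 1702.04
  gamma        AIC = 1693.19  <- selected
  exponential  AIC = 1885.33
```

New sequences are classified with `predict(fit, records)`; fitted
pipelines round-trip through JSON with `save_classifier()` /
`load_classifier()`.

## Command line

A thin wrapper ships at `inst/cli/lncsig` (find it with
`system.file("cli/lncsig", package = "lncsig")`):

```sh
lncsig simulate --out-dir sim --n 500 --seed 1
lncsig features --lnc sim/lncrna_like.fasta --mrna sim/mrna_like.fasta --out-dir feat
lncsig train    --lnc sim/lncrna_like.fasta --mrna sim/mrna_like.fasta \
                --combo BPDC --balance smote --out-dir run --seed 1
lncsig predict  --model run/model.json --fasta new.fasta --out predictions.tsv
lncsig fitdist  --features feat/bp.tsv --column bp_snr
lncsig combos   list
```

Every run writes a JSON manifest (flags, seed, versions, energy-table
checksums). Exit codes: 0 success, 2 input error, 3 numeric failure.

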