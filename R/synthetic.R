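## Seeded generator of labelled synthetic sequences.
##
## The coding-like class concatenates i.i.d. codons from a (sharpened)
## codon-usage distribution, which plants the period-3 signal the
## classifier exploits; the non-coding-like class is a first-order Markov
## chain over nucleotides with no frame structure. Together they emulate
## the statistical contrast between mRNA and lncRNA without copying any
## organism's data.

#' Generator configuration
#'
#' @param n_per_class sequences per class (default 500).
#' @param length_range `(min, max)` sequence length in nt (default
#'   `c(200, 1000)`: the lncRNA length floor up to typical transcript
#'   scale); min must be at least 9 for period-3 analysis.
#' @param codon_usage 64-simplex of codon weights for the coding class;
#'   default [default_codon_usage()] of the seed.
#' @param markov_order1 4x4 row-stochastic nucleotide transition matrix
#'   for the non-coding class; default [default_markov_matrix()].
#' @param codon_bias_strength temperature exponent on `codon_usage`
#'   (weights proportional to `usage^strength`): 0 erases all bias (every
#'   codon equally likely, i.i.d. uniform bases), 1 uses the table as-is,
#'   larger sharpens it. Default 2.
#' @param seed integer RNG seed.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_per_class = 500L, length_range = c(200L, 1000L),
                             codon_usage = NULL, markov_order1 = NULL,
                             codon_bias_strength = 2, seed = 1L) {
  stopifnot(n_per_class >= 1, length(length_range) == 2,
            length_range[1] >= 9, length_range[1] <= length_range[2],
            codon_bias_strength >= 0)
  if (is.null(codon_usage)) codon_usage <- default_codon_usage(seed)
  if (is.null(markov_order1)) markov_order1 <- default_markov_matrix()
  stopifnot(length(codon_usage) == 64, all(codon_usage >= 0),
            abs(sum(codon_usage) - 1) < 1e-9)
  stopifnot(is.matrix(markov_order1), all(dim(markov_order1) == 4),
            all(markov_order1 >= 0),
            all(abs(rowSums(markov_order1) - 1) < 1e-9))
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 codon_usage = codon_usage, markov_order1 = markov_order1,
                 codon_bias_strength = codon_bias_strength,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default skewed codon-usage table
#'
#' Concentrates mass on a random 20-codon subset (exponential weights,
#' normalized), emulating codon bias without copying any organism's usage
#' table. Deterministic per seed.
#'
#' @param seed integer RNG seed.
#' @return named 64-vector on the simplex.
#' @export
default_codon_usage <- function(seed = 1L) {
  codons <- all_kmers(3)
  with_seed(seed, {
    chosen <- sample(codons, 20)
    w <- stats::setNames(rep(0, 64), codons)
    w[chosen] <- rexp(20)
    w / sum(w)
  })
}

#' Default non-coding transition matrix
#'
#' A mildly structured row-stochastic matrix (slight purine/pyrimidine
#' alternation preference and CG-step depletion, echoing broad features of
#' vertebrate non-coding sequence) used for the lncRNA-like class when no
#' matrix is supplied.
#'
#' @return 4x4 row-stochastic matrix with ACGT dimnames.
#' @export
default_markov_matrix <- function() {
  m <- matrix(c(
    0.28, 0.22, 0.26, 0.24,  # from A
    0.30, 0.26, 0.08, 0.36,  # from C (depleted CG step)
    0.24, 0.26, 0.26, 0.24,  # from G
    0.22, 0.26, 0.28, 0.24   # from T
  ), 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
  m / rowSums(m)
}

## Uniform integer on [lo, hi]; safe when lo == hi (unlike sample(lo:hi, 1)).
draw_length <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

## Sharpen a simplex by temperature exponent; strength 0 gives uniform.
sharpen_usage <- function(usage, strength) {
  if (strength == 0) return(stats::setNames(rep(1 / 64, 64), names(usage)))
  w <- usage^strength
  w / sum(w)
}

#' Generate coding-like (mRNA-class) sequences
#'
#' Each sequence is a concatenation of codons drawn i.i.d. from the
#' sharpened codon-usage distribution; the length is uniform on the
#' configured range, rounded down to a codon multiple (lengths that round
#' to zero are resampled). Labelled 1 (mRNA). Deterministic per seed.
#'
#' @param config a [generator_config()].
#' @return sequence-set data.frame.
#' @export
generate_mrna_like <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  usage <- sharpen_usage(config$codon_usage, config$codon_bias_strength)
  codons <- all_kmers(3)
  with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_per_class), function(i) {
      repeat {
        len <- 3L * (draw_length(config$length_range[1],
                                 config$length_range[2]) %/% 3L)
        if (len > 0) break
      }
      paste(sample(codons, len %/% 3L, replace = TRUE, prob = usage),
            collapse = "")
    }, character(1))
    seq_records(sprintf("mrna_like_%04d", seq_len(config$n_per_class)),
                seqs, label = 1L)
  })
}

#' Generate non-coding-like (lncRNA-class) sequences
#'
#' First-order Markov chains over nucleotides with the configured
#' transition matrix, started from its stationary distribution (power
#' iteration; an error if the chain has no reachable stationary
#' distribution). No reading-frame structure. Labelled 0 (lncRNA).
#'
#' @param config a [generator_config()].
#' @return sequence-set data.frame.
#' @export
generate_lncrna_like <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  P <- config$markov_order1
  pi0 <- stationary_distribution(P, init = rep(0.25, 4))
  with_seed(config$seed + 1L, {
    seqs <- vapply(seq_len(config$n_per_class), function(i) {
      len <- draw_length(config$length_range[1], config$length_range[2])
      s <- integer(len)
      s[1] <- sample.int(4, 1, prob = pi0)
      for (t in seq_len(len - 1L))
        s[t + 1L] <- sample.int(4, 1, prob = P[s[t], ])
      paste(BASES[s], collapse = "")
    }, character(1))
    seq_records(sprintf("lncrna_like_%04d", seq_len(config$n_per_class)),
                seqs, label = 0L)
  })
}

#' Generate a balanced two-class synthetic dataset
#'
#' @param config a [generator_config()].
#' @return list with `lnc` and `mrna` sequence sets (`n_per_class` each)
#'   and the `config`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  list(lnc = generate_lncrna_like(config),
       mrna = generate_mrna_like(config),
       config = config)
}
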