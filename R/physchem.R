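## Physicochemical energy features.
##
## Three energies per k-mer (solvation, stacking, hydrogen bonding, kcal/mol)
## come from a user-supplied table; a sequence's three features are the
## k-mer-frequency-weighted mean energies. Tables of order k can be averaged
## down to order k-1 (tetranucleotide -> trinucleotide -> dinucleotide), and
## the overlapping-k-mer Markov transition matrix is built and exportable.

ENERGY_COLS <- c("solvation", "stacking", "hbond")

#' Construct and validate an energy table
#'
#' @param k k-mer order (2, 3 or 4).
#' @param energies numeric matrix, one row per k-mer (rownames are k-mers
#'   over `{A,C,G,T}`), columns `solvation`, `stacking`, `hbond`.
#' @return an object of class `"energy_table"`.
#' @export
energy_table <- function(k, energies) {
  stopifnot(k %in% 2:4)
  kmers <- all_kmers(k)
  rn <- toupper(rownames(energies))
  dup <- rn[duplicated(rn)]
  if (length(dup)) stop("duplicate k-mer(s): ", paste(unique(dup), collapse = ", "))
  missing <- setdiff(kmers, rn)
  if (length(missing))
    stop("incomplete energy table, missing: ", paste(head(missing, 8), collapse = ", "),
         if (length(missing) > 8) " ...")
  extra <- setdiff(rn, kmers)
  if (length(extra)) stop("unexpected k-mer(s) for order ", k, ": ",
                          paste(head(extra, 8), collapse = ", "))
  e <- as.matrix(energies[match(kmers, rn), ENERGY_COLS, drop = FALSE])
  storage.mode(e) <- "double"
  if (any(!is.finite(e))) stop("non-finite energy value in table")
  rownames(e) <- kmers
  structure(list(k = as.integer(k), energies = e), class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat("Physicochemical energy table: ", 4^x$k, " ", x$k, "-mers\n", sep = "")
  print(head(x$energies, 4))
  if (nrow(x$energies) > 4) cat("  ...\n")
  invisible(x)
}

#' Load an energy table from TSV
#'
#' Expected columns: `kmer`, `solvation`, `stacking`, `hbond`; exactly one
#' row per k-mer of the given order (case-insensitive keys).
#'
#' @param path TSV file path.
#' @param k k-mer order (2, 3 or 4).
#' @return an `"energy_table"`.
#' @export
load_energy_table <- function(path, k) {
  if (!file.exists(path)) stop("energy table not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("kmer", ENERGY_COLS)
  if (!all(need %in% names(d)))
    stop("energy table must have columns: ", paste(need, collapse = ", "))
  for (col in ENERGY_COLS)
    if (!is.numeric(d[[col]])) stop("non-numeric values in column '", col, "'")
  m <- as.matrix(d[, ENERGY_COLS])
  rownames(m) <- d$kmer
  energy_table(k, m)
}

#' Bundled illustrative energy table
#'
#' Loads the synthetic dinucleotide (k = 2) or trinucleotide (k = 3)
#' energy table shipped with the package. These values are illustrative
#' stand-ins with physically plausible magnitudes (hydrogen-bond energy
#' scales with G+C content, stacking and solvation vary smoothly); they are
#' NOT measured energies. Supply a real table via [load_energy_table()]
#' for scientific use.
#'
#' @param k 2 or 3.
#' @return an `"energy_table"`.
#' @export
example_energy_table <- function(k = 3) {
  stopifnot(k %in% 2:3)
  f <- system.file("extdata",
                   sprintf("synthetic_%snucleotide_energies.tsv",
                           if (k == 2) "di" else "tri"),
                   package = "lncsig", mustWork = TRUE)
  load_energy_table(f, k)
}

#' Average an energy table down one order
#'
#' The energy of each (k-1)-mer is the unweighted arithmetic mean of the
#' energies of all order-k k-mers containing it as a contiguous substring,
#' one term per distinct occurrence position (so e.g. AAA contributes twice
#' to AA: once with AA as prefix, once as suffix).
#'
#' @param table an `"energy_table"` of order k >= 3.
#' @return an `"energy_table"` of order k - 1.
#' @export
derive_lower_order_table <- function(table) {
  stopifnot(inherits(table, "energy_table"), table$k >= 3)
  sub <- all_kmers(table$k - 1L)
  e <- t(vapply(sub, function(m) {
    containing <- c(paste0(m, BASES), paste0(BASES, m))
    colMeans(table$energies[containing, , drop = FALSE])
  }, numeric(3)))
  colnames(e) <- ENERGY_COLS
  energy_table(table$k - 1L, e)
}

## Overlapping N-free k-mer counts via Biostrings (windows containing N are
## excluded from every bin).
kmer_counts <- function(seq, k) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
}

#' First-order transition matrix over overlapping k-mers
#'
#' Models the sequence as a Markov chain on overlapping k-mer states:
#' `counts[i, j]` is the number of adjacent k-mer pairs (positions t and
#' t+1, both N-free), so only transitions between k-mers overlapping in
#' k-1 bases can be nonzero. `probs` is the row-normalized count matrix;
#' rows with zero count are all-zero.
#'
#' @param seq a single normalized sequence.
#' @param k k-mer order (the state space has 4^k states).
#' @return an object of class `"transition_matrix"`: list with `k`,
#'   `counts` and `probs` (4^k x 4^k matrices with k-mer dimnames).
#' @export
transition_matrix <- function(seq, k) {
  stopifnot(k >= 1)
  if (nchar(seq) < k + 1) stop("sequence shorter than k+1")
  pair_counts <- kmer_counts(seq, k + 1L) # each (k+1)-mer is one transition
  if (sum(pair_counts) == 0) stop("no N-free k-mer transitions in sequence")
  kmers <- all_kmers(k)
  counts <- matrix(0L, 4^k, 4^k, dimnames = list(kmers, kmers))
  nz <- pair_counts[pair_counts > 0]
  for (w in names(nz)) {
    i <- substr(w, 1, k)
    j <- substr(w, 2, k + 1L)
    counts[i, j] <- counts[i, j] + as.integer(nz[[w]])
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 0
  structure(list(k = as.integer(k), counts = counts, probs = probs),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  occupied <- sum(rowSums(x$counts) > 0)
  cat("Overlapping ", x$k, "-mer transition matrix: ", 4^x$k, " states, ",
      occupied, " occupied, ", sum(x$counts), " transitions\n", sep = "")
  invisible(x)
}

#' Write a transition matrix as TSV
#'
#' Long format: `from`, `to`, `count`, `prob`, nonzero rows only.
#'
#' @param tm a `"transition_matrix"`.
#' @param path output path.
#' @export
write_transition_tsv <- function(tm, path) {
  idx <- which(tm$counts > 0, arr.ind = TRUE)
  d <- data.frame(from = rownames(tm$counts)[idx[, 1]],
                  to = colnames(tm$counts)[idx[, 2]],
                  count = tm$counts[idx], prob = tm$probs[idx])
  d <- d[order(d$from, d$to), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Stationary distribution of a (possibly empirical, possibly reducible)
## transition matrix by power iteration, started from the empirical k-mer
## frequencies.
stationary_distribution <- function(probs, init, tol = 1e-12, max_iter = 10000) {
  p <- init / sum(init)
  for (it in seq_len(max_iter)) {
    p_new <- as.vector(p %*% probs)
    s <- sum(p_new)
    if (s == 0) stop("transition matrix has no reachable stationary distribution")
    p_new <- p_new / s
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  stop("stationary distribution did not converge in ", max_iter, " iterations")
}

#' Energy features of one sequence
#'
#' Each feature is the weighted mean table energy, `sum_m f(m) E(m)`. By
#' default the weights `f` are the empirical overlapping k-mer frequencies
#' (N-free windows, normalized to sum to 1) — the empirical stationary
#' distribution up to end effects, well-defined on short sequences. With
#' `weighting = "stationary"` the stationary distribution of the fitted
#' first-order k-mer transition matrix is used instead (power iteration).
#'
#' @param seq a single normalized sequence.
#' @param table an `"energy_table"` (its order k sets the k-mer order).
#' @param weighting `"empirical"` (default) or `"stationary"`.
#' @return named numeric vector `(solvation, stacking, hbond)`.
#' @export
energy_features <- function(seq, table, weighting = c("empirical", "stationary")) {
  stopifnot(inherits(table, "energy_table"))
  weighting <- match.arg(weighting)
  counts <- kmer_counts(seq, table$k)
  total <- sum(counts)
  if (total == 0) stop("no N-free ", table$k, "-mer in sequence")
  f <- counts / total
  if (weighting == "stationary") {
    tm <- transition_matrix(seq, table$k)
    f <- stationary_distribution(tm$probs, init = f)
    names(f) <- rownames(table$energies)
  }
  vals <- as.vector(f %*% table$energies[names(f), , drop = FALSE])
  names(vals) <- ENERGY_COLS
  vals
}

#' Physicochemical features for a sequence set
#'
#' Dinucleotide (`dp_*`) and trinucleotide (`tp_*`) frequency-weighted mean
#' energies, three each.
#'
#' @param records sequence-set data.frame.
#' @param di_table order-2 `"energy_table"`.
#' @param tri_table order-3 `"energy_table"`.
#' @param weighting passed to [energy_features()].
#' @return feature-matrix data.frame: `id`, `label`, `dp_solvation`,
#'   `dp_stacking`, `dp_hbond`, `tp_solvation`, `tp_stacking`, `tp_hbond`.
#' @export
physchem_features <- function(records, di_table, tri_table,
                              weighting = "empirical") {
  stopifnot(di_table$k == 2, tri_table$k == 3)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    dp <- tryCatch(energy_features(records$seq[i], di_table, weighting),
                   error = function(e) stop("record '", records$id[i], "': ",
                                            conditionMessage(e), call. = FALSE))
    tp <- energy_features(records$seq[i], tri_table, weighting)
    c(dp_solvation = dp[["solvation"]], dp_stacking = dp[["stacking"]],
      dp_hbond = dp[["hbond"]],
      tp_solvation = tp[["solvation"]], tp_stacking = tp[["stacking"]],
      tp_hbond = tp[["hbond"]])
  })
  cbind(data.frame(id = records$id, label = records$label,
                   stringsAsFactors = FALSE),
        as.data.frame(do.call(rbind, rows)))
}
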