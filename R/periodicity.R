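## Base-periodicity (period-3) spectral features.
##
## Coding sequences carry a period-3 signal from codon structure, visible as
## a peak of the base-indicator power spectrum at frequency 1/3. Two features
## summarize it per sequence: the peak power and its signal-to-noise ratio.

#' Binary base-indicator vectors
#'
#' For each base b in A, C, G, T, the indicator vector holds 1 at positions
#' where the sequence equals b. Positions holding `N` are 0 in all four
#' vectors, so an N-free sequence's four indicators sum to the all-ones
#' vector.
#'
#' @param seq a single normalized sequence (uppercase, `{A,C,G,T,N}`).
#' @return an N x 4 binary matrix with columns `A`, `C`, `G`, `T`.
#' @export
indicator_vectors <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- vapply(BASES, function(b) as.numeric(chars == b), numeric(length(chars)))
  dimnames(m) <- list(NULL, BASES)
  m
}

#' Base-indicator power spectrum and period-3 summary
#'
#' Computes `S[k] = sum_b |DFT(u_b)[k]|^2`, the power spectrum summed over
#' the four base-indicator sequences (unnormalized DFT of length N, no
#' zero-padding, so Parseval gives `sum_k S[k] = N * #non-N positions`).
#' The period-3 peak is `S` at the DFT bin nearest N/3, and the SNR is that
#' peak divided by the mean of `S` over all non-DC bins (k = 1..N-1); the
#' DC bin encodes composition, not periodicity, and is excluded. A
#' homopolymer has zero power off DC and is assigned SNR 0 by convention.
#'
#' @param seq a single normalized sequence of length at least 9 (so the
#'   period-3 bin is at least 3 and distinct from DC).
#' @return an object of class `"power_spectrum"`: a list with `N`, `S`
#'   (length-N vector indexed by frequency k = 0..N-1), `peak_index`
#'   (0-based k of the period-3 bin), `peak` and `snr`.
#' @export
power_spectrum <- function(seq) {
  u <- indicator_vectors(seq)
  n <- nrow(u)
  if (n < 9) stop("sequence too short for period-3 analysis (length ", n, " < 9)")
  S <- rowSums(Mod(stats::mvfft(u))^2)
  k_peak <- as.integer(round(n / 3))
  peak <- S[k_peak + 1L]
  noise <- mean(S[2:n])
  ## off-DC power of a homopolymer is zero in exact arithmetic; guard the
  ## 0/0 with a threshold relative to the total power (Parseval scale N^2)
  snr <- if (noise > sum(S) * 1e-12) peak / noise else 0
  structure(
    list(N = n, S = S, peak_index = k_peak, peak = peak, snr = snr),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("Base-indicator power spectrum\n")
  cat("  length N     :", x$N, "\n")
  cat("  period-3 bin :", x$peak_index, "(k = round(N/3))\n")
  cat("  peak power   :", format(x$peak), "\n")
  cat("  SNR          :", format(x$snr), "\n")
  invisible(x)
}

#' Period-3 features for a sequence set
#'
#' One row per record with columns `bp_peak` (power at the period-3 bin)
#' and `bp_snr` (peak over mean non-DC power).
#'
#' @param records sequence-set data.frame.
#' @return feature-matrix data.frame: `id`, `label`, `bp_peak`, `bp_snr`.
#' @export
bp_features <- function(records) {
  feats <- lapply(seq_len(nrow(records)), function(i) {
    ps <- tryCatch(power_spectrum(records$seq[i]),
                   error = function(e) stop("record '", records$id[i], "': ",
                                            conditionMessage(e), call. = FALSE))
    c(bp_peak = ps$peak, bp_snr = ps$snr)
  })
  feats <- do.call(rbind, feats)
  data.frame(id = records$id, label = records$label,
             bp_peak = feats[, "bp_peak"], bp_snr = feats[, "bp_snr"],
             stringsAsFactors = FALSE)
}
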