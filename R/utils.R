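#' @keywords internal
"_PACKAGE"

#' @importFrom stats mvfft fft rnorm runif rexp var sd predict dlnorm dgamma dexp
#' @importFrom utils read.delim write.table head tail packageVersion
#' @importFrom grDevices chull
#' @importFrom graphics plot lines legend hist curve
NULL

BASES <- c("A", "C", "G", "T")

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## All k-mers over ACGT in lexicographic order (matches Biostrings ordering).
all_kmers <- function(k) {
  stopifnot(k >= 1)
  g <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  do.call(paste0, g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
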