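## Sequence input/output and normalization.
##
## A sequence set is a plain data.frame with columns
##   id (character), seq (character over {A,C,G,T,N}), label (integer 0/1/NA),
##   length (integer)
## Labels: 0 = lncRNA, 1 = mRNA (positive class), NA = unlabelled.

## IUPAC ambiguity codes other than N; all collapse to N on load.
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a sequence set
#'
#' Builds the package's standard sequence container: a data.frame with
#' columns `id`, `seq`, `label` and `length`. Sequences are normalized
#' (uppercased, `U` mapped to `T`, IUPAC ambiguity codes other than `N`
#' mapped to `N`); characters outside the accepted alphabet are an error.
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of nucleotide sequences.
#' @param label class label applied to all records: `0` (lncRNA), `1`
#'   (mRNA), or `NA` for unlabelled.
#' @return data.frame with one row per sequence.
#' @export
seq_records <- function(ids, seqs, label = NA_integer_) {
  stopifnot(length(ids) == length(seqs))
  seqs <- normalize_sequence(seqs)
  if (any(nchar(seqs) == 0)) stop("empty sequence in input")
  data.frame(
    id = as.character(ids),
    seq = seqs,
    label = as.integer(label),
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
}

#' Normalize nucleotide sequences
#'
#' Uppercases, maps `U` to `T` (RNA to DNA alphabet) and collapses IUPAC
#' ambiguity codes other than `N` to `N`, warning with the count of
#' replaced characters. Any character outside the IUPAC nucleotide
#' alphabet is rejected.
#'
#' @param seqs character vector.
#' @return normalized character vector over `{A,C,G,T,N}`.
#' @export
normalize_sequence <- function(seqs) {
  out <- toupper(seqs)
  out <- chartr("U", "T", out)
  bad <- gsub(paste0("[ACGTN", paste(IUPAC_AMBIG, collapse = ""), "]"), "", out)
  if (any(nchar(bad) > 0)) {
    chars <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    stop("invalid sequence character(s): ", paste(chars, collapse = ", "))
  }
  n_ambig <- sum(nchar(out)) -
    sum(nchar(gsub(paste0("[", paste(IUPAC_AMBIG, collapse = ""), "]"), "", out)))
  if (n_ambig > 0) {
    warning(n_ambig, " IUPAC ambiguity character(s) mapped to N")
    out <- chartr(paste(IUPAC_AMBIG, collapse = ""),
                  strrep("N", length(IUPAC_AMBIG)), out)
  }
  out
}

#' Read labelled sequences from a FASTA file
#'
#' One record per FASTA entry, in file order; the id is the first
#' whitespace-delimited token of the header. Sequences are normalized as in
#' [normalize_sequence()]. Empty entries are skipped with a warning. The
#' label is assigned file-wide: the two-file interface (one FASTA per
#' class) carries the class, not the headers.
#'
#' @param path FASTA file path (multi-line sequences allowed).
#' @param label class label for every record in the file: `0` (lncRNA),
#'   `1` (mRNA) or `NA`.
#' @return sequence-set data.frame (see [seq_records()]).
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ## cheap structural check so a malformed file fails with a line number
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA (sequence line before first header) at line ",
         nonblank[1], " of ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  seqs <- as.character(x)
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    warning(sum(empty), " empty FASTA entr(ies) skipped: ",
            paste(ids[empty], collapse = ", "))
    ids <- ids[!empty]; seqs <- seqs[!empty]
  }
  if (length(seqs) == 0) stop("no non-empty sequences in ", path)
  seq_records(ids, seqs, label = label)
}

#' Write a sequence set to FASTA
#'
#' @param records sequence-set data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Filter sequences by length and N content
#'
#' Retains records with `length >= min_len` and a fraction of `N`
#' characters at most `max_n_frac`, reporting the number removed.
#'
#' @param records sequence-set data.frame.
#' @param min_len minimum length in nt (default 200, the conventional
#'   lncRNA length floor).
#' @param max_n_frac maximum tolerated fraction of ambiguous positions.
#' @return the filtered sequence set.
#' @export
filter_by_length <- function(records, min_len = 200L, max_n_frac = 0.1) {
  stopifnot(min_len >= 1, max_n_frac >= 0, max_n_frac <= 1)
  if (nrow(records) == 0) return(records)
  n_count <- nchar(records$seq) - nchar(gsub("N", "", records$seq, fixed = TRUE))
  keep <- records$length >= min_len & n_count / records$length <= max_n_frac
  removed <- sum(!keep)
  if (removed > 0)
    message(removed, " record(s) removed by length/N filter (",
            sum(records$length < min_len), " short, ",
            sum(n_count / records$length > max_n_frac), " N-rich)")
  records[keep, , drop = FALSE]
}

#' Write a feature matrix as TSV
#'
#' First columns are `id` and `label`, then the named feature columns.
#'
#' @param features feature-matrix data.frame with `id` and `label` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  first <- intersect(c("id", "label"), names(features))
  rest <- setdiff(names(features), first)
  write.table(features[, c(first, rest), drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Align rows of several feature matrices by id; error on mismatch.
align_by_id <- function(mats) {
  ids <- mats[[1]]$id
  for (m in mats) {
    if (!identical(sort(m$id), sort(ids)))
      stop("row-id mismatch across feature families")
  }
  lapply(mats, function(m) m[match(ids, m$id), , drop = FALSE])
}
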