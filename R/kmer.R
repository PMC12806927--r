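#' Overlapping k-mer tokens of a sequence
#'
#' Slides a window of width `k` with stride 1, yielding exactly
#' `nchar(seq) - k + 1` tokens.  Any window containing a character other
#' than A/C/G/T (after upper-casing) becomes the unknown token `[UNK]`.
#'
#' @param seq A single nucleotide string of length >= `k`.
#' @param k Token width.
#' @return Character vector of tokens.
#' @examples
#' kmer_tokens("ACGTAC", 3) # ACG CGT GTA TAC
#' @export
kmer_tokens <- function(seq, k = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(k)
  n <- nchar(seq)
  if (n < k) {
    abort(paste0("sequence length ", n, " < k = ", k))
  }
  s <- toupper(seq)
  tokens <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  tokens[grepl("[^ACGT]", tokens)] <- "[UNK]"
  tokens
}

#' All k-mers over {A, C, G, T} in lexicographic order
#'
#' @param k Word length (1..8).
#' @return Character vector of length `4^k`.
#' @export
all_kmers <- function(k = 3L) {
  k <- as.integer(k)
  if (k < 1L || k > 8L) abort("k must be in 1..8")
  bases <- c("A", "C", "G", "T")
  grids <- rev(rep(list(bases), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' k-mer frequency vector of one sequence
#'
#' Counts overlapping k-mer occurrences in lexicographic slot order over
#' `{A, C, G, T}^k`; windows containing any non-ACGT character are
#' excluded from the counts.  With `normalize = TRUE` (the default) counts
#' are divided by the number of valid windows, so the vector sums to 1 for
#' an unambiguous sequence and is the zero vector when no window is valid
#' (e.g. an all-N sequence).
#'
#' @param seq A single nucleotide string (case-insensitive), length >= `k`.
#' @param k Word length.
#' @param normalize Divide counts by the number of valid windows.
#' @return Named numeric vector of length `4^k`.
#' @export
kmer_frequency_vector <- function(seq, k = 3L, normalize = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  drop(kmer_frequency_matrix(seq, k = k, normalize = normalize))
}

# Vectorised counting over many sequences; rows = sequences, columns =
# lexicographic k-mers.  Biostrings counts only unambiguous windows, which
# is exactly the exclusion rule used here.
kmer_frequency_matrix <- function(seqs, k = 3L, normalize = TRUE) {
  k <- as.integer(k)
  if (k < 1L || k > 8L) abort("k must be in 1..8")
  n <- nchar(seqs)
  if (any(n < k)) {
    abort(paste0("sequence length ", min(n), " < k = ", k))
  }
  set <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  if (normalize) {
    valid <- rowSums(counts)
    counts <- counts / pmax(valid, 1L) # all-ambiguous row stays zero
  }
  counts
}

#' Concatenated pair feature vectors
#'
#' The classical-model representation of sequence-pair examples: the k-mer
#' frequency vector of the first anchor window concatenated with that of
#' the second, giving `2 * 4^k` features per example (128 at the default
#' `k = 3`).
#'
#' @param pairs Tibble of pair examples (`id`, `seq_a`, `seq_b`, `label`).
#' @param k Word length.
#' @param normalize Passed to the per-sequence counting.
#' @return A tibble with columns `id`, `label` and `2 * 4^k` feature
#'   columns named `a_<kmer>` and `b_<kmer>`.
#' @export
pair_features <- function(pairs, k = 3L, normalize = TRUE) {
  stopifnot(all(c("seq_a", "seq_b", "label") %in% names(pairs)))
  ids <- pairs$id %||% paste0("ex", seq_len(nrow(pairs)))
  if (nrow(pairs) == 0L) {
    km <- all_kmers(k)
    empty <- matrix(numeric(), 0L, 2L * length(km),
      dimnames = list(NULL, c(paste0("a_", km), paste0("b_", km)))
    )
    return(dplyr::bind_cols(
      tibble::tibble(id = character(), label = integer()),
      tibble::as_tibble(empty)
    ))
  }
  fa <- kmer_frequency_matrix(pairs$seq_a, k = k, normalize = normalize)
  fb <- kmer_frequency_matrix(pairs$seq_b, k = k, normalize = normalize)
  colnames(fa) <- paste0("a_", colnames(fa))
  colnames(fb) <- paste0("b_", colnames(fb))
  dplyr::bind_cols(
    tibble::tibble(id = ids, label = as.integer(pairs$label)),
    tibble::as_tibble(fa), tibble::as_tibble(fb)
  )
}

# Numeric feature matrix (examples x features) from a pair_features tibble.
feature_matrix <- function(features) {
  stopifnot(all(c("id", "label") %in% names(features)))
  m <- as.matrix(features[setdiff(names(features), c("id", "label"))])
  rownames(m) <- features$id
  m
}

#' Token vocabulary for the deep sequence-pair classifier
#'
#' The DNA-language vocabulary: the five special tokens `[PAD]`, `[UNK]`,
#' `[CLS]`, `[SEP]`, `[MASK]` at indices 0..4, followed by all `4^k`
#' k-mers in lexicographic order, for `4^k + 5` tokens in total (69 at
#' `k = 3`).
#'
#' @param k Token width (1..8).
#' @return A list of class `dhl_vocabulary` with elements `tokens`
#'   (ordered character vector), `index` (named integer vector of 0-based
#'   indices) and `k`.
#' @export
build_vocabulary <- function(k = 3L) {
  k <- as.integer(k)
  if (k < 1L || k > 8L) abort("k must be in 1..8")
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
  tokens <- c(specials, all_kmers(k))
  structure(
    list(
      tokens = tokens,
      index = setNames(seq_along(tokens) - 1L, tokens),
      k = k
    ),
    class = "dhl_vocabulary"
  )
}

#' @export
print.dhl_vocabulary <- function(x, ...) {
  cat("<dhl_vocabulary> k = ", x$k, ", ", length(x$tokens), " tokens\n", sep = "")
  cat("  ", paste(head(x$tokens, 8L), collapse = " "), " ...\n", sep = "")
  invisible(x)
}

#' Write a vocabulary, one token per line
#'
#' @param vocab A [build_vocabulary()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}
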