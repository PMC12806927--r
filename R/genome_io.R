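#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a named character vector,
#' one element per chromosome.  Sequence names are taken as the first
#' whitespace-delimited word of each header; sequences are upper-cased so
#' downstream k-mer handling is case-insensitive.  Ambiguity codes other
#' than N are rejected: the pipeline's alphabet is A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences
#'   (class `dhl_genome`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt", "ACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    abort(paste0(
      "duplicate FASTA header(s): ",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(paste0(
      "empty FASTA record(s): ",
      paste(nms[!nzchar(seqs)], collapse = ", ")
    ))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0(
      "non-ACGTN characters in record(s): ",
      paste(nms[bad], collapse = ", ")
    ))
  }
  names(seqs) <- nms
  new_genome(seqs)
}

new_genome <- function(seqs) {
  structure(seqs, class = c("dhl_genome", "character"))
}

#' @export
print.dhl_genome <- function(x, ...) {
  cat("<dhl_genome> ", length(x), " chromosome(s), ",
    format(sum(nchar(x)), big.mark = ","), " bp total\n",
    sep = ""
  )
  for (nm in names(x)) {
    cat("  ", nm, ": ", format(nchar(x[[nm]]), big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences (as returned by
#'   [read_genome_fasta()] or [simulate_genome()]).
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  set <- Biostrings::BStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read loop interactions from a BEDPE file
#'
#' Parses tab-separated BEDPE (0-based half-open coordinates): columns
#' `chrom1 start1 end1 chrom2 start2 end2` with an optional 7th label
#' column (1 = interacting loop, 0 = negative; default 1 so positive-only
#' files load directly).  Columns beyond the 7th are ignored.  Within each
#' intra-chromosomal line the two anchors are reordered so the first
#' anchor's centre is the smaller one.
#'
#' @param path Path to a BEDPE file.
#' @return A tibble with columns `chrom1, start1, end1, chrom2, start2,
#'   end2, label`, one row per interaction.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BEDPE file not found: ", path))
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_loops())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map2(fields, lineno, parse_bedpe_line)
  loops <- dplyr::bind_rows(rows)
  order_anchors(loops)
}

parse_bedpe_line <- function(f, lineno) {
  if (length(f) < 6L) {
    abort(paste0("BEDPE line ", lineno, ": expected >= 6 tab-separated columns, got ", length(f)))
  }
  coords <- suppressWarnings(as.integer(f[c(2L, 3L, 5L, 6L)]))
  if (anyNA(coords)) {
    abort(paste0("BEDPE line ", lineno, ": non-integer coordinate"))
  }
  if (coords[1L] < 0L || coords[3L] < 0L ||
    coords[1L] >= coords[2L] || coords[3L] >= coords[4L]) {
    abort(paste0("BEDPE line ", lineno, ": require 0 <= start < end for both anchors"))
  }
  label <- 1L
  if (length(f) >= 7L) {
    label <- suppressWarnings(as.integer(f[7L]))
    if (is.na(label) || !label %in% c(0L, 1L)) {
      abort(paste0("BEDPE line ", lineno, ": label column must be 0 or 1"))
    }
  }
  tibble::tibble(
    chrom1 = f[1L], start1 = coords[1L], end1 = coords[2L],
    chrom2 = f[4L], start2 = coords[3L], end2 = coords[4L],
    label = label
  )
}

empty_loops <- function() {
  tibble::tibble(
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    label = integer()
  )
}

# Reorder anchors within each loop so anchor 1 has the smaller centre
# (ties and inter-chromosomal rows ordered by (chrom, centre)).
order_anchors <- function(loops) {
  if (nrow(loops) == 0L) {
    return(loops)
  }
  c1 <- (loops$start1 + loops$end1) %/% 2L
  c2 <- (loops$start2 + loops$end2) %/% 2L
  swap <- (loops$chrom1 == loops$chrom2 & c1 > c2) |
    (loops$chrom1 > loops$chrom2)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <-
      loops[swap, c("chrom2", "start2", "end2")]
    loops[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  loops
}

#' Write loop interactions to a BEDPE file
#'
#' @param loops Tibble of loops as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  check_loops(loops)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\t%d",
    loops$chrom1, loops$start1, loops$end1,
    loops$chrom2, loops$start2, loops$end2, loops$label
  )
  writeLines(lines, path)
  invisible(path)
}

check_loops <- function(loops) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "label")
  if (!all(need %in% names(loops))) {
    abort(paste0(
      "loops must have columns: ", paste(need, collapse = ", ")
    ))
  }
  invisible(loops)
}

#' Write a paired-sequence dataset
#'
#' One record per line, tab-separated: `seq_a`, the literal delimiter token
#' `[SEP]`, `seq_b`, and the binary label, under a header line.  The two
#' subsequences of every example must have equal length (the configured
#' window size), so a 256 bp window setting yields a 512 bp sequence
#' payload per record.  [read_pair_dataset()] inverts this writer exactly.
#'
#' @param pairs Tibble with columns `seq_a`, `seq_b`, `label` (extra
#'   columns such as `id` and `chrom` are not serialised).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_dataset <- function(pairs, path) {
  stopifnot(all(c("seq_a", "seq_b", "label") %in% names(pairs)))
  if (nrow(pairs) > 0L && any(nchar(pairs$seq_a) != nchar(pairs$seq_b))) {
    abort("seq_a and seq_b must have equal length in every example")
  }
  lines <- c(
    "seq_a\tsep\tseq_b\tlabel",
    sprintf("%s\t[SEP]\t%s\t%d", pairs$seq_a, pairs$seq_b, as.integer(pairs$label))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a paired-sequence dataset
#'
#' @param path Path written by [write_pair_dataset()].
#' @return A tibble with columns `id` (`ex<n>` in file order), `seq_a`,
#'   `seq_b`, `label`.
#' @export
read_pair_dataset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("pair dataset file not found: ", path))
  }
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "seq_a\tsep\tseq_b\tlabel") {
    abort(paste0("not a pair dataset file (missing header): ", path))
  }
  lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      id = character(), seq_a = character(),
      seq_b = character(), label = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L | vapply(fields, `[`, "", 2L) != "[SEP]")
  if (length(bad) > 0L) {
    abort(paste0("malformed pair dataset record at line ", bad[1L] + 1L))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  label <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(label) || !all(label %in% c(0L, 1L))) {
    abort("pair dataset labels must be 0 or 1")
  }
  tibble::tibble(
    id = paste0("ex", seq_len(nrow(m))),
    seq_a = m[, 1L], seq_b = m[, 3L], label = label
  )
}
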