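#' Dataset construction settings
#'
#' Bundles the parameters of anchor-window dataset construction: the
#' half-window (`flank`, 128 bp by default so each anchor contributes a
#' 256 bp window and each example a 512 bp payload), the maximum
#' centre-to-centre interaction distance (1 Mb, inclusive), the held-out
#' chromosome(s) used only for testing (chr9), the negative:positive
#' ratio (1:1) and the random seed driving negative sampling.
#'
#' @param flank Half-window in bases; each anchor window is `2 * flank` bp.
#' @param max_distance Maximum centre-to-centre distance in bases
#'   (inclusive cap).
#' @param holdout_chromosomes Character vector of chromosomes reserved for
#'   the test split.
#' @param neg_pos_ratio Negatives drawn per positive.
#' @param max_n_frac Maximum tolerated fraction of N bases in an extracted
#'   window.
#' @param negative_distance_mode `"uniform"` draws negative anchor
#'   distances uniformly on `[2 * flank, max_distance]`; `"match"`
#'   resamples them from the empirical positive distances.
#' @param seed Integer seed for negative sampling.
#' @return A list of class `dhl_dataset_config`.
#' @export
dataset_config <- function(flank = 128L,
                           max_distance = 1000000L,
                           holdout_chromosomes = "chr9",
                           neg_pos_ratio = 1,
                           max_n_frac = 0.1,
                           negative_distance_mode = c("uniform", "match"),
                           seed = 1L) {
  flank <- as.integer(flank)
  max_distance <- as.integer(max_distance)
  negative_distance_mode <- match.arg(negative_distance_mode)
  if (flank <= 0L) abort("flank must be > 0")
  if (max_distance < 2L * flank) abort("max_distance must be >= 2 * flank")
  if (neg_pos_ratio <= 0) abort("neg_pos_ratio must be > 0")
  if (max_n_frac < 0 || max_n_frac > 1) abort("max_n_frac must be in [0, 1]")
  structure(
    list(
      flank = flank, max_distance = max_distance,
      holdout_chromosomes = as.character(holdout_chromosomes),
      neg_pos_ratio = neg_pos_ratio, max_n_frac = max_n_frac,
      negative_distance_mode = negative_distance_mode,
      seed = as.integer(seed)
    ),
    class = "dhl_dataset_config"
  )
}

#' Centre a fixed-length window on each anchor
#'
#' For an anchor `[start, end)` the centre is `floor((start + end) / 2)`
#' and the window is the half-open interval `[centre - flank,
#' centre + flank)`, i.e. exactly `2 * flank` bases.
#'
#' @param anchors Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param flank Half-window in bases.
#' @param genome Optional genome (named character vector); when supplied,
#'   an `in_bounds` column reports whether the window lies entirely inside
#'   its chromosome.
#' @return A tibble with columns `chrom`, `start`, `end` (the windows) and,
#'   with a genome, `in_bounds`.
#' @export
center_window <- function(anchors, flank, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(anchors)))
  flank <- as.integer(flank)
  centre <- (anchors$start + anchors$end) %/% 2L
  out <- tibble::tibble(
    chrom = anchors$chrom,
    start = centre - flank,
    end = centre + flank
  )
  if (!is.null(genome)) {
    len <- chrom_length_of(genome, out$chrom)
    out$in_bounds <- out$start >= 0L & !is.na(len) & out$end <= len
  }
  out
}

chrom_length_of <- function(genome, chrom) {
  len <- setNames(nchar(unclass(genome)), names(genome))
  unname(len[chrom])
}

#' Centre-to-centre interaction distance
#'
#' @param loops Tibble of intra-chromosomal loops ([read_bedpe()] layout).
#' @return Integer vector of absolute centre-to-centre distances in bases.
#' @export
interaction_distance <- function(loops) {
  check_loops(loops)
  if (nrow(loops) > 0L && any(loops$chrom1 != loops$chrom2)) {
    abort("interaction_distance is defined for intra-chromosomal loops only")
  }
  c1 <- (loops$start1 + loops$end1) %/% 2L
  c2 <- (loops$start2 + loops$end2) %/% 2L
  abs(c2 - c1)
}

#' Filter loops by chromosome, distance and window bounds
#'
#' Keeps intra-chromosomal loops whose centre-to-centre distance is at
#' most `cfg$max_distance` and whose two centred windows lie entirely
#' within the chromosome.  Input order is preserved.  The counts dropped
#' per reason are attached as the `"drop_counts"` attribute and reported
#' with a message.
#'
#' @param loops Tibble of loops.
#' @param genome Genome the loops index into.
#' @param cfg A [dataset_config()].
#' @return The surviving loops (possibly empty), with a `drop_counts`
#'   attribute.
#' @export
filter_interactions <- function(loops, genome, cfg = dataset_config()) {
  check_loops(loops)
  if (nrow(loops) == 0L) {
    out <- loops
    attr(out, "drop_counts") <- c(inter_chromosomal = 0L, too_distant = 0L, out_of_bounds = 0L)
    return(out)
  }
  intra <- loops$chrom1 == loops$chrom2
  dist <- ifelse(intra, abs(
    (loops$start2 + loops$end2) %/% 2L - (loops$start1 + loops$end1) %/% 2L
  ), NA_integer_)
  near <- intra & dist <= cfg$max_distance
  w1 <- center_window(
    tibble::tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1),
    cfg$flank, genome
  )
  w2 <- center_window(
    tibble::tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2),
    cfg$flank, genome
  )
  bounded <- w1$in_bounds & w2$in_bounds
  keep <- intra & near & bounded
  drops <- c(
    inter_chromosomal = sum(!intra),
    too_distant = sum(intra & !near),
    out_of_bounds = sum(intra & near & !bounded)
  )
  inform(paste0(
    "filter_interactions: kept ", sum(keep), "/", nrow(loops),
    " (dropped inter-chromosomal ", drops[["inter_chromosomal"]],
    ", > max distance ", drops[["too_distant"]],
    ", out-of-bounds window ", drops[["out_of_bounds"]], ")"
  ))
  out <- loops[keep, , drop = FALSE]
  attr(out, "drop_counts") <- drops
  out
}

#' Sample background (negative) interactions
#'
#' Draws `round(neg_pos_ratio * n_positives)` label-0 anchor pairs by
#' rejection sampling.  Each negative is drawn on the chromosome of a
#' matched positive (so the class balance holds within every chromosome
#' and therefore within both the training and holdout splits), with a
#' centre-to-centre distance either uniform on `[2 * flank, max_distance]`
#' or resampled from the positive distances, both windows in bounds, at
#' most `max_n_frac` N bases per window, and neither window overlapping
#' any positive anchor window.  Deterministic given `cfg$seed`.
#'
#' @param positives Tibble of already-filtered positive loops.
#' @param genome Genome to sample from.
#' @param cfg A [dataset_config()].
#' @param max_attempts Rejection-sampling attempts allowed per negative.
#' @return Tibble of negative loops (`label` 0), anchors equal to their
#'   centred windows.
#' @export
sample_negative_interactions <- function(positives, genome,
                                         cfg = dataset_config(),
                                         max_attempts = 2000L) {
  check_loops(positives)
  n_pos <- nrow(positives)
  n_neg <- round(cfg$neg_pos_ratio * n_pos)
  if (n_neg == 0L) {
    return(empty_loops())
  }

  flank <- cfg$flank
  chrom_len <- setNames(nchar(unclass(genome)), names(genome))
  pos_windows <- positive_windows_by_chrom(positives, flank)
  pos_dist <- interaction_distance(positives)

  # chromosome of each requested negative: match positives row-by-row at
  # ratio 1, otherwise resample from the positive chromosome distribution
  chroms <- if (n_neg == n_pos) {
    positives$chrom1
  } else {
    NULL # filled under the seed below
  }

  withr::with_seed(cfg$seed, {
    if (is.null(chroms)) {
      chroms <- sample(positives$chrom1, n_neg, replace = TRUE)
    }
    out <- vector("list", n_neg)
    for (i in seq_len(n_neg)) {
      chrom <- chroms[[i]]
      L <- chrom_len[[chrom]]
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        d <- if (cfg$negative_distance_mode == "match") {
          sample(pos_dist, 1L)
        } else {
          sample.int(cfg$max_distance - 2L * flank + 1L, 1L) + 2L * flank - 1L
        }
        lo <- flank
        hi <- L - flank - d
        if (hi < lo) next
        c1 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        c2 <- c1 + d
        s1 <- c1 - flank
        s2 <- c2 - flank
        if (windows_clash(pos_windows[[chrom]], c(s1, s2), flank)) next
        if (n_fraction(genome, chrom, s1, flank) > cfg$max_n_frac) next
        if (n_fraction(genome, chrom, s2, flank) > cfg$max_n_frac) next
        out[[i]] <- c(s1, s2)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(paste0(
          "negative sampling failed: placed ", i - 1L, " of ", n_neg,
          " negatives before exhausting ", max_attempts, " attempts"
        ))
      }
    }
  })

  starts <- do.call(rbind, out)
  tibble::tibble(
    chrom1 = chroms, start1 = starts[, 1L], end1 = starts[, 1L] + 2L * flank,
    chrom2 = chroms, start2 = starts[, 2L], end2 = starts[, 2L] + 2L * flank,
    label = 0L
  )
}

positive_windows_by_chrom <- function(positives, flank) {
  w1 <- center_window(tibble::tibble(
    chrom = positives$chrom1, start = positives$start1, end = positives$end1
  ), flank)
  w2 <- center_window(tibble::tibble(
    chrom = positives$chrom2, start = positives$start2, end = positives$end2
  ), flank)
  w <- dplyr::bind_rows(w1, w2)
  split(w[c("start", "end")], w$chrom)
}

# TRUE if either proposed window [s, s + 2*flank) overlaps any positive window
windows_clash <- function(pos, starts, flank) {
  if (is.null(pos) || nrow(pos) == 0L) {
    return(FALSE)
  }
  query <- IRanges::IRanges(start = starts + 1L, width = 2L * flank)
  subject <- IRanges::IRanges(start = pos$start + 1L, end = pos$end)
  any(IRanges::overlapsAny(query, subject))
}

n_fraction <- function(genome, chrom, start, flank) {
  s <- substr(genome[[chrom]], start + 1L, start + 2L * flank)
  nchar(gsub("[^N]", "", s)) / nchar(s)
}

#' Extract paired anchor-window sequences
#'
#' Pulls the plus-strand sequence of both centred anchor windows of each
#' loop, giving a combined payload of `4 * flank` bases per example
#' (512 bp at defaults).  Examples with more than `max_n_frac` N bases in
#' either window are dropped with a message; the count is attached as the
#' `"n_ambiguous_dropped"` attribute.
#'
#' @param loops Tibble of loops that pass [filter_interactions()].
#' @param genome Genome to extract from.
#' @param cfg A [dataset_config()].
#' @param ids Optional example identifiers (default `ex<row>`).
#' @return Tibble with columns `id`, `chrom`, `seq_a`, `seq_b`, `label`.
#' @export
extract_pairs <- function(loops, genome, cfg = dataset_config(), ids = NULL) {
  check_loops(loops)
  if (nrow(loops) == 0L) {
    out <- tibble::tibble(
      id = character(), chrom = character(), seq_a = character(),
      seq_b = character(), label = integer()
    )
    attr(out, "n_ambiguous_dropped") <- 0L
    return(out)
  }
  if (is.null(ids)) ids <- paste0("ex", seq_len(nrow(loops)))
  w1 <- center_window(
    tibble::tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1),
    cfg$flank, genome
  )
  w2 <- center_window(
    tibble::tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2),
    cfg$flank, genome
  )
  if (any(!w1$in_bounds | !w2$in_bounds)) {
    abort("extract_pairs: out-of-bounds window; run filter_interactions first")
  }
  seq_a <- substr(genome[loops$chrom1], w1$start + 1L, w1$end)
  seq_b <- substr(genome[loops$chrom2], w2$start + 1L, w2$end)
  nfrac <- function(s) nchar(gsub("[^N]", "", s)) / nchar(s)
  ok <- nfrac(seq_a) <= cfg$max_n_frac & nfrac(seq_b) <= cfg$max_n_frac
  if (any(!ok)) {
    inform(paste0(
      "extract_pairs: dropped ", sum(!ok),
      " example(s) with > ", cfg$max_n_frac * 100, "% ambiguous (N) bases"
    ))
  }
  out <- tibble::tibble(
    id = ids, chrom = loops$chrom1,
    seq_a = unname(seq_a), seq_b = unname(seq_b),
    label = as.integer(loops$label)
  )[ok, , drop = FALSE]
  attr(out, "n_ambiguous_dropped") <- sum(!ok)
  out
}

#' Split examples into training and holdout sets by chromosome
#'
#' @param pairs Tibble of pair examples with a `chrom` column.
#' @param cfg A [dataset_config()]; `cfg$holdout_chromosomes` defines the
#'   test set.
#' @return A list with elements `train` and `test` (disjoint, covering the
#'   input).
#' @export
split_by_chromosome <- function(pairs, cfg = dataset_config()) {
  stopifnot("chrom" %in% names(pairs))
  in_test <- pairs$chrom %in% cfg$holdout_chromosomes
  if (length(cfg$holdout_chromosomes) > 0L && nrow(pairs) > 0L && !any(in_test)) {
    warn(paste0(
      "holdout chromosome(s) ", paste(cfg$holdout_chromosomes, collapse = ", "),
      " absent from the data; test set is empty"
    ))
  }
  list(
    train = pairs[!in_test, , drop = FALSE],
    test = pairs[in_test, , drop = FALSE]
  )
}

#' Build a balanced train/test dataset from loops and a genome
#'
#' End-to-end dataset construction: filter the positive loops (distance
#' cap, window bounds), extract their window pairs (dropping ambiguous
#' ones), draw matched negatives from motif-free background, extract the
#' negative pairs, and split by holdout chromosome.  At
#' `neg_pos_ratio = 1` the result is 1:1 balanced within every chromosome
#' and hence within each split.
#'
#' @param genome Genome (named character vector).
#' @param positives Tibble of positive loops (label 1).
#' @param cfg A [dataset_config()].
#' @return A list of class `dhl_dataset`: `train`, `test` (pair tibbles)
#'   and `report` (named counts of kept/dropped examples).
#' @export
build_dataset <- function(genome, positives, cfg = dataset_config()) {
  check_loops(positives)
  kept <- filter_interactions(positives, genome, cfg)
  pos_pairs <- extract_pairs(
    kept, genome, cfg,
    ids = sprintf("pos%05d", seq_len(nrow(kept)))
  )
  # restrict to positives whose pairs survived so negatives match 1:1
  surv <- kept[match(pos_pairs$id, sprintf("pos%05d", seq_len(nrow(kept)))), , drop = FALSE]
  negatives <- sample_negative_interactions(surv, genome, cfg)
  neg_pairs <- extract_pairs(
    negatives, genome, cfg,
    ids = sprintf("neg%05d", seq_len(nrow(negatives)))
  )
  all_pairs <- dplyr::bind_rows(pos_pairs, neg_pairs)
  splits <- split_by_chromosome(all_pairs, cfg)
  report <- c(
    input_positives = nrow(positives),
    attr(kept, "drop_counts"),
    ambiguous_dropped = attr(pos_pairs, "n_ambiguous_dropped") +
      attr(neg_pairs, "n_ambiguous_dropped"),
    positives = nrow(pos_pairs),
    negatives = nrow(neg_pairs),
    train = nrow(splits$train),
    test = nrow(splits$test)
  )
  structure(
    list(train = splits$train, test = splits$test, report = report),
    class = "dhl_dataset"
  )
}

#' @export
print.dhl_dataset <- function(x, ...) {
  cat("<dhl_dataset>\n")
  cat(
    "  train: ", nrow(x$train), " examples (", sum(x$train$label == 1L),
    " pos / ", sum(x$train$label == 0L), " neg)\n",
    sep = ""
  )
  cat(
    "  test:  ", nrow(x$test), " examples (", sum(x$test$label == 1L),
    " pos / ", sum(x$test$label == 0L), " neg)\n",
    sep = ""
  )
  invisible(x)
}
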