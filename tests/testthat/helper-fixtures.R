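# Shared fixtures and independent brute-force oracles.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

tiny_genome <- function(lengths = c(chr1 = 4000L, chr2 = 4000L, chr9 = 4000L),
                        seed = 99L) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, random_seq, character(1L))
  })
  structure(seqs, class = c("dhl_genome", "character"))
}

random_loops <- function(genome, n, max_dist = 2000L, anchor_w = 100L,
                         seed = 7L, label = 1L) {
  chrom_len <- setNames(nchar(unclass(genome)), names(genome))
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_len), n, replace = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      L <- chrom_len[[chrom[i]]]
      s1 <- sample.int(L - max_dist - 2L * anchor_w, 1L)
      d <- sample.int(max_dist, 1L)
      s2 <- s1 + d
      tibble::tibble(
        chrom1 = chrom[i], start1 = s1, end1 = s1 + anchor_w,
        chrom2 = chrom[i], start2 = s2, end2 = s2 + anchor_w,
        label = as.integer(label)
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Brute-force overlapping k-mer dictionary counting (independent of the
# Biostrings-backed implementation).
bf_kmer_counts <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  kmers <- dhloop::all_kmers(k)
  counts <- setNames(integer(length(kmers)), kmers)
  for (i in seq_len(n - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    if (!grepl("[^ACGT]", w)) counts[[w]] <- counts[[w]] + 1L
  }
  counts
}

# All-pairs rank statistic for AUC, ties counting one half.
bf_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Small linearly separable two-cluster feature set in the pair_features
# tibble layout.
separable_features <- function(n_per_class = 30L, seed = 5L) {
  withr::with_seed(seed, {
    x0 <- matrix(stats::rnorm(n_per_class * 4L, mean = 0, sd = 0.2), ncol = 4L)
    x1 <- matrix(stats::rnorm(n_per_class * 4L, mean = 3, sd = 0.2), ncol = 4L)
  })
  m <- rbind(x0, x1)
  colnames(m) <- paste0("f", 1:4)
  dplyr::bind_cols(
    tibble::tibble(
      id = paste0("ex", seq_len(2L * n_per_class)),
      label = rep(c(0L, 1L), each = n_per_class)
    ),
    tibble::as_tibble(m)
  )
}

# Random prediction tibble over given ids.
random_predictions <- function(ids, seed) {
  withr::with_seed(seed, {
    score <- stats::runif(length(ids))
  })
  tibble::tibble(id = ids, label = as.integer(score >= 0.5), score = score)
}

# Independent re-statement of the anchor-ordering rule used by the BEDPE
# reader (anchor 1 gets the smaller centre).
order_anchors_ref <- function(loops) {
  for (i in seq_len(nrow(loops))) {
    c1 <- (loops$start1[i] + loops$end1[i]) %/% 2L
    c2 <- (loops$start2[i] + loops$end2[i]) %/% 2L
    if (c1 > c2) {
      tmp <- loops[i, c("chrom1", "start1", "end1")]
      loops[i, c("chrom1", "start1", "end1")] <-
        loops[i, c("chrom2", "start2", "end2")]
      loops[i, c("chrom2", "start2", "end2")] <- tmp
    }
  }
  loops
}

# A small, fast pipeline configuration for module-level tests.
small_pipeline_config <- function(seed = 1L, motif_prob = 1.0) {
  dhloop::pipeline_config(
    sim = dhloop::sim_config(
      n_chromosomes = 3L, chrom_length = 150000L, n_loops = 120L,
      motif_prob = motif_prob,
      loop_length_range = c(400L, 30000L)
    ),
    seed = seed
  )
}
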