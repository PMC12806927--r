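#' Synthetic loop-data simulation settings
#'
#' Configures the desk-scale simulator: a multi-chromosome genome of
#' i.i.d. random nucleotides, positive loops whose two anchors carry
#' planted motif instances, and a truth manifest of every insertion.
#' Defaults emulate a small CTCF-mediated loop study: four 500 kb
#' chromosomes (chr1-chr3 plus chr9 so the standard holdout is
#' exercised), 500 loops with centre distances uniform between 256 bp and
#' 100 kb, and a JASPAR-style 19 bp CTCF consensus planted on the first
#' anchor with its reverse complement on the second (convergent
#' orientation), each with probability `motif_prob`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_loops Number of positive loops to plant.
#' @param motif_a Motif planted at the centre of the first anchor.
#' @param motif_b Motif planted at the centre of the second anchor
#'   (default: reverse complement of `motif_a`).
#' @param motif_prob Probability that a positive anchor carries its motif
#'   (1 = always; 0 = positives indistinguishable from background).
#' @param loop_length_range Two-element integer range of centre-to-centre
#'   loop lengths in bases; defaults to 256 bp up to 100 kb (or the
#'   chromosome length, whichever is smaller).
#' @param base_composition Probabilities of A, C, G, T (in that order);
#'   the default matches the ~41% GC content of the human genome, giving
#'   the GC-rich CTCF consensus its natural contrast against background.
#' @param chrom_names Optional explicit chromosome names; by default
#'   `chr1..chr<n-1>` plus `chr9`.
#' @param seed Integer seed; the simulation is a pure function of the
#'   configuration including the seed.
#' @return A list of class `dhl_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4L,
                       chrom_length = 500000L,
                       n_loops = 500L,
                       motif_a = "TGGCCACCAGGGGGCGCTA",
                       motif_b = NULL,
                       motif_prob = 1.0,
                       loop_length_range = NULL,
                       base_composition = c(A = 0.295, C = 0.205, G = 0.205, T = 0.295),
                       chrom_names = NULL,
                       seed = 1L) {
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_length <- as.integer(chrom_length)
  if (is.null(motif_b)) motif_b <- reverse_complement(motif_a)
  if (is.null(loop_length_range)) {
    loop_length_range <- c(256L, max(256L, min(100000L, chrom_length)))
  }
  if (is.null(chrom_names)) {
    chrom_names <- if (n_chromosomes >= 2L) {
      c(paste0("chr", seq_len(n_chromosomes - 1L)), "chr9")
    } else {
      "chr1"
    }
  }
  if (length(chrom_names) != n_chromosomes || anyDuplicated(chrom_names)) {
    abort("chrom_names must be n_chromosomes unique names")
  }
  loop_length_range <- as.integer(loop_length_range)
  if (length(loop_length_range) != 2L ||
    loop_length_range[1L] > loop_length_range[2L]) {
    abort("loop_length_range must be c(min, max) with min <= max")
  }
  if (loop_length_range[2L] > chrom_length) {
    abort("loop_length_range maximum must not exceed chrom_length")
  }
  if (motif_prob < 0 || motif_prob > 1) abort("motif_prob must be in [0, 1]")
  if (grepl("[^ACGT]", motif_a) || grepl("[^ACGT]", motif_b)) {
    abort("motifs must be ACGT strings")
  }
  if (length(base_composition) != 4L || abs(sum(base_composition) - 1) > 1e-8) {
    abort("base_composition must be 4 probabilities summing to 1")
  }
  structure(
    list(
      n_chromosomes = n_chromosomes, chrom_length = chrom_length,
      n_loops = as.integer(n_loops),
      motif_a = motif_a, motif_b = motif_b, motif_prob = motif_prob,
      loop_length_range = loop_length_range,
      base_composition = unname(base_composition),
      chrom_names = chrom_names, seed = as.integer(seed)
    ),
    class = "dhl_sim_config"
  )
}

#' Reverse complement of a DNA string
#'
#' @param seq A single ACGTN string.
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Simulate a random genome
#'
#' Draws every position independently from `base_composition`.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A genome (named character vector, class `dhl_genome`).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "dhl_sim_config"))
  bases <- c("A", "C", "G", "T")
  seqs <- withr::with_seed(derive_seed(cfg$seed, "genome"), {
    vapply(cfg$chrom_names, function(nm) {
      paste(
        sample(bases, cfg$chrom_length, replace = TRUE, prob = cfg$base_composition),
        collapse = ""
      )
    }, character(1L))
  })
  new_genome(seqs)
}

#' Plant motif-bearing loops in a genome
#'
#' Draws `n_loops` intra-chromosomal anchor pairs with centre distances
#' uniform in `loop_length_range`, all anchor neighbourhoods pairwise
#' disjoint, and — independently per anchor with probability
#' `motif_prob` — overwrites the anchor centre with the configured motif
#' (motif on the first anchor, its partner on the second).  Overwriting
#' rather than inserting keeps all coordinates valid and window lengths
#' fixed.  The manifest records every planted position.
#'
#' @param genome A genome from [simulate_genome()].
#' @param cfg The same [sim_config()].
#' @param exclusion Half-width in bases of the per-anchor neighbourhood
#'   kept disjoint across loops (>= any extraction flank, so anchor
#'   windows never overlap).
#' @param max_attempts Rejection-sampling attempts per loop.
#' @return A list of class `dhl_sim`: `genome` (with motifs planted),
#'   `positives` (loop tibble, label 1) and `manifest` (tibble of planted
#'   motif positions: `loop`, `anchor`, `chrom`, `motif_start`, `motif`,
#'   `planted`).
#' @export
plant_loops <- function(genome, cfg = sim_config(), exclusion = 200L,
                        max_attempts = 5000L) {
  stopifnot(inherits(cfg, "dhl_sim_config"))
  chrom_len <- setNames(nchar(unclass(genome)), names(genome))
  half_w <- as.integer(exclusion)
  anchor_w <- 2L * half_w
  d_min <- max(cfg$loop_length_range[1L], anchor_w) # anchors must not self-overlap
  d_max <- cfg$loop_length_range[2L]
  len_a <- nchar(cfg$motif_a)
  len_b <- nchar(cfg$motif_b)

  placed <- withr::with_seed(derive_seed(cfg$seed, "loops"), {
    used <- lapply(chrom_len, function(...) IRanges::IRanges())
    rows <- vector("list", cfg$n_loops)
    plant <- matrix(FALSE, cfg$n_loops, 2L)
    for (i in seq_len(cfg$n_loops)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        chrom <- sample(names(chrom_len), 1L)
        L <- chrom_len[[chrom]]
        d <- d_min + sample.int(d_max - d_min + 1L, 1L) - 1L
        lo <- half_w
        hi <- L - half_w - d
        if (hi < lo) next
        c1 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        c2 <- c1 + d
        cand <- IRanges::IRanges(start = c(c1, c2) - half_w + 1L, width = anchor_w)
        if (any(IRanges::overlapsAny(cand, used[[chrom]]))) next
        used[[chrom]] <- c(used[[chrom]], cand)
        rows[[i]] <- list(chrom = chrom, c1 = c1, c2 = c2)
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(paste0(
          "loop placement failed: placed ", i - 1L, " of ", cfg$n_loops,
          " loops before exhausting ", max_attempts, " attempts"
        ))
      }
    }
    plant[] <- runif(2L * cfg$n_loops) < cfg$motif_prob
    list(rows = rows, plant = plant)
  })

  chroms <- vapply(placed$rows, `[[`, "", "chrom")
  c1 <- vapply(placed$rows, function(r) as.integer(r$c1), integer(1L))
  c2 <- vapply(placed$rows, function(r) as.integer(r$c2), integer(1L))

  # anchors reported as [centre - half_w, centre + half_w); motif overwrites
  # the anchor centre so any centred extraction window >= the motif holds it
  ms_a <- c1 - len_a %/% 2L
  ms_b <- c2 - len_b %/% 2L
  g <- unclass(genome)
  for (i in seq_along(chroms)) {
    if (placed$plant[i, 1L]) {
      substr(g[[chroms[i]]], ms_a[i] + 1L, ms_a[i] + len_a) <- cfg$motif_a
    }
    if (placed$plant[i, 2L]) {
      substr(g[[chroms[i]]], ms_b[i] + 1L, ms_b[i] + len_b) <- cfg$motif_b
    }
  }

  positives <- tibble::tibble(
    chrom1 = chroms, start1 = c1 - half_w, end1 = c1 + half_w,
    chrom2 = chroms, start2 = c2 - half_w, end2 = c2 + half_w,
    label = 1L
  )
  manifest <- tibble::tibble(
    loop = rep(seq_along(chroms), each = 2L),
    anchor = rep(c("a", "b"), length(chroms)),
    chrom = rep(chroms, each = 2L),
    motif_start = as.vector(rbind(ms_a, ms_b)),
    motif = rep(c(cfg$motif_a, cfg$motif_b), length(chroms)),
    planted = as.vector(t(placed$plant))
  )
  structure(
    list(genome = new_genome(g), positives = positives, manifest = manifest),
    class = "dhl_sim"
  )
}

#' @export
print.dhl_sim <- function(x, ...) {
  cat("<dhl_sim> ", nrow(x$positives), " loops on ",
    length(x$genome), " chromosome(s); ",
    sum(x$manifest$planted), "/", nrow(x$manifest), " anchors motif-bearing\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate and write a complete synthetic dataset
#'
#' Runs [simulate_genome()] and [plant_loops()] and writes the three
#' files the dataset builder consumes unchanged: a FASTA genome, a BEDPE
#' file of positive loops and a JSON truth manifest.  Bit-identical
#' output for the same configuration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the paths written: `fasta`, `bedpe`,
#'   `manifest`.
#' @export
generate_dataset <- function(cfg = sim_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- plant_loops(simulate_genome(cfg), cfg)
  fasta <- file.path(out_dir, "genome.fa")
  bedpe <- file.path(out_dir, "loops.bedpe")
  manifest <- file.path(out_dir, "manifest.json")
  write_genome_fasta(sim$genome, fasta)
  write_bedpe(sim$positives, bedpe)
  jsonlite::write_json(
    list(
      config = unclass(cfg)[setdiff(names(unclass(cfg)), character())],
      manifest = sim$manifest
    ),
    manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  c(fasta = fasta, bedpe = bedpe, manifest = manifest)
}
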