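test_that("centre windows are exactly 2*flank bases at the floor midpoint", {
  w <- center_window(
    tibble::tibble(chrom = "chr1", start = 1000L, end = 1500L),
    flank = 128L
  )
  expect_equal(as.list(w), list(chrom = "chr1", start = 1122L, end = 1378L))

  g <- tiny_genome()
  w2 <- center_window(
    tibble::tibble(chrom = "chr1", start = 0L, end = 100L),
    flank = 128L, genome = g
  )
  expect_false(w2$in_bounds) # centre 50 < flank

  withr::with_seed(17L, {
    anchors <- tibble::tibble(
      chrom = "chr1",
      start = sample.int(10000L, 1000L, replace = TRUE),
      end = integer(1000L)
    )
    anchors$end <- anchors$start + sample.int(500L, 1000L, replace = TRUE)
  })
  w3 <- center_window(anchors, flank = 128L)
  expect_true(all(w3$end - w3$start == 256L))
})

test_that("interaction distance is the absolute centre difference", {
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = 100L, end1 = 200L,
    chrom2 = "chr1", start2 = 900L, end2 = 1000L, label = 1L
  )
  expect_equal(interaction_distance(loops), 800L)

  same <- dplyr::mutate(loops, start2 = start1, end2 = end1)
  expect_equal(interaction_distance(same), 0L)

  inter <- dplyr::mutate(loops, chrom2 = "chr2")
  expect_error(interaction_distance(inter), "intra-chromosomal")
})

test_that("interaction distance equals its brute-force formula on random loops", {
  g <- tiny_genome()
  loops <- random_loops(g, 40L, seed = 23L)
  got <- interaction_distance(loops)
  ref <- abs(
    (loops$start1 + loops$end1) %/% 2L - (loops$start2 + loops$end2) %/% 2L
  )
  expect_equal(got, ref)
})

test_that("the distance cap is inclusive at 1 Mb", {
  g <- structure(
    c(chrA = strrep("A", 2100000L)),
    class = c("dhl_genome", "character")
  )
  mk <- function(d) {
    tibble::tibble(
      chrom1 = "chrA", start1 = 10000L, end1 = 10200L,
      chrom2 = "chrA", start2 = 10000L + d, end2 = 10200L + d, label = 1L
    )
  }
  kept <- suppressMessages(filter_interactions(mk(1000000L), g))
  dropped <- suppressMessages(filter_interactions(mk(1000001L), g))
  expect_equal(nrow(kept), 1L)
  expect_equal(nrow(dropped), 0L)
  expect_equal(attr(dropped, "drop_counts")[["too_distant"]], 1L)
})

test_that("filtering agrees with a brute-force re-check of all three predicates", {
  g <- tiny_genome()
  cfg <- dataset_config(max_distance = 1200L)
  loops <- random_loops(g, 20L, max_dist = 2000L, seed = 29L)
  loops$chrom2[1:3] <- setdiff(names(g), loops$chrom1[1:3][1])[1] # force inter-chrom
  loops$start1[4] <- 10L
  loops$end1[4] <- 20L # out-of-bounds window
  kept <- suppressMessages(filter_interactions(loops, g, cfg))

  keep_ref <- logical(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    r <- loops[i, ]
    if (r$chrom1 != r$chrom2) next
    c1 <- (r$start1 + r$end1) %/% 2L
    c2 <- (r$start2 + r$end2) %/% 2L
    if (abs(c2 - c1) > cfg$max_distance) next
    L <- nchar(g[[r$chrom1]])
    if (c1 - cfg$flank < 0L || c1 + cfg$flank > L) next
    if (c2 - cfg$flank < 0L || c2 + cfg$flank > L) next
    keep_ref[i] <- TRUE
  }
  attr(kept, "drop_counts") <- NULL
  expect_equal(as.data.frame(kept), as.data.frame(loops[keep_ref, ]))
})

test_that("negative sampling is balanced, non-overlapping and seed-deterministic", {
  cfg0 <- sim_config(n_chromosomes = 3L, chrom_length = 120000L, n_loops = 100L, seed = 3L)
  sim <- plant_loops(simulate_genome(cfg0), cfg0)
  cfg <- dataset_config(max_distance = 50000L, seed = 13L)
  pos <- suppressMessages(filter_interactions(sim$positives, sim$genome, cfg))

  neg <- sample_negative_interactions(pos, sim$genome, cfg)
  expect_equal(nrow(neg), nrow(pos))
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$chrom1 == neg$chrom2))
  expect_true(all(interaction_distance(neg) <= cfg$max_distance))

  # brute-force overlap check of every negative window vs every positive window
  pw1 <- center_window(tibble::tibble(
    chrom = pos$chrom1, start = pos$start1, end = pos$end1
  ), cfg$flank)
  pw2 <- center_window(tibble::tibble(
    chrom = pos$chrom2, start = pos$start2, end = pos$end2
  ), cfg$flank)
  pw <- rbind(pw1, pw2)
  nw <- rbind(
    tibble::tibble(chrom = neg$chrom1, start = neg$start1, end = neg$end1),
    tibble::tibble(chrom = neg$chrom2, start = neg$start2, end = neg$end2)
  )
  overlap <- FALSE
  for (i in seq_len(nrow(nw))) {
    same <- pw$chrom == nw$chrom[i]
    if (any(pw$start[same] < nw$end[i] & nw$start[i] < pw$end[same])) {
      overlap <- TRUE
      break
    }
  }
  expect_false(overlap)

  # determinism: same seed identical, different seed different
  neg_again <- sample_negative_interactions(pos, sim$genome, cfg)
  expect_identical(as.data.frame(neg), as.data.frame(neg_again))
  cfg14 <- dataset_config(max_distance = 50000L, seed = 14L)
  neg14 <- sample_negative_interactions(pos, sim$genome, cfg14)
  expect_false(identical(as.data.frame(neg), as.data.frame(neg14)))

  # no positives -> no negatives
  expect_equal(nrow(sample_negative_interactions(pos[0, ], sim$genome, cfg)), 0L)
})

test_that("extracted pairs carry 512 bp payloads and recover planted motifs", {
  cfg0 <- sim_config(n_chromosomes = 2L, chrom_length = 100000L, n_loops = 40L, seed = 5L)
  sim <- plant_loops(simulate_genome(cfg0), cfg0)
  cfg <- dataset_config(max_distance = 100000L)
  pos <- suppressMessages(filter_interactions(sim$positives, sim$genome, cfg))
  pairs <- extract_pairs(pos, sim$genome, cfg)
  expect_true(all(nchar(pairs$seq_a) + nchar(pairs$seq_b) == 512L))
  # every motif-bearing anchor window contains the planted string
  expect_true(all(grepl(cfg0$motif_a, pairs$seq_a, fixed = TRUE)))
  expect_true(all(grepl(cfg0$motif_b, pairs$seq_b, fixed = TRUE)))
  # and the extracted window equals the genome substring at the window
  w <- center_window(
    tibble::tibble(chrom = pos$chrom1, start = pos$start1, end = pos$end1),
    cfg$flank
  )
  expect_identical(
    pairs$seq_a[1],
    substr(sim$genome[[w$chrom[1]]], w$start[1] + 1L, w$end[1])
  )
})

test_that("windows exceeding the N-fraction threshold are dropped", {
  g <- structure(
    c(chr1 = paste0(
      strrep("A", 1000L),
      strrep("N", 100L), # inside the first anchor window
      strrep("A", 3000L)
    )),
    class = c("dhl_genome", "character")
  )
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = 950L, end1 = 1150L,
    chrom2 = "chr1", start2 = 2950L, end2 = 3150L, label = 1L
  )
  cfg <- dataset_config(max_distance = 10000L)
  # window a covers ~100 N of 256 (39%) -> dropped
  out <- suppressMessages(extract_pairs(loops, g, cfg))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_ambiguous_dropped"), 1L)

  # same loop with a permissive threshold is kept
  cfg2 <- dataset_config(max_distance = 10000L, max_n_frac = 0.5)
  expect_equal(nrow(extract_pairs(loops, g, cfg2)), 1L)
})

test_that("chromosome holdout splits partition the examples", {
  pairs <- tibble::tibble(
    id = paste0("ex", 1:100),
    chrom = rep(c("chr9", "chr1"), c(10L, 90L)),
    seq_a = "A", seq_b = "A", label = 1L
  )
  sp <- split_by_chromosome(pairs, dataset_config())
  expect_equal(nrow(sp$test), 10L)
  expect_equal(nrow(sp$train), 90L)
  expect_setequal(c(sp$train$id, sp$test$id), pairs$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)

  sp_all <- split_by_chromosome(pairs, dataset_config(holdout_chromosomes = character()))
  expect_equal(nrow(sp_all$train), 100L)

  expect_warning(
    split_by_chromosome(pairs, dataset_config(holdout_chromosomes = "chrX")),
    "absent"
  )

  # brute-force membership oracle on a random assignment
  withr::with_seed(37L, {
    pairs$chrom <- sample(c("chr1", "chr2", "chr9"), 100L, replace = TRUE)
  })
  sp2 <- split_by_chromosome(pairs, dataset_config())
  expect_identical(sp2$test$id, pairs$id[pairs$chrom == "chr9"])
  expect_identical(sp2$train$id, pairs$id[pairs$chrom != "chr9"])
})

test_that("built datasets are balanced within train and test with no leakage", {
  cfg0 <- sim_config(n_chromosomes = 3L, chrom_length = 150000L, n_loops = 120L, seed = 9L)
  sim <- plant_loops(simulate_genome(cfg0), cfg0)
  cfg <- dataset_config(max_distance = 100000L, seed = 2L)
  ds <- suppressMessages(build_dataset(sim$genome, sim$positives, cfg))

  expect_equal(sum(ds$train$label == 1L), sum(ds$train$label == 0L))
  expect_equal(sum(ds$test$label == 1L), sum(ds$test$label == 0L))
  expect_true(all(ds$test$chrom == "chr9"))
  expect_false(any(ds$train$chrom == "chr9"))
  expect_gt(nrow(ds$test), 0L)

  # determinism of the whole build
  ds2 <- suppressMessages(build_dataset(sim$genome, sim$positives, cfg))
  expect_identical(
    as.data.frame(ds$train), as.data.frame(ds2$train)
  )
})
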