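# Two-assembly gap closure and scaffold placement.

test_that("gap flanks are fetched, truncated at ends and at adjacent gaps", {
  seq <- rand_seq(100000L, 1L)
  old <- seq_records("chr", paste0(substr(seq, 1L, 20000L), strrep("N", 100L),
                                   substr(seq, 20101L, 100000L)))
  gap <- data.frame(seqid = "chr", start = 20000L, end = 20100L)
  fl <- extract_gap_flanks(old, gap)
  expect_equal(fl$left$len, 10000L)
  expect_equal(fl$left$seq, substr(old$seq, 10001L, 20000L))
  expect_equal(fl$right$seq, substr(old$seq, 20101L, 30100L))

  old2 <- seq_records("chr", paste0(substr(seq, 1L, 4000L), strrep("N", 50L),
                                    substr(seq, 4051L, 50000L)))
  gap2 <- data.frame(seqid = "chr", start = 4000L, end = 4050L)
  fl2 <- extract_gap_flanks(old2, gap2)
  expect_equal(fl2$left$len, 4000L)       # truncated by the sequence start

  # two gaps 6 kb apart: the right flank of the first stops at the second
  old3 <- seq_records("chr", paste0(substr(seq, 1L, 20000L), strrep("N", 50L),
                                    substr(seq, 20051L, 26000L), strrep("N", 50L),
                                    substr(seq, 26051L, 60000L)))
  g3 <- find_n_runs(old3$seq)
  g3$seqid <- "chr"
  fl3 <- extract_gap_flanks(old3, g3[1L, ])
  expect_equal(fl3$right$len, g3$start[2L] - g3$end[1L])
})

test_that("planted closable gaps close with exact spans; conflicts are flagged", {
  genome <- seq_records(c("c1", "c2"),
                        c(rand_seq(250000L, 11L), rand_seq(200000L, 12L)))
  deg <- degrade_assembly(genome, n_gaps = 4L, gap_len_range = c(200, 800),
                          n_excised_scaffolds = 0L, seed = 13L)
  cl <- fill_gaps(deg$old, genome)
  expect_true(all(cl$status == "closed"))
  tg <- deg$truth$gaps
  m <- merge(cl, tg, by = c("seqid", "start", "end"))
  expect_equal(nrow(m), 4L)
  expect_equal(m$estimated_span, m$span)   # zero span error

  # flanks on two different contigs -> conflicting
  idx <- build_seed_index(genome)
  fl <- list(left = seq_records("L", substr(genome$seq[1L], 50001L, 60000L)),
             right = seq_records("R", substr(genome$seq[2L], 50001L, 60000L)))
  fl$left$len <- 10000L; fl$right$len <- 10000L
  expect_equal(close_gap(fl, idx, genome)$status, "conflicting")

  # a flank degraded to ~85% identity fails the strict >90 rule
  mut <- with_seed(14L,
    mutate_positions_for_test(substr(genome$seq[1L], 50001L, 60000L),
                              sample.int(10000L, 1500L)))
  fl2 <- list(left = seq_records("L", mut),
              right = seq_records("R", substr(genome$seq[1L], 70001L, 80000L)))
  fl2$left$len <- 10000L; fl2$right$len <- 10000L
  expect_equal(close_gap(fl2, idx, genome)$status, "unresolved")
})

test_that("excised scaffolds place back at full fraction on one contig", {
  genome <- seq_records("chr1", rand_seq(220000L, 21L))
  deg <- degrade_assembly(genome, n_gaps = 0L, gap_len_range = c(100, 200),
                          n_excised_scaffolds = 2L,
                          scaffold_len_range = c(8000, 15000), seed = 22L)
  idx <- build_seed_index(genome)
  for (i in seq_len(nrow(deg$scaffolds))) {
    p <- place_scaffold(deg$scaffolds[i, ], idx, genome)
    expect_equal(p$status, "placed")
    expect_equal(p$contig, "chr1")
    expect_gte(p$placed_fraction, 99)
    tr <- deg$truth$placements[i, ]
    expect_equal(p$pieces$tstart[1L], tr$start)
  }
  # reverse-complement invariance
  s <- deg$scaffolds[1L, ]
  s$seq <- revcomp(s$seq)
  pr <- place_scaffold(s, idx, genome)
  expect_equal(pr$status, "placed")
  expect_equal(pr$strand, "-")
})

test_that("composite and random scaffolds fall to partial/unplaced", {
  genome <- seq_records("chrA", rand_seq(150000L, 31L))
  idx <- build_seed_index(genome)
  # 60% genuine + 40% random, joined by an N gap: placed, fraction in (50, 65)
  scf <- seq_records("mix", paste0(substr(genome$seq, 30001L, 42000L),
                                   strrep("N", 100L), rand_seq(8000L, 32L)))
  p <- place_scaffold(scf, idx, genome)
  expect_equal(p$status, "placed")
  expect_gt(p$placed_fraction, 50)
  expect_lt(p$placed_fraction, 65)

  rnd <- seq_records("rnd", rand_seq(20000L, 33L))
  expect_equal(place_scaffold(rnd, idx, genome)$status, "unplaced")
})

test_that("gapfill reports count statuses and conserve placed length", {
  closures <- data.frame(status = c(rep("closed", 5L), rep("conflicting", 2L)))
  placements <- data.frame(status = c("placed", "placed", "partial"),
                           length = c(1000L, 2500L, 700L))
  rep1 <- gapfill_report(closures, placements)
  expect_equal(unname(rep1$gap_counts["closed"]), 5L)
  expect_equal(unname(rep1$gap_counts["conflicting"]), 2L)
  expect_equal(unname(rep1$scaffold_counts["placed"]), 2L)
  expect_equal(rep1$placed_length, 3500L)

  rep0 <- gapfill_report(NULL, NULL)
  expect_true(all(rep0$gap_counts == 0L))
  expect_equal(rep0$placed_length, 0)
})

test_that("random degrade/close configurations recover every closable gap", {
  with_seed(41L, {
    for (cfg in 1:5) {
      genome <- seq_records("g", random_dna(180000L))
      deg <- degrade_assembly(genome, n_gaps = 3L,
                              gap_len_range = c(150, 500),
                              n_excised_scaffolds = 0L,
                              seed = sample.int(1e6, 1L))
      cl <- fill_gaps(deg$old, genome)
      expect_true(all(cl$status == "closed"))
      tg <- deg$truth$gaps[order(deg$truth$gaps$start), ]
      expect_equal(cl$estimated_span[order(cl$start)], tg$span)
    }
  })
})
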