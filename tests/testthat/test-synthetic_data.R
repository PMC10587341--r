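# The synthetic-data generator: determinism, construction rules, and the
# statistical structure of the planted data.

test_that("segment libraries are deterministic per seed and well-formed", {
  spec <- locus_spec("IGH", n_v = 5L, n_d = 3L, n_j = 3L, n_c = 1L)
  l1 <- make_segment_library(spec, 1L)
  l2 <- make_segment_library(spec, 1L)
  expect_identical(l1, l2)
  l3 <- make_segment_library(spec, 2L)
  expect_true(any(l1$seq != l3$seq))

  v <- l1[l1$seg_type == "V", ]
  for (i in seq_len(nrow(v))) {
    expect_true(startsWith(v$seq[i], "ATG"))
    aa <- translate_dna(v$seq[i])
    expect_false(grepl("*", aa, fixed = TRUE))   # no stop before the RSS
    cys <- substr(aa, v$cys_pos[i] / 3 + 1, v$cys_pos[i] / 3 + 1)
    expect_equal(cys, "C")
  }
  j <- l1[l1$seg_type == "J", ]
  for (i in seq_len(nrow(j))) {
    motif_aa <- translate_dna(substr(j$seq[i], j$motif_pos[i] + 1L,
                                     j$motif_pos[i] + 12L))
    expect_match(motif_aa, "^[FW]G.G")
  }
  expect_match(l1$name, "^IGH[VDJC][0-9]+$")
})

test_that("library round-trips through FASTA + metadata TSV", {
  spec <- locus_spec("TRB", n_v = 4L, n_d = 2L, n_j = 3L, n_c = 1L)
  lib <- make_segment_library(spec, 5L)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_segment_library(lib, fa, tsv)
  back <- read_segment_library(fa, tsv)
  expect_identical(back$seq, lib$seq)
  expect_identical(back$seg_type, lib$seg_type)
  expect_identical(back$cys_pos, lib$cys_pos)
})

test_that("plant_locus embeds segments whose truth intervals reproduce the planted sequence", {
  tl <- make_test_locus("TRA", n_v = 8L, n_j = 5L, n_c = 1L, seed = 11L)
  tr <- tl$truth
  expect_equal(nrow(tr), 14L)
  expect_true(all(tr$functionality == "F"))
  for (i in seq_len(nrow(tr))) {
    planted <- substr(tl$chromosome$seq, tr$start[i] + 1L, tr$end[i])
    entry <- tl$lib$seq[match(tr$name[i], tl$lib$name)]
    expect_identical(planted, entry)
  }
})

test_that("cassettes repeat in the specified order and defects force truth labels", {
  cass <- list(types = c("D", "J", "C"),
               counts = matrix(c(1L, 2L, 1L), nrow = 3L, ncol = 3L,
                               byrow = TRUE))
  tl <- make_test_locus("TRB", n_v = 0L, seed = 21L, cassette = cass)
  expect_equal(paste(tl$truth$seg_type, collapse = ""),
               strrep("DJJC", 3L))

  spec <- locus_spec("IGK", n_v = 6L, n_j = 2L, n_c = 1L,
                     defect_rates = c(stop_codon = 1))
  lib <- make_segment_library(spec, 22L)
  pl <- plant_locus(lib, spec, 23L)
  vt <- pl$truth[pl$truth$seg_type == "V", ]
  expect_true(all(vt$functionality == "P"))
  expect_true(all(grepl("internal_stop", vt$defects)))
})

test_that("minus-strand loci are emitted reverse-complemented with valid truth", {
  tl <- make_test_locus("IGL", n_v = 5L, n_j = 2L, n_c = 2L, seed = 31L,
                        strand = "-")
  expect_true(all(tl$truth$strand == "-"))
  for (i in seq_len(nrow(tl$truth))) {
    tr <- tl$truth[i, ]
    planted <- revcomp(substr(tl$chromosome$seq, tr$start + 1L, tr$end))
    expect_identical(planted, tl$lib$seq[match(tr$name, tl$lib$name)])
  }
})

test_that("chromosome ends carry the requested telomere and satDNA arrays", {
  chrom <- seq_records("c", rand_seq(20000L, 41L))
  pe <- plant_chromosome_ends(chrom, telomere_units = 3000L, seed = 42L)
  L <- nchar(pe$chromosome$seq)
  expect_identical(substr(pe$chromosome$seq, L - 17999L, L),
                   strrep("TTAGGG", 3000L))
  expect_equal(pe$telomere$end - pe$telomere$start, 18000L)

  same <- plant_chromosome_ends(chrom, telomere_units = 0L, seed = 42L)
  expect_identical(same$chromosome$seq, chrom$seq)

  sat <- plant_chromosome_ends(chrom, telomere_units = 0L,
                               satdna_pattern = rand_seq(23L, 43L),
                               satdna_copies = 200L, seed = 44L)
  expect_equal(sat$satdna$end - sat$satdna$start, 4600L)
})

test_that("degrade_assembly plants recoverable gaps and scaffolds", {
  genome <- seq_records("chr1", rand_seq(200000L, 51L))
  deg <- degrade_assembly(genome, n_gaps = 5L, gap_len_range = c(100, 600),
                          n_excised_scaffolds = 1L,
                          scaffold_len_range = c(5000, 10000), seed = 52L)
  runs <- find_n_runs(deg$old$seq[1L])
  expect_equal(nrow(runs), 5L)
  expect_equal(runs$end - runs$start,
               deg$truth$gaps$span[order(deg$truth$gaps$start)])
  pl <- deg$truth$placements
  expect_identical(deg$scaffolds$seq[1L],
                   substr(genome$seq, pl$start + 1L, pl$end))
})

test_that("diploid regions carry binomial-count phased SNPs", {
  d0 <- make_diploid_region(5000L, 0, seed = 61L)
  expect_identical(d0$hap1$seq, d0$hap2$seq)

  d <- make_diploid_region(100000L, 0.001, seed = 5L)
  n <- nrow(d$sites)
  expect_lt(abs(n - 100), 3 * sqrt(100 * 0.999) + 1)
  h1 <- strsplit(d$hap1$seq, "")[[1L]]
  h2 <- strsplit(d$hap2$seq, "")[[1L]]
  expect_true(all(h1[d$sites$pos + 1L] != h2[d$sites$pos + 1L]))
  expect_equal(sum(h1 != h2), n)
  expect_true(all(d$sites$gt == "0|1"))
})

test_that("simulated long reads have truthful origins, balance and coverage", {
  d <- make_diploid_region(60000L, 0.001, seed = 71L)
  sim <- simulate_long_reads(list(d$hap1, d$hap2), depth = 30L,
                             mean_len = 8000L, error_rate = 0, seed = 72L)
  expect_lte(abs(sum(sim$paf$hap == 1L) - sum(sim$paf$hap == 2L)), 1L)
  # error-free reads match their origin haplotype verbatim
  for (i in seq_len(10L)) {
    p <- sim$paf[i, ]
    src <- if (p$hap == 1L) d$hap1$seq else d$hap2$seq
    frag <- substr(src, p$tstart + 1L, p$tend)
    got <- sim$reads$seq[match(p$qname, sim$reads$id)]
    if (p$strand == "-") got <- revcomp(got)
    expect_identical(got, frag)
  }
  # coverage within 20% of target away from the margins
  depth <- integer(60000L)
  for (i in seq_len(nrow(sim$paf))) {
    p <- sim$paf[i, ]
    depth[(p$tstart + 1L):p$tend] <- depth[(p$tstart + 1L):p$tend] + 1L
  }
  interior <- depth[8001L:52000L]
  expect_lt(abs(mean(interior) - 30) / 30, 0.2)
})

test_that("simulated transcripts follow the usage weights and junction rules", {
  spec <- locus_spec("IGK", n_v = 3L, n_j = 2L, n_c = 1L)
  lib <- make_segment_library(spec, 81L)
  vn <- lib$name[lib$seg_type == "V"]
  jn <- lib$name[lib$seg_type == "J"]

  # point mass
  w <- list(v = setNames(c(1, 0, 0), vn), j = setNames(c(1, 0), jn))
  sim <- simulate_transcripts(lib, w, junction_model(), n = 25L, seed = 82L)
  expect_true(all(sim$truth$v_call == vn[1L]))
  expect_true(all(sim$truth$j_call == jn[1L]))

  # zero trimming and no N nucleotides leave V verbatim at the 5' end
  sim0 <- simulate_transcripts(lib, w, junction_model(n_max = 0L, trim_max = 0L),
                               n = 10L, seed = 83L)
  vseq <- lib$seq[match(vn[1L], lib$name)]
  expect_true(all(startsWith(sim0$transcripts$seq, vseq)))

  # malformed weights
  bad <- list(v = setNames(c(0.5, 0.2, 0.2), vn), j = setNames(c(1, 0), jn))
  expect_error(simulate_transcripts(lib, bad, junction_model(), 5L, 84L),
               class = "imm_parameter_error")

  # multinomial recovery at n = 2000: every V frequency within 3 SE
  spec10 <- locus_spec("TRA", n_v = 10L, n_j = 4L, n_c = 1L)
  lib10 <- make_segment_library(spec10, 85L)
  v10 <- lib10$name[lib10$seg_type == "V"]
  j10 <- lib10$name[lib10$seg_type == "J"]
  w10 <- list(v = setNames(rep(0.1, 10L), v10),
              j = setNames(rep(0.25, 4L), j10))
  simN <- simulate_transcripts(lib10, w10, junction_model(), n = 2000L,
                               seed = 9L)
  freq <- table(factor(simN$truth$v_call, levels = v10)) / 2000
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_true(all(abs(freq - 0.1) <= 3 * se))
})

test_that("generators are byte-identical under a repeated seed", {
  g1 <- degrade_assembly(seq_records("c", rand_seq(60000L, 91L)), 2L,
                         c(100, 300), 0L, seed = 92L, margin = 11000L)
  g2 <- degrade_assembly(seq_records("c", rand_seq(60000L, 91L)), 2L,
                         c(100, 300), 0L, seed = 92L, margin = 11000L)
  expect_identical(g1, g2)
  s1 <- simulate_long_reads(list(seq_records("a", rand_seq(5000L, 93L)),
                                 seq_records("b", rand_seq(5000L, 93L))),
                            10L, 1000L, 0.01, seed = 94L)
  s2 <- simulate_long_reads(list(seq_records("a", rand_seq(5000L, 93L)),
                                 seq_records("b", rand_seq(5000L, 93L))),
                            10L, 1000L, 0.01, seed = 94L)
  expect_identical(s1, s2)
})
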