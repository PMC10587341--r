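# Het-SNP pileup, wMEC phasing (exact DP vs brute force), read
# partitioning, haplotype consensus and MHC transcript validation.

test_that("error-free pileup recovers the interior truth sites exactly", {
  d <- make_diploid_region(60000L, 0.001, seed = 5L)
  sim <- simulate_long_reads(list(d$hap1, d$hap2), depth = 30L,
                             mean_len = 10000L, error_rate = 0, seed = 6L)
  sites <- pileup_het_snps(sim$reads, sim$paf, d$reference)
  interior <- d$sites[d$sites$pos >= 10000L & d$sites$pos < 50000L, ]
  got <- sites[sites$pos >= 10000L & sites$pos < 50000L, ]
  expect_identical(got$pos, interior$pos)
  expect_identical(got$ref, interior$ref)
  expect_identical(got$alt, interior$alt)
  # homozygous columns are never called
  expect_true(all(sites$pos %in% d$sites$pos))
})

test_that("noisy pileup keeps recall and precision at defaults", {
  d <- make_diploid_region(50000L, 0.001, seed = 7L)
  sim <- simulate_long_reads(list(d$hap1, d$hap2), depth = 30L,
                             mean_len = 10000L, error_rate = 0.02, seed = 8L)
  sites <- pileup_het_snps(sim$reads, sim$paf, d$reference)
  interior <- function(x) x[x$pos >= 10000L & x$pos < 40000L, ]
  tp <- sum(interior(sites)$pos %in% interior(d$sites)$pos)
  recall <- tp / nrow(interior(d$sites))
  precision <- tp / nrow(interior(sites))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("consistent reads phase with zero MEC; a contradicting read costs one", {
  m <- rbind(r1 = c(0L, 0L, NA), r2 = c(NA, 0L, 1L))
  b <- phase_wmec(as_allele_matrix(m))
  expect_length(b, 1L)
  expect_equal(b[[1L]]$mec, 0)
  expect_equal(b[[1L]]$hap0, "001")
  expect_equal(b[[1L]]$hap1, "110")

  m3 <- rbind(m, r3 = c(0L, 1L, NA))
  b3 <- phase_wmec(as_allele_matrix(m3))
  expect_equal(b3[[1L]]$mec, brute_mec(m3))
  expect_equal(b3[[1L]]$mec, 1)
  expect_equal(b3[[1L]]$hap0, "001")

  # disjoint site sets with no spanning read give two blocks
  md <- rbind(r1 = c(0L, 1L, NA, NA), r2 = c(NA, NA, 0L, 1L))
  expect_length(phase_wmec(as_allele_matrix(md)), 2L)
})

test_that("exact DP equals brute-force MEC on 200 random instances", {
  with_seed(55L, {
    for (i in 1:200) {
      nr <- sample(2:10, 1L)
      nc <- sample(2:5, 1L)
      m <- matrix(NA_integer_, nr, nc,
                  dimnames = list(sprintf("r%02d", 1:nr), NULL))
      for (r in 1:nr) {
        a <- sort(sample.int(nc, sample(2:nc, 1L)))
        span <- a[1L]:a[length(a)]           # contiguous coverage
        m[r, span] <- sample(0:1, length(span), replace = TRUE)
      }
      keep <- colSums(!is.na(m)) > 0L
      m <- m[, keep, drop = FALSE]
      if (ncol(m) == 0L) next
      blocks <- phase_wmec(as_allele_matrix(m))
      expect_equal(sum(vapply(blocks, `[[`, numeric(1L), "mec")),
                   brute_mec(m))
    }
  })
})

test_that("phasing is invariant under read permutation up to a global flip", {
  with_seed(66L, {
    truth <- sample(0:1, 12L, replace = TRUE)
    m <- matrix(NA_integer_, 8L, 12L,
                dimnames = list(sprintf("r%d", 1:8), NULL))
    for (r in 1:8) {
      s <- sample.int(7L, 1L)
      cols <- s:(s + 5L)
      hap <- sample(0:1, 1L)
      m[r, cols] <- if (hap == 0L) truth[cols] else 1L - truth[cols]
    }
    b1 <- phase_wmec(as_allele_matrix(m))[[1L]]
    perm <- sample.int(8L)
    b2 <- phase_wmec(as_allele_matrix(m[perm, , drop = FALSE]))[[1L]]
    expect_equal(b1$mec, b2$mec)
    expect_true(b2$hap0 == b1$hap0 || b2$hap0 == b1$hap1)
  })
})

test_that("full-region phasing recovers the planted haplotypes in one block", {
  d <- make_diploid_region(100000L, 0.001, seed = 5L)
  sim <- simulate_long_reads(list(d$hap1, d$hap2), depth = 30L,
                             mean_len = 20000L, error_rate = 0, seed = 6L)
  sites <- pileup_het_snps(sim$reads, sim$paf, d$reference)
  mat <- read_allele_matrix(sim$reads, sim$paf, sites)
  blocks <- phase_wmec(mat)
  expect_length(blocks, 1L)
  truth0 <- strrep("0", nrow(sites))   # haplotype 1 carries the ref allele
  expect_true(blocks[[1L]]$hap0 == truth0 || blocks[[1L]]$hap1 == truth0)
  expect_equal(blocks[[1L]]$mec, 0)

  parts <- partition_reads(mat, blocks)
  tru <- sim$paf$hap[match(parts$read, sim$paf$qname)]
  acc <- mean((parts$hap + 1L) == tru, na.rm = TRUE)
  expect_equal(max(acc, 1 - acc), 1)

  # tie reads stay unassigned
  tie <- as_allele_matrix(rbind(a = c(0L, 0L), b = c(1L, 1L),
                                t = c(0L, 1L)))
  bt <- phase_wmec(tie)
  pt <- partition_reads(tie, bt)
  expect_true(is.na(pt$hap[pt$read == "t"]))
})

test_that("haplotype consensus reproduces the truth and falls back to reference", {
  d <- make_diploid_region(50000L, 0.001, seed = 9L)
  sim <- simulate_long_reads(list(d$hap1, d$hap2), depth = 30L,
                             mean_len = 10000L, error_rate = 0.02, seed = 8L)
  sites <- pileup_het_snps(sim$reads, sim$paf, d$reference)
  mat <- read_allele_matrix(sim$reads, sim$paf, sites)
  blocks <- phase_wmec(mat)
  parts <- partition_reads(mat, blocks)
  acc <- mean((parts$hap + 1L) == sim$paf$hap[match(parts$read, sim$paf$qname)],
              na.rm = TRUE)
  acc <- max(acc, 1 - acc)
  expect_gte(acc, 0.95)
  side0 <- parts$read[!is.na(parts$hap) & parts$hap == 0L]
  cons <- haplotype_consensus(sim$reads, sim$paf, side0, d$reference)
  c1 <- strsplit(cons$seq, "")[[1L]]
  h <- strsplit(d$hap1$seq, "")[[1L]]
  h2 <- strsplit(d$hap2$seq, "")[[1L]]
  err <- min(mean(c1 != h), mean(c1 != h2))
  expect_lte(err, 0.001)                      # >= 99.9% identity

  none <- haplotype_consensus(sim$reads, sim$paf, character(0), d$reference)
  expect_identical(none$seq, d$reference$seq)
})

test_that("MHC validation counts per-haplotig gene loci backed by transcripts", {
  gene1 <- rand_seq(900L, 81L)
  gene2 <- rand_seq(900L, 82L)
  pad <- function(n, s) rand_seq(n, s)
  hap1 <- seq_records("hap1", paste0(pad(3000L, 83L), gene1, pad(2000L, 84L),
                                     gene2, pad(2500L, 85L), gene1,
                                     pad(1500L, 86L), gene2, pad(3000L, 87L)))
  hap2 <- seq_records("hap2", paste0(pad(3000L, 88L), gene1, pad(2000L, 89L),
                                     gene2, pad(3000L, 90L)))
  alleles <- seq_records(c("DQB_01", "DQA_01"), c(gene1, gene2))
  txs <- seq_records(paste0("t", 1:6),
                     c(gene1, gene1, gene2, gene2, gene1, gene2))
  res <- validate_mhc_genes(alleles, rbind(hap1, hap2), txs)
  counts <- table(res$haplotig[res$validated], res$gene[res$validated])
  expect_equal(unname(counts["hap1", "DQB"]), 2L)
  expect_equal(unname(counts["hap2", "DQB"]), 1L)
  expect_equal(unname(counts["hap1", "DQA"]), 2L)

  # a transcript at ~90% identity is not credible at the 95% rule
  tx_bad <- seq_records("bad", with_seed(91L,
    mutate_positions_for_test(gene1, sample.int(900L, 90L))))
  res_b <- validate_mhc_genes(alleles, rbind(hap1, hap2), tx_bad)
  expect_true(all(res_b$n_transcripts == 0L))

  # a single credible transcript does not validate a locus
  res_1 <- validate_mhc_genes(seq_records("DQB_01", gene1), hap2,
                              seq_records("t1", gene1))
  expect_false(any(res_1$validated))
  expect_equal(res_1$n_transcripts, 1L)

  expect_error(validate_mhc_genes(alleles, hap1[0, ], txs),
               class = "imm_validation_error")
})
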