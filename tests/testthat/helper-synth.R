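# Shared fixtures and independent oracles, all generated in code.

rand_seq <- function(n, seed) with_seed(seed, random_dna(n))

rand_records <- function(n, len_range, seed, prefix = "s") {
  with_seed(seed, {
    lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
    seq_records(sprintf("%s%03d", prefix, seq_len(n)),
                vapply(lens, function(l) random_dna(l), character(1L)))
  })
}

# brute-force N50: largest observed length L whose >=L sequences still
# cover half the assembly, scanned directly from the definition
brute_n50 <- function(lengths) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# brute-force weighted MEC over all read bipartitions
brute_mec <- function(m, w = NULL) {
  if (is.null(w)) w <- m * 0 + 1
  nr <- nrow(m)
  best <- Inf
  for (msk in 0:(2^(nr - 1L) - 1L)) {          # fix read 1 on side 0
    side <- c(0L, as.integer(intToBits(msk))[seq_len(nr - 1L)])
    cost <- 0
    for (j in seq_len(ncol(m))) {
      act <- which(!is.na(m[, j]))
      if (length(act) == 0L) next
      s0 <- act[side[act] == 0L]; s1 <- act[side[act] == 1L]
      c_a0 <- sum(w[s0, j] * (m[s0, j] != 0L)) + sum(w[s1, j] * (m[s1, j] != 1L))
      c_a1 <- sum(w[s0, j] * (m[s0, j] != 1L)) + sum(w[s1, j] * (m[s1, j] != 0L))
      cost <- cost + min(c_a0, c_a1)
    }
    if (cost < best) best <- cost
  }
  best
}

# wrap a raw allele matrix as the structure phase_wmec() expects
as_allele_matrix <- function(m, w = NULL, pos = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%02d", seq_len(nrow(m)))
  structure(list(m = m, w = if (is.null(w)) m * 0 + 1 else w,
                 pos = pos %||% (seq_len(ncol(m)) * 100L), reads = rownames(m)),
            class = "allele_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mutate_positions_for_test <- function(seq, positions)
  immloci:::mutate_positions(seq, positions)

# a small defect-free locus with its annotation inputs
make_test_locus <- function(locus = "TRB", n_v = 6L, n_j = 4L, n_c = 1L,
                            seed = 1L, strand = "+", cassette = NULL,
                            defect_rates = c(stop_codon = 0, frameshift = 0,
                                             rss_mutation = 0)) {
  spec <- locus_spec(locus, n_v = n_v, n_j = n_j, n_c = n_c,
                     cassette = cassette, defect_rates = defect_rates,
                     strand = strand)
  lib <- make_segment_library(spec, seed)
  pl <- plant_locus(lib, spec, seed + 1000L)
  list(spec = spec, lib = lib, chromosome = pl$chromosome, truth = pl$truth)
}

expect_same_segments <- function(ann, truth) {
  key <- function(d) paste(d$seg_type, d$start, d$end)
  expect_setequal(key(ann), key(truth))
  m <- merge(as.data.frame(ann), truth, by = c("seg_type", "start", "end"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$functionality.x, m$functionality.y)
}
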