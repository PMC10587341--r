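# V(D)J assignment, CDR3 extraction, usage and CDRH3 profiles.

make_rep_sim <- function(n = 150L, seed = 9L, n_v = 8L, n_d = 3L, n_j = 4L) {
  spec <- locus_spec("IGH", n_v = n_v, n_d = n_d, n_j = n_j, n_c = 1L)
  lib <- make_segment_library(spec, seed)
  vn <- lib$name[lib$seg_type == "V"]
  jn <- lib$name[lib$seg_type == "J"]
  w <- list(v = setNames(rep(1 / n_v, n_v), vn),
            j = setNames(rep(1 / n_j, n_j), jn))
  sim <- simulate_transcripts(lib, w, junction_model(), n = n, seed = seed + 1L)
  list(lib = lib, sim = sim)
}

test_that("simulated transcripts are assigned their true segments", {
  x <- make_rep_sim(n = 120L, seed = 9L)
  ann <- annotate_repertoire(x$sim$transcripts, x$lib)
  tr <- x$sim$truth
  expect_true(all(ann$assigned))
  expect_identical(ann$v_call, tr$v_call)
  expect_identical(ann$j_call, tr$j_call)
  expect_identical(ann$c_call, tr$c_call)
  expect_gte(mean(ann$d_call == tr$d_call, na.rm = TRUE), 0.99)
  expect_identical(ann$cdr3_nt, tr$junction)
  expect_identical(ann$productive, tr$productive)
  # locus consistency invariant
  expect_true(all(ann$locus == "IGH"))
})

test_that("pure random sequence stays unassigned", {
  x <- make_rep_sim(n = 5L, seed = 11L)
  rnd <- rand_records(10L, c(500L, 800L), seed = 12L, prefix = "rnd")
  ann <- assign_vdj(rnd, x$lib)
  expect_false(any(ann$assigned))
})

test_that("assignment is invariant to UTR-like flanks", {
  x <- make_rep_sim(n = 40L, seed = 13L)
  base <- annotate_repertoire(x$sim$transcripts, x$lib)
  flanked <- x$sim$transcripts
  with_seed(14L, {
    flanked$seq <- paste0(vapply(seq_len(nrow(flanked)), function(i)
      random_dna(sample(0:200, 1L)), character(1L)),
      flanked$seq,
      vapply(seq_len(nrow(flanked)), function(i)
        random_dna(sample(0:200, 1L)), character(1L)))
  })
  ann <- annotate_repertoire(flanked, x$lib)
  expect_identical(ann$v_call, base$v_call)
  expect_identical(ann$j_call, base$j_call)
  expect_identical(ann$cdr3_nt, base$cdr3_nt)
})

test_that("CDR3 rules: frame, motif requirement", {
  x <- make_rep_sim(n = 30L, seed = 15L)
  lib <- x$lib
  w <- list(v = setNames(c(1, rep(0, 7L)), lib$name[lib$seg_type == "V"]),
            j = setNames(c(1, rep(0, 3L)), lib$name[lib$seg_type == "J"]))
  # zero trimming, no N: CDR3 equals the generator junction verbatim
  sim0 <- simulate_transcripts(lib, w, junction_model(n_max = 0L, trim_max = 0L),
                               n = 10L, seed = 16L)
  ann0 <- annotate_repertoire(sim0$transcripts, lib)
  expect_identical(ann0$cdr3_nt, sim0$truth$junction)

  # force an out-of-frame junction: productive FALSE
  tx <- sim0$transcripts[1L, ]
  v <- lib[lib$name == ann0$v_call[1L], ]
  insert_at <- v$cys_pos + 6L
  tx$seq <- paste0(substr(tx$seq, 1L, insert_at), "G",
                   substr(tx$seq, insert_at + 1L, nchar(tx$seq)))
  annx <- annotate_repertoire(tx, lib)
  expect_false(annx$productive)

  # destroy the J motif: CDR3 undefined
  j <- lib[lib$name == ann0$j_call[1L], ]
  tx2 <- sim0$transcripts[2L, ]
  motif_tx <- regexpr(substr(j$seq, j$motif_pos + 1L, j$motif_pos + 12L),
                      tx2$seq, fixed = TRUE)[1L]
  substr(tx2$seq, motif_tx, motif_tx + 2L) <- "CTT"    # F -> L
  ann2 <- annotate_repertoire(tx2, lib)
  expect_true(is.na(ann2$cdr3_nt))
  expect_false(ann2$productive)
})

test_that("usage profiles count combinations and conserve totals", {
  x <- make_rep_sim(n = 100L, seed = 17L)
  lib <- x$lib
  vn <- lib$name[lib$seg_type == "V"]
  jn <- lib$name[lib$seg_type == "J"]
  w <- list(v = setNames(c(1, rep(0, length(vn) - 1L)), vn),
            j = setNames(c(1, rep(0, length(jn) - 1L)), jn))
  sim <- simulate_transcripts(lib, w, junction_model(), n = 100L, seed = 18L)
  ann <- annotate_repertoire(sim$transcripts, lib)
  up <- usage_profile(ann, "IGH")
  expect_equal(up$total, 100L)
  vj <- aggregate(n ~ v_call + j_call, up$counts, sum)
  expect_equal(nrow(unique(up$counts[c("v_call", "j_call")])), 1L)
  expect_equal(sum(up$counts$n), 100L)
  # link conservation out of V nodes
  v_out <- up$links[up$links$source %in% vn, ]
  expect_equal(sum(v_out$value), 100L)
})

test_that("ultralong CDRH3 flags recover the planted V/D selectivity", {
  spec <- locus_spec("IGH", n_v = 6L, n_d = 3L, n_j = 3L, n_c = 1L)
  lib <- make_segment_library(spec, 19L)
  # add one long D (ultralong CDRH3 donor)
  longd <- lib[lib$seg_type == "D", ][1L, ]
  longd$name <- "IGHD8"
  # T-free alphabet: stop-free in every reading frame, like a productive
  # ultralong donor
  longd$seq <- with_seed(20L, paste(sample(c("A", "C", "G"), 150L,
                                           replace = TRUE), collapse = ""))
  lib2 <- rbind(lib, longd)
  class(lib2) <- class(lib)
  vn <- lib2$name[lib2$seg_type == "V"]
  jn <- lib2$name[lib2$seg_type == "J"]
  unif <- list(v = setNames(rep(1 / 6, 6L), vn),
               j = setNames(rep(1 / 3, 3L), jn),
               d = setNames(c(rep(0.5, 2L), 0, 0), c(lib$name[lib$seg_type == "D"][1:2],
                                                     lib$name[lib$seg_type == "D"][3L],
                                                     "IGHD8")))
  point <- list(v = setNames(c(1, rep(0, 5L)), vn),
                j = setNames(rep(1 / 3, 3L), jn),
                d = setNames(c(0, 0, 0, 1), names(unif$d)))
  simA <- simulate_transcripts(lib2, unif, junction_model(), n = 90L, seed = 21L)
  simB <- simulate_transcripts(lib2, point, junction_model(), n = 10L, seed = 22L)
  simB$transcripts$id <- sub("^tx", "ux", simB$transcripts$id)
  txs <- rbind(simA$transcripts, simB$transcripts)
  ann <- annotate_repertoire(txs, lib2)
  prof <- cdrh3_profile(ann, ultralong_aa_threshold = 40L)
  expect_equal(sum(prof$histogram$count),
               sum(ann$productive & !is.na(ann$cdr3_aa)))
  if (nrow(prof$ultralong) > 0L) {
    expect_true(all(prof$ultralong$v_call == vn[1L]))
    expect_true(all(prof$ultralong$d_call == "IGHD8"))
  }
  expect_gte(nrow(prof$ultralong), 5L)
  # a threshold above the longest planted junction flags nothing
  prof_hi <- cdrh3_profile(ann, ultralong_aa_threshold = 200L)
  expect_equal(nrow(prof_hi$ultralong), 0L)
})
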