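# Segment finding, RSS detection, functionality classification and
# locus-organization formulas.

test_that("defect-free planted loci are recovered exactly", {
  tl <- make_test_locus("TRB", n_v = 10L, n_j = 6L, n_c = 1L, seed = 1L)
  ann <- annotate_locus(tl$chromosome, tl$lib)
  expect_equal(nrow(ann), 17L)
  expect_same_segments(ann, tl$truth)
  expect_true(all(ann$functionality == "F"))
})

test_that("near-duplicate library entries collapse to one reported segment", {
  tl <- make_test_locus("IGK", n_v = 3L, n_j = 2L, n_c = 1L, seed = 3L)
  lib <- tl$lib
  # add a 99%-similar twin of V1 that is not planted
  v1 <- lib[lib$name == "IGKV1", ]
  twin <- v1
  twin$name <- "IGKV9"
  twin$seq <- with_seed(4L, mutate_positions_for_test(v1$seq, sample.int(nchar(v1$seq), 3L)))
  lib2 <- rbind(lib, twin)
  class(lib2) <- class(lib)
  segs <- find_segments(tl$chromosome, lib2)
  # the overlap merge keeps the best-scoring (exact) entry only
  expect_equal(sum(segs$seg_type == "V"), 3L)
  expect_false("IGKV9" %in% segs$name)
})

test_that("reverse-strand loci annotate identically in locus orientation", {
  fwd <- make_test_locus("TRG", n_v = 5L, n_j = 3L, n_c = 1L, seed = 5L)
  ann_f <- annotate_locus(fwd$chromosome, fwd$lib)
  rc <- fwd$chromosome
  rc$seq <- revcomp(rc$seq)
  ann_r <- annotate_locus(rc, fwd$lib)
  expect_equal(nrow(ann_r), nrow(ann_f))
  expect_true(all(ann_r$strand == "-"))
  expect_identical(ann_r$name, ann_f$name)          # locus-oriented order
  expect_identical(ann_r$seg_type, ann_f$seg_type)
  expect_identical(build_locus_structure(ann_r)$formula,
                   build_locus_structure(ann_f)$formula)
})

test_that("RSS detection scores consensus-match fractions", {
  win <- paste0("CACAGTG", rand_seq(23L, 11L), "ACAAAAACC", rand_seq(21L, 12L))
  best <- immloci:::score_rss_window(win)
  expect_equal(best$score, 1.0)
  expect_equal(best$spacer_len, 23L)

  win2 <- paste0("CTCAGTG", rand_seq(23L, 13L), "ACAAAAACC", rand_seq(21L, 14L))
  best2 <- immloci:::score_rss_window(win2)
  expect_equal(best2$score, (6 / 7 + 1) / 2, tolerance = 1e-9)
  expect_gte(best2$score, 0.7)

  # false-positive rate on random flanks
  fp <- with_seed(11L, {
    sum(vapply(1:100, function(i) {
      b <- immloci:::score_rss_window(random_dna(60L))
      !is.null(b) && b$score >= 0.7
    }, logical(1L)))
  })
  expect_lte(fp, 5L)
})

test_that("the functionality cascade applies its rules in order", {
  spec <- locus_spec("IGH", n_v = 6L, n_j = 2L, n_c = 1L,
                     defect_rates = c(stop_codon = 1))
  lib <- make_segment_library(spec, 21L)
  pl <- plant_locus(lib, spec, 22L)
  ann <- annotate_locus(pl$chromosome, lib)
  vs <- ann[ann$seg_type == "V", ]
  expect_true(all(vs$functionality == "P"))
  expect_true(all(grepl("internal_stop", vs$defects)))

  spec2 <- locus_spec("IGH", n_v = 6L, n_j = 2L, n_c = 1L,
                      defect_rates = c(rss_mutation = 1))
  lib2 <- make_segment_library(spec2, 23L)
  pl2 <- plant_locus(lib2, spec2, 24L)
  ann2 <- annotate_locus(pl2$chromosome, lib2)
  vs2 <- ann2[ann2$seg_type == "V", ]
  expect_true(all(vs2$functionality == "ORF"))
  expect_true(all(grepl("bad_rss", vs2$defects)))

  spec3 <- locus_spec("IGH", n_v = 4L, n_j = 2L, n_c = 1L,
                      defect_rates = c(frameshift = 1))
  lib3 <- make_segment_library(spec3, 25L)
  pl3 <- plant_locus(lib3, spec3, 26L)
  ann3 <- annotate_locus(pl3$chromosome, lib3)
  vs3 <- ann3[ann3$seg_type == "V", ]
  expect_true(all(vs3$functionality == "P"))
  expect_true(all(grepl("frameshift", vs3$defects)))
})

test_that("formulas compress runs and cassettes as printed in the field", {
  seg <- function(locus, types) data.frame(
    name = paste0(locus, types, seq_along(types)), locus = locus,
    seg_type = types, stringsAsFactors = FALSE)
  trb <- seg("TRB", c("D", rep("J", 6L), "C",
                      "D", rep("J", 7L), "C",
                      "D", rep("J", 6L), "C"))
  expect_equal(build_locus_structure(trb)$formula, "[TRBD-(TRBJ)6/7-TRBC]3")

  igl <- seg("IGL", rep(c("J", "C"), 6L))
  expect_equal(build_locus_structure(igl)$formula, "(IGLJ-IGLC)6")

  one <- seg("IGH", "V")
  expect_equal(build_locus_structure(one)$formula, "IGHV")

  expect_equal(build_locus_structure(one[0, ])$formula, "")
})

test_that("expand(compress(x)) = x for generated structures and printed patterns", {
  expect_equal(expand_formula("[TRBD-(TRBJ)6/7-TRBC]3"),
               c("TRBD", rep("TRBJ", 6L), "TRBC",
                 "TRBD", rep("TRBJ", 7L), "TRBC",
                 "TRBD", rep("TRBJ", 6L), "TRBC"))
  expect_equal(expand_formula("(IGLJ-IGLC)6"), rep(c("IGLJ", "IGLC"), 6L))

  with_seed(31L, {
    for (i in 1:60) {
      types <- character(0)
      # random blocks plus an optional cassette with one varying element
      types <- c(types, rep("V", sample(0:30, 1L)))
      if (runif(1L) < 0.7) {
        copies <- sample(2:4, 1L)
        jc <- sample(2:7, copies, replace = runif(1L) < 0.5)
        for (ci in seq_len(copies)) types <- c(types, "D", rep("J", jc[ci]), "C")
      } else {
        types <- c(types, rep("J", sample(1:8, 1L)), rep("C", sample(1:2, 1L)))
      }
      if (length(types) == 0L) next
      seg <- data.frame(name = "x", locus = "TRB", seg_type = types,
                        stringsAsFactors = FALSE)
      st <- build_locus_structure(seg)
      expect_equal(expand_formula(st$formula), paste0("TRB", types),
                   info = st$formula)
    }
  })
})

test_that("locus summaries partition exactly into F/P/ORF", {
  tl1 <- make_test_locus("IGK", n_v = 4L, n_j = 2L, n_c = 1L, seed = 41L)
  tl2 <- make_test_locus("TRD", n_v = 3L, n_j = 2L, n_c = 1L, seed = 42L)
  s1 <- build_locus_structure(annotate_locus(tl1$chromosome, tl1$lib))
  s2 <- build_locus_structure(annotate_locus(tl2$chromosome, tl2$lib))
  agg <- summarize_loci(list(s1, s2))
  expect_true(all(agg$cells$total == agg$cells$F + agg$cells$P + agg$cells$ORF))
  expect_equal(sum(agg$type_totals$total), nrow(tl1$truth) + nrow(tl2$truth))
  expect_error(summarize_loci(list(s1, s1)), class = "imm_validation_error")

  empty <- aggregate_locus_counts(data.frame())
  expect_equal(unname(empty$grand["total"]), 0L)
})
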