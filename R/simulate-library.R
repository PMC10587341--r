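# Synthetic gene-segment reference libraries.  Entries mimic IMGT-style
# V/D/J/C segments: V entries are ATG-initiated open reading frames of
# 288 +/- 30 bp with conserved cysteines at IMGT-like codon positions and no
# internal stop; J entries carry the F/W-G-X-G motif at a recorded offset.

STOP_CODONS <- c("TAA", "TAG", "TGA")
CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

sample_codons <- function(n) paste(sample(CODONS, n, replace = TRUE), collapse = "")

#' Specification of one synthetic immune locus
#'
#' @param locus one of IGH, IGK, IGL, TRA, TRB, TRD, TRG.
#' @param n_v,n_d,n_j,n_c segment counts (D only meaningful for IGH/TRB/TRD).
#' @param cassette optional tandem D-J-C (or V-J-C) cassette description:
#'   a list with `types` (character vector of segment types forming the
#'   repeat unit) and `counts` (integer matrix, one row per cassette copy,
#'   one column per unit element). When given, the cassette replaces the
#'   plain D/J/C blocks.
#' @param defect_rates named fractions for `stop_codon`, `frameshift`
#'   (V only) and `rss_mutation` (V/D/J) per segment.
#' @param spacing mean inter-segment distance in bp.
#' @param strand locus strand on the emitted chromosome.
#' @param max_len optional chromosome length budget (parameter error when
#'   exceeded).
#' @return object of class `locus_spec`.
#' @export
locus_spec <- function(locus, n_v = 10L, n_d = 0L, n_j = 4L, n_c = 1L,
                       cassette = NULL,
                       defect_rates = c(stop_codon = 0, frameshift = 0,
                                        rss_mutation = 0),
                       spacing = 1500L, strand = "+", max_len = NULL) {
  locus <- match.arg(locus, IMM_LOCI)
  dr <- c(stop_codon = 0, frameshift = 0, rss_mutation = 0)
  dr[names(defect_rates)] <- defect_rates
  if (any(dr < 0 | dr > 1)) imm_parameter_error("defect rates must lie in [0,1]")
  if (!is.null(cassette)) {
    if (!is.matrix(cassette$counts) || nrow(cassette$counts) < 1L)
      imm_parameter_error("cassette$counts must be a matrix with >= 1 row")
    if (ncol(cassette$counts) != length(cassette$types))
      imm_parameter_error("cassette counts/types mismatch")
  }
  structure(list(locus = locus, n_v = n_v, n_d = n_d, n_j = n_j, n_c = n_c,
                 cassette = cassette, defect_rates = dr,
                 spacing = spacing, strand = strand, max_len = max_len),
            class = "locus_spec")
}

#' Generate a synthetic segment library for a locus
#'
#' Deterministic per (spec, seed). V entries: ATG start, no internal stop in
#' frame 0, first-CYS near codon 22 and second-CYS three codons from the end
#' (offset recorded in `cys_pos`, 0-based nt). J entries embed a
#' F/W-G-X-G-encoding motif at `motif_pos`.
#'
#' @param spec a [locus_spec()].
#' @param seed integer seed.
#' @return data.frame of class `segment_library` with columns `name`,
#'   `locus`, `seg_type`, `subgroup`, `seq`, `cys_pos`, `motif_pos`.
#' @export
make_segment_library <- function(spec, seed) {
  if (spec$n_v < 1L && spec$n_v + spec$n_j + spec$n_c + spec$n_d < 1L)
    imm_parameter_error("library needs at least one segment")
  loc <- spec$locus
  # cassettes may reference more segments per type than the plain counts
  need <- c(V = spec$n_v, D = spec$n_d, J = spec$n_j, C = spec$n_c)
  if (!is.null(spec$cassette)) {
    for (ti in seq_along(spec$cassette$types)) {
      ty <- spec$cassette$types[ti]
      need[ty] <- max(need[ty], max(spec$cassette$counts[, ti]))
    }
  }
  with_seed(seed, {
    rows <- list()
    mk <- function(name, type, subgroup, seq, cys = NA_integer_,
                   motif = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = name, locus = loc, seg_type = type, subgroup = subgroup,
        seq = seq, cys_pos = cys, motif_pos = motif, stringsAsFactors = FALSE)
    }
    for (i in seq_len(need[["V"]])) {
      ncod <- (288L + sample(-30:30, 1L)) %/% 3L
      cys2 <- ncod - 3L                      # 1-based codon index of 2nd-CYS
      codons <- sample(CODONS, ncod, replace = TRUE)
      codons[1L] <- "ATG"
      codons[22L] <- "TGT"                   # 1st-CYS
      codons[cys2] <- sample(c("TGT", "TGC"), 1L)
      mk(sprintf("%sV%d", loc, i), "V",
         sprintf("%sV%d", loc, (i %% 3L) + 1L),
         paste(codons, collapse = ""), cys = (cys2 - 1L) * 3L)
    }
    for (i in seq_len(need[["D"]])) {
      # >= 16 bp so seed-based mapping (k = 13) can anchor every D
      mk(sprintf("%sD%d", loc, i), "D", sprintf("%sD", loc),
         random_dna(sample(16:32, 1L), gc = 0.5))
    }
    for (i in seq_len(need[["J"]])) {
      pre <- sample(c(3L, 6L, 9L), 1L)
      fw <- sample(c("TTT", "TTC", "TGG"), 1L)
      g <- function() sample(c("GGA", "GGT", "GGC", "GGG"), 1L)
      motif <- paste0(fw, g(), sample_codons(1L), g())
      tail_c <- sample_codons(sample(3:5, 1L))
      mk(sprintf("%sJ%d", loc, i), "J", sprintf("%sJ", loc),
         paste0(sample_codons(pre %/% 3L), motif, tail_c), motif = pre)
    }
    for (i in seq_len(need[["C"]])) {
      mk(sprintf("%sC%d", loc, i), "C", sprintf("%sC", loc),
         random_dna(sample(300:330, 1L), gc = 0.5))
    }
    lib <- do.call(rbind, rows)
    class(lib) <- c("segment_library", "data.frame")
    lib
  })
}

#' Write a segment library as FASTA plus metadata TSV
#' @param lib segment library data.frame.
#' @param fasta_path,meta_path output files.
#' @return invisibly, the two paths.
#' @export
write_segment_library <- function(lib, fasta_path, meta_path) {
  write_fasta(seq_records(lib$name, lib$seq), fasta_path)
  write_tsv(lib[, c("name", "locus", "seg_type", "subgroup", "cys_pos",
                    "motif_pos")], meta_path)
  invisible(c(fasta_path, meta_path))
}

#' Read a segment library from FASTA plus metadata TSV
#' @param fasta_path,meta_path input files.
#' @return `segment_library` data.frame.
#' @export
read_segment_library <- function(fasta_path, meta_path) {
  fa <- read_fasta(fasta_path)
  meta <- read_tsv(meta_path)
  if (anyDuplicated(paste(meta$locus, meta$name)))
    imm_validation_error("duplicate (locus, name) in segment library")
  i <- match(meta$name, fa$id)
  if (anyNA(i)) imm_validation_error("library metadata references missing sequence")
  validate_dna_alphabet(fa$seq[i], meta$name, allow_n = FALSE)
  pref_type <- sub("^(IGH|IGK|IGL|TRA|TRB|TRD|TRG)([VDJC]).*$", "\\2", meta$name)
  if (any(pref_type != meta$seg_type))
    imm_validation_error("segment type inconsistent with name prefix")
  lib <- cbind(meta[, c("name", "locus", "seg_type", "subgroup")],
               seq = fa$seq[i],
               meta[, c("cys_pos", "motif_pos"), drop = FALSE])
  class(lib) <- c("segment_library", "data.frame")
  lib
}
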