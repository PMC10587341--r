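# Planting loci on synthetic chromosomes.  Segments are embedded in order
# with random spacer DNA; every V carries a 3' RSS, every J a 5' RSS and
# every D both, following the 12/23 rule (heavy-type loci use a 23-bp V
# spacer, light-type loci 12 bp).  Injected defects are recorded as truth.

HEAVY_LOCI <- c("IGH", "TRB", "TRD")

v_spacer_len <- function(locus) if (locus %in% HEAVY_LOCI) 23L else 12L

rss_string <- function(spacer_len) {
  paste0(RSS_HEPTAMER, random_dna(spacer_len, gc = 0.5), RSS_NONAMER)
}

mutate_rss <- function(rss, spacer_len) {
  # degrade heptamer and nonamer well below the 0.7 consensus-score threshold
  hp <- sample(7L, 3L)
  np <- 7L + spacer_len + sample(9L, 4L)
  mutate_positions(rss, c(hp, np))
}

#' Plant a locus on a synthetic chromosome
#'
#' Segments from the library are embedded in order (V block, then either the
#' cassette repeats or plain D/J/C blocks) separated by random spacer DNA.
#' Defects are injected per `spec$defect_rates` and the resulting truth
#' functionality recorded: stop codon or frameshift yields P, an RSS mutation
#' yields ORF. Reverse-strand loci are emitted reverse-complemented with
#' coordinates transformed accordingly.
#'
#' @param library a [make_segment_library()] data.frame.
#' @param spec the matching [locus_spec()].
#' @param seed integer seed.
#' @return list with `chromosome` (record data.frame) and `truth`
#'   (data.frame: name, locus, seg_type, seqid, start, end, strand,
#'   functionality, defects).
#' @export
plant_locus <- function(library, spec, seed) {
  if (!all(library$locus == spec$locus))
    imm_parameter_error("library locus does not match spec")
  loc <- spec$locus
  vsp <- v_spacer_len(loc)
  jsp <- if (vsp == 23L) 12L else 23L
  with_seed(seed, {
    parts <- character(0)
    at <- 0L                      # running chromosome offset
    truth <- list()
    push <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      at <<- at + nchar(s)
    }
    spacer <- function() push(random_dna(max(50L, as.integer(
      runif(1L, 0.5, 1.5) * spec$spacing))))
    lib_of <- function(ty) library[library$seg_type == ty, , drop = FALSE]

    place_segment <- function(entry) {
      ty <- entry$seg_type
      dr <- spec$defect_rates
      defects <- character(0)
      seq <- entry$seq
      if (ty == "V") {
        if (runif(1L) < dr[["stop_codon"]]) {
          ncod <- nchar(seq) %/% 3L
          ci <- sample(setdiff(5:(ncod - 5L), c(22L, ncod - 3L)), 1L)
          substr(seq, (ci - 1L) * 3L + 1L, ci * 3L) <- "TAA"
          defects <- c(defects, "internal_stop")
        }
        if (runif(1L) < dr[["frameshift"]]) {
          p <- sample(seq(10L, nchar(seq) - 10L), 1L)
          seq <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + 1L, nchar(seq)))
          defects <- c(defects, "frameshift")
        }
      }
      rss_bad <- ty %in% c("V", "D", "J") && runif(1L) < dr[["rss_mutation"]]
      if (rss_bad) defects <- c(defects, "bad_rss")
      func <- if (any(defects %in% c("internal_stop", "frameshift"))) "P"
              else if (rss_bad) "ORF" else "F"

      degrade <- function(r, sp) if (rss_bad) mutate_rss(r, sp) else r
      if (ty == "J") push(degrade(revcomp(rss_string(jsp)), jsp))
      if (ty == "D") push(degrade(revcomp(rss_string(12L)), 12L))
      start <- at
      push(seq)
      truth[[length(truth) + 1L]] <<- data.frame(
        name = entry$name, locus = loc, seg_type = ty,
        start = start, end = at, functionality = func,
        defects = paste(defects, collapse = ","), stringsAsFactors = FALSE)
      if (ty == "V") push(degrade(rss_string(vsp), vsp))
      if (ty == "D") push(degrade(rss_string(23L), 23L))
      spacer()
    }

    spacer()
    vlib <- lib_of("V")
    for (i in seq_len(spec$n_v)) place_segment(vlib[((i - 1L) %% nrow(vlib)) + 1L, ])
    if (!is.null(spec$cassette)) {
      cs <- spec$cassette
      idx <- setNames(rep(0L, 4L), c("V", "D", "J", "C"))
      for (copy in seq_len(nrow(cs$counts))) {
        for (el in seq_along(cs$types)) {
          ty <- cs$types[el]
          tl <- lib_of(ty)
          for (r in seq_len(cs$counts[copy, el])) {
            idx[ty] <- idx[ty] %% nrow(tl) + 1L
            place_segment(tl[idx[ty], ])
          }
        }
      }
    } else {
      dlib <- lib_of("D"); jlib <- lib_of("J"); clib <- lib_of("C")
      for (i in seq_len(spec$n_d)) place_segment(dlib[((i - 1L) %% max(1L, nrow(dlib))) + 1L, ])
      for (i in seq_len(spec$n_j)) place_segment(jlib[((i - 1L) %% max(1L, nrow(jlib))) + 1L, ])
      for (i in seq_len(spec$n_c)) place_segment(clib[((i - 1L) %% max(1L, nrow(clib))) + 1L, ])
    }

    chrom <- paste(parts, collapse = "")
    L <- nchar(chrom)
    if (!is.null(spec$max_len) && L > spec$max_len)
      imm_parameter_error("locus length %d exceeds budget %d", L, spec$max_len)
    tr <- do.call(rbind, truth)
    tr$seqid <- paste0("chr_", loc)
    tr$strand <- spec$strand
    if (spec$strand == "-") {
      chrom <- revcomp(chrom)
      new_start <- L - tr$end
      tr$end <- L - tr$start
      tr$start <- new_start
    }
    tr <- tr[, c("name", "locus", "seg_type", "seqid", "start", "end",
                 "strand", "functionality", "defects")]
    list(chromosome = seq_records(paste0("chr_", loc), chrom),
         truth = tr)
  })
}

#' Add a telomere array and a satellite-DNA array to a chromosome
#'
#' Appends `(TTAGGG)^units` at the 3' end and plants a satDNA array near the
#' 5' end (after a short random pad). Because the 5' insertion shifts
#' existing coordinates, the applied shift is returned so callers can adjust
#' previously recorded truth.
#'
#' @param chromosome single-record data.frame.
#' @param telomere_units number of TTAGGG copies to append (0 = none).
#' @param satdna_pattern repeat unit for the satDNA array, or `NULL`.
#' @param satdna_copies copy number of the satDNA array.
#' @param seed integer seed.
#' @param pad random padding placed 5' of the satDNA array.
#' @return list: `chromosome`, `telomere` (truth interval or NULL),
#'   `satdna` (truth interval or NULL), `shift` (bp added 5' of the
#'   original sequence).
#' @export
plant_chromosome_ends <- function(chromosome, telomere_units,
                                  satdna_pattern = NULL, satdna_copies = 0L,
                                  seed = 1L, pad = 500L) {
  with_seed(seed, {
    seq <- chromosome$seq[1L]
    shift <- 0L
    sat <- NULL
    if (!is.null(satdna_pattern) && satdna_copies > 0L) {
      head <- paste0(random_dna(pad), strrep(satdna_pattern, satdna_copies))
      sat <- data.frame(seqid = chromosome$id[1L], start = pad,
                        end = pad + nchar(satdna_pattern) * satdna_copies)
      shift <- nchar(head)
      seq <- paste0(head, seq)
    }
    tel <- NULL
    if (telomere_units > 0L) {
      tel <- data.frame(seqid = chromosome$id[1L], start = nchar(seq),
                        end = nchar(seq) + 6L * telomere_units)
      seq <- paste0(seq, strrep(TELOMERE_UNIT, telomere_units))
    }
    out <- chromosome
    out$seq <- seq
    list(chromosome = out, telomere = tel, satdna = sat, shift = shift)
  })
}
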