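# Gene-segment annotation: locate library entries in an assembly, detect
# recombination signal sequences (RSS) and classify functionality with an
# IMGT-style rule cascade:
#   (1) V coding defects (missing ATG, in-frame stop, frameshift)  -> P
#   (2) otherwise missing/degenerate RSS                           -> ORF
#   (3) otherwise                                                  -> F
# D and J segments are assessed on their RSS flanks only; C segments carry
# no RSS and default to F.

#' Locate gene segments in an assembly
#'
#' Every library entry is mapped with [map_query()]; hits with identity >=
#' `min_identity` and query coverage >= `min_coverage` are kept, overlapping
#' hits of the same segment type are merged keeping the best score (ties:
#' smaller start), and the result is ordered along each locus in locus
#' orientation (reverse-strand loci descend in chromosome coordinates).
#'
#' @param assembly record data.frame.
#' @param library segment library.
#' @param min_identity percent identity threshold (inclusive).
#' @param min_coverage percent of the library entry that must align.
#' @param scoring an [align_scoring()].
#' @param k seed k-mer size.
#' @return data.frame of class `gene_segments`: name, locus, seg_type,
#'   seqid, start, end, strand, score, identity, coverage.
#' @export
find_segments <- function(assembly, library, min_identity = 80,
                          min_coverage = 90, scoring = align_scoring(),
                          k = 13L) {
  if (nrow(library) == 0L) imm_parameter_error("empty segment library")
  index <- build_seed_index(assembly, k = k)
  hits <- list()
  for (i in seq_len(nrow(library))) {
    al <- map_query(library[i, c("name", "seq")] |>
                      (\(x) seq_records(x$name, x$seq))(),
                    index, assembly, scoring)
    if (nrow(al) == 0L) next
    al$coverage <- 100 * (al$qend - al$qstart) / al$qlen
    al <- al[al$identity >= min_identity & al$coverage >= min_coverage, ,
             drop = FALSE]
    if (nrow(al) == 0L) next
    al$name <- library$name[i]
    al$locus <- library$locus[i]
    al$seg_type <- library$seg_type[i]
    hits[[length(hits) + 1L]] <- al
  }
  empty <- data.frame(name = character(), locus = character(),
                      seg_type = character(), seqid = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  if (length(hits) == 0L) return(structure(empty, class = c("gene_segments", "data.frame")))
  h <- do.call(rbind, hits)
  h$seqid <- h$tname; h$start <- h$tstart; h$end <- h$tend
  # merge overlapping same-type hits, keeping the best score
  keep <- list()
  for (grp in split(h, list(h$seqid, h$seg_type), drop = TRUE)) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    cl <- cumsum(c(1L, ifelse(grp$start[-1L] >= cummax(grp$end)[-nrow(grp)], 1L, 0L)))
    for (sub in split(grp, cl)) {
      best <- sub[order(-sub$score, sub$start), , drop = FALSE][1L, ]
      keep[[length(keep) + 1L]] <- best
    }
  }
  out <- do.call(rbind, keep)[, c("name", "locus", "seg_type", "seqid",
                                  "start", "end", "strand", "score",
                                  "identity", "coverage")]
  # locus orientation: order by coordinate, reversed for minus-strand loci
  ord <- list()
  for (grp in split(out, list(out$seqid, out$locus), drop = TRUE)) {
    minus <- mean(grp$strand == "-") > 0.5
    ord[[length(ord) + 1L]] <- grp[order(if (minus) -grp$start else grp$start), ]
  }
  out <- do.call(rbind, ord)
  rownames(out) <- NULL
  structure(out, class = c("gene_segments", "data.frame"))
}

# fetch the RSS search window adjacent to a segment, oriented so that a
# canonical RSS reads heptamer-spacer-nonamer from offset 0
rss_window_seq <- function(seq, start, end, strand, side, window) {
  L <- nchar(seq)
  after <- (side == "3p") == (strand == "+")
  if (after) {
    if (end >= L) return(NULL)
    seq_slice(seq, end, min(L, end + window))
  } else {
    if (start <= 0L) return(NULL)
    revcomp(seq_slice(seq, max(0L, start - window), start))
  }
}

score_rss_window <- function(win, spacers = c(12L, 23L), tol = 1L) {
  if (is.null(win) || nchar(win) < 7L + min(spacers) - tol + 9L) return(NULL)
  hept <- strsplit(RSS_HEPTAMER, "")[[1L]]
  nona <- strsplit(RSS_NONAMER, "")[[1L]]
  cand_sp <- sort(unique(as.vector(outer(spacers, -tol:tol, "+"))))
  best <- NULL
  wch <- strsplit(win, "")[[1L]]
  n <- length(wch)
  for (o in 0:(n - 7L)) {
    hs <- sum(wch[(o + 1L):(o + 7L)] == hept) / 7
    for (sp in cand_sp) {
      np <- o + 7L + sp
      if (np + 9L > n) next
      ns <- sum(wch[(np + 1L):(np + 9L)] == nona) / 9
      sc <- (hs + ns) / 2
      pref <- min(abs(sp - spacers))
      if (is.null(best) || sc > best$score ||
          (sc == best$score && (o < best$offset ||
                                (o == best$offset && pref < best$pref)))) {
        best <- list(heptamer = paste(wch[(o + 1L):(o + 7L)], collapse = ""),
                     spacer_len = sp,
                     nonamer = paste(wch[(np + 1L):(np + 9L)], collapse = ""),
                     score = sc, offset = o, pref = pref)
      }
    }
  }
  best
}

#' Detect the recombination signal sequence flanking a segment
#'
#' Searches the relevant flank (3' of V, both flanks of D, 5' of J, in locus
#' orientation) within a 60-bp window, scoring candidate heptamer/nonamer
#' pairs by consensus-match fraction with spacer 12 or 23 +/- `tol`. Returns
#' the best candidate, or `NULL` when the best score falls below
#' `min_score` or the flank is truncated by a contig end.
#'
#' @param assembly record data.frame.
#' @param segment one row of a [find_segments()] result.
#' @param min_score minimum mean consensus-match fraction.
#' @param window flank window size in bp.
#' @param tol spacer-length tolerance.
#' @return list(heptamer, spacer_len, nonamer, score, side) or `NULL`.
#' @export
detect_rss <- function(assembly, segment, min_score = 0.7, window = 60L,
                       tol = 1L) {
  if (!segment$seg_type %in% c("V", "D", "J"))
    imm_parameter_error("RSS detection applies to V, D or J segments")
  seq <- assembly$seq[match(segment$seqid, assembly$id)]
  sides <- switch(segment$seg_type, V = "3p", J = "5p", D = c("5p", "3p"))
  best <- NULL
  for (side in sides) {
    win <- rss_window_seq(seq, segment$start, segment$end, segment$strand,
                          side, window)
    if (is.null(win)) {
      imm_log("warn", "RSS flank of %s truncated by contig end", segment$name)
      next
    }
    cand <- score_rss_window(win, tol = tol)
    if (!is.null(cand)) {
      cand$side <- side
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  best[c("heptamer", "spacer_len", "nonamer", "score", "side")]
}

# per-side RSS scores for a D segment (both flanks must pass)
d_rss_ok <- function(assembly, segment, min_score, window, tol) {
  seq <- assembly$seq[match(segment$seqid, assembly$id)]
  ok <- vapply(c("5p", "3p"), function(side) {
    win <- rss_window_seq(seq, segment$start, segment$end, segment$strand,
                          side, window)
    cand <- if (is.null(win)) NULL else score_rss_window(win, tol = tol)
    !is.null(cand) && cand$score >= min_score
  }, logical(1L))
  all(ok)
}

#' Classify the functionality of a located segment
#'
#' Applies the rule cascade described above against the matching library
#' entry. The segment sequence is read in locus orientation.
#'
#' @param assembly record data.frame.
#' @param segment one row of a [find_segments()] result.
#' @param library segment library (source of the reference entry).
#' @param config configuration list (uses `rss_min_score`, `rss_window`,
#'   `rss_spacer_tol`).
#' @param scoring an [align_scoring()].
#' @return the segment row with `functionality`, `defects` and `rss_score`
#'   columns filled in.
#' @export
classify_functionality <- function(assembly, segment, library,
                                   config = default_config(),
                                   scoring = align_scoring()) {
  seq <- assembly$seq[match(segment$seqid, assembly$id)]
  sseq <- seq_slice(seq, segment$start, segment$end)
  if (segment$strand == "-") sseq <- revcomp(sseq)
  ty <- segment$seg_type
  defects <- character(0)
  rss_score <- NA_real_
  if (ty == "V") {
    if (!startsWith(sseq, "ATG")) defects <- c(defects, "missing_start")
    ref <- library$seq[match(segment$name, library$name)]
    al <- local_align(ref, sseq, scoring)
    ops <- cigar_ops(al$cigar)
    shift <- sum(ops$len[ops$op == "I"]) - sum(ops$len[ops$op == "D"])
    if (shift %% 3L != 0L) defects <- c(defects, "frameshift")
    aa <- translate_dna(sseq)
    if (grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
      defects <- c(defects, "internal_stop")
  }
  if (length(defects) > 0L && ty == "V") {
    func <- "P"
  } else if (ty %in% c("V", "J")) {
    rss <- detect_rss(assembly, segment, min_score = config$rss_min_score,
                      window = config$rss_window, tol = config$rss_spacer_tol)
    if (is.null(rss)) { defects <- c(defects, "bad_rss"); func <- "ORF" }
    else { rss_score <- rss$score; func <- "F" }
  } else if (ty == "D") {
    if (d_rss_ok(assembly, segment, config$rss_min_score, config$rss_window,
                 config$rss_spacer_tol)) func <- "F"
    else { defects <- c(defects, "bad_rss"); func <- "ORF" }
  } else {
    func <- "F"
  }
  segment$functionality <- func
  segment$defects <- paste(defects, collapse = ",")
  segment$rss_score <- rss_score
  segment
}

cigar_ops <- function(cigar) {
  if (!nzchar(cigar)) return(data.frame(len = integer(), op = character()))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Annotate a locus end-to-end
#'
#' [find_segments()] followed by [classify_functionality()] on every hit.
#'
#' @inheritParams find_segments
#' @param config configuration list.
#' @return `gene_segments` data.frame with functionality columns.
#' @export
annotate_locus <- function(assembly, library, config = default_config(),
                           scoring = align_scoring()) {
  segs <- find_segments(assembly, library,
                        min_identity = config$min_identity,
                        min_coverage = config$min_coverage,
                        scoring = scoring, k = config$kmer_size)
  if (nrow(segs) == 0L) return(segs)
  out <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i)
    classify_functionality(assembly, segs[i, ], library, config, scoring)))
  structure(out, class = c("gene_segments", "data.frame"))
}

#' Export annotated segments as GFF3 features
#'
#' @param segments `gene_segments` data.frame.
#' @param source source column value.
#' @return data.frame acceptable to [write_gff3()].
#' @export
segments_to_gff3 <- function(segments, source = "immloci") {
  data.frame(seqid = segments$seqid, source = source,
             type = paste0(segments$seg_type, "_gene_segment"),
             start = segments$start, end = segments$end,
             score = ".", strand = segments$strand, phase = ".",
             attributes = sprintf(
               "ID=%s_%d;Name=%s;functionality=%s;defects=%s;rss_score=%s",
               segments$name, seq_len(nrow(segments)), segments$name,
               segments$functionality %||% ".",
               ifelse(nzchar(segments$defects %||% ""), segments$defects, "none"),
               ifelse(is.na(segments$rss_score %||% NA), ".",
                      sprintf("%.3f", segments$rss_score))),
             stringsAsFactors = FALSE)
}
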