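# Two-assembly comparison: decide which N-gaps of an old assembly are closed
# by a new assembly, and place unplaced scaffolds.  "Within one contig" is
# operationalized as: same target sequence, consistent strand, and
# coordinate-ordered flanks/pieces.

#' Extract the flanking sequences of an assembly gap
#'
#' Fetches up to `flank_len` non-N bases on each side of a maximal N-run,
#' truncating (with a logged warning) at sequence ends or adjacent gaps.
#'
#' @param assembly record data.frame (the old assembly).
#' @param gap one-row data.frame with `seqid`, `start`, `end` (a maximal
#'   N-run).
#' @param flank_len flank length in bp.
#' @return list with `left`/`right` record data.frames (possibly
#'   zero-length sequences when fully truncated).
#' @export
extract_gap_flanks <- function(assembly, gap, flank_len = 10000L) {
  seq <- assembly$seq[match(gap$seqid, assembly$id)]
  L <- nchar(seq)
  runs <- find_n_runs(seq)
  left_lim <- max(c(0L, runs$end[runs$end <= gap$start]))
  right_lim <- min(c(L, runs$start[runs$start >= gap$end]))
  ls <- max(left_lim, gap$start - flank_len)
  re <- min(right_lim, gap$end + flank_len)
  if (gap$start - ls < flank_len || re - gap$end < flank_len)
    imm_log("warn", "gap %s:%d-%d flank truncated", gap$seqid, gap$start, gap$end)
  mk <- function(suffix, s, len) {
    r <- seq_records(sprintf("%s_gap%d_%s", gap$seqid, gap$start, suffix),
                     if (nzchar(s)) s else "N")  # placeholder, len carries truth
    r$len <- len
    r
  }
  list(left = mk("L", if (gap$start > ls) seq_slice(seq, ls, gap$start) else "",
                 gap$start - ls),
       right = mk("R", if (re > gap$end) seq_slice(seq, gap$end, re) else "",
                  re - gap$end))
}

# top-scoring alignment of a flank/piece; chance micro-matches are rejected
# by requiring half the query to align
best_hit <- function(query, index, targets, scoring, min_identity,
                     min_coverage = 50) {
  if (nchar(query$seq[1L]) < 30L || query$seq[1L] == "N") return(NULL)
  al <- map_query(query, index, targets, scoring)
  if (nrow(al) == 0L) return(NULL)
  al <- al[1L, ]
  if (al$identity <= min_identity) return(NULL)
  if (100 * (al$qend - al$qstart) / al$qlen < min_coverage) return(NULL)
  al
}

#' Test whether a gap is closed by a new assembly
#'
#' Both flanks are mapped to the new assembly; the gap is `closed` iff both
#' flank identities exceed `min_identity`, land on the same target sequence
#' and strand, in consistent order, with an estimated span of at most
#' `max_span`. Different targets give `conflicting`; an unaligned or
#' below-threshold flank gives `unresolved`.
#'
#' @param flanks list from [extract_gap_flanks()].
#' @param new_index seed index over the new assembly ([build_seed_index()]).
#' @param new_assembly new assembly record data.frame.
#' @param min_identity percent identity threshold (strict).
#' @param scoring an [align_scoring()].
#' @param max_span largest plausible closed-gap span (bp).
#' @return list of class `gap_closure`: `status` (closed / unresolved /
#'   conflicting), `contig`, `estimated_span`, `left`, `right`.
#' @export
close_gap <- function(flanks, new_index, new_assembly, min_identity = 90,
                      scoring = align_scoring(), max_span = 1e7) {
  l <- best_hit(flanks$left, new_index, new_assembly, scoring, min_identity)
  r <- best_hit(flanks$right, new_index, new_assembly, scoring, min_identity)
  res <- list(left = l, right = r, contig = NA_character_,
              estimated_span = NA_real_)
  if (is.null(l) || is.null(r)) { res$status <- "unresolved"; return(structure(res, class = "gap_closure")) }
  if (l$tname != r$tname) { res$status <- "conflicting"; return(structure(res, class = "gap_closure")) }
  same_strand <- l$strand == r$strand
  span <- if (l$strand == "+") r$tstart - l$tend else l$tstart - r$tend
  if (!same_strand || span < 0 || span > max_span) {
    res$status <- "conflicting"
  } else {
    res$status <- "closed"
    res$contig <- l$tname
    res$estimated_span <- span
  }
  structure(res, class = "gap_closure")
}

#' Close every gap of an old assembly against a new one
#'
#' @param old_assembly,new_assembly record data.frames.
#' @param flank_len flank length in bp.
#' @param min_identity percent identity threshold (strict).
#' @param scoring an [align_scoring()].
#' @param max_span largest plausible closed-gap span.
#' @param k seed k-mer size.
#' @return data.frame, one row per gap: `seqid`, `start`, `end`, `status`,
#'   `contig`, `estimated_span`.
#' @export
fill_gaps <- function(old_assembly, new_assembly, flank_len = 10000L,
                      min_identity = 90, scoring = align_scoring(),
                      max_span = 1e7, k = 13L) {
  idx <- build_seed_index(new_assembly, k = k)
  rows <- list()
  for (i in seq_len(nrow(old_assembly))) {
    gaps <- find_n_runs(old_assembly$seq[i])
    if (nrow(gaps) == 0L) next
    gaps$seqid <- old_assembly$id[i]
    for (g in seq_len(nrow(gaps))) {
      fl <- extract_gap_flanks(old_assembly, gaps[g, ], flank_len)
      cl <- close_gap(fl, idx, new_assembly, min_identity, scoring, max_span)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = gaps$seqid[g], start = gaps$start[g], end = gaps$end[g],
        status = cl$status, contig = cl$contig,
        estimated_span = cl$estimated_span, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), status = character(),
                      contig = character(), estimated_span = numeric()))
  do.call(rbind, rows)
}

#' Place an unplaced scaffold on a new assembly
#'
#' The scaffold is split at its N-runs; each piece is mapped and pieces with
#' identity above `min_piece_identity` qualify. The scaffold is `placed`
#' when the qualifying matching bases exceed `min_fraction` percent of its
#' non-N length and all qualifying pieces hit one target in consistent
#' order and strand; `partial` when single-target but below the fraction;
#' `unplaced` otherwise.
#'
#' @param scaffold single-record data.frame.
#' @param new_index seed index over the new assembly.
#' @param new_assembly new assembly record data.frame.
#' @param min_fraction percent of non-N scaffold bases that must match.
#' @param min_piece_identity per-piece identity gate (strict).
#' @param min_piece_len pieces shorter than this are ignored.
#' @param scoring an [align_scoring()].
#' @return list of class `scaffold_placement`: `status`, `contig`, `strand`,
#'   `placed_fraction`, `pieces` (per-piece alignments).
#' @export
place_scaffold <- function(scaffold, new_index, new_assembly,
                           min_fraction = 50, min_piece_identity = 90,
                           min_piece_len = 50L, scoring = align_scoring()) {
  seq <- scaffold$seq[1L]
  runs <- find_n_runs(seq)
  bounds <- rbind(c(0L, 0L), as.matrix(runs), c(nchar(seq), nchar(seq)))
  pieces <- list()
  for (i in seq_len(nrow(bounds) - 1L)) {
    ps <- bounds[i, 2L]; pe <- bounds[i + 1L, 1L]
    if (pe - ps >= min_piece_len)
      pieces[[length(pieces) + 1L]] <- list(
        start = ps, rec = seq_records(sprintf("%s_p%d", scaffold$id[1L], ps),
                                      seq_slice(seq, ps, pe)))
  }
  non_n <- sum(strsplit(seq, "")[[1L]] != "N")
  hits <- list()
  for (p in pieces) {
    h <- best_hit(p$rec, new_index, new_assembly, scoring, min_piece_identity)
    if (!is.null(h)) { h$piece_start <- p$start; hits[[length(hits) + 1L]] <- h }
  }
  if (length(hits) == 0L)
    return(structure(list(status = "unplaced", contig = NA_character_,
                          strand = NA_character_, placed_fraction = 0,
                          pieces = NULL), class = "scaffold_placement"))
  ph <- do.call(rbind, hits)
  frac <- 100 * sum(ph$matches) / max(1L, non_n)
  one_contig <- length(unique(ph$tname)) == 1L
  one_strand <- length(unique(ph$strand)) == 1L
  ordered <- TRUE
  if (nrow(ph) > 1L && one_contig && one_strand) {
    o <- order(ph$piece_start)
    ordered <- if (ph$strand[1L] == "+") !is.unsorted(ph$tstart[o])
               else !is.unsorted(rev(ph$tstart[o]))
  }
  status <- if (one_contig && one_strand && ordered && frac > min_fraction)
    "placed" else if (one_contig) "partial" else "unplaced"
  structure(list(status = status,
                 contig = if (one_contig) ph$tname[1L] else NA_character_,
                 strand = if (one_strand) ph$strand[1L] else NA_character_,
                 placed_fraction = frac, pieces = ph),
            class = "scaffold_placement")
}

#' Summarize gap closures and scaffold placements
#'
#' @param closures data.frame from [fill_gaps()].
#' @param placements list of `scaffold_placement` objects, or a data.frame
#'   with `status` and `length` columns.
#' @return list: `gap_counts` (closed/unresolved/conflicting), `scaffold_counts`
#'   (placed/partial/unplaced), `placed_length` (total bp of placed scaffolds).
#' @export
gapfill_report <- function(closures, placements) {
  gc <- setNames(rep(0L, 3L), c("closed", "unresolved", "conflicting"))
  if (!is.null(closures) && nrow(closures)) {
    tb <- table(closures$status)
    gc[names(tb)] <- as.integer(tb)
  }
  sc <- setNames(rep(0L, 3L), c("placed", "partial", "unplaced"))
  placed_len <- 0
  if (!is.null(placements) && length(placements)) {
    if (is.data.frame(placements)) {
      tb <- table(placements$status)
      sc[names(tb)] <- as.integer(tb)
      placed_len <- sum(placements$length[placements$status == "placed"])
    } else {
      st <- vapply(placements, `[[`, character(1L), "status")
      tb <- table(st)
      sc[names(tb)] <- as.integer(tb)
      lens <- vapply(placements, function(p)
        if (p$status == "placed" && !is.null(p$pieces))
          sum(p$pieces$qlen[!duplicated(p$pieces$qname)]) else 0, numeric(1L))
      placed_len <- sum(lens)
    }
  }
  list(gap_counts = gc, scaffold_counts = sc, placed_length = placed_len)
}
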