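# Self-contained k-mer-seeded affine-gap local aligner.  The DP core lives in
# src/align.cpp; this file provides scoring objects, the canonical k-mer seed
# index, seed chaining by diagonal clustering, and banded extension.  Percent
# identity is 100 * matches / aligned-columns-including-gaps, matching PAF.

#' Alignment scoring scheme
#'
#' Conventional short-segment preset: match +2, mismatch -4, gap open -4,
#' gap extend -2 (penalties on the negative scale, `gap_open <= gap_extend
#' <= 0`).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open penalty for the first base of a gap (< 0).
#' @param gap_extend penalty for each further gap base (<= 0).
#' @return object of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                          gap_extend = -2L) {
  if (match <= 0 || mismatch >= 0 || gap_open >= 0 || gap_extend > 0 ||
      gap_open > gap_extend)
    imm_parameter_error("invalid scoring: need match>0, mismatch<0, gap_open<=gap_extend<=0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Optimal affine-gap local alignment of two sequences
#'
#' Exact Smith-Waterman-Gotoh when `band` is `NULL`; with a band only cells
#' within `band` of the centre diagonal `d0` are explored (equal to the full
#' DP whenever the band covers the optimum). Ties are broken deterministically:
#' highest score, then smallest target start, then smallest query start.
#' An empty optimum yields score 0 and an empty alignment.
#'
#' @param query,target DNA strings or single-row record data.frames.
#' @param scoring an [align_scoring()] object.
#' @param band half-width of the explored diagonal band, or `NULL` for the
#'   full DP.
#' @param d0 centre diagonal (target position minus query position).
#' @return list with `score`, `qstart`, `qend`, `tstart`, `tend` (0-based
#'   half-open), `cigar`, `matches`, `block_length`, `identity`.
#' @export
local_align <- function(query, target, scoring = align_scoring(),
                        band = NULL, d0 = 0L) {
  q <- if (is.data.frame(query)) query$seq[1L] else query
  t <- if (is.data.frame(target)) target$seq[1L] else target
  if (!nzchar(q) || !nzchar(t))
    imm_parameter_error("local_align requires non-empty sequences")
  res <- .cpp_local_align(q, t, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          if (is.null(band)) -1L else as.integer(band),
                          as.integer(d0))
  res$identity <- if (res$block_length > 0)
    100 * res$matches / res$block_length else 0
  res
}

#' Build a canonical k-mer seed index over target sequences
#'
#' Each k-mer and its reverse complement are collapsed to the
#' lexicographically smaller (canonical) form; k-mers containing N are
#' excluded.
#'
#' @param targets record data.frame (`id`, `seq`).
#' @param k k-mer size, 8-21.
#' @return object of class `seed_index`.
#' @export
build_seed_index <- function(targets, k = 13L) {
  if (k < 8L || k > 21L) imm_parameter_error("k must be within [8, 21]")
  k <- as.integer(k)
  tabs <- lapply(seq_len(nrow(targets)), function(i) {
    s <- targets$seq[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    fwd <- substring(s, pos, pos + k - 1L)
    rcs <- revcomp(s)
    rev <- substring(rcs, n - (pos + k - 1L) + 1L, n - pos + 1L)
    keep <- !grepl("N", fwd, fixed = TRUE)
    if (!any(keep)) return(NULL)
    fwd <- fwd[keep]; rev <- rev[keep]; pos <- pos[keep]
    canon <- pmin(fwd, rev)
    data.table(kmer = canon, tid = targets$id[i], pos = pos - 1L,
               tfwd = fwd <= rev)
  })
  dt <- rbindlist(tabs)
  if (nrow(dt)) setkeyv(dt, "kmer")
  structure(list(k = k, dt = dt,
                 tlens = setNames(nchar(targets$seq), targets$id)),
            class = "seed_index")
}

# k-mer positions of a query against an index; returns per-strand seed tables
query_seeds <- function(query_seq, index) {
  k <- index$k
  n <- nchar(query_seq)
  if (n < k || nrow(index$dt) == 0L) return(NULL)
  pos <- seq_len(n - k + 1L)
  fwd <- substring(query_seq, pos, pos + k - 1L)
  rcq <- revcomp(query_seq)
  rev <- substring(rcq, n - (pos + k - 1L) + 1L, n - pos + 1L)
  keep <- !grepl("N", fwd, fixed = TRUE)
  if (!any(keep)) return(NULL)
  q <- data.table(kmer = pmin(fwd[keep], rev[keep]), qpos = pos[keep] - 1L,
                  qfwd = fwd[keep] <= rev[keep])
  hits <- index$dt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits[, strand := ifelse(hits$qfwd == hits$tfwd, "+", "-")]
  hits
}

#' Map a query against indexed targets
#'
#' Seeds are clustered by (target, strand, diagonal), clusters with at least
#' `min_seed_hits` seeds are extended with a banded local alignment in a
#' window around the implied target interval; both strands are searched.
#' Results are sorted by score (descending); `unique_hit` flags a best score
#' at least `unique_ratio` times the runner-up.
#'
#' @param query single record (data.frame row) or DNA string.
#' @param index a [build_seed_index()] object over `targets`.
#' @param targets the record data.frame the index was built from.
#' @param scoring an [align_scoring()] object.
#' @param min_seed_hits minimum seeds per cluster.
#' @param unique_ratio best/second-best score ratio declaring uniqueness.
#' @param band extension band half-width; default adapts to query length.
#' @param diag_slack maximum diagonal spread within one cluster.
#' @return data.frame of alignments: `qname,qlen,qstart,qend,strand,tname,
#'   tlen,tstart,tend,matches,block_len,score,cigar,identity,unique_hit`.
#' @export
map_query <- function(query, index, targets, scoring = align_scoring(),
                      min_seed_hits = 2L, unique_ratio = 1.2, band = NULL,
                      diag_slack = 30L) {
  qid <- if (is.data.frame(query)) query$id[1L] else "query"
  qseq <- if (is.data.frame(query)) query$seq[1L] else query
  qlen <- nchar(qseq)
  empty <- data.frame(qname = character(), qlen = numeric(),
                      qstart = numeric(), qend = numeric(),
                      strand = character(), tname = character(),
                      tlen = numeric(), tstart = numeric(), tend = numeric(),
                      matches = numeric(), block_len = numeric(),
                      score = numeric(), cigar = character(),
                      identity = numeric(), unique_hit = logical(),
                      stringsAsFactors = FALSE)
  hits <- query_seeds(qseq, index)
  if (is.null(hits)) return(empty)
  k <- index$k
  # diagonal in forward-query coordinates per strand
  hits[, qpos_or := ifelse(hits$strand == "+", hits$qpos,
                           qlen - k - hits$qpos)]
  hits[, diag := hits$pos - hits$qpos_or]
  rows <- list()
  seqs <- setNames(targets$seq, targets$id)
  for (grp in split(as.data.frame(hits), list(hits$tid, hits$strand), drop = TRUE)) {
    grp <- grp[order(grp$diag, grp$qpos_or), ]
    cl_id <- cumsum(c(1L, diff(grp$diag) > diag_slack))
    for (cl in split(grp, cl_id)) {
      # distinct query positions count as support; clusters whose seeds
      # cover barely more than one k-mer of the query are chance matches
      if (length(unique(cl$qpos_or)) < min_seed_hits) next
      span <- diff(range(cl$qpos_or)) + k
      if (span < min(2L * k, max(k + 2L, qlen %/% 2L))) next
      tid <- cl$tid[1L]
      tseq <- seqs[[tid]]
      tlen <- nchar(tseq)
      dmed <- stats::median(cl$diag)
      spread <- diff(range(cl$diag))
      b <- if (!is.null(band)) band else
        max(40L, 2L * as.integer(spread) + 20L)
      pad <- b + k
      t_lo <- max(0L, as.integer(min(cl$diag) - pad))
      t_hi <- min(tlen, as.integer(max(cl$diag) + qlen + pad))
      if (t_hi <= t_lo) next
      win <- substr(tseq, t_lo + 1L, t_hi)
      qs <- if (cl$strand[1L] == "+") qseq else revcomp(qseq)
      al <- local_align(qs, win, scoring, band = b,
                        d0 = as.integer(round(dmed)) - t_lo)
      if (al$score <= 0) next
      qstart <- al$qstart; qend <- al$qend
      if (cl$strand[1L] == "-") { qstart <- qlen - al$qend; qend <- qlen - al$qstart }
      rows[[length(rows) + 1L]] <- list(
        qname = qid, qlen = qlen, qstart = qstart, qend = qend,
        strand = cl$strand[1L], tname = tid, tlen = tlen,
        tstart = t_lo + al$tstart, tend = t_lo + al$tend,
        matches = al$matches, block_len = al$block_length,
        score = al$score, cigar = al$cigar, identity = al$identity)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- as.data.frame(rbindlist(rows))
  out <- out[!duplicated(out[, c("tname", "strand", "tstart", "tend")]), ]
  out <- out[order(-out$score, out$tname, out$tstart), ]
  out$unique_hit <- FALSE
  if (nrow(out) == 1L) out$unique_hit <- TRUE
  else out$unique_hit[1L] <- out$score[1L] >= unique_ratio * out$score[2L]
  rownames(out) <- NULL
  out
}

#' Convert map_query results to PAF rows
#' @param aln data.frame from [map_query()].
#' @return data.frame acceptable to [write_paf()].
#' @export
alignments_to_paf <- function(aln) {
  aln$mapq <- ifelse(aln$unique_hit %||% TRUE, 60L, 0L)
  aln$tags <- sprintf("AS:i:%d\tcg:Z:%s", as.integer(aln$score), aln$cigar)
  aln[, c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
          "tstart", "tend", "matches", "block_len", "mapq", "tags")]
}
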