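# Full-length V(D)J transcript profiling: segment assignment, CDR3
# extraction and productivity, usage matrices and CDR(H)3 length profiles.
# D calls use deterministic run-length matching (>= d_min_match exact bases
# between the V and J alignment ends) because short D segments make
# alignment-score calls unstable.

# project a query position through an alignment's CIGAR onto the target;
# extrapolates colinearly outside the aligned range
project_qpos <- function(qstart, qend, tstart, tend, cigar, qpos) {
  if (qpos < qstart) return(tstart - (qstart - qpos))
  if (qpos >= qend) return(tend + (qpos - qend))
  ops <- cigar_ops(cigar)
  q <- qstart; t <- tstart
  for (r in seq_len(nrow(ops))) {
    len <- ops$len[r]
    switch(ops$op[r],
           M = {
             if (qpos < q + len) return(t + (qpos - q))
             q <- q + len; t <- t + len
           },
           I = {                     # consumes query only
             if (qpos < q + len) return(t)
             q <- q + len
           },
           D = { t <- t + len })
  }
  t
}

# longest exact common substring of a (short) pattern within text; returns
# 0-length when below min_len
longest_exact_match <- function(text, pattern, min_len) {
  nt <- nchar(text); np <- nchar(pattern)
  if (nt < min_len || np < min_len) return(0L)
  best <- 0L
  for (len in min(np, nt):min_len) {
    if (len <= best) break
    starts <- seq_len(np - len + 1L)
    subs <- substring(pattern, starts, starts + len - 1L)
    if (any(vapply(subs, function(s) grepl(s, text, fixed = TRUE), logical(1L)))) {
      best <- len
      break
    }
  }
  best
}

#' Assign V/(D)/J/C segments to full-length transcripts
#'
#' Best V and best J by alignment score (ties: higher identity, then
#' lexicographic name); the locus is fixed by the V call and J/C candidates
#' are restricted to it (chimeric V/J rejected). D (heavy-type loci only) is
#' searched between the V and J alignment ends and requires at least
#' `d_min_match` consecutive matching bases. Transcripts whose best V score
#' falls below `min_v_score` are unassigned.
#'
#' @param transcripts record data.frame.
#' @param library segment library covering the candidate loci.
#' @param scoring an [align_scoring()].
#' @param min_v_score minimum V alignment score for assignment.
#' @param d_min_match minimum exact D match run (bp).
#' @param k seed k-mer size.
#' @return data.frame, one row per transcript: `sequence_id`, `locus`,
#'   `v_call`, `d_call`, `j_call`, `c_call`, `v_score`, `v_identity`,
#'   `j_score`, `j_identity`, coordinates of the V end / J start on the
#'   transcript, and `assigned`.
#' @export
assign_vdj <- function(transcripts, library, scoring = align_scoring(),
                       min_v_score = 100, d_min_match = 8L, k = 13L) {
  # one index over all transcripts; each library entry mapped once
  idx <- build_seed_index(transcripts, k = k)
  hit_list <- list()
  for (j in seq_len(nrow(library))) {
    al <- map_query(seq_records(library$name[j], library$seq[j]), idx,
                    transcripts, scoring, min_seed_hits = 1L)
    al <- al[al$strand == "+", , drop = FALSE]
    if (nrow(al) == 0L) next
    al$name <- library$name[j]
    al$locus <- library$locus[j]
    al$seg_type <- library$seg_type[j]
    hit_list[[length(hit_list) + 1L]] <- al
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else NULL
  by_tx <- if (is.null(hits)) list() else split(hits, hits$tname)
  rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    th <- by_tx[[tx$id]]
    best_of <- function(type, loci = NULL) {
      if (is.null(th)) return(NULL)
      sub <- th[th$seg_type == type, , drop = FALSE]
      if (!is.null(loci)) sub <- sub[sub$locus %in% loci, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      sub <- sub[order(-sub$score, -sub$identity, sub$name), , drop = FALSE]
      sub[1L, ]
    }
    v <- best_of("V")
    out <- data.frame(sequence_id = tx$id, locus = NA_character_,
                      v_call = NA_character_, d_call = NA_character_,
                      j_call = NA_character_, c_call = NA_character_,
                      v_score = NA_real_, v_identity = NA_real_,
                      j_score = NA_real_, j_identity = NA_real_,
                      v_tstart = NA_integer_, v_tend = NA_integer_,
                      j_tstart = NA_integer_, j_tend = NA_integer_,
                      v_qstart = NA_integer_, v_qend = NA_integer_,
                      j_qstart = NA_integer_, j_qend = NA_integer_,
                      v_cigar = NA_character_, j_cigar = NA_character_,
                      assigned = FALSE, stringsAsFactors = FALSE)
    if (!is.null(v) && v$score >= min_v_score) {
      out$locus <- v$locus
      out$v_call <- v$name; out$v_score <- v$score; out$v_identity <- v$identity
      out$v_tstart <- v$tstart; out$v_tend <- v$tend; out$v_qstart <- v$qstart
      out$v_qend <- v$qend; out$v_cigar <- v$cigar
      jb <- best_of("J", loci = v$locus)
      if (!is.null(jb) && jb$tstart >= v$tend - 3L) {
        out$j_call <- jb$name; out$j_score <- jb$score
        out$j_identity <- jb$identity
        out$j_tstart <- jb$tstart; out$j_tend <- jb$tend
        out$j_qstart <- jb$qstart; out$j_qend <- jb$qend
        out$j_cigar <- jb$cigar
        out$assigned <- TRUE
        # D between V end and J start
        if (v$locus %in% HEAVY_LOCI) {
          gap <- substr(tx$seq, v$tend + 1L, jb$tstart)
          dsub <- library[library$seg_type == "D" & library$locus == v$locus, ,
                          drop = FALSE]
          dbest <- NULL; dlen <- 0L
          for (dj in seq_len(nrow(dsub))) {
            L <- longest_exact_match(gap, dsub$seq[dj], d_min_match)
            if (L > dlen || (L == dlen && L > 0L &&
                             (is.null(dbest) || dsub$name[dj] < dbest))) {
              dlen <- L; dbest <- dsub$name[dj]
            }
          }
          if (dlen >= d_min_match) out$d_call <- dbest
        }
        # C 3' of J
        cb <- best_of("C", loci = v$locus)
        if (!is.null(cb) && cb$tstart >= jb$tend - 3L) out$c_call <- cb$name
      }
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}

#' Extract CDR3 and decide productivity for one annotated transcript
#'
#' The CDR3 spans the codon of the conserved V 2nd-CYS (library-annotated)
#' through the codon preceding the J F/W-G-X-G motif. The motif must
#' actually be present at the mapped position on the transcript; otherwise
#' the CDR3 is undefined and the transcript unproductive. Productive
#' requires an in-frame CDR3 and no stop codon from the V start through the
#' end of J.
#'
#' @param annotation one row from [assign_vdj()].
#' @param transcript matching single-record data.frame.
#' @param library segment library (for `cys_pos` / `motif_pos`).
#' @return list: `cdr3_nt`, `cdr3_aa` (NA when undefined), `productive`.
#' @export
extract_cdr3 <- function(annotation, transcript, library) {
  na_out <- list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                 productive = FALSE)
  if (!isTRUE(annotation$assigned)) return(na_out)
  v <- library[match(annotation$v_call, library$name), ]
  j <- library[match(annotation$j_call, library$name), ]
  if (is.na(v$cys_pos) || is.na(j$motif_pos)) return(na_out)
  seq <- transcript$seq[1L]
  # transcript positions of the V 2nd-CYS codon and the J motif, projected
  # through the alignment CIGARs (gaps shift the mapping)
  cys_tx <- project_qpos(annotation$v_qstart, annotation$v_qend,
                         annotation$v_tstart, annotation$v_tend,
                         annotation$v_cigar, v$cys_pos)
  motif_tx <- project_qpos(annotation$j_qstart, annotation$j_qend,
                           annotation$j_tstart, annotation$j_tend,
                           annotation$j_cigar, j$motif_pos)
  if (is.na(cys_tx) || is.na(motif_tx) || motif_tx <= cys_tx) return(na_out)
  # verify the F/W-G-X-G motif on the transcript itself
  mseq <- substr(seq, motif_tx + 1L, motif_tx + 12L)
  aa_m <- translate_dna(mseq)
  if (nchar(aa_m) < 4L ||
      !grepl("^[FW]G.G", aa_m)) return(na_out)
  cdr3_nt <- substr(seq, cys_tx + 1L, motif_tx)
  in_frame <- nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- if (in_frame) translate_dna(cdr3_nt) else NA_character_
  vj <- substr(seq, annotation$v_tstart + 1L, annotation$j_tend)
  frame_off <- (annotation$v_qstart) %% 3L   # V aligned from its own frame
  aa_vj <- translate_dna(substr(vj, 1L + (3L - frame_off) %% 3L, nchar(vj)))
  productive <- in_frame && !grepl("*", aa_vj, fixed = TRUE) &&
    !is.na(cdr3_aa) && !grepl("*", cdr3_aa, fixed = TRUE)
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, productive = productive)
}

#' Annotate a transcript set end-to-end (AIRR-style table)
#'
#' [assign_vdj()] plus [extract_cdr3()] per transcript.
#'
#' @inheritParams assign_vdj
#' @return AIRR-style data.frame with columns `sequence_id`, `locus`,
#'   `v_call`, `d_call`, `j_call`, `c_call`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, plus scores.
#' @export
annotate_repertoire <- function(transcripts, library,
                                scoring = align_scoring(),
                                min_v_score = 100, d_min_match = 8L,
                                k = 13L) {
  ann <- assign_vdj(transcripts, library, scoring, min_v_score, d_min_match, k)
  extra <- lapply(seq_len(nrow(ann)), function(i)
    extract_cdr3(ann[i, ], transcripts[i, ], library))
  ann$cdr3_nt <- vapply(extra, `[[`, character(1L), "cdr3_nt")
  ann$cdr3_aa <- vapply(extra, `[[`, character(1L), "cdr3_aa")
  ann$productive <- vapply(extra, `[[`, logical(1L), "productive")
  ann
}

#' V-(D)-J usage profile of assigned transcripts
#'
#' @param annotations data.frame from [annotate_repertoire()] /
#'   [assign_vdj()].
#' @param locus locus to profile.
#' @return list: `counts` (per V/(D)/J combination), `links` (Sankey-ready
#'   source/target/value rows), `total` assigned transcripts.
#' @export
usage_profile <- function(annotations, locus) {
  a <- annotations[annotations$assigned & annotations$locus == locus &
                     !is.na(annotations$locus), , drop = FALSE]
  has_d <- locus %in% HEAVY_LOCI && any(!is.na(a$d_call))
  if (nrow(a) == 0L)
    return(list(counts = data.frame(), links = data.frame(), total = 0L))
  # transcripts without a confident D call keep their place in the profile
  if (has_d) a$d_call[is.na(a$d_call)] <- "D?"
  keys <- if (has_d) c("v_call", "d_call", "j_call") else c("v_call", "j_call")
  counts <- aggregate(list(n = a$sequence_id), by = a[keys], FUN = length)
  links <- if (has_d) {
    rbind(setNames(aggregate(list(value = a$sequence_id),
                             by = list(a$v_call, a$d_call), FUN = length),
                   c("source", "target", "value")),
          setNames(aggregate(list(value = a$sequence_id),
                             by = list(a$d_call, a$j_call), FUN = length),
                   c("source", "target", "value")))
  } else {
    setNames(aggregate(list(value = a$sequence_id),
                       by = list(a$v_call, a$j_call), FUN = length),
             c("source", "target", "value"))
  }
  list(counts = counts, links = links, total = nrow(a))
}

#' CDR(H)3 length profile with ultralong flagging
#'
#' Histogram of CDR3 amino-acid lengths over productive transcripts with a
#' defined CDR3; transcripts at or above `ultralong_aa_threshold` are
#' flagged and their V/D usage tabulated.
#'
#' @param annotations data.frame from [annotate_repertoire()].
#' @param ultralong_aa_threshold CDR3 length (aa) marking ultralong
#'   receptors.
#' @return list: `histogram` (length/count), `ultralong` (flagged
#'   transcripts with v_call/d_call), `total`.
#' @export
cdrh3_profile <- function(annotations, ultralong_aa_threshold = 40L) {
  a <- annotations[annotations$productive & !is.na(annotations$cdr3_aa), ,
                   drop = FALSE]
  if (nrow(a) == 0L)
    return(list(histogram = data.frame(length = integer(), count = integer()),
                ultralong = data.frame(), total = 0L))
  len <- nchar(a$cdr3_aa)
  hist <- aggregate(list(count = a$sequence_id), by = list(length = len),
                    FUN = length)
  ul <- a[len >= ultralong_aa_threshold,
          c("sequence_id", "v_call", "d_call", "j_call", "cdr3_aa"),
          drop = FALSE]
  list(histogram = hist, ultralong = ul, total = nrow(a))
}
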