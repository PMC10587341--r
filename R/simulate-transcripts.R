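# Recombined V(D)J transcript simulation: trimmed V + N nucleotides +
# (D for heavy-type loci) + N + trimmed J + C, with segment usage drawn from
# explicit weights and truth assignments recorded.

#' Junction model for transcript simulation
#'
#' @param n_max maximum length of each untemplated N stretch.
#' @param trim_max maximum exonucleolytic trim at V 3', J 5' and D ends.
#' @param p_inframe probability that a transcript is built in frame and
#'   stop-free across V-through-J (selection proxy; repertoires are
#'   predominantly productive).
#' @return list of junction parameters.
#' @export
junction_model <- function(n_max = 5L, trim_max = 6L, p_inframe = 0.95) {
  if (trim_max > 6L)
    imm_parameter_error("trim_max > 6 may truncate the V 2nd-CYS codon")
  list(n_max = as.integer(n_max), trim_max = as.integer(trim_max),
       p_inframe = p_inframe)
}

check_weights <- function(w, what) {
  if (abs(sum(w) - 1) > 1e-9)
    imm_parameter_error("%s usage weights must sum to 1", what)
  w
}

#' Simulate full-length recombined transcripts
#'
#' Each transcript is `trimmed V + N + (D) + N + trimmed J + C`. V and J are
#' drawn from `usage_weights$v` / `usage_weights$j` (named probability
#' vectors over library entry names); D (heavy-type loci only) from
#' `usage_weights$d` or uniformly. With probability `p_inframe` the junction
#' is adjusted to keep CDR3 in frame and stop-free.
#'
#' @param library a [make_segment_library()] data.frame for one locus.
#' @param usage_weights list with elements `v`, `j` and optionally `d`, `c`.
#' @param junction a [junction_model()].
#' @param n number of transcripts.
#' @param seed integer seed.
#' @return list: `transcripts` (record data.frame), `truth` (data.frame with
#'   per-transcript v/d/j/c names, junction string = true CDR3 nt,
#'   `productive` intent and junction coordinates).
#' @export
simulate_transcripts <- function(library, usage_weights, junction = junction_model(),
                                 n = 100L, seed = 1L) {
  loc <- library$locus[1L]
  has_d <- loc %in% HEAVY_LOCI && any(library$seg_type == "D")
  vw <- check_weights(usage_weights$v, "V")
  jw <- check_weights(usage_weights$j, "J")
  dw <- if (has_d) {
    if (!is.null(usage_weights$d)) check_weights(usage_weights$d, "D")
    else {
      dn <- library$name[library$seg_type == "D"]
      setNames(rep(1 / length(dn), length(dn)), dn)
    }
  } else NULL
  cn <- library$name[library$seg_type == "C"]
  if (length(cn) == 0L) imm_parameter_error("library has no C segment")
  entry <- function(nm) library[match(nm, library$name), ]
  with_seed(seed, {
    tx <- vector("list", n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      vn <- sample(names(vw), 1L, prob = vw)
      jn <- sample(names(jw), 1L, prob = jw)
      dn <- if (has_d) sample(names(dw), 1L, prob = dw) else NA_character_
      cnm <- if (!is.null(usage_weights$c))
        sample(names(usage_weights$c), 1L, prob = usage_weights$c) else cn[1L]
      v <- entry(vn); j <- entry(jn); cc <- entry(cnm)
      tv <- sample(0:junction$trim_max, 1L)
      tj <- sample(0:min(junction$trim_max, j$motif_pos), 1L)
      vseq <- substr(v$seq, 1L, nchar(v$seq) - tv)
      jseq <- substr(j$seq, tj + 1L, nchar(j$seq))
      dseq <- ""
      if (has_d) {
        d <- entry(dn)
        dmax_trim <- max(0L, (nchar(d$seq) - 8L) %/% 2L)
        td5 <- sample(0:min(junction$trim_max, dmax_trim), 1L)
        td3 <- sample(0:min(junction$trim_max, dmax_trim), 1L)
        dseq <- substr(d$seq, td5 + 1L, nchar(d$seq) - td3)
      }
      inframe <- runif(1L) < junction$p_inframe
      make_junctions <- function() {
        n1 <- random_dna(sample(0:junction$n_max, 1L), gc = 0.6)
        n2 <- random_dna(sample(0:junction$n_max, 1L), gc = 0.6)
        if (inframe) {
          cdr3_len <- (nchar(vseq) - v$cys_pos) + nchar(n1) + nchar(dseq) +
            nchar(n2) + (j$motif_pos - tj)
          delta <- cdr3_len %% 3L
          if (delta != 0L) n2 <- paste0(n2, random_dna(3L - delta, gc = 0.6))
        }
        list(n1 = n1, n2 = n2)
      }
      seq_vj <- NULL
      for (attempt in 1:25) {
        jn2 <- make_junctions()
        seq_vj <- paste0(vseq, jn2$n1, dseq, jn2$n2, jseq)
        if (!inframe) break
        if (!grepl("*", translate_dna(seq_vj), fixed = TRUE)) break
      }
      seq <- paste0(seq_vj, cc$seq)
      cdr3_start <- v$cys_pos
      motif_tx <- nchar(vseq) + nchar(jn2$n1) + nchar(dseq) + nchar(jn2$n2) +
        (j$motif_pos - tj)
      id <- sprintf("tx%05d", i)
      tx[[i]] <- seq_records(id, seq)
      truth[[i]] <- data.frame(
        id = id, locus = loc, v_call = vn, d_call = dn, j_call = jn,
        c_call = cnm, junction = substr(seq, cdr3_start + 1L, motif_tx),
        cdr3_start = cdr3_start, cdr3_end = motif_tx,
        productive = (motif_tx - cdr3_start) %% 3L == 0L &&
          !grepl("*", translate_dna(seq_vj), fixed = TRUE),
        stringsAsFactors = FALSE)
    }
    list(transcripts = do.call(rbind, tx), truth = do.call(rbind, truth))
  })
}
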