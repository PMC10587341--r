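# Assembly statistics: N50, gap census, consensus quality (QV), and a
# purpose-built tandem-repeat finder feeding telomere and satellite-DNA
# annotation.

#' Contig/scaffold N50
#'
#' Smallest length L such that sequences of length >= L sum to at least half
#' of the total.
#'
#' @param lengths positive integer vector.
#' @return N50 in bp.
#' @export
contig_n50 <- function(lengths) {
  if (length(lengths) == 0L) imm_parameter_error("empty length list")
  if (any(lengths <= 0)) imm_parameter_error("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Find maximal N-runs (assembly gaps)
#'
#' @param seq DNA string.
#' @param min_len minimum run length reported.
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
find_n_runs <- function(seq, min_len = 1L) {
  m <- gregexpr("N+", seq)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer()))
  len <- attr(m, "match.length")
  keep <- len >= min_len
  data.frame(start = as.integer(m[keep]) - 1L,
             end = as.integer(m[keep]) - 1L + len[keep])
}

#' Consensus quality from homozygous-error counts
#'
#' Phred-scaled: `-10 * log10(n_errors / genome_size)`; zero errors return
#' the configured cap.
#'
#' @param n_homozygous_errors total homozygous SNP + indel events.
#' @param genome_size assembly size in bp.
#' @param cap QV returned when no errors are observed.
#' @return QV (real; round for the conventional integer Phred).
#' @export
estimate_qv <- function(n_homozygous_errors, genome_size, cap = 99) {
  if (genome_size <= 0) imm_parameter_error("genome_size must be positive")
  if (n_homozygous_errors == 0) return(cap)
  -10 * log10(n_homozygous_errors / genome_size)
}

#' Error rate as a percentage of the genome
#'
#' @param n_errors error event count.
#' @param genome_size assembly size in bp.
#' @return `100 * n_errors / genome_size`.
#' @export
error_rate_percent <- function(n_errors, genome_size) {
  if (genome_size <= 0) imm_parameter_error("genome_size must be positive")
  100 * n_errors / genome_size
}

#' Whole-assembly statistics
#'
#' @param records assembly record data.frame.
#' @return list: `n_sequences`, `total_length`, `n50`, `gaps` (per-sequence
#'   N-run data.frame with `seqid`).
#' @export
assembly_stats <- function(records) {
  gaps <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    g <- find_n_runs(records$seq[i])
    if (nrow(g)) cbind(seqid = records$id[i], g, stringsAsFactors = FALSE)
  }))
  list(n_sequences = nrow(records),
       total_length = sum(nchar(records$seq)),
       n50 = contig_n50(nchar(records$seq)),
       gaps = gaps %||% data.frame(seqid = character(), start = integer(),
                                   end = integer()))
}

# lexicographically smallest rotation of a repeat unit
smallest_rotation <- function(s) {
  n <- nchar(s)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(s, i, n), substr(s, 1L, i - 1L)), character(1L))
  sort(rots)[1L]
}

#' Find short tandem repeats
#'
#' Candidate periods are proposed by k-mer distance voting (distances between
#' repeated k-mer occurrences); arrays are delimited by the match profile of
#' the sequence against itself at lag p, a per-phase majority consensus is
#' derived, and purity is the fraction of array bases matching the tiled
#' consensus. Maximal non-overlapping records with `copies >= min_copies`
#' and `purity >= min_purity` are reported, consensus normalized to its
#' lexicographically smallest rotation.
#'
#' @param seq DNA string.
#' @param max_period largest repeat period considered.
#' @param min_copies minimum copy number.
#' @param min_purity minimum percent purity.
#' @return data.frame: `start`, `end`, `period`, `copy_number`,
#'   `consensus`, `purity`.
#' @export
find_tandem_repeats <- function(seq, max_period = 2000L, min_copies = 3,
                                min_purity = 85) {
  if (max_period > 2000L) imm_parameter_error("max_period must be <= 2000")
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      purity = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ch <- strsplit(seq, "")[[1L]]
  # k-mer distance voting for candidate periods
  k <- 8L
  periods <- integer(0)
  if (n >= 3L * k) {
    pos <- seq_len(n - k + 1L)
    km <- substring(seq, pos, pos + k - 1L)
    dt <- data.table(kmer = km, pos = pos)
    dt <- dt[, if (.N > 1L) list(d = diff(pos)), by = "kmer"]
    if (nrow(dt)) {
      votes <- table(dt$d[dt$d <= max_period])
      # a genuine period p draws roughly one vote per array position
      periods <- as.integer(names(votes))[votes >= pmax(3L, min_copies - 1L)]
    }
  }
  periods <- sort(unique(periods))
  if (length(periods) == 0L) return(empty)

  recs <- list()
  for (p in periods) {
    if (p >= n) next
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    # close match gaps of < p/2 (isolated substitutions break single positions)
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    good <- which(r$values)
    if (length(good) == 0L) next
    # merge good runs separated by short bad runs (an isolated substitution
    # breaks two single positions); a lax tolerance would creep into flanks
    merged <- list(); cur <- c(starts[good[1L]], ends[good[1L]])
    if (length(good) > 1L) for (gi in good[-1L]) {
      if (starts[gi] - cur[2L] - 1L <= max(2L, p %/% 8L)) cur[2L] <- ends[gi]
      else { merged[[length(merged) + 1L]] <- cur; cur <- c(starts[gi], ends[gi]) }
    }
    merged[[length(merged) + 1L]] <- cur
    for (iv in merged) {
      arr_start <- iv[1L]; arr_end <- iv[2L] + p   # include final period
      alen <- arr_end - arr_start + 1L
      copies <- alen / p
      if (copies < min_copies) next
      # per-phase majority consensus
      idx <- arr_start:arr_end
      phase <- (idx - arr_start) %% p
      cons <- vapply(0:(p - 1L), function(ph) {
        tb <- table(ch[idx[phase == ph]])
        names(tb)[which.max(tb)]
      }, character(1L))
      hit <- ch[idx] == cons[phase + 1L]
      # trim edge positions that do not match the tiled consensus
      lo <- 1L; hi <- length(idx)
      while (lo < hi && !hit[lo]) lo <- lo + 1L
      while (hi > lo && !hit[hi]) hi <- hi - 1L
      arr_start <- idx[lo]; arr_end <- idx[hi]
      idx <- idx[lo:hi]; phase <- (idx - arr_start) %% p
      cons <- vapply(0:(p - 1L), function(ph) {
        tb <- table(ch[idx[phase == ph]])
        names(tb)[which.max(tb)]
      }, character(1L))
      alen <- arr_end - arr_start + 1L
      copies <- alen / p
      if (copies < min_copies) next
      purity <- 100 * mean(ch[idx] == cons[phase + 1L])
      if (purity < min_purity) next
      recs[[length(recs) + 1L]] <- data.frame(
        start = arr_start - 1L, end = arr_end, period = p,
        copy_number = copies,
        consensus = smallest_rotation(paste(cons, collapse = "")),
        purity = purity, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  # prefer records covering more positions, then smaller period; drop overlaps
  out <- out[order(-(out$end - out$start), out$period), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(out)) > i &
                  out$start < out$end[i] & out$end > out$start[i])
    keep[ov] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

telomere_rotations <- function(unit = TELOMERE_UNIT) {
  unique(c(smallest_rotation(unit), smallest_rotation(revcomp(unit))))
}

#' Call telomeres at chromosome ends
#'
#' Tandem-repeat records whose consensus matches the telomere unit (TTAGGG
#' or its complement), touching either sequence end within `end_slack`, of
#' total length >= `min_len`. Arrays away from the ends are not telomeres.
#'
#' @param chromosome single-record data.frame.
#' @param min_len minimum telomere length (bp).
#' @param end_slack maximum distance from the sequence end (bp).
#' @return data.frame: `seqid`, `arm` ("p" = start, "q" = end), `start`,
#'   `end`, `length`.
#' @export
call_telomeres <- function(chromosome, min_len = 15000L, end_slack = 1000L) {
  seq <- chromosome$seq[1L]
  L <- nchar(seq)
  # only the terminal windows need scanning
  win <- min(L, max(min_len * 3L, 100000L))
  scan <- function(s, offset) {
    tr <- find_tandem_repeats(s, max_period = 12L, min_copies = 10)
    if (nrow(tr)) tr$start <- tr$start + offset
    if (nrow(tr)) tr$end <- tr$end + offset
    tr
  }
  tr <- rbind(scan(substr(seq, 1L, win), 0L),
              if (L > win) scan(substr(seq, L - win + 1L, L), L - win))
  if (is.null(tr) || nrow(tr) == 0L)
    return(data.frame(seqid = character(), arm = character(),
                      start = integer(), end = integer(), length = integer()))
  tel <- tr[tr$consensus %in% telomere_rotations() &
              (tr$end - tr$start) >= min_len, , drop = FALSE]
  if (nrow(tel) == 0L)
    return(data.frame(seqid = character(), arm = character(),
                      start = integer(), end = integer(), length = integer()))
  tel$arm <- ifelse(tel$start <= end_slack, "p",
                    ifelse(L - tel$end <= end_slack, "q", NA))
  tel <- tel[!is.na(tel$arm), , drop = FALSE]
  if (nrow(tel) == 0L)
    return(data.frame(seqid = character(), arm = character(),
                      start = integer(), end = integer(), length = integer()))
  data.frame(seqid = chromosome$id[1L], arm = tel$arm, start = tel$start,
             end = tel$end, length = tel$end - tel$start,
             stringsAsFactors = FALSE)
}

#' Classify tandem-repeat arrays against a satellite-DNA database
#'
#' Each record's consensus (tried across all rotations and both strands) is
#' aligned against every database entry; the best family with identity
#' strictly above `min_identity` is assigned. Overlapping or adjacent calls
#' of the same family are merged with copy numbers summed.
#'
#' @param repeats data.frame from [find_tandem_repeats()] (with `seqid`
#'   column when multiple sequences are involved).
#' @param sat_db record data.frame of satDNA family sequences.
#' @param min_identity percent identity threshold (strict).
#' @param scoring an [align_scoring()].
#' @param merge_gap maximum distance between merged same-family calls.
#' @return data.frame: `seqid`, `start`, `end`, `family`, `identity`,
#'   `copy_number`.
#' @export
classify_satdna <- function(repeats, sat_db, min_identity = 80,
                            scoring = align_scoring(), merge_gap = 100L) {
  empty <- data.frame(seqid = character(), start = integer(), end = integer(),
                      family = character(), identity = numeric(),
                      copy_number = numeric(), stringsAsFactors = FALSE)
  if (nrow(repeats) == 0L) return(empty)
  if (!"seqid" %in% names(repeats)) repeats$seqid <- "seq"
  calls <- list()
  for (i in seq_len(nrow(repeats))) {
    cons <- repeats$consensus[i]
    best_fam <- NULL; best_id <- -1
    for (j in seq_len(nrow(sat_db))) {
      fam <- sat_db$seq[j]
      # doubling the consensus makes every rotation a substring
      for (qs in c(cons, revcomp(cons))) {
        al <- local_align(fam, strrep(qs, 2L + (nchar(fam) %/% nchar(qs))),
                          scoring)
        cov_id <- if (nchar(fam) > 0)
          100 * al$matches / max(nchar(fam), al$block_length) else 0
        if (cov_id > best_id) { best_id <- cov_id; best_fam <- sat_db$id[j] }
      }
    }
    if (!is.null(best_fam) && best_id > min_identity)
      calls[[length(calls) + 1L]] <- data.frame(
        seqid = repeats$seqid[i], start = repeats$start[i],
        end = repeats$end[i], family = best_fam, identity = best_id,
        copy_number = repeats$copy_number[i], stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  merged <- list()
  for (grp in split(out, list(out$seqid, out$family), drop = TRUE)) {
    grp <- grp[order(grp$start), , drop = FALSE]
    cur <- grp[1L, ]
    for (i in seq_len(nrow(grp))[-1L]) {
      if (grp$start[i] <= cur$end + merge_gap) {
        cur$end <- max(cur$end, grp$end[i])
        cur$copy_number <- cur$copy_number + grp$copy_number[i]
        cur$identity <- max(cur$identity, grp$identity[i])
      } else { merged[[length(merged) + 1L]] <- cur; cur <- grp[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$seqid, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
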