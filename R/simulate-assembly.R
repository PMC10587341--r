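# Degrading a finished genome into an "old" assembly: N-gaps replace known
# intervals and excised segments become unplaced scaffolds, with true spans
# and origins recorded.  Also: diploid regions with heterozygous SNPs and
# long-read simulation with per-read truth alignments.

# sample `n` disjoint intervals with margins on a set of records
sample_intervals <- function(records, n, len_range, margin) {
  taken <- lapply(records$id, function(...) matrix(numeric(0), ncol = 2L))
  names(taken) <- records$id
  out <- list()
  tries <- 0L
  while (length(out) < n && tries < 2000L) {
    tries <- tries + 1L
    ri <- sample.int(nrow(records), 1L, prob = nchar(records$seq))
    L <- nchar(records$seq[ri])
    len <- as.integer(round(runif(1L, len_range[1L], len_range[2L])))
    if (L < len + 2L * margin) next
    start <- as.integer(floor(runif(1L, margin, L - margin - len)))
    iv <- taken[[records$id[ri]]]
    if (nrow(iv) && any(start < iv[, 2L] + margin & start + len > iv[, 1L] - margin))
      next
    taken[[records$id[ri]]] <- rbind(iv, c(start, start + len))
    out[[length(out) + 1L]] <- data.frame(seqid = records$id[ri],
                                          start = start, end = start + len,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) < n)
    imm_parameter_error("could not place %d disjoint intervals", n)
  do.call(rbind, out)
}

#' Degrade a genome into an old assembly with gaps and unplaced scaffolds
#'
#' Random disjoint intervals are replaced by N-runs (gaps) or excised into
#' separate scaffold records; the genome itself plays the role of the "new"
#' assembly. Truth records both the gap spans (old and new coordinates) and
#' the scaffold origins.
#'
#' @param genome record data.frame (the "new", complete assembly).
#' @param n_gaps number of N-gaps to introduce.
#' @param gap_len_range numeric length-2 range of gap lengths (bp).
#' @param n_excised_scaffolds number of segments to excise as scaffolds.
#' @param scaffold_len_range length range for excised scaffolds (bp).
#' @param seed integer seed.
#' @param margin minimum distance between planted intervals and sequence
#'   ends (keeps 10-kb flanks clean).
#' @return list: `old` (degraded assembly), `scaffolds` (records), `truth`
#'   (list with `gaps` and `placements` data.frames).
#' @export
degrade_assembly <- function(genome, n_gaps, gap_len_range = c(100, 1000),
                             n_excised_scaffolds = 0L,
                             scaffold_len_range = c(5000, 20000),
                             seed = 1L, margin = 12000L) {
  with_seed(seed, {
    # reserve slots at the maximum length, then shrink per role so the
    # intervals stay disjoint
    lmax <- max(c(gap_len_range,
                  if (n_excised_scaffolds > 0) scaffold_len_range))
    ivs <- sample_intervals(genome, n_gaps + n_excised_scaffolds,
                            c(lmax, lmax), margin)
    roles <- rep(c("gap", "scaffold"),
                 c(n_gaps, n_excised_scaffolds))[sample.int(nrow(ivs))]
    # re-draw lengths per role, anchored at each interval start
    ivs$end <- ivs$start + ifelse(
      roles == "gap",
      as.integer(round(runif(nrow(ivs), gap_len_range[1L], gap_len_range[2L]))),
      as.integer(round(runif(nrow(ivs), scaffold_len_range[1L],
                             scaffold_len_range[2L]))))
    old <- genome
    gaps <- list(); placements <- list(); scaffolds <- list()
    for (sid in unique(ivs$seqid)) {
      sub <- ivs[ivs$seqid == sid, , drop = FALSE]
      rsub <- roles[ivs$seqid == sid]
      o <- order(sub$start)
      sub <- sub[o, , drop = FALSE]; rsub <- rsub[o]
      seq <- genome$seq[genome$id == sid]
      shift <- 0L
      for (i in seq_len(nrow(sub))) {
        s_new <- sub$start[i]; e_new <- sub$end[i]
        len <- e_new - s_new
        s_old <- s_new - shift
        if (rsub[i] == "gap") {
          substr(seq, s_old + 1L, s_old + len) <- strrep("N", len)
          gaps[[length(gaps) + 1L]] <- data.frame(
            seqid = sid, start = s_old, end = s_old + len,
            new_seqid = sid, new_start = s_new, new_end = e_new,
            span = len, stringsAsFactors = FALSE)
        } else {
          scf_id <- sprintf("scaffold_%d", length(scaffolds) + 1L)
          scaffolds[[length(scaffolds) + 1L]] <- seq_records(
            scf_id, substr(seq, s_old + 1L, s_old + len))
          seq <- paste0(substr(seq, 1L, s_old),
                        substr(seq, s_old + len + 1L, nchar(seq)))
          placements[[length(placements) + 1L]] <- data.frame(
            scaffold = scf_id, seqid = sid, start = s_new, end = e_new,
            strand = "+", stringsAsFactors = FALSE)
          shift <- shift + len
        }
      }
      old$seq[old$id == sid] <- seq
    }
    list(old = old,
         scaffolds = if (length(scaffolds)) do.call(rbind, scaffolds) else NULL,
         truth = list(gaps = if (length(gaps)) do.call(rbind, gaps) else
                        data.frame(),
                      placements = if (length(placements))
                        do.call(rbind, placements) else data.frame()))
  })
}

#' Simulate a diploid region with phased heterozygous SNPs
#'
#' Haplotype 2 differs from haplotype 1 by `Binomial(length, snp_density)`
#' substitutions at recorded sites; truth genotypes are phased `0|1`
#' (haplotype 1 carries the reference allele).
#'
#' @param length region length in bp.
#' @param snp_density per-base heterozygous SNP probability.
#' @param seed integer seed.
#' @param id region name.
#' @return list: `reference` (= haplotype 1 record), `hap1`, `hap2`,
#'   `sites` (phased truth VCF-style data.frame).
#' @export
make_diploid_region <- function(length, snp_density, seed, id = "region") {
  with_seed(seed, {
    h1 <- random_dna(length)
    n_snp <- rbinom(1L, length, snp_density)
    pos <- if (n_snp > 0L) sort(sample.int(length, n_snp)) else integer(0)
    h2 <- h1
    ref <- if (n_snp > 0L) substring(h1, pos, pos) else character(0)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1L), USE.NAMES = FALSE)
    for (i in seq_along(pos)) substr(h2, pos[i], pos[i]) <- alt[i]
    sites <- data.frame(chrom = rep(id, n_snp), pos = pos - 1L,
                        id = rep(".", n_snp), ref = ref, alt = alt,
                        qual = rep(".", n_snp), filter = rep("PASS", n_snp),
                        info = rep(".", n_snp), gt = rep("0|1", n_snp),
                        phased = rep(TRUE, n_snp), allele1 = rep(0L, n_snp),
                        allele2 = rep(1L, n_snp), stringsAsFactors = FALSE)
    list(reference = seq_records(id, h1),
         hap1 = seq_records(paste0(id, "_hap1"), h1),
         hap2 = seq_records(paste0(id, "_hap2"), h2),
         sites = sites)
  })
}

#' Simulate long reads from a pair of haplotypes
#'
#' Reads alternate between the two haplotypes, start uniformly, have
#' geometric-tail lengths around `mean_len`, carry substitution errors at
#' `error_rate`, and may come from either strand. The truth PAF records each
#' read's origin interval, strand and haplotype (tag `hp:i:N`).
#'
#' @param haplotypes list of two single-record data.frames of equal length.
#' @param depth target per-haplotype-pair coverage.
#' @param mean_len mean read length (bp).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param region_id reference name used in the truth PAF.
#' @return list: `reads` (FASTQ-style data.frame), `paf` (truth alignments
#'   with extra column `hap`).
#' @export
simulate_long_reads <- function(haplotypes, depth, mean_len, error_rate,
                                seed, region_id = NULL) {
  h1 <- haplotypes[[1L]]$seq[1L]; h2 <- haplotypes[[2L]]$seq[1L]
  if (nchar(h1) != nchar(h2))
    imm_parameter_error("haplotypes must have equal length (substitution model)")
  L <- nchar(h1)
  rid <- region_id %||% haplotypes[[1L]]$id[1L]
  with_seed(seed, {
    n_reads <- ceiling(depth * L / mean_len)
    min_len <- max(200L, as.integer(mean_len / 2))
    q <- min(40L, as.integer(round(-10 * log10(max(error_rate, 1e-4)))))
    qchar <- rawToChar(as.raw(33L + q))
    reads <- vector("list", n_reads); paf <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      hap <- ((i - 1L) %% 2L) + 1L
      len <- min_len + rgeom(1L, 1 / max(1, mean_len - min_len))
      len <- min(len, L)
      start <- as.integer(floor(runif(1L, 0, L - len + 1)))
      src <- if (hap == 1L) h1 else h2
      frag <- substr(src, start + 1L, start + len)
      n_err <- rbinom(1L, len, error_rate)
      if (n_err > 0L) frag <- mutate_positions(frag, sample.int(len, n_err))
      strand <- sample(c("+", "-"), 1L)
      out_seq <- if (strand == "+") frag else revcomp(frag)
      id <- sprintf("read_%05d", i)
      reads[[i]] <- data.frame(id = id, desc = "", seq = out_seq,
                               qual = strrep(qchar, len),
                               stringsAsFactors = FALSE)
      paf[[i]] <- data.frame(qname = id, qlen = len, qstart = 0L, qend = len,
                             strand = strand, tname = rid, tlen = L,
                             tstart = start, tend = start + len,
                             matches = len - n_err, block_len = len,
                             mapq = 60L, tags = sprintf("hp:i:%d", hap),
                             hap = hap, stringsAsFactors = FALSE)
    }
    list(reads = do.call(rbind, reads), paf = do.call(rbind, paf))
  })
}
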