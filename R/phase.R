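# Read-backed phasing of a diploid region: heterozygous-SNP pileup from
# colinear read alignments, a read-by-site allele matrix, weighted
# minimum-error-correction (wMEC) phasing with exact column DP on small
# active sets, read partitioning and reference-guided haplotype consensus,
# plus transcript-backed MHC gene validation.

# per-read base vector over reference coordinates (substitution-only model:
# truth/realigned PAF rows are colinear)
read_ref_bases <- function(read_seq, paf_row) {
  s <- if (paf_row$strand == "+") read_seq else revcomp(read_seq)
  list(start = paf_row$tstart, bases = strsplit(s, "")[[1L]])
}

#' Call heterozygous SNPs from aligned reads
#'
#' For each reference position covered at depth >= `min_depth`, a site is
#' reported when exactly two alleles each reach fraction >= `min_alt_frac`
#' (tri-allelic columns are skipped with a warning; homozygous columns are
#' never called).
#'
#' @param reads FASTQ-style data.frame (`id`, `seq`).
#' @param alignments PAF data.frame with colinear read placements.
#' @param region single-record reference data.frame.
#' @param min_depth minimum coverage.
#' @param min_alt_frac minimum fraction for each of the two alleles.
#' @return data.frame: `chrom`, `pos` (0-based), `ref`, `alt`, `depth`,
#'   `alt_fraction`.
#' @export
pileup_het_snps <- function(reads, alignments, region, min_depth = 10L,
                            min_alt_frac = 0.25) {
  ref <- strsplit(region$seq[1L], "")[[1L]]
  L <- length(ref)
  depth <- integer(L)
  mism <- list()
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    rb <- read_ref_bases(reads$seq[match(a$qname, reads$id)], a)
    span <- (a$tstart + 1L):a$tend
    depth[span] <- depth[span] + 1L
    d <- which(rb$bases != ref[span])
    if (length(d))
      mism[[length(mism) + 1L]] <- data.frame(pos = span[d],
                                              base = rb$bases[d],
                                              stringsAsFactors = FALSE)
  }
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), depth = integer(),
                    alt_fraction = numeric(), stringsAsFactors = FALSE)
  if (length(mism) == 0L) return(out)
  mm <- rbindlist(mism)
  counts <- mm[, list(n = .N), by = c("pos", "base")]
  for (p in unique(counts$pos)) {
    dp <- depth[p]
    if (dp < min_depth) next
    sub <- counts[counts$pos == p, ]
    nref <- dp - sum(sub$n)
    alleles <- c(setNames(nref, ref[p]), setNames(sub$n, sub$base))
    frac <- alleles / dp
    major <- names(frac)[frac >= min_alt_frac]
    if (length(major) < 2L) next
    if (length(major) > 2L) {
      imm_log("warn", "tri-allelic site at %d skipped", p - 1L)
      next
    }
    alt <- setdiff(major, ref[p])
    if (length(alt) != 1L) next   # both major alleles non-ref: skip
    out <- rbind(out, data.frame(
      chrom = region$id[1L], pos = p - 1L, ref = ref[p], alt = alt,
      depth = dp, alt_fraction = unname(frac[alt]), stringsAsFactors = FALSE))
  }
  out[order(out$pos), ]
}

#' Build the read-by-site allele matrix
#'
#' Rows are reads, columns are het sites ordered by position; entries are 0
#' (ref allele), 1 (alt allele) or NA (site not covered or a third allele).
#'
#' @param reads FASTQ-style data.frame.
#' @param alignments PAF data.frame.
#' @param sites het-site data.frame ([pileup_het_snps()] or a truth VCF).
#' @param weights optional per-entry weight (default 1).
#' @return list of class `allele_matrix`: `m` (integer matrix), `w` (weight
#'   matrix), `pos` (0-based site positions), `reads` (row ids).
#' @export
read_allele_matrix <- function(reads, alignments, sites, weights = NULL) {
  pos <- sites$pos
  m <- matrix(NA_integer_, nrow = nrow(alignments), ncol = length(pos),
              dimnames = list(alignments$qname, NULL))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    rb <- read_ref_bases(reads$seq[match(a$qname, reads$id)], a)
    cov <- which(pos >= a$tstart & pos < a$tend)
    if (length(cov) == 0L) next
    b <- rb$bases[pos[cov] - a$tstart + 1L]
    m[i, cov] <- ifelse(b == sites$ref[cov], 0L,
                        ifelse(b == sites$alt[cov], 1L, NA_integer_))
  }
  keep <- rowSums(!is.na(m)) > 0L
  m <- m[keep, , drop = FALSE]
  w <- if (is.null(weights)) (m * 0L + 1L) else weights[keep, , drop = FALSE]
  structure(list(m = m, w = w, pos = pos, reads = rownames(m)),
            class = "allele_matrix")
}

# column cost of a read-side assignment (bitmask over active reads):
# haplotypes are complementary, so cost = min over the hap0 allele
col_cost <- function(alleles, weights, side_bits) {
  # side_bits: logical matrix n_masks x n_active (TRUE -> haplotype 1)
  a1 <- alleles == 1L
  c0 <- side_bits %*% (weights * as.numeric(!a1)) +            # hap1 gets allele1
    (!side_bits) %*% (weights * as.numeric(a1))                # hap0 gets allele0
  c1 <- side_bits %*% (weights * as.numeric(a1)) +
    (!side_bits) %*% (weights * as.numeric(!a1))
  pmin(c0, c1)
}

#' Phase an allele matrix by weighted minimum error correction
#'
#' Connected components of the read-overlap graph become phase blocks.
#' Within a block, when no column has more than `max_exact_reads` active
#' reads an exact dynamic program over columns (state = bipartition of the
#' active reads) yields the optimal MEC; larger instances fall back to a
#' greedy score-based partitioning whose MEC cost is still evaluated
#' exactly for the reported bipartition. hap0 carries allele 0 at the first
#' column of each block; hap1 is its complement.
#'
#' @param matrix an `allele_matrix`.
#' @param max_exact_reads active-read bound for the exact DP.
#' @return list of `phase_block` objects: `columns`, `pos`, `hap0`, `hap1`,
#'   `assignment` (named 0/1/NA per read), `mec`.
#' @export
phase_wmec <- function(matrix, max_exact_reads = 15L) {
  m <- matrix$m; w <- matrix$w
  if (is.null(m) || ncol(m) == 0L || nrow(m) == 0L) return(list())
  nc <- ncol(m)
  # connected components over columns via shared reads
  comp <- seq_len(nc)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(m))) {
      cols <- which(!is.na(m[r, ]))
      if (length(cols) > 1L) {
        tgt <- min(comp[cols])
        if (any(comp[cols] != tgt)) { comp[cols] <- tgt; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  blocks <- list()
  for (cid in unique(comp)) {
    cols <- which(comp == cid)
    bm <- m[, cols, drop = FALSE]; bw <- w[, cols, drop = FALSE]
    rows <- which(rowSums(!is.na(bm)) > 0L)
    bm <- bm[rows, , drop = FALSE]; bw <- bw[rows, , drop = FALSE]
    active <- lapply(seq_len(ncol(bm)), function(j) which(!is.na(bm[, j])))
    if (max(lengths(active)) <= max_exact_reads)
      bl <- phase_block_exact(bm, bw, active)
    else
      bl <- phase_block_greedy(bm, bw)
    bl$columns <- cols
    bl$pos <- matrix$pos[cols]
    # convention: hap0 carries allele 0 at the first column
    if (substr(bl$hap0, 1L, 1L) == "1") {
      tmp <- bl$hap0; bl$hap0 <- bl$hap1; bl$hap1 <- tmp
      bl$assignment <- 1L - bl$assignment
    }
    blocks[[length(blocks) + 1L]] <- structure(bl, class = "phase_block")
  }
  blocks[order(vapply(blocks, function(b) b$pos[1L], numeric(1L)))]
}

# exact column DP; state = bitmask over the column's active reads
phase_block_exact <- function(bm, bw, active) {
  ncb <- ncol(bm)
  layers <- vector("list", ncb)
  prev_active <- integer(0)
  prev_f <- NULL
  for (j in seq_len(ncb)) {
    act <- active[[j]]
    n_act <- length(act)
    masks <- 0:(2^n_act - 1L)
    bits <- matrix(FALSE, length(masks), n_act)
    for (b in seq_len(n_act)) bits[, b] <- bitwAnd(bitwShiftR(masks, b - 1L), 1L) == 1L
    cost <- as.numeric(col_cost(bm[act, j], bw[act, j], bits))
    if (j == 1L) {
      f <- cost
      back <- rep(NA_integer_, length(masks))
    } else {
      shared <- intersect(prev_active, act)
      if (length(shared) == 0L) {
        best_prev <- which.min(prev_f)
        f <- cost + prev_f[best_prev]
        back <- rep(best_prev, length(masks))
      } else {
        pi <- match(shared, prev_active); ci <- match(shared, act)
        proj <- function(msk, idx) {
          p <- 0L
          for (k in seq_along(idx))
            p <- p + bitwShiftL(bitwAnd(bitwShiftR(msk, idx[k] - 1L), 1L), k - 1L)
          p
        }
        prev_masks <- 0:(length(prev_f) - 1L)
        pproj <- vapply(prev_masks, proj, integer(1L), idx = pi)
        gmin <- tapply(prev_f, pproj, min)
        garg <- tapply(seq_along(prev_f), pproj, function(ix) ix[which.min(prev_f[ix])])
        cproj <- vapply(masks, proj, integer(1L), idx = ci)
        key <- as.character(cproj)
        f <- cost + as.numeric(gmin[key])
        back <- as.integer(garg[key])
      }
    }
    layers[[j]] <- list(act = act, back = back, f = f)
    prev_active <- act
    prev_f <- f
  }
  # traceback
  assignment <- rep(NA_integer_, nrow(bm))
  j <- ncb
  state <- which.min(layers[[j]]$f)
  mec <- layers[[j]]$f[state]
  while (j >= 1L) {
    act <- layers[[j]]$act
    msk <- state - 1L
    for (k in seq_along(act)) {
      bit <- bitwAnd(bitwShiftR(msk, k - 1L), 1L)
      assignment[act[k]] <- bit
    }
    state <- layers[[j]]$back[state]
    j <- j - 1L
    if (j >= 1L && is.na(state)) break
  }
  finish_block(bm, bw, assignment, mec_known = mec)
}

# greedy partitioning: reads in order of first covered column, each assigned
# to the side minimizing weighted mismatch against the running consensus
phase_block_greedy <- function(bm, bw) {
  nr <- nrow(bm); ncb <- ncol(bm)
  votes <- matrix(0, 2L, ncb)   # weighted allele-1 "mass" per hap
  tot <- matrix(0, 2L, ncb)
  assignment <- rep(NA_integer_, nr)
  ord <- order(apply(bm, 1L, function(r) which(!is.na(r))[1L]))
  for (r in ord) {
    cols <- which(!is.na(bm[r, ]))
    hap_allele <- function(h) ifelse(tot[h, cols] > 0,
                                     as.integer(votes[h, cols] / tot[h, cols] > 0.5),
                                     NA_integer_)
    mism <- function(h) {
      ha <- hap_allele(h)
      sum(bw[r, cols] * (ha != bm[r, cols]), na.rm = TRUE)
    }
    side <- if (mism(1L) <= mism(2L)) 1L else 2L
    assignment[r] <- side - 1L
    votes[side, cols] <- votes[side, cols] + bw[r, cols] * bm[r, cols]
    tot[side, cols] <- tot[side, cols] + bw[r, cols]
  }
  finish_block(bm, bw, assignment)
}

# derive per-column haplotype alleles (weighted majority within each side)
# and the exact MEC cost of the reported bipartition
finish_block <- function(bm, bw, assignment, mec_known = NULL) {
  ncb <- ncol(bm)
  hap0 <- integer(ncb)
  mec <- 0
  for (j in seq_len(ncb)) {
    act <- which(!is.na(bm[, j]))
    s0 <- act[assignment[act] == 0L]; s1 <- act[assignment[act] == 1L]
    w1_0 <- sum(bw[s0, j] * bm[s0, j]); w_0 <- sum(bw[s0, j])
    w1_1 <- sum(bw[s1, j] * bm[s1, j]); w_1 <- sum(bw[s1, j])
    # hap0 allele a, hap1 gets 1-a; choose a minimizing column cost
    cost_a0 <- w1_0 + (w_1 - w1_1)
    cost_a1 <- (w_0 - w1_0) + w1_1
    a <- if (cost_a1 < cost_a0) 1L else 0L
    hap0[j] <- a
    mec <- mec + min(cost_a0, cost_a1)
  }
  list(hap0 = paste(hap0, collapse = ""),
       hap1 = paste(1L - hap0, collapse = ""),
       assignment = setNames(assignment, rownames(bm)),
       mec = mec_known %||% mec)
}

#' Assign reads to haplotypes of phased blocks
#'
#' Each read goes to the haplotype minimizing its weighted mismatches; exact
#' ties stay unassigned.
#'
#' @param matrix an `allele_matrix`.
#' @param blocks list from [phase_wmec()].
#' @return data.frame: `read`, `block`, `hap` (0/1/NA).
#' @export
partition_reads <- function(matrix, blocks) {
  rows <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    h0 <- as.integer(strsplit(b$hap0, "")[[1L]])
    for (r in matrix$reads) {
      rv <- matrix$m[r, b$columns]
      cov <- which(!is.na(rv))
      if (length(cov) == 0L) next
      wv <- matrix$w[r, b$columns]
      d0 <- sum(wv[cov] * (rv[cov] != h0[cov]))
      d1 <- sum(wv[cov] * (rv[cov] != (1L - h0[cov])))
      rows[[length(rows) + 1L]] <- data.frame(
        read = r, block = bi,
        hap = if (d0 < d1) 0L else if (d1 < d0) 1L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(read = character(), block = integer(), hap = integer()))
  do.call(rbind, rows)
}

#' Reference-guided haplotype consensus
#'
#' Per-position weighted majority over the assigned reads; positions without
#' coverage take the reference base.
#'
#' @param reads FASTQ-style data.frame.
#' @param alignments PAF data.frame.
#' @param read_ids reads assigned to this haplotype.
#' @param region single-record reference.
#' @param id output record id.
#' @return single-record data.frame (haplotig over the reference span).
#' @export
haplotype_consensus <- function(reads, alignments, read_ids, region,
                                id = "haplotig") {
  ref <- strsplit(region$seq[1L], "")[[1L]]
  L <- length(ref)
  counts <- matrix(0L, 5L, L, dimnames = list(c(DNA_BASES, "N"), NULL))
  al <- alignments[alignments$qname %in% read_ids, , drop = FALSE]
  for (i in seq_len(nrow(al))) {
    a <- al[i, ]
    rb <- read_ref_bases(reads$seq[match(a$qname, reads$id)], a)
    span <- (a$tstart + 1L):a$tend
    bi <- match(rb$bases, rownames(counts))
    ok <- !is.na(bi)
    idx <- cbind(bi[ok], span[ok])
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
  }
  cov <- colSums(counts)
  cons <- ref
  covered <- which(cov > 0L)
  if (length(covered))
    cons[covered] <- rownames(counts)[apply(counts[, covered, drop = FALSE],
                                            2L, which.max)]
  seq_records(id, paste(cons, collapse = ""))
}

#' Validate MHC gene loci with haplotigs and full-length transcripts
#'
#' Step 1: gene alleles are mapped to the haplotigs; hits above
#' `min_locus_identity` become candidate loci (overlapping hits of the same
#' gene merge). Step 2: transcripts are mapped to the gene alleles to select
#' candidate transcripts per gene. Step 3: a candidate transcript is
#' credible for a locus iff it aligns essentially full-length with overall
#' identity (matches over transcript length) >= `min_tx_identity`. Step 4:
#' a locus is validated iff supported by >= `min_transcripts` credible
#' transcripts.
#'
#' @param gene_alleles record data.frame of gene allele sequences (gene name
#'   taken as the id prefix before the last underscore, or the full id).
#' @param haplotigs record data.frame.
#' @param transcripts record data.frame.
#' @param min_locus_identity step-1 identity threshold (strict >).
#' @param min_tx_identity step-3 overall identity threshold (inclusive >=).
#' @param min_transcripts validation support threshold.
#' @param scoring an [align_scoring()].
#' @return data.frame: `haplotig`, `gene`, `start`, `end`, `n_transcripts`,
#'   `validated`.
#' @export
validate_mhc_genes <- function(gene_alleles, haplotigs, transcripts,
                               min_locus_identity = 80, min_tx_identity = 95,
                               min_transcripts = 2L,
                               scoring = align_scoring()) {
  if (is.null(haplotigs) || nrow(haplotigs) == 0L)
    imm_validation_error("no haplotigs supplied")
  gene_of <- function(id) sub("_[^_]*$", "", id)
  idx <- build_seed_index(haplotigs, k = 13L)
  # step 1: candidate loci
  loci <- list()
  for (i in seq_len(nrow(gene_alleles))) {
    al <- map_query(gene_alleles[i, ], idx, haplotigs, scoring)
    al <- al[al$identity > min_locus_identity &
               100 * (al$qend - al$qstart) / al$qlen > 80, , drop = FALSE]
    if (nrow(al) == 0L) next
    al$gene <- gene_of(gene_alleles$id[i])
    loci[[length(loci) + 1L]] <- al[, c("tname", "tstart", "tend", "gene")]
  }
  if (length(loci) == 0L)
    return(data.frame(haplotig = character(), gene = character(),
                      start = integer(), end = integer(),
                      n_transcripts = integer(), validated = logical()))
  lc <- do.call(rbind, loci)
  merged <- list()
  for (grp in split(lc, list(lc$tname, lc$gene), drop = TRUE)) {
    grp <- grp[order(grp$tstart), , drop = FALSE]
    cur <- grp[1L, ]
    for (i in seq_len(nrow(grp))[-1L]) {
      if (grp$tstart[i] < cur$tend) cur$tend <- max(cur$tend, grp$tend[i])
      else { merged[[length(merged) + 1L]] <- cur; cur <- grp[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  loci_df <- do.call(rbind, merged)
  # step 2: candidate transcripts per gene
  gidx <- build_seed_index(gene_alleles, k = 13L)
  tx_gene <- list()
  for (i in seq_len(nrow(transcripts))) {
    al <- map_query(transcripts[i, ], gidx, gene_alleles, scoring)
    if (nrow(al) == 0L) next
    tx_gene[[transcripts$id[i]]] <- unique(gene_of(al$tname))
  }
  # step 3 + 4: credible transcripts per locus
  loci_df$n_transcripts <- 0L
  for (t in names(tx_gene)) {
    tx <- transcripts[transcripts$id == t, ]
    al <- map_query(tx, idx, haplotigs, scoring)
    if (nrow(al) == 0L) next
    al$overall_identity <- 100 * al$matches / al$qlen
    for (k in seq_len(nrow(al))) {
      if (al$overall_identity[k] < min_tx_identity) next
      hit <- which(loci_df$tname == al$tname[k] &
                     loci_df$gene %in% tx_gene[[t]] &
                     al$tstart[k] < loci_df$tend &
                     al$tend[k] > loci_df$tstart)
      if (length(hit))
        loci_df$n_transcripts[hit[1L]] <- loci_df$n_transcripts[hit[1L]] + 1L
    }
  }
  data.frame(haplotig = loci_df$tname, gene = loci_df$gene,
             start = loci_df$tstart, end = loci_df$tend,
             n_transcripts = loci_df$n_transcripts,
             validated = loci_df$n_transcripts >= min_transcripts,
             stringsAsFactors = FALSE)
}

#' Export phased blocks as a phased VCF data.frame
#'
#' @param blocks list from [phase_wmec()].
#' @param sites het-site data.frame used to build the matrix.
#' @return data.frame acceptable to [write_vcf()], with `PS` phase-set tags.
#' @export
blocks_to_vcf <- function(blocks, sites) {
  rows <- lapply(blocks, function(b) {
    h0 <- strsplit(b$hap0, "")[[1L]]
    s <- sites[match(b$pos, sites$pos), ]
    data.frame(chrom = s$chrom, pos = s$pos, id = ".", ref = s$ref,
               alt = s$alt, qual = ".", filter = "PASS", info = ".",
               gt = paste0(h0, "|", 1L - as.integer(h0)),
               phased = TRUE, ps = b$pos[1L] + 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
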