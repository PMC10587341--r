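# GFF3 / PAF / VCF / BED readers and writers.  All coordinate conversion
# between on-disk dialects and the internal 0-based half-open convention is
# centralized here: GFF3 and VCF are 1-based inclusive on disk, PAF and BED
# are already 0-based half-open.

#' Read a GFF3 file
#'
#' Start/end are converted from 1-based inclusive to 0-based half-open.
#' The `ID` attribute is required and surfaced as column `id`.
#'
#' @param path GFF3 file.
#' @return data.frame: `seqid`, `source`, `type`, `start`, `end`, `score`,
#'   `strand`, `phase`, `attributes`, `id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) imm_format_error("file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) imm_format_error("GFF3 '%s' has no feature lines", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L))
    imm_format_error("GFF3 '%s': expected 9 tab-separated columns", path)
  m <- do.call(rbind, parts)
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1))
    imm_format_error("GFF3 '%s': non-integer coordinates", path)
  if (any(start1 > end1))
    imm_format_error("GFF3 '%s': start > end at line %d", path,
                     which(start1 > end1)[1L])
  if (any(!grepl("(^|;)ID=", m[, 9L])))
    imm_validation_error("GFF3 '%s': feature without ID attribute", path)
  id <- sub(".*?(^|;)ID=([^;]+).*", "\\2", m[, 9L], perl = TRUE)
  data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
             start = start1 - 1L, end = end1, score = m[, 6L],
             strand = m[, 7L], phase = m[, 8L], attributes = m[, 9L],
             id = id, stringsAsFactors = FALSE)
}

#' Write features to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive on-disk dialect.
#'
#' @param features data.frame as returned by [read_gff3()] (column
#'   `attributes` must contain an `ID=`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  if (any(!grepl("(^|;)ID=", features$attributes)))
    imm_validation_error("feature without ID attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(features$seqid, features$source, features$type,
                   features$start + 1L, features$end, features$score,
                   features$strand, features$phase, features$attributes,
                   sep = "\t"), con)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' The 12 mandatory columns are parsed; extra columns are preserved verbatim
#' in `tags`. Percent identity is computable as `100 * matches / block_len`.
#'
#' @param path PAF file.
#' @return data.frame: `qname,qlen,qstart,qend,strand,tname,tlen,tstart,tend,
#'   matches,block_len,mapq,tags`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) imm_format_error("file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) imm_format_error("PAF '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12L))
    imm_format_error("PAF '%s': fewer than 12 columns at line %d", path,
                     which(lengths(parts) < 12L)[1L])
  num_cols <- c(2L, 3L, 4L, 7L, 8L, 9L, 10L, 11L, 12L)
  grab <- function(i) vapply(parts, `[[`, character(1L), i)
  nums <- lapply(num_cols, function(i) suppressWarnings(as.numeric(grab(i))))
  if (anyNA(unlist(nums)))
    imm_format_error("PAF '%s': non-integer coordinate field", path)
  data.frame(qname = grab(1L), qlen = nums[[1L]], qstart = nums[[2L]],
             qend = nums[[3L]], strand = grab(5L), tname = grab(6L),
             tlen = nums[[4L]], tstart = nums[[5L]], tend = nums[[6L]],
             matches = nums[[7L]], block_len = nums[[8L]], mapq = nums[[9L]],
             tags = vapply(parts, function(p)
               paste(p[-seq_len(12L)], collapse = "\t"), character(1L)),
             stringsAsFactors = FALSE)
}

#' Write alignments to PAF
#'
#' @param aln data.frame as returned by [read_paf()] or [map_query()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  tags <- if ("tags" %in% names(aln)) aln$tags else ""
  ln <- paste(aln$qname, aln$qlen, aln$qstart, aln$qend, aln$strand,
              aln$tname, aln$tlen, aln$tstart, aln$tend, aln$matches,
              aln$block_len, aln$mapq %||% 255L, sep = "\t")
  ln <- ifelse(nzchar(tags), paste(ln, tags, sep = "\t"), ln)
  writeLines(ln, path)
  invisible(path)
}

#' Percent identity of PAF-style alignments
#'
#' Defined as `100 * matches / block_len` (aligned columns including gaps).
#'
#' @param aln alignment data.frame.
#' @return numeric vector of percent identities in `[0, 100]`.
#' @export
paf_identity <- function(aln) {
  ifelse(aln$block_len > 0, 100 * aln$matches / aln$block_len, 0)
}

#' Read a single-sample VCF
#'
#' POS is converted to 0-based. The GT field is parsed, including the phased
#' `|` notation.
#'
#' @param path VCF file.
#' @return data.frame: `chrom`, `pos` (0-based), `id`, `ref`, `alt`, `qual`,
#'   `filter`, `info`, `gt`, `phased`, `allele1`, `allele2`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) imm_format_error("file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) imm_format_error("VCF '%s' has no records", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 10L))
    imm_format_error("VCF '%s': records must carry FORMAT and one sample", path)
  grab <- function(i) vapply(parts, `[[`, character(1L), i)
  pos1 <- suppressWarnings(as.integer(grab(2L)))
  if (anyNA(pos1)) imm_format_error("VCF '%s': non-integer POS", path)
  fmt <- strsplit(grab(9L), ":", fixed = TRUE)
  smp <- strsplit(grab(10L), ":", fixed = TRUE)
  gt <- mapply(function(f, s) {
    i <- match("GT", f)
    if (is.na(i) || i > length(s)) NA_character_ else s[[i]]
  }, fmt, smp)
  alt <- grab(5L)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi & is.na(gt)))
    imm_validation_error("VCF '%s': multi-allelic record without GT", path)
  phased <- grepl("|", gt, fixed = TRUE)
  al <- strsplit(gt, "[/|]")
  data.frame(chrom = grab(1L), pos = pos1 - 1L, id = grab(3L), ref = grab(4L),
             alt = alt, qual = grab(6L), filter = grab(7L), info = grab(8L),
             gt = gt, phased = phased,
             allele1 = suppressWarnings(as.integer(vapply(al, `[`, character(1L), 1L))),
             allele2 = suppressWarnings(as.integer(vapply(al, function(a)
               if (length(a) > 1L) a[2L] else NA_character_, character(1L)))),
             stringsAsFactors = FALSE)
}

#' Write single-sample SNP records to VCF
#'
#' @param variants data.frame as returned by [read_vcf()].
#' @param path output file.
#' @param sample sample name for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = "sample1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  fmt <- if ("ps" %in% names(variants)) "GT:PS" else "GT"
  smp <- if ("ps" %in% names(variants))
    paste(variants$gt, variants$ps, sep = ":") else variants$gt
  writeLines(paste(variants$chrom, variants$pos + 1L,
                   variants$id %||% ".", variants$ref, variants$alt,
                   variants$qual %||% ".", variants$filter %||% "PASS",
                   variants$info %||% ".", fmt, smp, sep = "\t"), con)
  invisible(path)
}

#' Read a BED file (0-based half-open, native)
#'
#' @param path BED file.
#' @return data.frame: `seqid`, `start`, `end`, plus `name` when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) imm_format_error("file '%s' not found", path)
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("seqid", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df
}

#' Write intervals to BED
#'
#' @param intervals data.frame with `seqid`, `start`, `end` and optional
#'   further columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a generic TSV with header
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
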