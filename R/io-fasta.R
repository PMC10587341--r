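# FASTA / FASTQ I/O.  Records travel as a plain data.frame with columns
# id / desc / seq (and qual for FASTQ); sequences are uppercase DNA over
# {A,C,G,T,N}.  Parsing is delegated to Biostrings; validation (unique ids,
# alphabet) is enforced here.

#' Read a FASTA file
#'
#' Sequences are uppercased on read; lowercase input is accepted, characters
#' outside {A,C,G,T,N} (including U) are rejected.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) imm_format_error("file '%s' not found", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) imm_format_error(
                    "malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(set) == 0L) imm_format_error("FASTA '%s' contains no records", path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(id))) imm_validation_error("FASTA '%s' has an empty record id", path)
  if (anyDuplicated(id))
    imm_validation_error("duplicate id '%s' in '%s'", id[duplicated(id)][1L], path)
  seqs <- toupper(as.character(set))
  validate_dna_alphabet(seqs, id)
  if (any(nchar(seqs) < 1L)) imm_validation_error("zero-length sequence in '%s'", path)
  seq_records(id, seqs, desc)
}

#' Write records to FASTA
#'
#' @param records data.frame with `id`, `seq` and optional `desc`.
#' @param path output file.
#' @param wrap_width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  validate_records(records)
  set <- Biostrings::BStringSet(records$seq)
  desc <- if ("desc" %in% names(records)) records$desc else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap_width))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `desc`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) imm_format_error("file '%s' not found", path)
  set <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) imm_format_error("malformed FASTQ '%s': %s", path,
                                         conditionMessage(e)))
  if (length(set) == 0L) imm_format_error("FASTQ '%s' contains no records", path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(id))
    imm_validation_error("duplicate id '%s' in '%s'", id[duplicated(id)][1L], path)
  out <- seq_records(id, toupper(as.character(set)),
                     ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""))
  out$qual <- as.character(Biostrings::quality(set))
  out
}

#' Write records to FASTQ
#'
#' @param records data.frame with `id`, `seq` and optional `qual` (constant
#'   quality "I" is used when absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  validate_records(records)
  qual <- if ("qual" %in% names(records)) records$qual else
    vapply(nchar(records$seq), function(n) strrep("I", n), character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  invisible(path)
}

validate_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records)))
    imm_validation_error("records must be a data.frame with columns id and seq")
  if (nrow(records) == 0L) imm_validation_error("no records to write")
  if (any(!nzchar(records$id))) imm_validation_error("empty record id")
  if (anyDuplicated(records$id))
    imm_validation_error("duplicate record id '%s'",
                         records$id[duplicated(records$id)][1L])
  validate_dna_alphabet(records$seq, records$id)
  invisible(TRUE)
}

# fetch a 0-based half-open slice of a record's sequence
seq_slice <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}
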