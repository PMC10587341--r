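# Shared low-level helpers: sequence manipulation, seeded RNG scoping,
# validation and error signalling.

DNA_BASES <- c("A", "C", "G", "T")
RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"
TELOMERE_UNIT <- "TTAGGG"
IMM_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRD", "TRG")

imm_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "imm_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

imm_format_error <- function(msg, ...) imm_error("imm_format_error", msg, ...)
imm_validation_error <- function(msg, ...) imm_error("imm_validation_error", msg, ...)
imm_parameter_error <- function(msg, ...) imm_error("imm_parameter_error", msg, ...)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the session RNG temporarily seeded to `seed` and restores
#' the previous RNG state afterwards, so generators never leak global random
#' state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    imm_parameter_error("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse-complement a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a DNA string in frame 0
#'
#' Trailing bases beyond the last complete codon are ignored; codons
#' containing N translate to X.
#'
#' @param x character scalar DNA.
#' @return amino-acid string ("*" marks stops).
#' @export
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n, 3L)
  aa <- Biostrings::GENETIC_CODE[substring(x, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Random DNA with cattle-like GC content
#'
#' Spacer/intergenic background used throughout the synthetic-data module:
#' i.i.d. bases at GC 0.42 by default. Draws from the current RNG stream;
#' callers wrap it in [with_seed()].
#'
#' @param n length in bp.
#' @param gc GC fraction.
#' @return DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# mutate k random positions of a string to a different base (current RNG)
mutate_positions <- function(seq, positions) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
  }
  paste(s, collapse = "")
}

# substitution errors at a per-base rate (current RNG)
add_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  mutate_positions(seq, sample.int(n, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a sequence-record data.frame
#'
#' The plain container used for all sequence sets: columns `id`, `desc`,
#' `seq`.
#'
#' @param id record identifiers.
#' @param seq uppercase DNA strings.
#' @param desc optional descriptions.
#' @return data.frame with columns `id`, `desc`, `seq`.
#' @export
seq_records <- function(id, seq, desc = "") {
  data.frame(id = as.character(id),
             desc = rep(as.character(desc), length.out = length(id)),
             seq = as.character(seq), stringsAsFactors = FALSE)
}

validate_dna_alphabet <- function(seqs, ids, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad))
    imm_validation_error("sequence '%s' contains characters outside {A,C,G,T%s}",
                         ids[bad[1L]], if (allow_n) ",N" else "")
  invisible(TRUE)
}
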