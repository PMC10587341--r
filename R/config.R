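# Flat key-value configuration: every tunable threshold of the pipeline has a
# key and a default.  Files are plain "key = value" text, one pair per line.

#' Default pipeline configuration
#'
#' Returns the full set of tunable thresholds with their defaults. Units are
#' percent for identities/fractions named `*_pct`/`min_identity`/`min_fraction`,
#' base pairs for lengths, raw alignment score for `min_v_score`.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    # alignment
    kmer_size = 13L, match = 2L, mismatch = -4L, gap_open = -4L,
    gap_extend = -2L, min_seed_hits = 2L, unique_ratio = 1.2,
    # segment finding / classification
    min_identity = 80, min_coverage = 90, rss_min_score = 0.7,
    rss_window = 60L, rss_spacer_tol = 1L,
    # gap closure / scaffold placement
    gap_flank_len = 10000L, gap_min_identity = 90, gap_max_span = 1e7,
    scaffold_min_fraction = 50, scaffold_min_piece_identity = 90,
    scaffold_min_piece_len = 50L,
    # telomere / satDNA / tandem repeats
    telomere_min_len = 15000L, telomere_end_slack = 1000L,
    satdna_min_identity = 80, trf_max_period = 2000L, trf_min_copies = 3,
    trf_min_purity = 85,
    # QV
    qv_cap = 99,
    # phasing / MHC validation
    het_min_depth = 10L, het_min_alt_frac = 0.25, phase_max_exact_reads = 15L,
    mhc_locus_min_identity = 80, mhc_transcript_min_identity = 95,
    mhc_min_transcripts = 2L,
    # repertoire
    d_min_match = 8L, min_v_score = 100, ultralong_cdr3_aa = 40L
  )
}

#' Read a flat key-value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored. Values
#' parseable as numbers become numeric. Unknown keys are kept; known keys
#' override the defaults.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return named list merged over [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) imm_format_error("config file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) imm_format_error("malformed config line: '%s'", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Write a configuration list to a flat key-value file
#'
#' @param cfg named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE),
                            character(1L))), path)
  invisible(path)
}

#' Short digest of a configuration (for log lines)
#'
#' A small order-independent FNV-style hash of the `key=value` pairs, so runs
#' can be matched to the exact thresholds used.
#'
#' @param cfg named list.
#' @return 8-hex-digit string.
#' @export
config_digest <- function(cfg) {
  txt <- paste(sort(sprintf("%s=%s", names(cfg),
                            vapply(cfg, function(v) format(v, digits = 15),
                                   character(1L)))), collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 216613626
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777.0 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

imm_log <- function(level, msg, ...) {
  lv <- getOption("immloci.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (ranks[[level]] >= ranks[[lv]])
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    sprintf(msg, ...)))
  invisible(NULL)
}
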