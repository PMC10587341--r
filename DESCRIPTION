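Package: immloci
Title: Annotation of Immune Gene Loci, Assembly QC, Haplotype Phasing and
    Repertoire Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-assembly analysis toolkit for the adaptive immune loci of
    vertebrate genomes. Locates immunoglobulin (IG) and T-cell receptor (TR)
    V/D/J/C gene segments in an assembly, detects recombination signal
    sequences (RSS), classifies segment functionality under IMGT-style
    criteria, and compresses locus organization into cassette-repeat
    formulas. Also provides assembly quality control (N50, gap census,
    consensus QV, telomere and satellite-DNA annotation), two-assembly gap
    closure and scaffold placement, read-backed haplotype phasing of
    MHC-like regions by weighted minimum error correction with
    transcript-based gene validation, and full-length V(D)J transcript
    repertoire profiling. A synthetic-data module generates genomes, reads
    and transcripts with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
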