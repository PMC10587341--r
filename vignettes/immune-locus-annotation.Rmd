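---
title: "Annotating immune gene loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating immune gene loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immloci)
```

# The problem

The immunoglobulin (IG) and T-cell receptor (TR) loci of vertebrate genomes
are large arrays of short gene segments — variable (V), diversity (D),
joining (J) and constant (C) — that are somatically recombined during B- and
T-cell maturation. Annotating them in a genome assembly means (i) locating
every segment against a reference library, (ii) deciding whether each copy
is functional (F), a pseudogene (P), or an open reading frame with defective
recombination elements (ORF), and (iii) summarizing the locus organization,
which in cattle includes tandem cassettes such as three D–J–C repeats in
TRB. Around the loci themselves sit the standard post-assembly questions:
how good is the assembly (N50, consensus quality, gaps, telomeres,
satellite DNA), which gaps of an older assembly does it close, can the
highly polymorphic MHC region be phased into haplotypes, and what does the
expressed V(D)J repertoire look like in full-length transcripts.

`immloci` implements this whole post-assembly layer as a reusable, tested
pipeline. Because the genome-wide results of any particular animal are not
reproducible at desk scale, every stage is exercised against a
synthetic-data module that plants ground truth: the tests then ask for
*exact* recovery, not plausibility.

# Segment annotation

## Locating segments

Library entries are mapped with a self-contained k-mer-seeded aligner
(`build_seed_index()`, `map_query()`): canonical k-mers (k = 13 by default,
configurable between 8 and 21) seed clusters by target, strand and
diagonal; clusters with at least two distinct seed positions are extended
by a banded affine-gap local alignment (Gotoh) written in C++. The band
adapts to the diagonal spread of the seeds, so error-free matches run in a
narrow band while indel-rich matches widen it. Percent identity is defined
PAF-style as matches over aligned columns including gaps; the default
scoring is match +2, mismatch −4, gap open −4, gap extend −2, a
conventional short-segment preset. Ties in the DP are broken
deterministically (highest score, then smallest target start, then
smallest query start), which makes every downstream result reproducible.

Hits with identity ≥ 80% and query coverage ≥ 90% (both configurable) are
kept; overlapping hits of the same segment type collapse to the best score,
so near-duplicate library alleles do not produce double annotations.
Reverse-strand loci are reported in locus orientation.

## RSS detection

Recombination signal sequences are scored against the canonical consensus
(heptamer `CACAGTG`, nonamer `ACAAAAACC`) in a 60-bp flank window — 3′ of
V, 5′ of J, both flanks of D — allowing spacers of 12 or 23 bp ± 1. The
score is the mean of the heptamer and nonamer consensus-match fractions; a
candidate below 0.7 counts as absent. These are deliberately simple,
transparent statistics rather than a trained position weight matrix: on
random flanks the false-positive rate at the 0.7 cutoff is a few percent
(measured in the test suite), and on planted canonical signals the score
is exactly 1.

## Functionality classification

The IMGT-style decision is codified as an ordered cascade:

1. **P (pseudogene)** — the V coding region lacks an ATG start, contains an
   in-frame stop, or carries an indel-induced frameshift relative to its
   library entry (detected from the alignment CIGAR).
2. **ORF** — the coding region is intact but the RSS is missing or scores
   below threshold.
3. **F (functional)** — otherwise.

D segments are short and read in multiple frames, so they are assessed on
their RSS flanks only (both must pass); J segments likewise on their 5′
RSS; C genes carry no RSS and are classified F in this model. Splice-site
checks are part of the cascade's contract but are vacuous here because the
synthetic loci are intron-free; the extension point is the
`bad_splice` defect flag. The exact published criteria figure behind this
cascade is not publicly quoted, so the cascade mirrors the standard IMGT
functionality definitions; all thresholds are configuration keys.

## Locus formulas

`build_locus_structure()` compresses the ordered segment-type sequence:
runs collapse to `(TYPE)n`, and tandem cassettes — the unit with the most
contiguous copies, ties to the longer unit, scanned greedily from the left
— render as `[unit]k`, e.g. `(TRBV)8-[TRBD-(TRBJ)6/7-TRBC]3`. Copy-count
variation is allowed at one unit element. A varying element's counts are
rendered as the *shortest cyclic generator* of the per-copy count vector:
counts (6, 7, 6) render `6/7` and expansion cycles the listed values, so
`expand_formula()` is an exact inverse for every formula the package
emits. Counts that are not prefix-cyclic (say 6, 6, 7) render in full
(`6/6/7`) rather than lose information.

# Assembly QC

`contig_n50()` follows the standard definition (largest length still
covering half the assembly — verified in tests against a brute-force scan).
`estimate_qv()` converts homozygous error *events* (SNPs plus indels, not
affected bases) into a Phred consensus quality, `−10·log10(n/size)`, with a
cap (default 99) when no errors are observed; counting events is what
reproduces the published Q51 from the published counts. The published indel
error *rate* is not derivable from the printed counts and genome size, so
only the SNP rate and the combined QV are treated as reproducible numbers.

The tandem-repeat finder is a purpose-built simplification of the classic
tools: k-mer distance voting proposes candidate periods, the lag-p match
profile delimits arrays (merging breaks no longer than max(2, p/8), so
isolated substitutions join but random flanks do not creep in), a per-phase
majority gives the consensus (normalized to its lexicographically smallest
rotation), and purity is the fraction of array bases matching the tiled
consensus. Records need ≥ 3 copies and ≥ 85% purity by default. Telomeres
are the subset of arrays whose consensus matches `TTAGGG` (or its
complement), touch a sequence end within 1 kb, and span ≥ 15 kb; satellite
arrays are assigned to a family database by aligning the doubled consensus
(rotation-invariant) on both strands, keeping families at > 80% identity
(strict), and merging adjacent same-family calls with copy numbers summed.

# Gap closure and scaffold placement

For each maximal N-run of the old assembly, 10-kb non-N flanks (truncated
at sequence ends and neighboring gaps) are mapped to the new assembly. A
gap is **closed** iff both flanks exceed 90% identity (strict), land on the
same target sequence and strand in consistent order, and imply a span of
at most 10 Mb — the operational form of "within one contig", replacing
manual checking; different targets are **conflicting**, anything else
**unresolved**. Unplaced scaffolds are split at their N-runs; pieces above
90% identity qualify, and a scaffold is **placed** when qualifying matches
exceed 50% of its non-N length on a single, consistently ordered target.
Because the published wording leaves the "50% alignment identity" measure
ambiguous, it is implemented as coverage × identity (matching bases over
scaffold length), with both knobs configurable. Chance micro-matches are
excluded by requiring half of a flank or piece to align.

# MHC phasing and validation

Heterozygous SNPs are called from colinear long-read alignments: a site
needs depth ≥ 10 and exactly two alleles each at fraction ≥ 0.25.
Phasing solves the weighted minimum-error-correction (wMEC) problem that
underlies read-backed phasers: connected components of the read-overlap
graph become blocks; within a block an exact dynamic program over columns
(state = bipartition of the column's active reads) gives the optimal MEC
whenever no column has more than 15 active reads, verified in the tests
against exhaustive bipartition; beyond that a greedy score-based
partitioning takes over (the reported MEC is still evaluated exactly for
the returned bipartition). At 30× coverage the greedy path recovers planted
haplotypes without error in the fixed-seed suites. By convention hap0
carries allele 0 at the first column of each block; hap1 is its complement.

Haplotigs are reference-guided consensi (per-position weighted majority
over each read set, reference base where uncovered) rather than de novo
assemblies: consensus suffices to test the phasing contract at desk scale.
MHC gene validation follows a four-step transcript cross-check: map gene
alleles to haplotigs (candidate loci, identity > 80%), map transcripts to
gene alleles, keep a transcript iff it aligns essentially full length to a
candidate locus at overall identity ≥ 95% (inclusive — overall identity is
matches over transcript length, which folds "fully aligned" and identity
into one number), and validate a locus iff ≥ 2 credible transcripts
support it ("multiple" is operationalized as 2, configurable).

# Repertoire profiling

Full-length transcripts are assigned the best V and J by alignment score
(ties: higher identity, then name), with the locus fixed by the V call and
J/C restricted to it — chimeric V/J combinations are rejected rather than
scored. D calls (heavy-type loci) require ≥ 8 consecutive exactly matching
bases between the V and J alignment ends; short D segments make
alignment-score calls unstable, whereas run-length matching is
deterministic. The CDR3 spans the library-annotated V 2nd-CYS codon through
the codon preceding the J F/W-G-X-G motif; both positions are projected
through the alignment CIGARs, and the motif must actually be present on
the transcript. A transcript is productive iff its CDR3 is in frame and
the V-through-J translation is stop-free. The "ultralong" CDRH3 report
flags receptors at ≥ 40 aa (the literature uses "ultra-long" without a
printed cutoff; 40 aa separates the cattle ultralong class cleanly from
conventional junctions and is configurable).

# The synthetic-data module

The generator is first-class, tested code: every downstream stage is
validated against what it plants.

* **Libraries** — V entries are ATG-initiated, stop-free ORFs of 288 ± 30
  bp with cysteines at IMGT-like codon positions (1st-CYS near codon 22,
  2nd-CYS three codons from the segment end, position recorded); J entries
  embed an F/W-G-X-G motif at a recorded offset; D entries are 16–32 bp
  (long enough for k = 13 seeding); C entries ~300 bp.
* **Loci** — segments embedded in order with random spacer DNA (i.i.d.
  bases at GC 0.42, cattle-like — a neutral background that produces
  spurious RSS hits only at the measured few-percent rate), each V/D/J
  flanked by canonical RSS following the 12/23 rule (heavy-type loci use a
  23-bp V spacer, light-type 12 bp). Defects are injected per segment:
  a forced in-frame stop or a 1-bp frameshift (V only, truth P), or a
  degraded RSS (V/D/J, truth ORF). Reverse-strand loci are emitted
  reverse-complemented with transformed truth coordinates.
* **Assembly degradation** — disjoint intervals become N-gaps (old
  coordinates, spans and new-assembly origins recorded) or are excised as
  unplaced scaffolds.
* **Diploid regions and reads** — haplotype 2 differs from haplotype 1 by
  Binomial(L, density) substitutions at recorded sites; reads alternate
  haplotypes, start uniformly, have geometric-tail lengths, carry
  substitution errors at a flat rate, and come from either strand with
  their true intervals in a PAF.
* **Transcripts** — trimmed V + N + (D) + N + trimmed J + C with segment
  usage from explicit weights; with probability 0.95 the junction is
  adjusted to be in frame and stop-free, a proxy for the selection that
  makes real repertoires predominantly productive.

What the generator does **not** emulate: realistic long-read error
profiles (homopolymer indels), somatic hypermutation, alternative splicing,
introns in C genes, nested loci sharing V segments, and allele-level
sequence diversity within a library. Passing the planted-recovery suites
therefore demonstrates that the algorithms are correct under their stated
models — substitution-dominated errors, colinear alignments, intron-free
segments — not that they are robust to every artifact of real data.

# Numerical choices and problem sizes

All randomized operations take an explicit integer seed and restore the
session RNG (`with_seed()`); identical seeds give byte-identical outputs.
Degenerate inputs are defined rather than accidental: empty alignments
score 0, an empty segment list gives an empty structure/formula, a read
equally close to both haplotypes stays unassigned, zero errors return the
QV cap.

The test and acceptance suites run at sizes chosen to make exhaustive
checking feasible while keeping every code path honest: chromosomes of
20–250 kb, 100-kb diploid regions at SNP density 10⁻³ with 30× reads of
mean 20 kb, repertoires of 2,000 transcripts, MEC instances of ≤ 12 reads
for the brute-force cross-check, and 300-pair random suites for the
aligner-versus-oracle comparisons.

# Limitations

* The functionality cascade cannot be validated against the original
  manual criteria figure; its extension points (splice checks, J motif
  absence, C exon structure) are documented but unexercised.
* The aligner is a segment-scale tool: whole-genome all-vs-all alignment
  and multi-target chaining are out of scope.
* Phasing calls SNPs from one read set; merging call sets across
  technologies is not modeled.
* The tandem-repeat finder targets clean arrays; highly diverged or
  higher-order repeat structures (as in real centromeres) will fragment.
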