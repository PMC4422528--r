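---
title: "Annotation lift-over and inheritance-model variant filtering: methods"
author: "enulift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation lift-over and inheritance-model variant filtering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ENU (N-ethyl-N-nitrosourea) mutagenesis screens produce mutant mouse lines
whose causative point mutations must be pinned down by sequencing. The most
suitable strain for a screen is often not the strain of the standard,
well-annotated reference assembly: mapping reads to a closely related,
strain-matched assembly gives better alignments and far fewer spurious
variants, but such alternative assemblies carry little or no gene
annotation, and their coordinates differ from the annotated assembly.

`enulift` addresses both halves of this problem for cohorts of mutant lines
sequenced against an un-annotated target assembly:

1. **Annotation lift-over** — exon sequences of the annotated source
   assembly are placed on the target assembly by best single-hit local
   alignment; exon intervals and whole-gene spans are derived and attached
   to variant records as VCF INFO tags.
2. **Variant filtration** — candidate causative mutations are isolated per
   line by a cascade of inheritance-model genotype selection, cross-line
   privacy, exon/gene containment, one-variant-per-gene exclusion, optional
   linkage-region restriction, and ENU-type base-change flagging.

A deterministic simulator generates complete synthetic studies (genome
pair, exon catalog, multi-line cohort with planted causative variants) so
that every step can be validated against a known truth.

# Exon and gene lift-over

## The built-in aligner

Production use of this approach typically delegates alignment to an
external aligner emitting 12-column tabular hits, which `enulift` accepts
via `readTabularHits()` and `selectBest()`. The package also ships its own
k-mer seed-and-extend aligner so that the complete pipeline runs
self-contained and is testable at desk scale:

* **Seeding.** Every k-mer of the target genome (default `k = 16`; k-mers
  containing N are skipped) is indexed in a sorted seed table. Query k-mers
  are looked up on both strands (the reverse complement is resolved at
  query time).
* **Chaining.** Seed matches are grouped into candidate loci by chromosome
  and diagonal; seeds whose diagonals differ by at most the band width
  (default 16) join one cluster, which tolerates small indels between
  assemblies.
* **Extension.** Each candidate locus is extended by a local
  (Smith–Waterman) alignment with affine gaps over a window padded around
  the cluster. Scoring is match +1, mismatch −2, gap open −4, gap extend
  −1 (a gap of length L costs 4 + L). A full traceback yields exact match,
  mismatch, gap-open and column counts.
* **Best hit.** The single highest-scoring alignment is kept, mirroring a
  one-hit-per-query aligner configuration. Ties break by percent identity,
  then alignment length, then lowest (chromosome name, start), then plus
  strand — a total order, so the result never depends on input order
  (`selectBest()` applies the same order to external hit lists). Hits
  covering less than `minCoverage` (default 0.7) of the query are
  discarded; exons without an acceptable hit are dropped and counted, not
  errors.

Percent identity is `100 * matches / alignment columns` (the tabular
format's convention), reported to 2 decimals.

## Catalog orientation and feature strand

Exon catalog sequences are stored in **forward-genome orientation** — the
orientation of the source chromosome's plus strand — with the `strand`
column recording the gene's direction. Under this convention the strand of
a lifted feature is the *composition* of the gene strand with the hit
strand: two minuses give plus. (Had sequences been stored
transcript-oriented, the hit strand alone would carry the gene's target
orientation; the composition rule requires the forward-genome convention,
which the simulator emits and `readExonTable()` documents.)

## Gene spans

A gene's span runs from the outermost lifted exon start to the outermost
lifted exon end — covering exons and introns — on the gene's majority
chromosome; exons lifted elsewhere are excluded from the span and logged.
When the majority is tied, the lexicographically smallest chromosome name
wins; the gene strand is the majority exon strand with ties resolving to
plus. These are deliberate deterministic tie-breaks for a situation (split
lifts) that a sound lift leaves rare.

## Identity bookkeeping

`identitySummary()` reports per-source-chromosome hit counts, minimum and
mean identity plus the overall mean. All best hits are kept regardless of
identity — low-identity hits are recorded, not filtered — so divergence
between assemblies is visible rather than silently discarded.

# Annotation

Five INFO tags are attached per variant record, testing containment of the
single reference base at POS (a deletion's REF span is deliberately not
used — the simplest defensible convention, stated here):

| tag | content |
|-----|---------|
| EID | exon IDs of lifted exons containing the position |
| GID | gene IDs of the exons in EID |
| GIR | gene IDs of all lifted gene spans containing the position |
| GNM | gene names of the exons in EID |
| GNR | gene names of the spans in GIR |

Tags with empty value lists are omitted; lists are deduplicated and
sorted, and tags are replaced (not appended), so annotation is idempotent
and output is byte-stable. Empty gene names are dropped from GNM/GNR.

# The filtering cascade

Per line, in order, with counts recorded after every stage:

1. **Privacy + inheritance model.** Keep sites where every sample of the
   line shows the expected genotype — homozygous alternative (`1/1`) for
   recessive lines, heterozygous (`0/1`) for dominant lines — and every
   sample of every *other* line is homozygous reference. Genotypes are
   compared as unordered, unphased allele-index pairs.
2. **Exon/gene containment.** `level = "exon"` requires a non-empty EID;
   `level = "gene"` requires a non-empty GIR.
3. **One variant per gene.** A site is excluded iff *any* gene span
   containing it holds two or more sites of the input set — ENU is highly
   unlikely to hit one gene twice, so multi-hit genes indicate strain
   artifacts. Exclusion is evaluated once against the input set, not
   re-iterated.
4. **Linkage regions.** Where a line has experimentally established
   linkage regions, sites outside them are dropped; without regions the
   stage is the identity and the summary marks it not applicable.
5. **ENU typing.** The predominant ENU-induced changes, T>C, A>G, T>A and
   A>T (a reverse-complement-closed set), are flagged (`ENU=1`) and
   counted; flagging is annotate-and-report by default because ENU counts
   are a reporting column, not a hard filter — `enuOnly = TRUE` turns it
   into one.

Design choices where the design was genuinely open:

* **Missing genotypes** are strict by default: a missing call anywhere
  among the tested samples excludes the site, mirroring the requirement
  that *all* individuals show the genotype. A lenient mode treats missing
  calls in *other* lines as compatible with homozygous reference, which
  suits practical low-coverage data; a missing call in the target line
  always excludes.
* **Multi-allelic sites** are tested literally against the expected
  allele-index pair: `2/2` does not satisfy recessive `1/1`. ENU typing is
  evaluated for the alt allele the line's expected genotype carries
  (allele index 1).
* **Overlapping genes**: a site inside two spans is excluded if *either*
  gene is multi-hit — the conservative reading.
* **Dominant lines** test only the exact `0/1` pattern; no additional
  constraint on hom-alt carriers is imposed beyond other lines being
  `0/0`.

Stage monotonicity (each stage's output is a subset of its input) and
cross-line exclusivity (privacy makes candidate lists disjoint across
lines) hold by construction and are enforced by tests.

# The simulator

`simConfig()` defaults encode the study design the package targets: 8
mutant lines sequenced with 4, 4, 4, 4, 2, 2, 2, 2 animals; inheritance
recessive, dominant, dominant, recessive, then dominant; linkage regions
available for lines 4 and 7 only; 5000 shared strain variants; 200 private
noise variants per line; 1% source-to-target divergence. The genome scale
— 4 chromosomes of 200 kb with 40 non-overlapping stranded genes — is a
desk-scale choice that keeps the full pipeline under two minutes on one
CPU while leaving variant sites sparse (<1% of bases).

The generated study has three variant classes on the target assembly:

* **Shared strain variants**, `1/1` in every sample of every line —
  natural differences between the experimental strain and the reference,
  which privacy must remove.
* **Private noise variants** per line, carrying the line's expected
  genotype in *all* its samples (the worst case for the privacy filter,
  which random genotypes would make too easy). They are placed 70%
  intergenic, 20% intronic and 10% as exonic pairs inside one gene, to
  exercise the containment and one-per-gene stages specifically. Noise
  avoids every line's planted gene so that recovery of the plant is
  decidable.
* **One planted causative variant per line**: exonic (≥5 bases from exon
  edges, so end-trimming by local alignment cannot uncover it), an
  ENU-type allele on a T/A reference base, expected genotype in the line,
  `0/0` elsewhere.

Divergence is i.i.d. substitution; by default there are no indels, so
source and target coordinates coincide and lift-over correctness is
checkable against the identity map. An optional indel mode shifts
downstream coordinates and records them in a coordinate map
(`mapSourceToTarget()`, NA for deleted bases).

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: read-level errors and coverage (inputs begin
at the VCF), genotype-calling uncertainty, repetitive sequence (uniform
random DNA makes exons essentially unique, flattering the aligner),
realistic mutational spectra or CpG structure, and structural variation
beyond small indels. The filters under test are spectrum-agnostic except
the four-pair ENU flag, which the simulator plants explicitly.

# Numerical choices and degenerate inputs

* Intervals are `GRanges` (1-based, closed) everywhere inside the package;
  BED (0-based half-open) and VCF/tabular (1-based) conversions happen
  only at the read/write boundary.
* `k = 16` makes random seed collisions vanishingly rare (4^16 ≈ 4·10^9)
  while tolerating ~1–2% divergence over typical exon lengths;
  `minCoverage = 0.7` rejects fragmentary placements.
* Expected mean hit identity under divergence d is 100·(1−d); local
  alignment trims mismatches within a couple of bases of query ends,
  biasing identity upward by O(d/L) per exon — negligible against the
  sampling error of a few hundred exons, and verified within three
  standard errors by the test suite.
* Empty inputs degrade explicitly: an empty hit list yields an empty
  identity table with an undefined overall mean (flagged), zero-record
  VCFs round-trip, and a line with no linkage region reports the stage as
  not applicable rather than zero.
* All randomness flows from the single configuration seed; repeated runs
  are byte-identical, and output serialization (sorted INFO tags, sorted
  values, fixed header) is deterministic by construction.

# Validation problem sizes

The test suite validates the cascade against a brute-force oracle on 100
randomized cohorts (up to 50 sites × 16 samples, 2–4 lines, random
level/missing/ENU-only options); runs the full pipeline on the default
8-line design (5000 shared + 1600 noise sites, d = 0.01) expecting 8/8
planted variants recovered with zero shared-variant leakage; checks
self-lift exactness and the divergence sweep d ∈ {0.005, 0.01, 0.02} on
2 × 100 kb genomes with 20–25 genes; and exercises byte-level format
fidelity end to end. `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed.

# Known limitations

* The built-in aligner is designed for closely related assemblies (a few
  percent divergence, small indels); it is not a spliced or whole-genome
  aligner, and repeat-rich regions resolve to a single best hit by
  tie-break rather than being flagged ambiguous.
* Containment is positional: a deletion overlapping an exon boundary only
  through its REF span is not called exonic.
* Functional consequence (missense/synonymous) is out of scope; the
  cascade ranks positions, not effects.
* Known-variant databases tied to the source assembly's coordinates are
  deliberately not consulted; cross-line privacy plays that role within
  the cohort.
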