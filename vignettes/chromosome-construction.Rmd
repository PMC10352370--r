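---
title: "Reference-guided chromosome construction and fossil-gene screening: methods"
author: "chromStitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided chromosome construction and fossil-gene screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromStitch)
```

# Overview

chromStitch re-implements, as a tested and reusable pipeline, the kind of
bespoke computation used to lift a draft primate assembly to chromosome
level with a close relative as the guide: draft contigs are mapped to the
reference, filtered, checked for chimeric misjoins against mate-pair read
concordance, split where unsupported, ordered and oriented along the
reference, stitched with gaps proportional to their reference distance, and
the result is audited (uncovered reference regions, assembly metrics,
interchromosomal translocations against another assembly, and a translated
six-frame screen for endogenous viral elements, EVEs). Everything runs on
synthetic genomes with recorded ground truth, so the whole pipeline can be
validated end to end without any sequencing download.

This vignette explains the models and procedures, the parameters that
matter, the design choices made where the underlying method was
under-specified, and what the synthetic validation does and does not show.

# The chromosome builder

## Inputs and coordinate conventions

The builder consumes contigs (FASTA), a reference genome (FASTA),
contig-to-reference alignments (PAF, the minimap2 interchange), and paired
short-read alignments on contig coordinates (a paired-alignment TSV or a
minimal SAM). All internal coordinates are 0-based half-open; the 1-based
inclusive formats (AGP, GFF3) are converted at the I/O boundary only, and
this convention is property-tested by round trips.

## Filtration

Contigs shorter than `min_contig_len` (default 10 kb; a contig of exactly
10 kb is kept) are excluded, as are alignments whose reference span is
contained in the span of a larger contig's alignment. A contig losing all
of its alignments to containment is excluded as redundant.

## Breakpoint classification and validation

A contig's alignments fall into one of three mapping classes: a single
consistent placement; multiple segments on one chromosome; or segments on
different chromosomes. Adjacent query segments nominate a candidate
breakpoint when they land on different chromosomes, or on the same
chromosome with a reference gap above `far_distance`. The method this
reimplements never quantified "far from each other"; the default here is
100 kb, configurable.

The candidate breakpoint position is the midpoint of the unaligned query
interval between the two segments (the shared coordinate when they abut).
Each candidate is then confronted with the read pairs: a pair is concordant
when both mates map to the same contig in convergent (FR) orientation with
an insert inside `insert_mean * (1 +/- insert_tol)` — by default 2600 bp
+/- 30%, the mate-pair library geometry the pipeline models — and it
*supports* a junction when its inner span physically bridges the position
(first mate ends before it, second mate starts after it). Junctions with
fewer than `min_support` (default 3) spanning concordant pairs are split; a
junction with no reads at all is always split. A real chimeric join cannot
be bridged by any genuine pair, which is exactly the signal exploited.
Mate-pair chemistry is assumed normalised to FR orientation upstream.

## Ordering, gap sizing, merging

Each contig is placed on the chromosome of its highest-identity alignment
(ties: lower reference start, then name), spanned by the chain of its
blocks there. Placements are sorted by reference start. Between consecutive
placements at reference distance `d > 0`, a gap of `round(gap_scale * d)` N
bases is inserted; `gap_scale` defaults to 1 — the simplest reading of a
gap "proportional to" the mapping distance, and the one that makes rendered
coordinates track the reference. Overlapping placements are merged at the
sequence level: the overlap suffix of the left sequence is aligned globally
to the overlap prefix of the right one, and at identity of at least
`overlap_merge_identity` (default 0.95) the two are joined cutting at the
overlap midpoint, so merged length equals the sum minus the overlap.
Whether the original method built a consensus or trimmed is unstated;
trimming at the midpoint with an identity guard was chosen because it is
deterministic and conserves bases verifiably. Disagreeing overlaps are left
abutting with a zero-length gap and a conflict flag.

Regions where three or more placements mutually overlap have no reliable
automatic order; the contigs involved are flagged for manual review and
excluded from the layout (the upstream method resolved these by eye in a
genome browser; no algorithmic description exists, so only the flagging is
automated). Two placements with identical spans are reported as ambiguous
and resolved by keeping the alphabetically first contig.

The layout serialises as AGP v2.1 plus FASTA; an independent renderer
re-builds the FASTA from the AGP and the component sequences, and the test
suite asserts byte equality.

## Uncovered regions, gap patching, rescue

Reference intervals covered by no placement are reported after extension by
`flank_ext` (default 1 kb) on both sides, clamped at chromosome ends, with
touching extensions merged — these are the regions a local re-assembly
would target. Local assembly itself is out of scope; the builder accepts
externally produced candidate sequences and patches gaps with them: a
candidate anchoring to both flanks (identity at least
`overlap_merge_identity` over `flank_ext` bases) fills the gap with its
interior; a candidate anchoring to one flank shortens it. Unplaced contigs
are retained in the final set when they carry at least one gene, exon or
CDS feature in the supplied annotation.

# Assembly metrics

N50 uses the sorted-descending cumulative rule with the boundary at
"greater or equal to half", and always returns a member of the input;
"longer than 100 kb" is strict. Genome fraction is the union of aligned
reference spans over the reference length. Feature coverage classifies each
gene/exon/CDS as complete (span inside the covered union), partial
(intersecting), or missing. Library totals for fixed-length paired
libraries are `pairs * 2 * read_length`; trimmed variable-length libraries
are not reproducible from read counts alone, so their printed totals enter
the table as data.

# Translocation detection

Given a whole-genome alignment of two chromosome-level assemblies, each
query chromosome is assigned its homolog by majority of aligned bases
(robust to naming). Blocks aligning a query chromosome to a non-homologous
target are merged when co-linear — ascending on both genomes for forward
blocks, descending on the target for reverse ones — within `merge_dist`
(default 50 kb) on both genomes; merged fragments of at least `min_len`
(default 10 kb, the size rule of the comparison this mirrors) become links.
A reciprocal swap is seen twice, once from each genome's coordinates;
links are canonically ordered and two links of the same chromosome pair
whose spans agree within `mirror_tol` (default 25 kb, covering coordinate
shift from nearby indels) are counted once, matching how arcs are counted
in circular plots. The merge distance bridges aligner fragmentation without
fusing events that the simulator keeps at least 60 kb apart on full-size
chromosomes; on much smaller toy genomes it should be scaled down
accordingly.

# The translated (TBLASTN-like) EVE screen

The screen searches protein queries against all six reading frames of a
genome. Stages, mirroring the classic translated-search architecture:

1. **Translation.** Three forward frames and three frames of the reverse
   complement; stops become `*`, ambiguous codons `X`; initiator-codon
   special-casing is disabled so translation is position-independent. An
   exact coordinate map converts any amino-acid span back to its genomic
   nucleotide span (tested for all frames).
2. **Seeding.** Exact `word_size`-mer matches (default 3 aa) between query
   and frame; a candidate requires two word hits on the same
   query-subject diagonal within 64 aa. On unrelated sequence,
   co-diagonal double hits are rare; diverged homologous regions produce
   them densely.
3. **Ungapped pre-score.** Each candidate diagonal is scored by its best
   ungapped segment (maximum subarray of per-residue substitution scores);
   candidates below `ungapped_min` (default 40) are discarded. This is the
   usual staging between word hits and gapped extension; matches that
   reach significance only through heavily gapped alignments with no
   ungapped core can be missed, which is acceptable for the pseudogenised,
   indel-light insertions targeted here.
4. **Gapped verification.** Smith-Waterman local alignment with affine
   gaps (BLOSUM62, gap open 11 / extend 1) over a window of a few query
   lengths around the surviving seeds, implemented in C++. By default a
   stop codon hard-breaks the subject: alignments never extend through
   `*`, reflecting pseudogenised targets; a readthrough mode scores `*` as
   a -4 mismatch instead.
5. **Statistics and filters.** Raw scores convert to bit scores and
   E-values by the Karlin-Altschul closed form `E = K m n exp(-lambda S)`
   with the common gapped BLOSUM62(11,1) parameters lambda = 0.267,
   K = 0.041; the search space is the raw product of query length and
   total translated letters, with no length correction — a documented
   simplification adequate at the megabase scales used here. Hits must
   have query coverage strictly above `qcov_min` (default 0.5) and
   E-value strictly below `evalue_max` (default 0.05).

The original screen reported only the tool name and these two thresholds;
matrix, gap costs and statistics defaults are this package's choices. Hits
of one query on one chromosome and strand merge into *sites* within
1 kb — "site" had no published definition, and merging also unifies
frameshifted copies that surface as same-locus hits in different frames.
The per-chromosome summary reports counts, density per Mb, a chi-square
statistic against a length-proportional expectation, and the coefficient
of variation of density, quantifying how uniformly sites are spread.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every claim in the test suite is computed.

* **Reference**: uniform-composition random chromosomes (default 3 x
  500 kb).
* **Sample genome**: reciprocal interchromosomal translocations
  (equal-length swaps, default 3 x 15 kb, hence length-neutral), per-base
  substitutions (default 0.1%, a plausible within-genus divergence), and
  deletions (default 4 x 5 kb) which later surface as uncovered regions.
  Variant spans stay 15 kb clear of chromosome ends and 12 kb clear of
  each other (swaps up to 60 kb apart where chromosomes allow), so every
  inter-variant segment can host a contig passing the 10 kb filter and
  distinct swap events are never bridged by co-linear merging.
* **Contigs**: normal lengths (default 60 +/- 12 kb) tiling each
  chromosome, abutting or overlapping by up to 300 bp; fragment boundaries
  are forced at deletion junctions and translocation edges, where real
  assemblies break; tails under 10 kb are absorbed into the previous
  fragment. Chimeras concatenate two fragments from different chromosomes
  (and different reference loci) with no linker, giving a sharp, testable
  join offset; `misjoin_rate` is realised as a deterministic
  `round(rate * n_fragments)` chimera count. Optional contained duplicates
  and deliberately short fragments exercise the filtration rules. The
  default configuration yields about 25 fragments, 5 chimeras and 20
  contigs over 1.5 Mb.
* **Read pairs**: drawn per contiguous source segment at the requested
  coverage (Poisson counts), insert from a normal truncated to
  `insert_mean * (1 +/- insert_tol)` with sd set to half the tolerance
  band (so the window is about +/- 2 sd), FR orientation, default 10x.
  Because pairs are drawn within contiguous source segments, no pair ever
  spans a chimeric join — such fragments are physically impossible — while
  true junctions get ordinary spanning coverage.
* **Truth alignments**: contig placements are emitted directly as PAF
  against the reference (mapped through deletions and translocation
  content sources), so tests need no external aligner; the records match
  what an aligner would ideally report.
* **EVE loci**: a protein is reverse-translated with uniform-random
  synonymous codons (codon bias is irrelevant to a protein-space search),
  mutated to the requested amino-acid divergence, and inserted on a random
  strand at loci at least 10 kb apart.

What the generator does **not** emulate: sequencing error and quality
models, platform-specific artefacts, repeats and segmental duplications,
diploid heterozygosity, GC bias, and real codon usage. Passing tests
therefore demonstrate the correctness of the algorithms under their stated
assumptions — sharp breakpoints, noise-free alignments, unique sequence —
not performance on real sequencing data, where alignment fuzz and repeats
dominate the difficulty.

# Numerical choices and degenerate inputs

* Breakpoint at the midpoint of the unaligned query interval; ties and
  zero-length intervals use the shared coordinate; positions are clamped
  strictly inside the contig.
* Best placement ties break by lower reference start, then contig name;
  identical spans are reported and resolved alphabetically.
* An overlap engulfing a whole sequence cannot be merged; inside the
  automatic layout it is flagged as a conflict and the placements abut
  (the standalone merge operation treats it as an error, since containment
  filtration should have removed it).
* Empty inputs return empty results everywhere except where a statistic is
  undefined (N50 of nothing is an error).
* Derived RNG streams: each simulation stage draws from a seed derived
  from the configuration seed by a fixed integer map, so stages are
  independently reproducible and all derived seeds stay within 32-bit
  range.

# Problem sizes

The test suite and the acceptance script use 3 x 500 kb genomes for the
builder, translocation and EVE scenarios (about 20 contigs at 10x pair
coverage; a 1.5 Mb scan genome with 24 planted sites for a 500-aa query)
and 2 x 120 kb genomes for unit scenarios. These sizes keep the full suite
under a minute of compute while every code path — including the seed,
pre-score and gapped stages of the scanner — is exercised with non-trivial
candidate counts.

# Known limitations

* The builder trusts the reference arrangement: genuine rearrangements in
  the sample relative to the reference are re-arranged back into reference
  order (the translocation detector exists precisely to report them
  afterwards).
* Gap lengths are reference distances; expansion or contraction in the
  sample is invisible to the layout.
* The scanner's statistics omit BLAST's composition-based and
  length-corrected refinements, and the two-hit plus ungapped staging can
  miss weak, heavily gapped homologies.
* Manual resolution of complex structural-variation regions is only
  flagged, never attempted.

# A worked example

```{r demo, eval = FALSE}
library(chromStitch)
res <- runDemo(out_dir = "demo_out", sim = simConfig(seed = 1))
res$summary
res$validation
```

The output bundle contains the rendered chromosomes (FASTA + AGP v2.1),
the uncovered-region BED, breakpoint and validation tables, translocation
links and EVE site tables, all reproducible bit-for-bit from the seed.
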