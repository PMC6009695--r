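---
title: "ribostitch: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribostitch: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bacterial genomes carry the ribosomal RNA operon (16S, 23S and 5S genes,
"rDNA", typically 5-7 kb) in 1 to ~15 copies. Within one genome the copies
are nearly identical, which collapses them into a single subgraph of the de
Bruijn graph built from short reads: a de novo assembly breaks at every
operon, and copy number and genomic context are lost. Two empirical
observations make the problem tractable. First, the sequence *flanking* each
rDNA copy is effectively unique within a genome (about 1 kb of flank is
sufficient to discriminate copies). Second, both the rDNA and its flanks are
conserved between related genomes, so a closed reference from the same
species usually carries each operon in the correct context.

ribostitch exploits both: reads are *baited* onto the reference's annotated
rDNA regions (operon plus flank), each bait set is subassembled into a
per-operon *pseudocontig* built only from the isolate's own reads, baiting
is iterated against the concatenated pseudocontigs, and the final
pseudocontigs steer the full-read de Bruijn graph through the collapsed
repeat — "de fere novo" (from almost nothing) assembly. The crucial property
is that the final sequence comes from the reads, not the reference: the
reference only tells the assembler *which flank pairs with which*.

## Pipeline model

### scan — annotation normalisation

Real references should come with rRNA annotations (e.g. a Barrnap GFF3 or a
GenBank file); `scan_rrnas()` filters and normalises them. Features are
classified into 16S/23S/5S by case-insensitive substring match on the
product text, mirroring the labels standard annotators emit. For synthetic
genomes and desk-scale tests a built-in detector finds exemplar subunit
sequences by shared k-mer density (defaults `k = 31`, density ≥ 0.5, merged
interval ≥ 80% of the exemplar length; strand from k-mer orientation). At 2%
exemplar divergence the expected density of intact 31-mers is
`0.98^31 ≈ 0.53`, which motivates the 0.5 threshold; the detector is not an
HMM scanner and is documented as a convenience, not a replacement for real
annotation.

### select — operon inference

rRNA feature *midpoints* (robust to gene order on either strand) are grouped
per replicon with the exact Fisher–Jenks natural-breaks dynamic program,
using the number of 16S annotations as the class count. The DP is `O(k n²)`
and exact; inputs are tiny (≤ ~45 features). Each class becomes an operon
cluster whose span is extended by `flank` (default 1000 bp, the empirically
sufficient discriminating length) and clamped at sequence bounds. The
cluster file is plain text and hand-editable; `load_cluster_file()` rebuilds
clusters verbatim, bypassing Jenks, so users can correct pathological
groupings.

### seed — baiting and iterative subassembly

Reads are mapped with a built-in seed-and-extend mapper (k-mer diagonal
voting, then banded affine-gap extension with match +1, mismatch −1, gap
open −3, gap extend −1). A placement is reported when its identity
(matches / aligned columns) reaches `min_identity = 0.8` — the package-wide
80% threshold below which a reference is considered too divergent. All
score-tied placements are kept: a read internal to the repeat cannot be
assigned to one copy, and deliberately joins *every* cluster whose region it
overlaps (flank-anchored reads are the discriminating ones). Mates follow
their partners into each partition, and unmapped mates are rescued by
alignment inside the insert window (mean + 4 sd, estimated from proper
pairs).

Each partition is assembled with the single-k de Bruijn assembler; when the
partition's mean mapping identity is at least `trust_identity = 0.8` the
reference region is threaded through the graph as a trusted contig,
otherwise the reads are assembled alone. The longest contig becomes the
pseudocontig and is length-checked: shorter than `min_length = 6000` (a
conservative minimum for a 16S+23S+5S operon) or longer than
`max_factor = 3` times the expected length (span + 2·flank) indicates a
parameter or reference problem; the cluster is frozen at its last accepted
pseudocontig and not reseeded, and the user is warned. Mapping depth per
cluster and iteration is logged — a marked decrease is another recommended
warning sign.

Accepted pseudocontigs are concatenated into a *pseudogenome* separated by
1000 bp runs of `N` (long enough that no read pair spans a spacer; the order
is arbitrary since only flanking context matters). Iterations 2..I (default
3) map all reads against the previous pseudogenome, with each pseudocontig
acting as one region without further flank growth.

A note on convergence: because mates are pulled into partitions and
iterations 2+ treat the whole pseudocontig as the bait region, pseudocontigs
extend by roughly an insert length at their edges each round on clean data.
Iteration is therefore *content-stable* rather than a literal fixed point:
each round reproduces the operon-plus-flank core exactly and grows only
outward. The QC upper bound (3× expected length) caps this growth. The test
suite asserts content stability, not byte equality.

### Final de fere novo assembly

Both assemblies — de novo control and de fere novo — use the same single-k
de Bruijn assembler (default `k = min(127, ⌊0.55·read_length⌋)` rounded to
odd, i.e. 55 for 100 bp reads): canonical k-mer counting, discarding of
k-mers below `min_kmer_count = 2`, tip clipping below `2k` bp, popping of
bubbles whose branches align at ≥ 0.9 identity (keeping the higher-coverage
branch), and unitig extraction. This is deliberately simpler than a multi-k
assembler; pluggability of external mappers is provided through SAM
ingestion (`read_sam()`).

The de fere novo step is the package's concrete interpretation of
"trusted contig" semantics. Each pseudocontig's k-mers are walked through
the read graph. Trusted pseudocontigs may patch walk gaps of up to 2 missing
k-mers from their own sequence; untrusted ones may not. At every branching
node on the walk the supported (in-edge, out-edge) pairing is recorded; a
pairing proposed only by an untrusted pseudocontig is rejected when it has
zero spanning-read support while an alternative junction is supported by at
least 5 reads. Conflicting pairings cancel. Each pseudocontig's walk is then
re-emitted as a single contig, extended in both directions through
uniquely-resolved junctions and simple nodes (stopping at unresolved
branches, dead ends, or edge revisits — the revisit rule means perfect
tandem rDNA repeats remain out of reach, a known limitation shared with the
underlying approach). Unitigs wholly covered by these guided contigs are
dropped; everything else is kept. Since local junction pairings at a
collapsed 3-copy repeat are individually ambiguous (the entry node pairs
three in-edges with one out-edge), it is the walk itself — flank, repeat,
flank in one piece — that performs the repeat resolution.

### score — junction validation

For every cluster the reference flank sequences are matched into the
assembly with a local aligner at BLAST-like thresholds (identity ≥ 0.95
over ≥ 50% of the flank; all qualifying hits kept). A cluster is:

* **correct** — upstream and downstream flanks hit the *same* contig, same
  strand, in reference order, separated by the rDNA span within ±20%, each
  hit covering ≥ 90% of its flank (`min_extension`);
* **ambiguous** — more than one configuration satisfies the above, or
  evidence is present but inconsistent;
* **incorrect** — a flank is fused at junction distance to a partner that
  contradicts the reference (wrong cluster, side or orientation);
* **unassembled** — a contig end falls within the rDNA or flanking region.

The ±20% span tolerance quantifies "joins two contigs across an rDNA
region"; it is deliberately loose enough to absorb small indels yet tight
enough that a fusion to the wrong (differently-sized) region fails the
geometry test. `count_region_snps()` compares two assemblies over each rDNA
region ± 1 kb, reporting substitution columns (indels separately, never
counted as SNPs) and marking regions below 80% identity unalignable.

### snag and stack — diagnostics

`snag_entropy()` computes per-column Shannon entropy over aligned rDNA
regions in bits over the A/C/G/T distribution; gaps and Ns are excluded from
both the distribution and the consensus depth, keeping entropy within
[0, 2]. ("Consensus depth" is taken as the non-gap count; the alternative —
count agreeing with the consensus base — is noted but not used.) Profiles
are smoothed with a centered 351 bp moving average whose window shrinks
symmetrically at the edges. A small center-star aligner (global banded
pairwise alignments against the longest sequence, merged gap structure)
handles unaligned input up to 10 sequences of 20 kb; larger jobs should
supply a pre-aligned FASTA from a real MSA tool.

`stack_coverage()` compares mean read depth over the rDNA spans against
randomly placed background intervals (each as long as the mean cluster
region, never overlapping an rDNA region, sampled with a caller-supplied
seed). Depth is measured over spans rather than flank-extended regions
because a collapsed reference still carries unique flanks at 1× coverage,
which would dilute the copy-number signal. "Sufficiently exceeds" is
quantified as ratio ≥ 1.5 by default (no canonical value exists; with a
2× collapse the expected ratio is 2.0, so 1.5 splits the two hypotheses).

## The simulators and what a green test establishes

`synth_operon_genome()` builds the canonical fixture: `n` byte-identical
operon copies (default 5 kb, with proportionally sized 16S/23S/5S
sub-features) planted in random background with `flank_length` (default
1500 bp) reserved on each side. Random background makes every flank unique
(~25% pairwise identity), which is the genuine structure of the biological
problem — but real flanks can be partially repetitive, and real rDNA copies
differ by a few bases; the fixture is the *clean* version of the problem.
`mutate_genome()` implements two substitution models: geometric
inter-substitution gaps with parameter `f` (equivalent to i.i.d.
Bernoulli(f) per base, the natural reading of "geometrically distributed
mutations at frequency f") applied either uniformly or restricted to
non-rDNA positions (rDNA bases are never altered under `flanking_only`,
matching the empirical pattern that rDNA is far more conserved than its
flanks). `simulate_reads()` draws uniform fragment starts with
Normal(300, 10) inserts, 100 bp mates and i.i.d. per-base substitution
errors at a configurable rate with constant matching quality scores. GC
bias, indel errors and machine-specific error profiles are *not* modelled;
a green pipeline test therefore establishes correctness of the
repeat-resolution logic, not robustness to every real-world read pathology.

All generators are seed-deterministic: identical seeds give byte-identical
output.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; conversions
  happen only in I/O code. Features crossing a circular origin are clamped
  at the boundary with a warning rather than wrapped.
* Alignment gap costs are `open + ext·length` (a length-1 gap costs 4).
  Mapper ties are broken to the leftmost (record, position); all co-best
  placements are retained for partitioning.
* Jenks ties are broken towards the lexicographically smallest break
  positions (the DP keeps the first optimum scanning split points in
  ascending order).
* The assembler materialises both strands of every canonical k-mer; contigs
  are emitted in canonical orientation (lexicographic minimum of the
  sequence and its reverse complement) and sorted by descending length, so
  output is deterministic for a given input.
* An empty read partition yields a zero-length pseudocontig marked
  `too_short`; a run in which every cluster fails QC aborts with a
  diagnostic pointing at k-mer size, flank length and reference choice.
* `k` must be odd throughout (a k-mer can then never equal its own reverse
  complement, so the palindromic-seed case cannot arise).

## Known limitations

* Perfect tandem rDNA repeats (no unique sequence between copies) cannot be
  resolved: guided extension stops when it would revisit an edge.
* The built-in mapper and single-k assembler favour self-containment over
  fidelity to any specific external tool; external alignments can be
  supplied as SAM, and the scoring machinery is tool-agnostic.
* The exemplar-based rRNA detector requires close exemplars (it is k-mer
  exact matching, not a profile model) and reports only hits ≥ 80% of the
  exemplar length.
* Reference-strain selection, polishing-tool integration, visualisation and
  external assembly metrics are out of scope.
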