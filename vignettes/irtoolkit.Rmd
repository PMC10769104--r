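---
title: "Detecting intron retention and comparing transcript annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intron retention and comparing transcript annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtoolkit)
```

## The problem

Transcript assemblers (StringTie2, Scallop2 and relatives) reconstruct
full-length transcripts from RNA-seq alignments, and their accuracy is
routinely judged against a reference annotation (Ensembl/GENCODE, RefSeq,
CHM13). Two facts complicate that judgement. First, the major annotations
disagree with each other, most strongly at the level of complete splice
structures. Second, assemblers differ systematically in how often they emit
transcripts that retain intronic sequence, and annotations differ in how
many such transcripts they record — Ensembl's `retained_intron` biotype is
one of its largest, while RefSeq contains very few comparable entries. An
assembler that produces many intron-retaining transcripts can therefore
look better or worse than a competitor purely depending on which annotation
is used as truth.

This package provides the machinery to quantify and adjust for these
effects: structural-similarity metrics between annotations, an
abundance-gated classifier for intron retention within an assembly, and
the matching/precision apparatus used to evaluate assemblies against
references.

## Transcript structure as sets

A transcript is a chain of exons alternating with introns. For a
multi-exon transcript $t$ we derive:

* $B(t)$ — the set of **intron-exon boundaries**, the genomic coordinates
  of intron start and end points (splice sites). Transcript start/end
  positions are *not* boundaries, so annotations differing only in
  TSS/TES agree perfectly at this level.
* $J(t)$ — the set of **junctions**, each an intron written as its
  coordinate pair.
* $C(t)$ — the **intron chain**, the full ordered tuple of junctions.

Single-exon transcripts contribute nothing to any of the three sets. Sets
lift to genes and annotations by union: $B(g) = \cup_{t \in g} B(t)$,
$B(T) = \cup_{g \in T} B(g)$, and likewise for $J$ and $C$. Structural
similarity between annotations $T_1, T_2$ is the Jaccard index at each
level, e.g. $J_C(T_1,T_2) = |C(T_1) \cap C(T_2)| / |C(T_1) \cup C(T_2)|$.
The three levels are ordered: identical chains imply identical junction
sets imply identical boundary sets, so similarity can only fall (or stay)
as the level gets stricter, which is exactly what makes the chain level
diagnostic.

Internally each element is a canonical string key embedding chromosome and
strand, so set algebra is exact — no floating point, no interval fuzz.
Identity is strand-aware by default ("." only matches "."); every
comparing function takes `ignore_strand = TRUE` for sensitivity analysis.
Either endpoint convention (exon ends vs intron ends) yields the same
Jaccard values when applied uniformly; we use intron endpoints, and the
test suite asserts the values against an independently coded enumeration.

When both sets are empty (two annotations of single-exon transcripts) the
Jaccard index is undefined and reported as `NA`, never as 0 or 1.

## Gene correspondence

Genes in two annotations use unrelated identifier namespaces, so pairs are
constructed structurally: $g_1 \in T_1$ and $g_2 \in T_2$ form a pair when
$B(g_1) \cap B(g_2) \neq \emptyset$. Only multi-exon genes (at least one
multi-exon transcript) participate; one gene may pair with several.
`pair_genes()` reports the per-pair Jaccard at all three levels, and
`jaccard_distribution()` summarises a set of pairs with nearest-rank
percentiles (the value at rank $\lceil p \cdot n\rceil$ of the sorted
values) — the interpolation rule is stated because different quantile
definitions differ visibly on small or strongly discretised samples.
`validate_pairs_against_catalog()` reports what fraction of an externally
supplied id-pair catalog (for instance one derived from HGNC nomenclature)
is recovered by the structural pairing.

An open choice: whether annotation-level sets should exclude *all*
single-exon transcripts or all transcripts of genes lacking multi-exon
transcripts. We exclude single-exon transcripts only — they carry no
splice structure either way, so the sets are identical under both readings;
the distinction matters only for gene-level pairing, which is restricted to
multi-exon genes explicitly.

## Intron retention in an assembly

Whether a transcript "retains an intron" is only meaningful relative to
another transcript. Within one assembly, transcript $t$ (abundance
$p(t)$) has intron retention if some other transcript $r$ (abundance
$p(r)$, multi-exon, same chromosome, compatible strand) satisfies
$p(r)/p(t) \geq \mathrm{cr}$ (**coverage ratio**, default 0.5) and one of:

1. the genomically first exon of $t$ starts strictly inside an intron of
   $r$ and extends past it into the following exon (partial retention at
   the left end);
2. the mirror image at the right end — the last exon of $t$ starts before
   an intron of $r$ and ends strictly inside it;
3. some exon of $t$ fully contains an intron of $r$ (entire retention,
   closed-interval containment — an exon exactly equal to the intron
   counts).

The partial criteria are additionally gated by the **length ratio**
(default 0): the fraction of the reference intron covered by the terminal
exon, $\mathrm{overlap}/|I|$, must reach `lr`. The numerator is the
overlap length, not the whole terminal-exon length: that keeps the ratio
in $[0,1)$ for genuinely partial events and makes flagging monotone in the
threshold. Criterion 3 ignores `lr` entirely.

Several conventions deserve explicit statement:

* **Thresholds are inclusive** (`>=`): the default cr = 0.5 flags a
  reference with exactly half the candidate's abundance; this makes the
  documented default meaningful at its own boundary.
* **"First/last" is genomic**, not 5'→3': criteria 1 and 2 are exact
  mirror images, so classification is strand-symmetric.
* **Partial and entire are disjoint per reference intron**: the terminal
  exon's inner endpoint must fall *strictly* inside the intron for a
  partial call; if the exon covers the whole intron, that is criterion 3.
  This keeps the partial-only and entire-only operating modes (the CLI's
  `-wo` and `-po`) a clean partition of the evidence.
* **Degenerate abundances**: if $p(t)$ is 0 or unknown the ratio is
  treated as unbounded and the gate passes whenever $p(r) > 0$; a missing
  $p(r)$ or two missing abundances pass the gate (a missing abundance is
  not treated as evidence against retention; the fully abundance-blind
  case is reported once per run).
* **No iteration**: references may themselves be flagged; classification
  is single-pass, and the verdict is independent of iteration order.
* **Eligibility**: a single-exon candidate can be flagged (its only exon
  is both first and last); a single-exon reference supports nothing.

Candidate references are restricted to span-overlapping transcripts via a
`GenomicRanges` interval index; since every criterion requires overlap,
this is purely an optimisation, and the test suite verifies exact
agreement with an unindexed all-pairs classifier on randomized assemblies.

`ir_partition()` splits an assembly into the flagged and kept parts —
the filtering step that makes an assembler's output comparable across
annotations with different appetites for retained introns.

## Evaluation machinery

`match_transcripts()` mirrors the transcript-level measure of GffCompare:
a multi-exon assembled transcript matches when its intron chain is
coordinate-identical to a reference transcript's; a single-exon transcript
matches when it overlaps a single-exon reference transcript by at least
80% — reciprocally, of both lengths, by default. The published rule names
only the percentage, so the stricter reciprocal reading is the default and
`reciprocal = FALSE` gives the one-directional variant. Precision is
matched/assembled; the raw matched count is the recall proxy. Two
assembled transcripts matching the same reference both count (mirroring
precision's numerator); `dedupe = TRUE` counts distinct references
instead.

**Adjusted precision** compares two assemblies with mixed outcomes: the
higher-recall assembly has its lowest-abundance transcripts removed one at
a time — ties broken lexicographically by transcript id, so the trace is
reproducible — until the matching counts equalise; its precision at that
point is compared with the other's raw precision.

`annotation_intersection()`/`annotation_union()` build composite
references with "=" class-code semantics: the intersection keeps query
transcripts matching the reference, the union adds the non-matching ones
to the reference. The same matching predicate (including the single-exon
overlap rule) is used so that `query == reference` yields the expected
identities.

`threshold_sweep()` traces precision and matching count of the kept
assembly over a grid of `lr` or `cr` values — the precision-sensitivity
curve used to choose operating points.

## Synthetic data: what it emulates and what it does not

All tests run on generated data:

* `example_annotation_pair()` and `example_ir_assembly()` are fixed,
  hand-constructed encodings of the two worked examples with known
  outcomes (Jaccard 5/6, 5/8, 1/3; one retention event per criterion).
* `simulate_annotation_pair()` builds annotation pairs whose per-level
  Jaccard is known *by construction*: shared genes contribute identical
  structure, chain-private genes contribute disjoint structure in fresh
  windows, and subchain-private transcripts add chains without adding
  junctions or boundaries. The generator counts elements as it builds, so
  the expected value is independent of the set machinery being tested.
* `simulate_ir_assembly()` plants retention events of a requested
  criterion and abundance ratio, each in its own genomic window, with
  geometry satisfying exactly one criterion; truth labels follow. Events
  at ratio $q$ are recoverable precisely when $q \geq$ cr, giving sharp
  threshold-bracketing tests.

Both generators are deterministic given a seed (the session RNG state is
saved and restored) and emit byte-identical GTF on identical seeds.

These generators emulate coordinate structure, abundance ratios and
sharing patterns. They do **not** emulate realistic expression
distributions, read-level noise, alignment artifacts, overlapping gene
dense regions, or the biological mixture of event types in real
assemblies. Passing tests therefore demonstrate correctness of the
definitions and algorithms, not field performance on any particular
dataset; the full-genome comparisons (Ensembl-vs-RefSeq Jaccard, HGNC
catalog recovery) require the pinned external inputs and are wired in
`scripts/external_checks.R`.

Problem sizes in the default suite were chosen to exercise the interval
index against quadratic oracles while keeping the suite quick on a laptop:
around a hundred randomized assemblies up to 200 transcripts for the
classifier, tens of randomized fixtures for similarity and matching.

## GTF handling

The reader accepts the attribute dialects of Ensembl, GENCODE, RefSeq,
CHM13, StringTie and Scallop: quoted or bare values, repeated keys,
semicolons inside quoted strings, gzip compression. Abundance is taken
from the first present key of a configurable list (default `cov`, `FPKM`,
`TPM`, `RPKM` — assemblers do not agree on a name), biotype likewise
(`transcript_biotype`, then `transcript_type`). Coordinates are 1-based
inclusive on disk and stay 1-based inclusive in the model; a derived
intron is `[prev_end + 1, next_start - 1]`, and length-1 introns are
legal. Exons listed out of order are sorted; exactly adjacent exons are
merged with a warning (a zero-length intron is meaningless); overlapping
exons mark a transcript as malformed, which is repaired by merging or
dropped per a switch, and reported either way. The writer reproduces the
original record text byte-for-byte for transcripts that were read and
never modified, and generates canonical records otherwise, so
read-write-read is the identity on the model.

The reader is intentionally small and self-contained because the package
guarantees record-level fidelity (line-numbered format errors,
byte-preserving output) that generic importers do not expose; the test
suite cross-checks its coordinate parsing against `rtracklayer` on
generated fixtures.

## Known limitations

* Matching is exact on coordinates; there is no tolerance for splice-site
  wobble, matching the "=" semantics it mirrors.
* Only "=" class-code semantics are implemented — no containment/overlap
  class codes, no locus- or exon-level accuracy metrics.
* Intron-retention quantification from read evidence (PSI/IR-ratio from
  BAMs) is out of scope; the classifier reasons about assembled structures
  and predicted abundances only.
* GFF3 is not parsed; inputs must be GTF.
* The abundance attribute actually consumed from a given assembler's
  output depends on the key list; if an assembly carries none of the
  default keys, classification falls back to the abundance-blind gate and
  says so.
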