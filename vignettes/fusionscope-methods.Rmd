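---
title: "FusionScope: methods and design notes"
author: "FusionScope maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FusionScope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FusionScope)
```

# Scope and model

FusionScope operates downstream of long-read fusion callers and isoform
quantifiers. Its unit of analysis is the *fusion call*: a sample, a 5'
and a 3' partner gene, two genomic breakpoints with strands, a read
support count, and caller provenance. The package assumes GTF-style
1-based fully-closed coordinates throughout; any half-open arithmetic is
internal to the coordinate helpers. Gene identity is by symbol, matching
how callers and the cancer-gene resources report partners.

The pipeline is a composition of deterministic set operations —
deduplication, filtering, classification, annotation — plus sequence
arithmetic for construct design. There is no statistical model fit
anywhere in the package: differential expression testing is deliberately
delegated to edgeR/DESeq2-class tools, whose *result tables* are the
package's input. What FusionScope owns is the filter that precedes them
and the consensus merge that follows them.

# Harmonization

Callers re-report the same biological junction with small coordinate
disagreements, so deduplication runs in two passes:

1. **Exact** — within one caller, identical (sample, genes, both
   breakpoints) collapse to one call.
2. **Windowed** — across callers, calls with the same ordered gene pair
   merge when *both* breakpoints lie within `dedup_window_bp` (default
   50 bp). Merging is single-linkage: if A–B and B–C are each within the
   window, A, B, C merge even when A–C is not. Single linkage was chosen
   because it makes the operation order-independent; the alternative
   (greedy first-come clustering) depends on input order. The
   representative call is the member with maximal support (ties: smallest
   `(pos5, pos3)`), support after merging is the *maximum* over members —
   callers count overlapping read sets, so summing would double-count —
   and caller sets are unioned.

Reciprocal orientations (same partners reversed, breakpoints matching
within the same window) collapse to the orientation with higher support;
equal support keeps both, cross-linked via `reciprocal_of`. Distinct
fusions are counted as per-sample unordered gene pairs, so a fusion and
its reciprocal are one event. Whether cohort-level support summaries
refer to pre- or post-merge calls is ambiguous in the field; the pipeline
report carries both medians.

# The filtering cascade

Stage order is fixed: gene gate → support → blacklist → strand →
control subtraction → breakpoint-class drop. The first four and the
control subtraction are mutually independent set intersections (verified
by a permutation test), so the order only affects which stage an
artifact is *attributed* to in the audit; the audit records, per stage,
the input/output sizes and the removed fusion keys, and chains exactly.

Design choices that the underlying procedure leaves open:

* **Strand consistency** is defined as: the reported breakpoint strands
  equal the annotated strands of both partner genes — the only
  configuration in which reading the chimera 5'→3' traverses both genes
  in coding direction. Calls with unknown strands (callers differ in
  whether they report them) and calls on unannotated genes pass through
  with a `strand_warn` flag rather than being dropped: failing open
  avoids discarding whole caller dialects.
* **Control subtraction** matches unordered gene pairs, not coordinates —
  the most conservative reading of "seen in healthy tissue". Any
  two-column pair file works; the package does not fetch control sets.
* **Pseudogene status** resolves by user-supplied list first, GTF biotype
  (`*pseudogene*`) as fallback.

# Breakpoint classification

Each breakpoint is evaluated against three transcript tiers: the MANE
Select transcript, the longest protein-coding transcript (maximal summed
exon length; ties broken by lexicographically smallest transcript id,
which the annotation does not specify), then all transcripts.
Escalation stops at the first tier giving a non-intronic class, so an
exonic tier-1 result is never downgraded; within a tier the most
informative class wins (CDS > UTR > non-coding exon). UTR side is
assigned from the classifying transcript's CDS in transcription
direction; transcripts without a CDS cannot yield UTR classes.

Intronic breakpoints within `near_exon_bp` (200 bp, inclusive) of an
exon boundary become `near_exon` and count as exonic: long-read aligners
are ambiguous at exon–intron junctions and most genuine fusion junctions
sit at splice sites. The boundary distance is measured against the exon
boundaries of the transcript that produced the intronic call — the tier
anchor for the 200 bp rule is otherwise unspecified. Fusions with both
breakpoints intronic/intergenic/unannotated are dropped; "potentially
functional" is reported as two flags (`functional_any`,
`functional_both` over {CDS, near_exon}) because cohort summaries
sometimes mean either reading.

# Prioritization resources

Oncogene/TSG status is the union over the supplied sources; a gene may
be both, and no reconciliation rule is imposed. The glioma subset of the
census is built by case-insensitive substring matching of keywords
(`glioma`, `astrocytoma`, `glioblastoma`, `oligodendroglioma`, `CNS`)
against comma/semicolon-separated tumor-type *tokens*, with exclusion at
token level — a token containing `paraganglioma` never matches even
though it contains "glioma". Essentiality summaries take, over the
selected glioma-lineage cell lines, the per-gene maximum dependency
probability (≥ 0.9 → highly essential) and minimum gene effect (≤ −1 →
effect hit); thresholds are deliberately lenient to keep downstream
prioritization inclusive. Genes absent from a matrix get missing
summaries and `FALSE` flags, never errors.

# Isoform analyses

**Expression filter.** An isoform enters differential-expression testing
iff it has ≥ `expr_min_count` (10) counts in at least as many samples as
the smallest group and ≥ `expr_min_total` (15) counts overall. The
filter is monotone in counts (property-tested).

**Consensus DE.** Two result tables are intersected on isoforms
significant in both (significance ≤ 0.05, |log2FC| ≥ 1, both inclusive
as printed) with concordant sign; the consensus row reports the mean
log2FC and the maximum significance. The operation is symmetric in its
two inputs.

**Percentile ranks** use midranks for ties scaled to (0, 100]; a single
isoform ranks 100th. The rank convention is the package's choice.

**Novel-isoform clustering** partitions each gene's novel (NIC/NNIC)
isoforms by exon count, then greedily clusters in order of genomic start:
a record joins a group iff its transcription-direction start is within
`boundary_tol_bp` (100 bp) of the group representative's start *and*
every exon boundary is within the tolerance of the representative's
corresponding boundary. The representative is the running mean of member
boundaries, rounded half-up to integers. Because running means can
drift, a post-hoc pass re-validates every member against the final
representative and re-clusters violators; the result is a true partition
(every record in exactly one group, all members within tolerance of
their final representative). Transcript "start" is the 5' end in
transcription direction; the genomic-vs-transcriptional reading of the
start-similarity step is not specified upstream, and the
transcription-direction reading was chosen for biological meaning.

**Breakpoint-proximal isoforms.** The search radius around a breakpoint
is 10% of the gene-span length clamped to [500, 2000] bp; the clamp
floor is read as the smallest allowed search radius (the "minimum
distance" phrasing is ambiguous; the alternative reading — a minimum
*required* distance — would exclude the exact-breakpoint matches the
analysis exists to find). "Non-canonical" boundaries are judged against
the tier-1 (else tier-2) canonical transcript with the same 100 bp
tolerance — judged against *all* transcripts, an annotated short
transcript initiating mid-gene could never count, yet precisely such
transcripts are informative. For the 5' partner only non-canonical
*ends* count (premature termination), for the 3' partner only
non-canonical *starts* (novel initiation). A fusion is *fusion-like* iff
both roles have a hit in the same sample; hits from other samples are
reported but never flag (the same-sample default matches how such
patterns are interpreted; both views are computable from the hit table).
An expression-asymmetry annotation (lowly expressed 5' partner, highly
expressed 3' partner by percentile) is attached but is never a filter.

# Construct design

Constructs express breakpoint-defined ORFs, not full-length fusion
transcripts: the 5' segment starts at the CDS start (ATG), not the
transcript start, because the constructs model tagged ORF expression.
The reference transcript per gene is the highest-tier transcript in
which the breakpoint classifies as CDS or near-exon; near-exon
breakpoints are snapped to the nearest exon boundary of that transcript
before splicing. Deep-intronic breakpoints (beyond the near-exon window)
are an assembly error, not a silent guess. An optional junction override
accepts experimentally confirmed coordinates.

When the 5' breakpoint lies in the 5' UTR, the truncation point is
meaningless at protein level, so the construct instead carries the
entire 5' CDS *minus its stop codon* fused to the 3' segment — keeping
the stop would terminate translation at the junction and the 3' moiety
could never be read; this trimming is the package's design choice.

Frame status compares the 3' moiety's codon phase at the junction with
the 3' gene's native CDS phase at its breakpoint (generalized to
segments beginning upstream of the 3' CDS). Translation uses the
standard nuclear codon table, no selenocysteine handling; the first stop
before the 3' gene's natural stop is recorded as premature, and the ORF
is the translation up to the first stop. Junction microhomology is the
maximal k for which the k bases ending at the junction match both
partners' references — computed by direct comparison and tested against
an exhaustive scan and a reverse-complement symmetry property.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
test conditions: two chromosomes plus a mitochondrial contig; 1–4
transcripts per gene with 1–8 exons; exon lengths 150–600 bp, introns
0.4–2 kb; UTRs 30–90 nt with CDS length a multiple of 3 and planted
ATG/TAA at the CDS bounds; ~8% pseudogene-biotype, ~6%
ribosomal-named, ~4% HLA-named genes and two mitochondrial genes to
exercise the blacklist. True fusions get CDS breakpoints ≥ 300 bp from
transcript ends, support 3–12 reads, emission through 1–3 callers with
±20 bp breakpoint jitter — below half the 50 bp window, so true
multi-caller emissions always merge — and ~30% reciprocal echoes at
strictly lower support. One artifact per cascade stage is planted per
round, each constructed to fail exactly its stage. Fusion pairs are
globally unique and gene-disjoint within a sample, so per-gene
breakpoints and planted truncations cannot leak between co-sampled
fusions; samples are assigned with two-choice load balancing so no
sample exhausts its disjoint gene pool. Planted novel-isoform clusters
are separated by more than twice the 100 bp tolerance with intra-cluster
jitter of at most a third of it, which makes exact recovery the correct
expectation. DE result tables are generated directly with planted
agreement strata (both-significant concordant, one-only,
discordant-sign) rather than by fitting count models — the model fits
are out of scope, and the strata are the ground truth the consensus
merge is tested against.

What the generator does *not* emulate: read-level evidence (no
FASTQ/BAM), alignment artifacts with structure (jitter is uniform, real
callers err systematically at homopolymers and repeats), expression-
dependent call sensitivity, multi-gene read-through chains, and real
GENCODE annotation complexity (overlapping genes, thousands of
transcripts). Passing tests therefore demonstrate algorithmic
correctness under the stated conditions, not calibrated performance on
real cohorts.

# Problem sizes and budgets

Unit tests run on hand-built toy annotations (4–6 genes) where every
expected value is derivable by hand or by an independent oracle
(exhaustive single-linkage clustering, naive interval membership, a
literal codon table, exhaustive microhomology scan). The cohort-scale
checks use one seeded simulated study of 50 genes, 50 true fusions, two
artifacts per class and 20 samples (10 tumor, 10 control) — chosen as a
desk-scale analogue of a ~50-sample cohort that keeps the full test
suite and the acceptance script each within a couple of minutes on one
CPU.

# Known limitations

* Gene identity is symbol-based; no alias resolution or cross-annotation
  id mapping.
* Control subtraction cannot distinguish a shared artifact from a true
  fusion recurrently present in controls.
* Breakpoint classification trusts the annotation version supplied; the
  annotation release is an input, not a constant.
* Construct ORF analysis assumes the junction preserves splicing of both
  reference transcripts outside the fused segment.
* The fusion-like pattern is positional evidence only; it does not
  establish that the isoforms derive from a fusion allele.
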