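---
title: "Consolidating hybrid transcriptome assemblies: methods and design"
author: "TxConsolidate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating hybrid transcriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TxConsolidate)
```

## The problem

No single transcriptome assembly strategy recovers a complete transcript
set.  Reference-guided assembly inherits every gap and mis-join of a draft
genome; de novo assembly produces millions of fragments, many redundant,
truncated or chimeric.  Pooling many assemblies (different assemblers,
different k-mers) raises completeness but multiplies redundancy and
artefacts.  TxConsolidate implements a two-tiered consolidation of such a
pool — a reference-guided branch of filters over genome-anchored transcript
models and a de novo branch of sequence-space reductions — followed by a
cross-branch merge, and provides the evaluation statistics needed to judge
any transcript set against a reference proteome of a related, well-annotated
species.

## The reference-guided branch

Input is a set of consolidated transcript models (exon chains on genome
contigs, e.g. read from GTF).  Three filters run in a fixed order, each a
clean partition of its input and idempotent on its survivors:

1. **Mapping coverage.** A model is kept iff its spliced length is at least
   90 % (`minCov = 0.90`, boundary kept) of the originating transcript
   length, carried as `sourceLength`.  Partial placements on a draft genome
   are discarded here.  We define coverage as spliced length over transcript
   length; soft-clip accounting is a property of the upstream mapper and is
   deliberately not modelled.
2. **Canonical splice sites.** Every intron must read `GT..AG` on the
   transcript's strand.  The canonical set defaults to GT–AG alone — the
   strictest defensible reading of "non-canonical" — with `GC-AG` and
   `AT-AC` available through `canonicalPairs`.  Single-exon models always
   pass.
3. **Longest-ORF locus rule.** Models are grouped into gene loci (connected
   components of same-contig, same-strand exonic overlap, with at least one
   shared base; abutting exons do not link).  Within a locus, a model is
   kept iff its longest ORF reaches 75 % of the locus-maximal longest ORF
   (boundary kept).  This removes fragmentary structures that mapping
   coverage cannot see.

## ORF model

CDS prediction throughout the package is **longest-ORF**: every maximal
ATG-to-stop span (the 5'-most ATG per stop-bounded frame segment; nested
ATGs never change the longest ORF and are not reported), optionally 3'-open
because assemblies contain truncated transcripts, across all six frames by
default since de novo contigs are unoriented.  Ties break deterministically
(forward strand, then leftmost).  A trained coding-potential model with
frameshift correction would recover CDSs from frameshifted contigs that
longest-ORF cannot; that capability is declared out of scope, and the
gap-free assembly rules below are chosen so the pipeline at least never
*introduces* new frameshifts.

## The de novo branch

1. **CDS extraction.** Transcripts are reduced to their longest-ORF CDS
   (minimum 200 nt), oriented to the coding strand.  This collapses
   UTR/strand/fragment complexity before any comparison and makes
   "forward-only" meaningful downstream.
2. **Containment dedup.** Iterating by decreasing length (ties by id), a
   transcript is removed iff an ungapped alignment against an already-kept
   transcript covers at least 90 % of it at 95 % identity or better — it is
   included in a longer sequence.  "90 % of the complete length" is read as
   the *shorter* sequence's length (cd-hit-est semantics); the alternative
   reading (fraction of the longer) would make removal harder and can be
   emulated by raising `minCov`.
3. **Clustering.** Single-linkage components under a canonical-k-mer
   criterion: two transcripts link iff their shared canonical 14-mers are at
   least 30 % of the smaller k-mer set.  This replaces a word-count (d2)
   distance with a linkage rule that has the same single-linkage cluster
   semantics but is exactly checkable against an all-pairs oracle; both
   parameters are exposed.  At these defaults, fragments that overlap by
   only a small fraction of their length do not link — cluster membership
   is a statement about overall sequence similarity, not about assemblable
   overlaps, which is why the assembler is also exercised directly on
   tiled fragments in the test-suite.
4. **Per-cluster assembly.** A greedy overlap-consensus assembler merges
   suffix–prefix overlaps and containments of at least 40 nt at 98 %
   identity, highest score (overlap length × identity) first, ties by id
   pair.  Only forward–forward overlaps are considered (reverse-complement
   joins are the classic chimera mechanism), and no gaps are ever
   introduced: an "infinite gap penalty" taken literally, so consensus
   columns are substitutions only (majority base, ties to the longer
   parent) and reading frames can never shift.  Every input member ends up
   either a contig or contained in one, and aligns ungapped to its contig.

## Cross-branch merge

Two asymmetric rules, evaluated in a fixed order.  First every de novo
transcript with an alignment from any reference-branch transcript covering
at least 95 % of it is removed (such transcripts differ from the anchored
structure only by minor indel/sequencing noise).  Then a reference
transcript is removed only if a *surviving* de novo transcript covers it
completely, without gaps.  The order is the conservative one — it prefers
genome-anchored structures when both rules would fire (an exactly duplicated
sequence survives as its reference copy) — and both thresholds are
configurable.

## Alignment engines

Every rule above consumes only coverage, identity and gap statistics, so
both internal aligners use unit scoring (match +1, mismatch −1, no
substitution matrix); `N` and ambiguous residues never match anything.

* **Ungapped nucleotide alignment** seeds exact 12-mers in both query
  orientations and extends each seeded diagonal to its maximal-scoring run
  (Kadane over the ±1 profile), returning the run with most aligned columns
  at the identity floor; ties prefer higher identity, then the forward
  orientation, then the smaller target start.  When seeding yields no
  qualifying run the aligner rescans every diagonal, making the result
  exactly the optimum over all ungapped placements; bulk callers (dedup,
  merge) disable this fallback because a containment-grade alignment always
  carries seed words, and a missed borderline case there merely makes the
  filter conservative.
* **Protein chain alignment** (used protein-vs-six-frame-translation and
  protein-vs-protein) seeds exact 5-residue words, extends ungapped per
  diagonal, decomposes diagonals into all strong positive runs (a deletion
  followed by a compensating insertion puts two true blocks on one
  diagonal; a run bridging a deep mismatch valley is also offered in split
  form), then chains blocks whose offsets on either axis are at most 30
  residues, maximising matches.  Runs from neighbouring diagonals may
  overlap by a few columns where junction-flanking residues happen to match
  on both; links trim the junction at the split that keeps the most
  matches — the same local optimum a banded dynamic program picks.  Gap
  columns are the unaligned residues between consecutive blocks summed over
  both axes, in amino-acid units.

E-values are never computed internally: Karlin–Altschul calibration is out
of scope, and every rule phrased as an e-value cutoff is applied verbatim
when records come from BLAST tabular input and otherwise replaced by a
minimum-matched-residues proxy — 33 for the stringent classification cutoff
(1e−20) and 16 for the permissive presence cutoff (1e−5), roughly the
information content of such hits at unit scoring.  Both are configurable,
and the substitution is the package's declared deviation from e-value
semantics.

Hits are ranked everywhere by `matches − mismatches − gap columns` (ties by
target id).  Leaving gaps out of the ranking lets a heavily gapped
paralog/isoform hit tie an exact hit of equal match count, which misranks
the obvious best hit; penalising each gap column one unit resolves this
while staying within unit scoring.

## Evaluation statistics

* **correct / incomplete / false.** For each transcript, all ORFs ≥ 200 nt
  are translated and aligned against candidate reference proteins (exact
  shared-word prefilter, then the chain aligner).  Among significant hits
  (identity ≥ 90 % and the 1e−20 cutoff or its proxy), the best hit
  classifies the transcript: reference covered ≥ 90 % with ≤ 1 % gap
  fraction → *correct*; reference under-covered but the translated ORF
  covered ≥ 90 % with the same gap limit → *incomplete* (the transcript-side
  coverage is the ORF's, matching the translated-query direction of the
  search); any other significant hit → *false*; otherwise *no hit*.
  Fractions are reported over transcripts with a significant hit.
* **u80.** A reference protein counts iff a *single* alignment to some
  transcript is ungapped and covers at least 80 % of the protein (boundary
  counted); multiple transcripts may not jointly cover a protein, and the
  identity floor is the permissive 70 % the metric was designed with.
  Coverage-qualified but gapped alignments are classed by gap fraction of
  the alignment length (0 %, ≤ 5 %, > 5 %), and `uncovered` otherwise; each
  protein gets its best class.  u80 is monotone under adding transcripts,
  so a union of assembly branches is never worse than its best branch.
* **Unique u80** counts, per transcript set, the proteins in that set's u80
  and no other's — the statistic that shows every assembly contributes
  something unique.
* **Presence test.** A protein is present in the combined (pre-merge) set
  iff it has a significant hit there (1e−5 cutoff or the 16-match proxy),
  and retained in the final set iff a significant final hit loses no more
  than 5 percentage points of identity against the best combined hit.
* **Paralog table.** Clusters are cross-tabulated against gene loci: columns
  single / multiple / no locus by the distinct loci of a cluster's members,
  rows unique / multiple cluster by whether the cluster shares a locus with
  another.  A cluster with no locus cannot share one, so the
  multiple-cluster/no-locus cell is structurally zero.

## The synthetic study system

All tests run on a seeded simulator, so nothing is downloaded and every
expectation is machine-checkable.

`makeGenome()` places each gene on its own contig: 2–9 exons of 150–400 nt
(internal exons rounded to a multiple of 3 so that exon skipping can
preserve frame, as symmetric exons do in real genomes), introns of
60–800 nt that always read GT..AG on the coding strand, a CDS of at least
60 % of the mature transcript flanked by 15–40 nt UTRs (the 5' UTR is kept
ATG-free so the annotated CDS is provably the longest ORF), GC content
0.42, and both strands.  Isoforms (1–4 per gene) skip one internal exon
each; a skip is accepted only if the isoform's longest ORF stays at or
above 75 % of the primary ORF with its stop intact, so clean isoform sets
pass the locus filter by construction.  The proteome carries one protein
per isoform (the translation of that isoform's longest ORF).  Generation
is deterministic given the seed and self-audits: spliced models must
reproduce the stored mature transcripts.

`corruptTranscripts()` applies truncation (to 70 % of length — with the
UTR/CDS geometry above this leaves reference coverage around 0.7–0.8,
safely inside the *incomplete* region), 50/50 chimera joins, heavy point
mutation (15 % per base, far below the 90 % identity floor, so such
records drop to *no hit*), internal deletions and strand flips.  Expected
classes are **computed, not asserted**: a Smith–Waterman label oracle
(`Biostrings::pairwiseAlignment`, unit scoring, linear gap penalty 4 — high
enough that spurious bridges into unrelated sequence never pay, low enough
that genuine small in-frame indels do) runs the same ORF enumeration,
candidate prefilter, significance rules and thresholds as the production
classifier, so labels stay correct if thresholds change, and agreement
between the two routes is a genuine two-implementation cross-check.

`makeTwoBranchInputs()` plants per-stage decoys — models with inflated
source lengths (mapping coverage ≈ 0.7), models with one intron boundary
shifted off GT..AG (the shift is re-checked at generation so a coincidental
GT is never planted), 3'-fragment models whose longest ORF is well under
75 % of their locus maximum but which pass both earlier stages — plus
containment fragments (50–70 % of a CDS, exact copies) in the de novo
branch.  Each decoy is constructed to fail exactly its own stage, so
removal lists can be compared to the plants as sets.

`makeMergeScenario()` additionally plants diverged paralog copies: 12 % of
interior codons mutated non-synonymously (first/last 15 codons untouched so
the ungapped containment stays end-to-end), leaving ~96 % nucleotide
identity — above the merge rule's floor, so the copy is collapsed onto its
host's reference transcript — but ~88 % protein identity, far past the
5-point presence tolerance, so exactly these proteins surface as losses.

What the simulator does **not** emulate: sequencing error profiles and
coverage variation, repeat- and paralog-rich genomes beyond the planted
copies, alternative splicing beyond single-exon skipping, non-canonical
introns in true genes, and fragmented/gapped draft contigs.  Passing tests
therefore demonstrate algorithmic correctness under controlled conditions,
not performance on real CHO-scale data.

## Numerical and determinism choices

All thresholds are inclusive on the keep side, matching the "less than …
removed" phrasing of the rules.  Orderings are deterministic everywhere
(length then id for iteration; score then id pair for greedy merging;
lexicographically smallest member id for locus and cluster labels; leftmost
optimum for tied alignment runs), so every pipeline product is byte-stable
without any RNG.  Genomic exon models live in `GRanges` (1-based closed,
the Bioconductor convention) so GTF I/O and interval overlap go through
`rtracklayer`/`GenomicRanges` without bespoke conversions; alignment block
coordinates are 0-based half-open as in PSL, converted only at format
boundaries.  BLAST tabular records are "blockless": aligned columns are
recovered exactly from span accounting (`qspan + sspan − length`), but
block structure is absent, so such records serve coverage/identity/gap
rules only.

Test problem sizes are chosen to exercise each property at meaningful scale
while keeping the default suite quick on a single core: oracle-equivalence
suites run 500 nucleotide pairs, 200 protein indel fixtures, 400 ORF
sequences and 200 clustering/locus instances; end-to-end scenarios use
bundles of 12–60 genes (about 20–150 transcripts).

## Known limitations

* Longest-ORF CDS prediction cannot rescue frameshifted contigs (no
  ESTScan-style correction) and ignores non-ATG starts and alternative
  genetic codes.
* The ungapped containment rule misses containments interrupted by true
  indels; such pairs fall through to clustering and assembly instead.
* Internal significance proxies are calibrated by information content, not
  by a database-size-aware statistic; when real e-values matter, import
  BLAST tabular alignments and the stated cutoffs apply verbatim.
* The greedy consensus assembler is exact on error-free, adequately
  overlapping fragments (as the tests prove) but is not a replacement for a
  quality-aware assembler on noisy data.
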