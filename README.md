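# TxConsolidate

Two-tiered consolidation of hybrid transcriptome assemblies, with
reference-proteome evaluation metrics.

## The problem

Pooling many transcriptome assemblies — reference-guided plus de novo
assemblies over a range of k-mers — recovers more of a transcriptome than
any single strategy, especially for organisms with only a draft genome
(CHO cell lines being the motivating case).  The price is a pool of
millions of sequences riddled with redundancy, truncations and chimeras.
TxConsolidate reduces such a pool to a non-redundant final transcript set
and quantifies what was gained and lost:

* **Reference branch** (genome-anchored transcript models): removes models
  with mapping coverage below 90 %, models with non-canonical (non GT..AG)
  splice sites, and models whose longest ORF falls below 75 % of the
  longest ORF at their gene locus (loci = connected components of
  same-strand exonic overlap).
* **De novo branch** (unoriented sequences): longest-ORF CDS extraction
  (≥ 200 nt), removal of transcripts 90 %-contained ungapped at ≥ 95 %
  identity in a longer one, canonical-k-mer single-linkage clustering, and
  per-cluster greedy overlap-consensus assembly restricted to forward,
  gap-free overlaps (≥ 40 nt at ≥ 98 %) so no chimeras or new frameshifts
  are introduced.
* **Merge**: a de novo transcript covered ≥ 95 % by a reference transcript
  is dropped; a reference transcript is dropped only when completely
  covered, ungapped, by a surviving de novo transcript.
* **Evaluation** against a reference proteome of a related species:
  * the **u80 metric** — the number of reference proteins with at least one
    *ungapped* alignment covering ≥ 80 % of the protein — with gap classes
    (0 %, ≤ 5 %, > 5 %) for covered-but-gapped proteins;
  * the **correct / incomplete / false** transcript classifier from the
    best significant protein hit (identity ≥ 90 %, 1e−20 cutoff or its
    internal 33-match proxy): reference ≥ 90 % covered with ≤ 1 % gaps →
    correct; reference < 90 % but translated ORF ≥ 90 % covered → incomplete;
    any other significant hit → false;
  * a **presence test** (a protein is retained if a significant final hit
    loses at most 5 identity points versus the combined pre-merge set);
  * a 2×3 **paralog table** cross-tabulating sequence clusters against gene
    loci.

A seeded simulator (`makeGenome()`, `corruptTranscripts()`,
`makeTwoBranchInputs()`, `makeMergeScenario()`, `makeTilingFragments()`)
generates toy genomes with multi-exon genes, exon-skipping isoforms,
proteomes and corrupted/decoy-laden transcript sets with oracle-computed
truth labels, so the entire workflow is testable offline.

## Worked example

```r
library(TxConsolidate)

bundle <- makeGenome(12, seed = 101)                 # 12 genes, isoforms, proteome
inputs <- makeTwoBranchInputs(bundle, seed = 102,    # branches with planted decoys
                              nLowCov = 2, nNonCanonical = 2,
                              nShortOrf = 2, nContain = 3)
res <- runPipeline(inputs$refModels, bundle$genome, inputs$denovo,
                   proteins = bundle$proteome, seed = 101)
res$report
#>      branch              stage input kept removed
#> 1 reference   mapping_coverage    34   32       2
#> 2 reference   canonical_splice    32   30       2
#> 3 reference       orf_fraction    30   28       2
#> 4    denovo     cds_extraction    15   15       0
#> 5    denovo dedupe_containment    15   12       3
#> 6    denovo            cluster    12   12      NA
#> 7    denovo           assemble    12   12      NA
#> 8     merge         merge_sets    40   28      12
```

Each planted decoy fell at exactly its own stage (2 + 2 + 2 in the
reference branch, 3 containments in the de novo branch), and the merge
removed the 12 de novo CDS contigs that the surviving reference models
already cover.  Evaluation of the final set:

```r
res$u80$u80
#> [1] 28        # all 28 isoform proteins have an ungapped >= 80% alignment
round(res$classification$fractions, 3)
#>    correct incomplete      false
#>          1          0          0
res$paralogTable
#>                  single_locus multiple_loci no_locus
#> unique_cluster             12             0        0
#> multiple_cluster            0             0        0
```

Individual engines are exported too:

```r
h <- translatedAlign(bundle$proteome[1], bundle$mature[[1]])
h
#> PairwiseHit g001.t1_p -> target [+/f1]: 1 block(s), id 100.0%, qcov 1.000, gapfrac 0.0000
```

A thin command-line front end covers every stage
(`simulate`, `orf`, `filter-ref`, `dedupe`, `cluster`, `assemble`, `merge`,
`evaluate`, `paralogs`, `pipeline`):

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/consolidate.R", package="TxConsolidate"))') \
    pipeline --gtf models.gtf --genome genome.fasta \
    --denovo denovo.fasta --proteins proteome.fasta --out outdir --seed 1
```

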