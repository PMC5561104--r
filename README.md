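# cistromekit

Integrative construction and annotation of reference cistromes from
ChIP-seq data.

## The problem

ChIP-seq compendia for a well-studied transcriptional regulator (TR)
contain dozens of peak sets from different labs, assays and treatment
conditions, and any single set mixes reproducible binding sites with
erratic or artefactual calls. `cistromekit` distills such compendia into
a **reference cistrome** — binding sites reproducibly observed across
studies — and then dissects it: in which experimental contexts each site
is bound (co-occurrence classes C1…Ck), which cofactors co-occupy it
(per-site signal correlation), and what chromatin state it sits in
(majority assignment and bp-weighted enrichment). It is aimed at
regulatory-genomics analysts integrating public peak sets, read
placements and chromatin-state segmentations.

## The methods at its core

**Majority-vote consensus.** Each input peak set is collapsed to one
vote per position; with vote depth `d(x)` = number of sets covering
position `x`, the consensus at severity `τ` is the set of maximal runs
with `d(x) ≥ τ`. `τ = 1` is the collapsed union, `τ = n` the per-base
intersection. A three-level hierarchy builds the reference: all
replicates within a study, `⌈0.75 · n_studies⌉` within a context, union
across contexts. The threshold is calibrated against shuffled random
inputs preserving interval counts, lengths and chromosomes
(`bedtools shuffle -chrom` behaviour).

**Median-of-ratios signal normalization.** Reads are counted in 50-bp
bins over ±5 kbp windows around site centers, giving a matrix `M[j, i]`
(bin row `j`, experiment `i`). With the per-row geometric mean
`G_j = (∏_i M[j,i])^(1/N)`, the size factor of experiment `i` is
`s_i = med_j M[j,i] / G_j`, and normalized profiles are `M[j,i] / s_i`
(rows with zeros excluded, or a pseudocount). A two-step variant makes
the same factor comparable between contexts and different factors
comparable within a context. Cofactor co-occupancy is the per-site
Pearson correlation between normalized, context-matched profiles.

## Worked example

```r
library(cistromekit)
library(GenomicRanges)

# three studies' peaks on one chromosome (1-based GRanges; BED I/O is
# 0-based half-open via read_bed()/write_bed())
studyA <- GRanges("chr1", IRanges(c(11, 51), c(30, 60)))
studyB <- GRanges("chr1", IRanges(21, 40))
studyC <- GRanges("chr1", IRanges(c(26, 56), c(35, 58)))

consensus <- refgen(list(studyA, studyB, studyC), tau = 2)
consensus
#> ConsensusResult: 2 interval(s), tau = 2 of 3 input set(s)
#> inputs: set1, set2, set3
consensus$intervals
#> GRanges object with 2 ranges and 1 metadata column:
#>       seqnames    ranges strand |   support
#>          <Rle> <IRanges>  <Rle> | <integer>
#>   [1]     chr1     21-35      * |         3
#>   [2]     chr1     56-58      * |         2
```

Two regions are supported by at least two of the three studies; the
first is covered by all three at its core (`support = 3`). At `tau = 3`
only the triple intersection `chr1 26-30` would survive.

```r
M <- matrix(c(2, 4, 6, 8, 16, 24), ncol = 2)  # 3 bins x 2 experiments
normchip_size_factors(M)
#> [1] 0.5 2.0
normchip_apply(M, normchip_size_factors(M))
#>      [,1] [,2]
#> [1,]    4    4
#> [2,]    8    8
#> [3,]   12   12
```

Experiment 2 is sequenced 4× deeper than experiment 1; dividing each
column by its size factor puts both on the common scale (4, 8, 12).

## Command line

The `refchip` script (installed under `inst/cli/`) exposes every stage
as a subcommand — `refgen`, `classify`, `calibrate`, `extract`,
`normalize`, `correlate`, `annotate`, `enrich`, `state-assign`,
`simulate` — and `run` drives the full workflow from a YAML plan file
(see `?run_plan` for the schema):

```sh
refchip refgen --inputs a.bed --inputs b.bed --tau 0.75 \
  --tau-mode fraction --genome hg19.chrom.sizes --out ref.bed
refchip run --plan plan.yaml --outdir results/
```

All outputs are plain BED/TSV plus a JSON manifest; re-running a plan
with the same seed is byte-identical.

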