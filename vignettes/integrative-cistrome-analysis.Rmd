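---
title: "Integrative cistrome analysis: models, parameters, and design choices"
author: "cistromekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative cistrome analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(cistromekit)
  library(GenomicRanges)
})
```

## The problem

Public repositories hold many ChIP-seq peak sets for the same
transcriptional regulator (TR), produced by different labs, antibodies,
platforms and peak callers, under different treatment conditions. Any one
peak set mixes reproducible, functional binding sites with erratic,
short-lived or artefactual calls. `cistromekit` implements a start-to-end
strategy for distilling such compendia into a *reference cistrome* — the
set of binding sites reproducibly observed across studies — and then
annotating it along three axes: which experimental contexts each site is
bound in, which cofactors co-occupy it, and what chromatin state it sits
in.

## The majority vote

The core primitive is a per-base majority vote over interval sets. Every
input peak set is first collapsed so it can contribute at most one vote
per genomic position; the vote depth at a position is then the number of
sets covering it, and maximal runs of positions with depth at least a
severity threshold $\tau$ become consensus intervals:

* $\tau = 1$ yields the collapsed union;
* $\tau = n$ yields the per-base intersection;
* intermediate $\tau$ interpolates between the two, and consensus sets
  are nested in $\tau$.

The implementation is a breakpoint sweep (every interval opens +1 at its
start and closes −1 at its end), which is exact, runs in
$O(m \log m)$ for $m$ intervals, and needs no minimum-overlap or
peak-center heuristics. Each consensus interval reports the maximum
depth inside it as its `support`; the per-interval score is our own
convention (the vote itself defines only the qualifying positions).

Collapsing within a set before voting is a deliberate interpretation:
without it, a peak set containing two overlapping records could cast two
votes at one position and a single study could dominate the vote.

### The hierarchy

`build_reference()` chains three votes, mirroring how multi-study
compendia are organized:

1. **replicates → study cistrome**: $\tau$ = number of replicates (a site
   must appear in *all* biological replicates of a study);
2. **studies → context cistrome**: fractional $\tau$, default 75% of the
   study cistromes, rounded **up** (`ceiling`): 75% of 4 studies is 3, of
   6 studies is 5. Rounding up is the conservative majority reading of a
   fractional rule; both the fraction and count modes are exposed;
3. **contexts → reference**: $\tau = 1$, the union — a site needs support
   in only one experimental context to enter the reference, because
   context-private binding is itself biologically meaningful (it is what
   the co-occurrence classes measure).

### Calibrating the threshold

`calibrate_tau()` rebuilds the consensus after replacing every input set
by a random set with the same interval count, the same lengths, and (by
default) the same chromosome assignment — the behaviour of
`bedtools shuffle -chrom`. Shuffled intervals may overlap each other,
as with the reference tool, and are collapsed before voting like real
inputs. Repeating this (1,000 replicates by default) gives, per
$\tau$, the distribution of consensus counts expected from coincidental
overlap. The package reports the full observed-vs-random table
(counts, bp, mean, SD, 5%/95% quantiles, enrichment) and deliberately
does **not** pick a threshold: the published decision rule is verbal
("balance false positives and negatives"), so the choice belongs to the
analyst and the plan file. Placement excludes nothing by default (no
mappability or blacklist masking); an exclusion set is honoured by
rejection sampling capped at 1,000 attempts per interval.

Replicate $r$, input $i$ draws its seed as
`(seed + 1000003 * (r - 1) * n_sets + 1000003 * i) mod (2^31 - 1)`
from the master seed, so any replicate is independently reproducible.

## Signal normalization

Around each reference site, reads are counted in a window of ±5 kbp
fractioned into 50-bp bins (200 bins per site; both parameters are
settable, the bin size must divide the window). The site center is
`floor((start + end) / 2)` in 0-based coordinates, windows and bins are
half-open, and reads are assigned by their placement midpoint by default
(5′-end and every-overlapping-bin modes are available) — the choice is
ours, as read assignment is underdetermined by "reads within each bin
were counted". Sites whose window would leave the chromosome are dropped
(with a message), not zero-padded, so the row universe is identical
across experiments.

Experiments are put on a common scale by a median-of-ratios size factor,
the DESeq estimator applied to the pooled (site, bin) rows: with
$M[j,i]$ the count of bin row $j$ in experiment $i$,

$$G_j = \Big(\prod_{i=1}^{N} M[j,i]\Big)^{1/N}, \qquad
  s_i = \mathrm{med}_j\, \frac{M[j,i]}{G_j},$$

and normalized profiles are $M[j,i]/s_i$. One size factor per
*experiment* is the only self-consistent reading of the method (the
ratio matrix is reduced over rows, and a scaling constant corrects each
profile); bins are pooled across all sites so that a single factor
scales the whole experiment. Numerical choices:

* rows containing any zero are excluded from both the geometric mean and
  the median (the count of excluded rows is reported); a geometric mean
  with a zero is degenerate, and exclusion is the convention of the
  method this extends. A pseudocount option is provided as the
  alternative;
* the geometric mean is computed in log space (identical to the product
  form to ~1e-12 on feasible inputs, without overflow);
* the median of an even number of ratios is the mean of the two central
  order statistics;
* normalization is an exact fixed point: size factors recomputed on a
  normalized matrix all equal the geometric mean of the original
  factors, which the tests assert to 1e-10.

### Two-step strategy

For cofactor analysis, profiles are normalized twice
(`two_step_normalize()`): first each factor's datasets are normalized
together across all contexts and averaged within each context (making
the same factor comparable *between* contexts), then, within each
context, the per-factor averages are normalized against each other
(making different factors comparable *within* a context). A factor with
a single dataset, or a context with a single factor, skips the
corresponding scaling with a warning — there is nothing to estimate a
ratio against.

## Cofactor co-occupancy

Co-occupancy is quantified per site: the Pearson correlation between the
TR-of-interest bin vector and the candidate cofactor bin vector over the
site's 200 bins, computed only between context-matched, normalized
profiles. Per-site-then-average (rather than one correlation over all
concatenated bins) is the reading consistent with "computed between
signal profiles measured in each binding site"; a concatenated mode is
available behind a flag. Sites where either vector is constant have no
defined correlation; they are excluded from class means and counted,
never imputed as zero — zero-imputation would bias class means toward 0
wherever windows are empty. Class means (`subset_mean()`) and the
per-site cofactor ranking with quartile labels
(`rank_sites_by_cofactor_support()`, Q1 = top, ties broken by stable
site order) are descriptive statistics; no p-values are attached, by
design.

## Chromatin states

Segmentations are consumed, never learned: a BED4 file with state labels
(as ChromHMM/Spectacle emit) is validated to be non-overlapping and
summarized into per-state genomic fractions. Two complementary overlays
are provided:

* `assign_majority_state()` labels each site with the state covering the
  largest share of its bases (ties: lexicographically smallest label —
  any fixed rule works, this one is deterministic without an RNG; sites
  outside the segmentation are `"unsegmented"`), for site-count
  fraction tables per co-occurrence class;
* `state_enrichment()` is bp-weighted: the fraction of a feature's bases
  in each state, over the state's share of the segmented genome, gives
  an observed/expected ratio per state, standardized to Z-scores
  **across states within each feature row** (sample SD). Row-wise
  standardization matches the heat-map usage of "features enriched or
  depleted in each chromatin state"; a column-wise mode would answer a
  different question (which feature most prefers a state) and can be
  obtained by transposing the input. With fewer than two distinct
  ratios in a row the Z-scores are undefined and flagged rather than
  forced to 0.

## The synthetic-data generator

All tests and the acceptance script run on synthetic data with planted,
recoverable structure; the generator is first-class, tested code. Its
defaults define the study conditions:

* **genome**: 3 chromosomes × 1 Mb — large enough that the probability
  of a coincidental full-depth overlap of sparse random sets is
  negligible, small enough for per-base oracle checks;
* **truth cistrome**: non-overlapping sites of 150–400 bp (typical
  ChIP-seq peak widths), placed uniformly by rejection sampling;
* **studies**: 8 studies detect each true site independently with
  probability 0.9, boundaries jittered by N(0, 10 bp), plus 50 uniform
  noise peaks per study; provenance (`true_*`/`noise_*`) is recorded in
  the name field so recovery is scored unambiguously. Under these
  conditions the fraction of sites recovered at $\tau = 6$ has the
  Binomial(8, 0.9) upper-tail expectation $P(X \ge 6) \approx 0.962$,
  which the acceptance checks verify to within 3 standard errors over
  600 sites;
* **signal**: a shared per-site Gaussian-bump mean profile (amplitude
  drawn once per site and shared by all bump-class experiments,
  emulating co-binding), scaled by planted per-experiment size factors
  and Poisson-sampled per bin. The default baseline of 15 reads/bin
  keeps every scaled mean at or above 5 for the planted factors
  (1, 2.5, 0.4), the regime in which zero-row exclusion does not
  distort the median of ratios — recovery is tested to within 2% on
  200 bins × 50 sites;
* **segmentation**: the genome tiled by 2-kb blocks cycling through five
  states, with features drawn from the planted state with probability
  0.8 and uniformly otherwise.

What the generator does *not* emulate — GC and mappability bias,
fragment-length effects, duplicate reads, broad/multimodal signal
(domain-type marks), inter-study peak-caller differences — bounds what
passing tests show: they validate the algorithms' correctness and
statistical behaviour under their stated assumptions, not robustness to
every artefact of real ChIP-seq. In particular the signal model is
unimodal by construction, matching the normalization's stated scope.

Problem sizes throughout (600 planted sites, 200 oracle instances on
50-kb toy chromosomes, 100–1,000 shuffle replicates, 200-site
correlation panels) were chosen so every statistical check has
comfortable power while the whole suite stays interactive on a laptop.

## Degenerate inputs and errors

Empty BED files yield empty sets with a warning; malformed lines fail
with their line number; intervals beyond chromosome bounds error unless
clipping is requested; `tau` outside `[1, n]` and fractional `tau`
outside `(0, 1]` are parameter errors; a reference site overlapping no
context is an error when the reference was built from those contexts
(it cannot happen for a true union) and class `C0` with a warning when
the reference is user-supplied; size-factor estimation refuses matrices
with a single experiment or with no all-positive row (pointing to the
pseudocount option).

## Orchestration

`run_plan()` drives the whole workflow from one declarative plan (YAML
through the `refchip` CLI, a plain list in R): validation problems are
enumerated before any computation; every stage writes plain TSV/BED plus
a JSON manifest recording package version, seed and parameters — never
timestamps — so re-running a plan is byte-identical. Every subcommand is
also callable standalone; the CLI holds no hidden state.

## Known limitations

* Strand is ignored everywhere; no strand-aware logic is planned.
* The normalization targets unimodal signal around point-source binding;
  broad domains violate its assumptions.
* Backgrounds are uniform within chromosomes; no GC- or
  mappability-matched shuffling.
* Overlap annotation is descriptive (replicate-support rules), without
  permutation p-values beyond the calibration module.
* Chromatin-state *naming* conventions are out of scope; labels pass
  through verbatim.
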