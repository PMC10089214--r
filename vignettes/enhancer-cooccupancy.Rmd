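---
title: "Methods: enhancer co-occupancy, superenhancer calling, and expression signatures"
author: "enhancerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer co-occupancy, superenhancer calling, and expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscape)
```

## What the package computes

Germinal-center (GC) B cells depend on a network of enhancers and
superenhancers (E/SEs) maintained by chromatin modifiers such as the
acetyltransferase CREBBP and the methyltransferase KMT2D, which are among the
most frequently mutated genes in follicular lymphoma and DLBCL.  A standard
analysis of this biology asks four questions: where do two factors co-occupy
chromatin (co-binding), which of those sites are enhancers or superenhancers
(SE calling), what chromatin state those sites carry (histone-mark
classification), and what transcriptional program changes when the factors
are lost (differential expression and gene-set enrichment).

`enhancerscape` implements that full analysis as composable, tested stages
over plain-text genomics formats (BED/narrowPeak, bedGraph, GTF, count TSV,
GMT), together with seeded synthetic-data generators whose planted ground
truth makes every stage verifiable at desk scale.  The package analyses
real peak sets and count matrices exactly as it analyses simulated ones; the
simulators exist so that the statistical machinery can be held to account
against known truth.

## Coordinate model

All intervals are `GenomicRanges::GRanges` objects in the Bioconductor
1-based closed convention.  The on-disk formats keep their native
conventions — BED-family files, bedGraph and the gene TSV dialect are
0-based half-open, GTF is 1-based closed — and the readers convert on the
way in, the writers on the way out, so a write/read round trip is exact.
Using the field's canonical container means results drop directly into the
wider Bioconductor ecosystem; the cost is remembering that a printed
`GRanges` start is one greater than the corresponding BED start.

Edge gaps are the distance currency for co-binding ("peaks within 1 kb"
reads most naturally as proximity of domain edges); midpoint-to-TSS distance
is used for gene assignment, where a point anchor is needed.  Both are
available in `classify_cobound()` via `anchor`.

## Enhancer and superenhancer calling

The SE caller follows the classic stitching-and-ranking recipe:

1. **Promoter exclusion with an embedding rescue** — peaks overlapping any
   TSS ± 2 kb window are dropped, *unless* their provisional ±12.5 kb
   stitched domain also contains a non-promoter peak, in which case they are
   rescued as part of a larger active chromatin domain
   (`exclude_promoter_peaks()`).
2. **Stitching** — remaining peaks within 12.5 kb of each other (edge gap,
   overlap counts as gap 0) are concatenated into candidate domains
   (`stitch()`).
3. **Scoring** — ChIP and input tracks are each scaled to per-million
   library counts *before* the region sums are subtracted; without that,
   "input-subtracted signal" is meaningless across library sizes.  Scores
   are floored at zero (`score_stitched_enhancers()`).
4. **Cutoff** — scores are sorted ascending against rank, both axes
   rescaled to [0, 1], and the cutoff placed where a line of slope 1 is
   tangent to the convex hockey-stick curve, i.e. at the point of maximal
   vertical distance *below* the diagonal (`call_superenhancers()`).
   Enhancers strictly above the cutoff are superenhancers: the tangent
   point itself remains a typical enhancer.

Numerical details that matter: ties at the tangent point resolve toward the
higher score (fewer, stronger SE calls); fewer than three enhancers, or an
all-equal score vector, yield zero SEs with a warning rather than a
degenerate cutoff.  The partition is invariant to positive rescaling of all
scores, and adding a constant (flattening the curve) never increases the SE
count — both properties are tested.

## Chromatin states and co-occupancy statistics

`classify_regions()` maps the three canonical histone marks to four states:
H3K4me3 presence is promoter-like and dominates; otherwise
H3K4me1+/H3K27ac+ is an active enhancer, H3K4me1+/H3K27ac− a poised
enhancer, and no mark leaves the region unmarked.  Mark presence defaults
to any (≥ 1 bp) overlap, since no quantitative definition of "presence" is
canonical; a minimum covered fraction can be required via `min_frac`, with
stacked peaks counted through their base union.

Co-binding of two peak sets uses strict `distance < 1000` bp (overlap
included at distance 0).  `overlap_summary()` produces Venn-style counts by
clustering both sets at the same threshold and counting clusters containing
both an A and a B region as shared — one shared event per cluster, the
declared resolution of the one-to-many ambiguity — so that
`A_only + shared_A = |A|` always holds.  Overlap significance is the
upper-tail hypergeometric probability (`stats::phyper`, log-space stable),
with all active E/SE domains as the population.  Enrichment comparisons
between co-bound and solo regions use a Mann–Whitney rank-sum test: exact by
enumeration of all `choose(n+m, n)` labelings for pooled sizes up to 12
(valid under ties), and above that a normal approximation with tie and
continuity corrections plus an Edgeworth kurtosis term
(γ₂ = −1.2(n²+m²+nm+n+m)/(nm(N+1))), which keeps the approximation within
~3×10⁻³ of the exact answer at the switchover boundary.

## Binned signal profiles

`profile_matrix()` centres a window (default 3 kb) on each region midpoint
(`floor((start+end)/2)`, a deterministic integer anchor), splits it into
100-bp bins, and sums track signal per bin.  Bins-per-million uses the
deepTools-compatible definition `raw × 1e6 / total mapped reads`.  The
window is configurable because profile conventions in the literature mix
3-kb and 6-kb (± 3 kb) windows for the same figure style; neither is
asserted as canonical here.  Bins that would fall before the chromosome
origin are zero-filled and counted in the `n_clipped` attribute.

## Differential expression

The expression stage re-implements a deliberately simple two-group
negative-binomial Wald test rather than wrapping an existing tool, so the
whole estimator chain is inspectable and testable:

* **Sanitization** — genes are removed by biotype class (rRNA, miRNA,
  pseudogene, antisense, read-through), chromosome (chrY), explicit id list
  (e.g. imprinted chrX genes), and symbol regex (e.g. immunoglobulin V/D/J
  segments), with per-rule removal counts reported.
* **Normalization** — median-of-ratios size factors over genes with nonzero
  counts in all samples; TPM (`rate = count / length_kb`, rescaled to 1e6
  per sample) for reporting and clustering.
* **Test** — per-gene dispersion by the method of moments on normalized
  counts within each group, pooled with degrees-of-freedom weights and
  floored at 1e-8 (or a fixed value); `log2_fc` compares group means, with
  an all-zero group mean replaced by a configurable pseudo-mean (default
  0.125 normalized counts, flagged in the output) to avoid infinities; the
  Wald statistic uses the delta-method standard error with per-sample size
  factors, and p-values are two-sided normal.  There is no dispersion
  shrinkage, LFC shrinkage, or independent filtering: the acceptance
  surface is parameter recovery on planted truth, not replication of any
  specific tool's estimator chain.
* **Calling** — Benjamini–Hochberg q-values (strict `q < 0.05`) combined
  with a linear fold-change threshold (`|FC| ≥ 1.2`, applied on the raw,
  unshrunken fold change — the declared reading of a linear-scale FC
  filter).

The normal Wald reference is mildly anticonservative at small sample sizes
(the usual t-vs-normal effect: at 10 samples per group the acceptance
script's measured null type-I fraction at p < 0.05 is about 0.065); the BH
step keeps false calls controlled, as the null simulations verify.

Unsupervised structure uses the top-500-SD genes, `1 − Pearson r` distance
and UPGMA (average-linkage) agglomeration via `stats::hclust`; constant
gene rows are dropped with a warning since their correlation is undefined.
Cross-species signature tracking goes through a two-column ortholog table
(`map_orthologs()`), with a declared keep-all or first-match policy for
1:many mappings.

## Preranked GSEA

`enrichment_score()` implements the weighted Kolmogorov–Smirnov running
sum: hits increment by `|score|^p / Σ_hits |score|^p` (p = 1 by default;
0 and 2 supported; an all-zero weight vector falls back to equal
increments), misses decrement by `1/(N − N_hits)`, and the enrichment score
is the running-sum value of maximal absolute deviation, sign retained.
When the positive and negative extrema tie in magnitude (to within
floating-point noise) the extremum reached first wins, fixing the sign
deterministically.  The leading edge contains the hits at or before the
extremum (at or after, for negative ES).

`preranked_gsea()` uses gene-label permutation — size-matched random sets
drawn from the ranking under a mandatory seed — rather than phenotype
permutation, because signatures are applied to externally supplied
rankings where no per-sample data exist.  The permutation p-value is
magnitude-based with add-one smoothing,
`p = (1 + #{|ES_null| ≥ |ES|}) / (n_perm + 1)`: this makes p exactly
uniform under the null (verified by a KS test in the acceptance suite) and
gives a minimal attainable value of `1/(n_perm+1)`, while the sign of the
enrichment is carried by ES and NES.  NES divides ES by the mean |null ES|
of matching sign, and the FDR q follows the sign-stratified ratio-of-tails
scheme over the pooled null NES distribution.  Default `n_perm = 1000`.

Gene-to-region linking for set-enrichment inputs uses distance-ranked
nearest-TSS assignment from the region midpoint, ties broken by gene id
(`assign_nearest_gene()`, `top_assigned_genes()`); annotation-tool
significance rankings are deliberately not imitated, and the output carries
an `assignment` attribute naming the rule so downstream users know genes
were ranked by distance.

## The synthetic-data generators

Each generator is a pure function of its parameters and an integer seed; a
master seed fans out to per-stage child seeds (`child_seed()`, an affine
hash modulo 2³¹−1) so any stage can be regenerated independently.  The
default conditions are:

* `simulate_genome()` — 3 chromosomes × 6 Mb, 300 non-overlapping genes of
  2–20 kb, strands Bernoulli(0.5), biotype mix 80% protein-coding with 5%
  each of rRNA/miRNA/pseudogene/antisense so the sanitization filters are
  exercised.
* `simulate_cooccupancy()` — 1000 A and 1000 B peaks (200–400 bp), a
  planted co-bound fraction of 0.6 with partner gaps uniform on
  0…999 bp; solo peaks are placed at least 5 kb (five thresholds) from any
  partner so the planted labels are unambiguous.
* `simulate_se_signal()` — 100 typical enhancer peaks plus 5 superenhancer
  clusters of 3–6 constituents within stitching range; SE constituents get
  10× the typical signal density (1 read/bp) with Poisson jitter over a
  0.05 read/bp background; the input track is flat background with Poisson
  jitter in 10-kb bins.  Units are spaced further apart than the stitching
  gap so each stitches to exactly one candidate.
* `simulate_counts()` — 2000 genes × 10 samples/group, lognormal baselines
  (meanlog log 100, sdlog 1), NB dispersion 0.1, 10% DE genes at |LFC| = 2
  with random sign, relative library sizes uniform on [0.7, 1.3]; 13 gene
  sets of 50, one planted at 80% same-direction DE genes, the rest random
  decoys.

These values are the package's statement of a realistic desk-scale GC
ChIP-seq/RNA-seq study: sub-kilobase co-binding, order-10× SE signal
enrichment, a 1.2-fold calling threshold regime, and three-versus-three to
ten-versus-ten replicate designs.  What the simulations deliberately do
*not* model: genome sequence content, mappability and GC bias,
fragment-length effects, copy-number variation, peak-caller artefacts,
overdispersion heterogeneity across genes, and correlated gene-gene
expression.  Passing the recovery tests therefore demonstrates that the
estimators are correct under their stated model, not that any real dataset
satisfies that model.

## Orchestration and reproducibility

`run_pipeline()` ties the stages into two workflows (chromatin:
annotation → co-binding → hypergeometric overlap → states → SE calling →
profiles; expression: filters → TPM → clustering → NB Wald → signatures →
GSEA panel) over a self-contained fixture directory, validating every input
and parameter before any stage writes output.  The `manifest.json` it
writes contains the package version, workflow, seed, parameters, and MD5
checksums of all inputs and outputs — and nothing time-dependent — so
identical configuration and seed reproduce the manifest byte for byte.

The test suite holds every stage to brute-force oracles (all-pairs
merging, exhaustive hypergeometric enumeration, direct running-sum
iteration, literal BH step-up, exhaustive UPGMA) and to planted-truth
recovery at the default conditions above, with simulation sizes chosen to
keep the whole suite in the low minutes on a single core: 1000 random
interval sets for the stitching oracle, 20 seeds for each recovery
surface, 500 permutations for GSEA calibration checks.

## Known limitations

* The NB test is two-group only: no covariates, batch terms, or multi-factor
  designs.
* Dispersion is estimated per gene without shrinkage; at very small
  replicate numbers (n = 2–3) its moments are noisy, and the Wald normal
  reference is anticonservative — the planted-truth tests use n ≥ 8.
* bigWig/bigBed and BAM inputs are out of scope; tracks arrive as bedGraph.
* SE calling implements the geometric cutoff only; copy-number correction
  and gene-mapping heuristics beyond nearest-TSS are not included.
* GSEA FDR uses the standard ratio-of-tails estimator, which is known to be
  conservative for small collections.
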