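# enhancerscape

Enhancer co-occupancy, superenhancer calling, and expression-signature
analysis for germinal-center B-cell regulatory genomics — built as small,
tested stages over plain-text formats, with seeded synthetic-data
generators so every statistical claim can be checked against planted
ground truth.

## Who this is for, and what it does

Chromatin modifiers such as CREBBP and KMT2D maintain the enhancer and
superenhancer (E/SE) network of germinal-center B cells, and their loss
rewires a distinct transcriptional program.  Analyzing that biology needs
four connected computations, all provided here:

1. **Co-occupancy** (`classify_cobound`, `overlap_summary`,
   `hypergeometric_overlap`, `rank_sum_test`) — which peaks of factor A sit
   within 1 kb of a peak of factor B; Venn-style shared/unique counts; the
   upper-tail hypergeometric
   `P(X ≥ k)` for the overlap of two region subsets within a population of
   active E/SEs; Mann–Whitney comparison of mark enrichment (exact by
   enumeration for pooled n ≤ 12, Edgeworth-corrected normal beyond).
2. **Superenhancer calling** (`call_enhancers` =
   `exclude_promoter_peaks` → `stitch` → `score_stitched_enhancers` →
   `call_superenhancers`) — promoter exclusion with an "embedded in a
   larger active domain" rescue, ±12.5 kb stitching, per-million
   input-subtracted signal ranking, and the signal-vs-rank cutoff at the
   point where a slope-1 line is tangent to the rescaled hockey-stick
   curve.
3. **Chromatin states** (`classify_regions`) — active
   (K4me1+/K4me3−/K27ac+), poised (K4me1+/K4me3−/K27ac−), promoter-like
   (K4me3+), or unmarked, from histone-mark peak overlap; plus binned,
   bins-per-million signal profiles around peak midpoints
   (`profile_matrix`).
4. **Expression signatures** (`filter_genes`, `tpm_normalize`,
   `nb_wald_test`, `call_de`, `make_signature`, `preranked_gsea`) —
   reference sanitization, TPM, a simplified negative-binomial Wald test
   (median-of-ratios size factors, method-of-moments dispersion), the
   `FDR < 0.05` and `|FC| ≥ 1.2` signature call, top-500-SD UPGMA sample
   clustering, and from-scratch preranked GSEA (weighted KS statistic
   `ES`, permutation `NES`, uniform permutation p, ratio-of-tails FDR).

A synthetic-data module (`simulate_genome`, `simulate_cooccupancy`,
`simulate_se_signal`, `simulate_mark_states`, `simulate_counts`,
`simulate_fixture`) generates all inputs with known truth tables, and
`run_pipeline()` runs the two end-to-end workflows with a deterministic
manifest.  See the methods vignette
(`vignettes/enhancer-cooccupancy.Rmd`) for the statistical details and
design decisions.

## Worked example

Simulate a genome with planted superenhancers and a planted expression
program, then recover both:

```r
library(enhancerscape)

gen <- simulate_genome(seed = 5)
sim <- simulate_se_signal(gen$chrom_sizes, n_enhancers = 100,
                          se_clusters = 5, enrichment_ratio = 10, seed = 42)
se <- call_enhancers(sim$peaks, sim$chip, sim$input, gen$genes)
se
#> se_call: 99 stitched enhancers, 5 super (cutoff score 527)
head(se$enhancers[order(se$enhancers$rank),
                  c("chrom", "start", "end", "constituents", "score", "is_super")], 6)
#>   chrom   start     end constituents      score is_super
#> 1  chr1 2445945 2454616            5 23889.8124     TRUE
#> 2  chr1 2144250 2152486            4 19240.6247     TRUE
#> 3  chr1  804882  809098            3 14394.8027     TRUE
#> 4  chr1 3350810 3354093            3 14270.3409     TRUE
#> 5  chr1 1608900 1614305            3 14220.2886     TRUE
#> 6  chr1 3317432 3317932            1   527.0089    FALSE
```

The five multi-constituent domains carrying ~10× signal are exactly the
planted superenhancers (`sim$truth`); the cutoff (527) sits at the top of
the typical-enhancer regime.  Co-binding and expression behave the same
way:

```r
co <- simulate_cooccupancy(gen$chrom_sizes, n_A = 1000, n_B = 1000,
                           cobound_fraction = 0.6, seed = 42)
classify_cobound(co$A, co$B)$fraction
#> [1] 0.6

cts <- simulate_counts(n_genes = 2000, n_per_group = 10, frac_de = 0.1,
                       lfc = 2, dispersion = 0.1, seed = 42)
de <- call_de(nb_wald_test(cts$se, "WT", "dHET"), fdr = 0.05, min_fc = 1.2)
de$results
#> de_result: 2000 genes, contrast dHET vs WT
#>   called: 125 up, 103 down

ranked <- ranked_list(de$results$gene_id, de$results$wald)
panel <- run_signature_panel(ranked, cts$sets, n_perm = 1000, seed = 42)
panel[panel$significant, c("set", "n_hits", "es", "nes", "p_perm", "q_fdr")]
#>              set n_hits         es     nes      p_perm q_fdr
#> 13 set_planted01     50 -0.9599318 -2.7064 0.000999001     0
```

The ~200 genes planted at |log2FC| = 2 drive 228 calls at the dual
threshold, and the one planted gene set (among 12 random decoys) is the
only signature the GSEA panel flags, at the minimal attainable permutation
p of 1/1001.

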