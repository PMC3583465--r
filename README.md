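# exondiff

Analysis of two-condition exon microarray experiments: gene-level
differential expression, exon-level alternative splicing, functional
enrichment, and the wet-lab companion statistics (qPCR relative
quantification and flow-cytometry apoptosis testing). The package is aimed
at transcriptomics analysts working with exon-tiling arrays — platforms
whose probes target individual exons, so a single hybridization yields both
transcript-level expression and relative exon-inclusion information.

Because raw array data are often unavailable or impractical at desk scale,
the package ships a synthetic exon-array generator with known spiked truth
(differentially expressed genes and shifted cassette exons), so every stage
of the pipeline can be exercised and benchmarked end to end.

## The method

For probes *p* grouped into genes *g* with samples in conditions
*control* and *treated*:

1. **Global mean normalization** — each array is scaled multiplicatively so
   its mean intensity equals the grand mean of all arrays; within-array
   ratios are untouched.
2. **Detection filter** — probes with intensity below 400 (in both
   condition means, by default) are removed.
3. **Transcript summarization** — the transcript-level signal of gene *g*
   in a condition is the geometric mean of all its retained probes across
   that condition's replicates.
4. **Differential expression** — a gene is called DE when the ratio
   `signal_treated / signal_control` is at least 2-fold in either
   direction. Reported as a signed fold-change (+r, or −1/r for
   down-regulation), so magnitudes are always ≥ 1.
5. **Splicing index (SI)** — the probe-normalized value of probe *p* is its
   condition-mean intensity; the GNPN (gene-normalized probe-normalized)
   value divides it by the geometric mean over all of *g*'s retained
   probes. GNPN cancels gene-level expression changes, so
   `SI(p) = GNPN_treated(p) / GNPN_control(p)` (ratio mode; a difference
   mode is also provided) deviates from 1 only where an exon's inclusion
   rate changed relative to its gene. Probes beyond a configurable
   threshold are alternative-splicing candidates.
6. **Enrichment** — a query gene set (the DE or AS genes) is tested
   against each functional term by the upper-tail hypergeometric
   probability P(X ≥ k) for an overlap of *k* among *n* query genes, *K*
   term genes and *N* universe genes, with Benjamini–Hochberg q-values
   across the tested terms.
7. **Validation-side statistics** — qPCR Ct tables are quantified with the
   2^−ΔΔCt method (ΔCt against a reference gene, ΔΔCt against the
   calibrator condition), and Annexin-V/PI quadrant percentages (early +
   late apoptotic) are compared across groups with a two-sample Student or
   Welch t-test computed directly from n / mean / SD summaries.

## Worked example

```r
library(exondiff)

xp  <- simulate_exon_experiment(sim_spec(n_genes = 500, seed = 42))
run <- run_pipeline(xp$intensity, xp$annotation, xp$design)
run
#> Exon-array pipeline run
#>   probes: 3944 in, 407 removed by filter, 3537 retained
#>   genes summarized: 469; DE: 12 (8 up / 4 down)
#>   AS candidate probes: 5 across 5 genes
#>   config hash: f6703b0cb40cabc05675166366f532da

score_de_calls(run$de, xp$truth)
#> # A tibble: 1 × 6
#>   n_true n_called    tp    fp sensitivity   fdp
#>    <int>    <int> <int> <int>       <dbl> <dbl>
#> 1     12       12    12     0           1     0
```

Of 500 simulated genes, 469 survive the 400-intensity filter with at least
one probe; 12 genes were spiked with a 4-fold shift and all 12 are
recovered by the 2-fold rule with no false calls. `autoplot(run$de)` draws
the MA-style fold-change plot, `autoplot(run$splice)` the SI distribution,
and `tidy()` / `glance()` turn any result into a tibble.

The companion statistics work from published-style summaries:

```r
two_sample_t(tibble::tibble(
  condition = c("treated", "control"),
  n = c(3, 3), mean = c(11.47, 4.77), sd = c(0.25, 0.40)))
#> Two-sample t-test (student), treated vs control
#> t = 24.6, df = 4, p = 1.62e-05 (significant at alpha = 0.05)
```

An 11.47% vs 4.77% apoptotic fraction over triplicates is a very strong
treatment effect: t = 24.6 on 4 degrees of freedom.

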