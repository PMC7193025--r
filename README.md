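# chemgsea

Screening environmental chemicals for association with a disease, on genetic
evidence alone. Direct measurement of chemical exposure is hard; curated
chemical–gene interaction sets (one gene set per chemical, CTD-style) make an
indirect screen possible: if a disease's associated genes concentrate inside a
chemical's interaction set, the chemical is a candidate modifier of the
disease. `chemgsea` implements that screen end to end for three gene-level
evidence streams and intersects the results.

## What it computes

**Gene-level scores**, per evidence stream:

- *Summary TWAS*: for each gene, `z = w'Z / sqrt(w'Lw)` from GWAS summary
  z-scores `Z`, eQTL expression weights `w` and an LD reference `L`, with a
  two-sided normal p-value.
- *Best-SNP*: the largest `|z|` among SNPs within a window (default 50 kb) of
  the gene body.
- *Expression*: the Welch two-sample t statistic between case and control
  samples.

**Chemical enrichment**, per stream: genes ranked by score magnitude
`r`, and for each chemical set `S` (overlap `N_H` of the `N`-gene universe)
the running-sum statistic

    ES(S) = max_j {  sum_{hits <= j} |r|^p / N_R  -  sum_{misses <= j} 1/(N - N_H)  },
    N_R   = sum_{hits} |r|^p,   p = 1 by default,

against a permutation null of same-size random sets:
`NES = (ES - mean(ES_null)) / SD(ES_null)` and the add-one empirical p-value
`p = (1 + #{ES_null >= ES}) / (n_perm + 1)`, plus BH q-values.

**Integration**: chemicals significant (`p < 0.05`) in the expression stream
AND at least one GWAS-side tissue stream are "common" per disease, with
explicit per-tissue accounting (`union = sum of tissue counts - multi-tissue
overlap`); the pan-disease set is the name intersection across diseases.

A synthetic-data module generates every input (AR(1)-LD GWAS z-scores,
normalized weights, overlapping chemical sets with planted causal subsets,
two-group expression) with known ground truth, so the whole pipeline is
testable without external downloads.

## Worked example

A small end-to-end run: 600 genes, 100 chemicals of which 3 are causal, two
diseases sharing the causal chemicals, 300 permutations.

```r
library(chemgsea)

cfg <- sim_config(n_genes = 600, n_snps_per_gene = 5, n_chemicals = 100,
                  set_size_range = c(10, 60), n_causal_chemicals = 3,
                  n_case = 30, n_control = 30, seed = 7001)
screen <- run_pipeline(cfg, gsea_config(n_permutations = 300, seed = cfg$seed))
screen
#> Synthetic chemical screen
#>   genes: 600, chemicals: 100 (3 causal)
#>   streams: colon.twas:colon, colon.expression, rectal.twas:rectum, rectal.expression
#> Chemical integration report (alpha = 0.05)
#>   colon: 4 common chemical(s)
#>   rectal: 3 common chemical(s)
#>   shared across diseases: 3
#>     chem_0001, chem_0002, chem_0003

head(tidy(screen)[, c("disease", "stream", "chemical", "es", "nes", "p_empirical")], 4)
#> # A tibble: 4 × 6
#>   disease stream     chemical     es   nes p_empirical
#>   <chr>   <chr>      <chr>     <dbl> <dbl>       <dbl>
#> 1 colon   twas:colon chem_0003 0.840  6.19     0.00332
#> 2 colon   twas:colon chem_0002 0.819  4.56     0.00332
#> 3 colon   twas:colon chem_0001 0.831  3.48     0.00332
#> 4 colon   twas:colon chem_0084 0.601  2.77     0.00332
```

The three planted causal chemicals (`chem_0001..chem_0003`) top the TWAS
stream at the minimum attainable p-value `1/301 = 0.00332` and are exactly
the pan-disease common set: they are the only chemicals passing all three
independent 0.05 screens. `glance(screen)` summarizes counts;
`autoplot(screen$report)` draws the intersection counts, and
`plot_enrichment(screen$scores$expression, screen$sets$members[[1]])` shows a
running-sum curve.

On-disk formats (tab-separated GWAS summaries, GMT gene sets, weights, LD
matrices, expression + groups, results tables) have paired `read_*`/`write_*`
functions; `write_simulation()` emits a complete simulated study directory.

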