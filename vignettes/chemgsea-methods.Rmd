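---
title: "Methods: chemical gene-set enrichment from GWAS, TWAS and expression evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical gene-set enrichment from GWAS, TWAS and expression evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Measuring a person's lifetime exposure to environmental chemicals directly is
close to impossible, but chemical–gene interactions are curated at scale in
toxicogenomics databases: for each chemical, the set of genes it is known to
interact with. If the genes associated with a disease concentrate inside a
chemical's interaction set, that chemical becomes a candidate modifier of the
disease — without any exposure measurement. `chemgsea` implements this screen
as a reusable pipeline with three gene-level evidence streams:

1. **Summary TWAS** — gene-level association statistics built from GWAS
   summary z-scores, per-gene eQTL expression weights and an LD reference.
2. **Best-SNP GWAS scores** — the most significant SNP statistic near each
   gene.
3. **Differential expression** — a two-group (case vs control) comparison of
   an expression matrix.

Each stream yields a ranked gene list. Every chemical gene set is tested
against that ranking with a running-sum enrichment statistic and a
permutation null; chemicals significant in several independent streams (and,
for related diseases, in both diseases) form the final candidate list.

## Models and statistics

### Summary TWAS

For one gene with expression weights $w$ (one entry per model SNP), GWAS
z-scores $Z$ at those SNPs and SNP correlation (LD) matrix $L$,

$$ z_{\mathrm{TWAS}} = \frac{w'Z}{\sqrt{w'Lw}} , $$

with a two-sided standard-normal p-value. Under the null ($Z \sim
\mathcal{N}(0, L)$) the statistic is exactly standard normal; planting a mean
$\lambda \, Lw / \sqrt{w'Lw}$ on $Z$ gives $E[z_{\mathrm{TWAS}}] = \lambda$,
which is how the synthetic generator controls effect sizes.

**Numerical policy.** The quadratic form $w'Lw$ is computed without
inversion. If the LD block is not numerically positive definite (smallest
eigenvalue below $10^{-8}$) it is ridged as $L \leftarrow 0.99\,L + 0.01\,I$
first; well-conditioned blocks are used exactly, so textbook cases reproduce
to machine precision while singular blocks (e.g. duplicated SNPs) still yield
a usable statistic. If $w'Lw$ remains non-positive the gene is skipped and
counted. Model SNPs absent from the GWAS are dropped *jointly* from $w$, $L$
and $Z$; a gene is skipped when no SNP remains. Allele harmonization is
assumed done upstream — the package does not flip strands or alleles.

### Gene ranking

Scores are magnitudes: $|z_{\mathrm{TWAS}}|$, the best in-window $|z|$
(default window 50 kb each side of the gene body — a conventional
SNP-to-gene assignment radius, configurable), or the absolute Welch
two-sample t statistic for expression. Lists are sorted descending with ties
broken by gene id, so a ranking is a pure function of its inputs. Genes
missing from a stream (no SNP in window, model skipped) are excluded from
that stream's universe rather than imputed to zero — each stream has its own
$N$. Welch's unequal-variance t is used for expression rather than a
moderated (shrinkage) statistic; at the default sample sizes (77 vs 117) the
difference is immaterial and the statistic stays self-contained.

### Enrichment score

For a ranked universe of $N$ genes with scores $r_j$ and a chemical set $S$
overlapping the universe in $N_H$ genes,

$$ ES(S) = \max_{1 \le j \le N} \left\{ \sum_{\substack{G_{j^*} \in S \\ j^* \le j}}
\frac{|r_{j^*}|^p}{N_R} - \sum_{\substack{G_{j^*} \notin S \\ j^* \le j}}
\frac{1}{N - N_H} \right\}, \qquad N_R = \sum_{G_j \in S} |r_j|^p . $$

The running sum ends at exactly $0$ (total hit mass $1$ minus total miss
mass $1$), so $0 \le ES \le 1$: this is a *one-sided* statistic — a set
concentrated at the bottom of the ranking scores 0, not negative. A classic
two-sided variant (signed maximum absolute deviation) is available behind
`two_sided = TRUE` for users who want depletion to be visible; it is not the
default and not used by the pipeline.

The exponent defaults to $p = 1$ (score-weighted hit increments, the
original GSEA default); $p = 0$ gives the unweighted Kolmogorov–Smirnov
form. One property worth knowing: "promoting a member gene to a better rank
never decreases ES" is exactly true at $p = 0$, but can fail at $p = 1$,
because promotion changes $N_R$ and can dilute a single dominant member's
hit mass. The test suite asserts the property at $p = 0$ only.

The implementation is a single $O(N)$ pass. The permutation engine uses an
algebraically equivalent shortcut — the maximum is always attained at a
member position, so only $N_H$ positions are visited per draw — and the
suite pins both paths to a brute-force double-loop oracle at $10^{-12}$.

### Permutation null, NES and empirical p

Only summary-level data exist, so the null permutes gene labels: each of
$\Lambda$ draws takes a uniformly random subset of the universe of the same
size as the observed overlap and records its ES. Under score exchangeability
this equals score permutation. Because the null depends on the set only
through its size, it is computed once per distinct size and shared across
chemicals of that size — with per-size child seeds, so results do not depend
on the order of the sets.

$$ NES_S = \frac{ES_S - \mathrm{mean}(ES^{\mathrm{null}}_S)}
{\mathrm{SD}(ES^{\mathrm{null}}_S)}, \qquad
p = \frac{1 + \#\{ES^{\mathrm{null}} \ge ES_S\}}{\Lambda + 1}. $$

The add-one estimator keeps $p \ge 1/(\Lambda+1)$ and never returns 0. If
the null SD collapses below $10^{-12}$ (constant scores), NES is set to 0
while the p-value is still computed from counts. Significance is declared on
the raw empirical p at $\alpha = 0.05$; Benjamini–Hochberg q-values are
reported in an extra column but do not gate significance, matching the
screening character of the analysis. Default size filters keep sets whose
universe overlap is 5–500 genes: below 5 the running-sum null is too coarse,
above 500 a "set" is closer to a background. Results are ordered by
empirical p, then NES (descending), then chemical name — NES breaks the
frequent ties at the attainable floor $1/(\Lambda+1)$ more informatively
than the alphabet. The per-chemical screen defaults to $\Lambda = 5000$
permutations; the bundled end-to-end pipeline uses $\Lambda = 1000$ to keep
a full two-disease run in the minutes range (p-value resolution $10^{-3}$,
ample for an $\alpha = 0.05$ screen).

### Integration

Per disease, a chemical is *common* when significant in the expression
stream AND in at least one GWAS-side tissue stream; the per-tissue
breakdown is retained so the counts obey
$|union| = \sum_t n_t - n_{\text{multi-tissue}}$. Chemicals absent
(untested) in a stream are flagged `NA`, never treated as non-significant,
and never declared common. Across diseases the pan-common set is the exact
name intersection (after whitespace trimming — chemical names are opaque
keys; no synonym resolution is attempted) of the per-disease common sets.

## The synthetic generator

The generator produces every input the pipeline consumes, with known ground
truth, emulating the statistical structure the analysis assumes:

- **LD**: one AR(1) block $L_{ij} = \rho^{|i-j|}$ (default $\rho = 0.5$,
  10 SNPs/gene) — the simplest positive-definite structure with realistic
  decay.
- **Weights**: i.i.d. normal, rescaled so $w'Lw = 1$ per gene.
- **GWAS z-scores**: $Z = \lambda\,Lw/\sqrt{w'Lw} + \varepsilon$,
  $\varepsilon \sim \mathcal{N}(0, L)$, so effects enter through the exact
  statistic the pipeline computes rather than through genotype-level
  simulation.
- **Chemical sets**: 500 sets with sizes uniform on 10–200 sampled from a
  2,000-gene universe (overlaps allowed), the first 5 causal; each causal
  set contributes a `causal_fraction` (default 0.5) share of its members to
  the causal gene pool.
- **Expression**: standard-normal genes-by-samples matrix, 77 cases vs 117
  controls (the tumor/mucosa sample sizes of the motivating expression
  dataset), with a $+\delta$ (default 1) shift in case samples of causal
  genes.

Default effect sizes ($\lambda = 4$, $\delta = 1$) are chosen for power
testing — strong enough that planted chemicals are recoverable through
three independent screens — not as estimates of any real chemical's effect.
A single global seed fans out to per-component child seeds by fixed offsets,
so every component is independently reproducible and the whole pipeline is
byte-identical across reruns.

What the generator does **not** emulate: minor-allele-frequency spectra,
genotype-level sampling noise in the weights, cross-tissue eQTL sharing,
microarray normalization artifacts, or correlated expression between genes.
Passing tests therefore demonstrate the *statistical machinery* — null
calibration, effect recovery, bookkeeping — on data satisfying the model's
assumptions; they do not certify performance on violations of those
assumptions (e.g. correlated genes inflating GSEA significance, a known
property of gene-label permutation nulls).

## Problem sizes used in the checks

Calibration checks run at 5,000 genes (TWAS null), 500 null chemical sets
at $\Lambda = 500$ (GSEA calibration and NES standardization), 1,000 causal
genes (effect recovery), 20 end-to-end replicates at the default scale
(planted-chemical recovery), and two full two-disease pipeline runs at
$\Lambda = 1000$ (determinism). These sizes give binomial/KS sampling error
comfortably inside the asserted bounds while keeping a full run on one core
in the minutes range.

## Known limitations

- One-sided ES: protective (bottom-concentrated) enrichment is invisible by
  design; use `two_sided = TRUE` to see it.
- Gene-label permutation assumes exchangeable scores; correlated gene scores
  (LD leaking across genes, co-expression) make the null anti-conservative.
- Exact-name chemical matching across streams; no synonym normalization.
- No allele/strand harmonization of GWAS against weights.
- The moderated-t machinery of microarray practice is intentionally not
  reimplemented; the expression stream uses plain Welch t.
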