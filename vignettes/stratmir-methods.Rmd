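---
title: "Methods: gender-stratified miRNA screens, qPCR validation and pathway overlap networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gender-stratified miRNA screens, qPCR validation and pathway overlap networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratmir)
```

## The analysis problem

Relapsing-remitting multiple sclerosis (RRMS) shows marked sex differences
in incidence and course. A natural screen design is therefore
*gender-stratified*: compare miRNA profiles of cases and controls
separately in men and in women, rather than pooling and adjusting. The
archetypal finding this package operationalizes is a cluster of miRNAs —
encoded in the imprinted DLK1-DIO3 locus on chromosome band 14q32 —
upregulated in male patients only, validated by RT-qPCR in an independent
cohort where the interesting signal is a *status-by-gender interaction*
(expression lower in healthy men than healthy women, rising in affected men
to meet or exceed the female level), and interpreted through a
network-based enrichment of the cluster's target genes in receptor tyrosine
kinase (RTK) signaling pathways.

`stratmir` implements that full chain as reusable, tested components:

1. **Differential expression** (`normalize_log_cpm()`, `moderated_de()`,
   `bh_adjust()`, `filter_de()`) — stratified moderated t-tests on log-CPM.
2. **Locus annotation** (`assign_band()`, `colocalization_summary()`,
   `locus_census()`) — band-level co-localization of hit sets.
3. **qPCR statistics** (`delta_ct()`, `log2fc_ddct()`,
   `qpcr_interaction()`, `qpcr_tukey()`) — relative quantification and the
   interaction analysis.
4. **Network enrichment** (`ora_grid()`, `pathway_mirna_counts()`,
   `select_outlier_pathways()`, `build_overlap_network()`,
   `subfamily_overrepresentation()`).
5. **Synthetic data** (`simulate_counts()`, `simulate_ct()`,
   `simulate_genesets()`) — seeded generators reproducing the statistical
   structure above, so the chain runs and is testable with no downloads.

`run_pipeline()` orchestrates all stages from one configuration.

## Differential expression model

Counts are normalized to log2 counts-per-million with a pseudocount
$c^* = \log_2\!\frac{(c + 0.5)\,10^6}{L + 1}$ where $L$ is the sample's
library size. Normalization is deliberately plain total-count CPM: the
upstream tooling this emulates names only a linear-model package, so the
default is the most auditable choice; trimmed-mean (TMM) factors would be a
reasonable alternative for data with stronger compositional effects.

Within each stratum, each feature is tested by a two-group linear model.
With pooled variance $s^2_g$ on $d = n_1 + n_2 - 2$ degrees of freedom, the
empirical-Bayes moderated variance is

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

a posterior mean under a scaled inverse-$\chi^2$ prior whose parameters
$(d_0, s_0^2)$ are fitted across features by matching the first two moments
of $\log s^2_g$ (Fisher's log-variance distribution; $d_0$ is obtained by
Newton inversion of the trigamma function). The moderated statistic

$$t_g = \frac{\widehat{\mathrm{lfc}}_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}}$$

is referred to a t distribution on $d_0 + d$ degrees of freedom. If the
moment system has no positive solution (e.g. all $s^2_g$ equal), the
implementation falls back to $d_0 = \infty$ with $\tilde s^2 =
\operatorname{median}(s^2)$ and warns; constant features return $t = 0$,
$p = 1$ rather than NaN. With `shrinkage = "none"` the statistic reduces
exactly to the classical pooled t-test. The test suite verifies agreement
with `limma` to near machine precision on simulated data; `limma` is used
only as an independent oracle, never as the implementation.

P-values are adjusted within stratum by the Benjamini-Hochberg step-up
rule, and hits are filtered with *strict* inequalities: adjusted
$p < 0.05$ and $|\mathrm{log_2FC}| > 1$ (boundary values excluded).
`power_sample_size()` exposes the companion design calculation: the
smallest per-group $n$ at which a two-sample t-test of standardized effect
$d$ reaches a target power, by exact noncentral-t enumeration. At
$d = 2$, $\alpha = 0.05$, power 0.8 (two-sided) this gives $n = 6$;
one-sided, $n = 5$. Published claims of $n = 4$ sufficing at these settings
are not reproducible from the standard two-sample calculation, so the
function exposes sidedness and thresholds rather than forcing any value.

## Locus co-localization

Band assignment is an exact-string lookup in a two-column annotation table;
unannotated identifiers are flagged, never dropped. Co-localization is
summarized as the fraction of the upregulated set whose band starts with a
prefix (default `"14q32"`, which covers the two DLK1-DIO3 sub-bands
14q32.2 and 14q32.31). Matching is by band-name prefix, not genomic
coordinates, because the underlying observation is made at band resolution.
No clustering significance test is computed: the co-localization is a
descriptive statement, and inventing a null model for it would overstate
the claim. The packaged census records 10 miRNA genes in 14q32.2 and 44 in
14q32.31 (54 total); the full 54-gene membership is not enumerated by name
because only the screen hits are annotated individually.

## qPCR relative quantification and interaction analysis

For each sample and target, $\Delta Ct = Ct_{\text{target}} -
Ct_{\text{reference}}$ against an endogenous small-RNA control (default
RNU6B), and $-\Delta Ct$ serves as the log2-expression proxy. The
case-versus-control log2 fold change is $-\Delta\Delta Ct =
\overline{-\Delta Ct}_{\text{case}} - \overline{-\Delta Ct}_{\text{ctrl}}$.

The interaction of health-disease status and gender is tested per target by
comparing the full factorial linear model against the additive model — an
F test with 1 numerator degree of freedom in the 2×2 design that remains
well-defined under the unbalanced cell sizes of a real validation cohort.
The response is Z-transformed per target first; since F statistics are
invariant under affine transformations of the response, this changes
nothing about the test (the suite asserts identity to $10^{-8}$) while
putting targets on a common scale for the assumption checks. Normality is
checked by Shapiro-Wilk on the full-model residuals and variance
homogeneity by the Brown-Forsythe (median-centered) variant of Levene's
test; whether to check residuals or raw cells is a genuine choice, and
residual-based was chosen because it matches what the F test actually
assumes. Interaction p-values are BH-adjusted across targets.

Post-hoc contrasts use Tukey's HSD on the *raw* $-\Delta Ct$ scale (so the
case-control contrast within a gender is directly the qPCR log2 fold
change), with the Tukey-Kramer standard error
$\sqrt{\frac{\mathrm{MSE}}{2}(1/n_i + 1/n_j)}$ for unequal group sizes and
p-values from the studentized-range distribution with $k = 4$ groups on
$N - 4$ degrees of freedom. `stats::TukeyHSD` is the independent oracle in
the tests. Disease stage (relapse/remission) is ignored in this module;
the stage contrast is available in the DE module as the same operation
restricted to cases.

## Network-based enrichment

Per (miRNA, pathway) pair, over-representation of the miRNA's target genes
in the pathway is the exact hypergeometric upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$ with both sets
intersected with the gene universe first. The default universe is the
union of all pathway genes — the standard ORA convention — configurable to
include target genes. Significance is *raw* $p < 0.05$ (with overlap
$k \ge 1$), not FDR-adjusted: the selection statistic downstream is the
count of significant miRNAs per pathway, and adjusting here would change
the meaning of that count.

Pathways are then ranked by their miRNA regulator count, and the heavily
co-targeted ones selected by the upper Tukey fence: counts strictly
exceeding $Q_3 + 1.5(Q_3 - Q_1)$. Quartiles use linear interpolation
between order statistics (R's default type 7), exposed as a knob because
integer counts make quartiles estimator-sensitive; with quartiles
$Q_1 = 1$ and $Q_3 = 3$ the fence is 6, i.e. "more than 6 miRNAs".

Selected pathways form an undirected overlap network: an edge wherever two
gene sets intersect at all, weighted by the Jaccard index
$|A \cap B| / |A \cup B|$. Completeness is the realized edge count over
the complete-graph denominator $n(n-1)/2$ (276 for 24 nodes). Finally,
over-representation of an annotated subfamily (e.g. RTK-activated
pathways) among the selected nodes is tested by a one-sided hypergeometric
tail against the background of all pathways regulated by at least one
miRNA. The original study's subfamily calculation lives in a supplement
that is not available; the hypergeometric test is the standard exact
replacement, and every result row carries a `method` field saying so.

## What the generators emulate — and what they do not

`simulate_counts()` draws negative-binomial counts (variance $\mu + \alpha
\mu^2$) at the screen's group sizes (8 male and 8 female cases, 4 + 4
controls), with per-feature baselines log-uniform over 5–500 counts,
per-sample library-size factors log-uniform over 0.7–1.4, and a planted
26-feature cluster upregulated *in male cases only* (log2 fold changes
uniform over 1.1–6, the span reported for the real cluster) plus 6
downregulated features. Dispersion defaults to $\alpha = 0.1$, a typical
bulk small-RNA value. Planted features take their baselines from the low
end of the abundance range (5–50 counts): imprinted-locus miRNAs are lowly
expressed in blood cells, and planting up-to-64-fold changes on abundant
features would inflate case library sizes enough that total-count CPM
shifts every null feature — a compositional artifact the emulated study
evidently did not suffer, since it reported exactly six downregulated
miRNAs. The truth table accompanying every simulation makes recovery tests
self-contained.

`simulate_ct()` draws Gaussian $-\Delta Ct$ values at the validation
cohort's sizes (16/20 cases, 10/10 controls) with cell means encoding the
crossing interaction (defaults $-8, -6, -5.2, -6$ for HC-M, HC-F, RRMS-M,
RRMS-F; within-cell SD 0.7 cycles, a typical qPCR replicate spread) and a
constant reference Ct of 25. Gaussian noise on the $-\Delta Ct$ scale
matches the ANOVA's normality assumption by construction, so passing
assumption checks on synthetic data says nothing about real Ct tables.

`simulate_genesets()` builds a 2000-gene universe and a 500-pathway
collection of 50-gene sets, 17 of which form a subfamily sharing a fixed
fraction (default 0.8) of their members through a common core pool —
pairwise Jaccard overlap rises with that fraction and reaches identity at
1. Each of 26 miRNAs draws 100 target genes, each taken from the subfamily
gene union with probability `convergence` (default 0.9) and uniformly
otherwise. The collection size matters: a 17-pathway subfamily inside a
few dozen pathways would dominate the count distribution's upper quartile
and the Tukey fence could never isolate it; at several hundred pathways
(matching the scale at which such screens report hundreds of enriched
pathways) the subfamily is a genuine outlier population. The 50-gene
pathway size, together with the universe and target-set sizes, puts the
background per-pair ORA hit probability near the nominal 5%, so background
pathways realistically accumulate counts of 1–3.

None of the generators simulate reads, amplification efficiency, multiple
reference genes, batch structure, or the imprinting biology of the locus;
passing tests demonstrate the statistical machinery, not fidelity to any
particular deposited dataset.

## Numerical and design choices

- **Strict filter inequalities** (`p_adj < 0.05`, `|lfc| > 1`): boundary
  rows are excluded, matching the screen's stated rule.
- **Variance-prior fallback**: no positive trigamma solution ⇒
  $d_0 = \infty$, $\tilde s^2 = \operatorname{median}(s^2)$, with a
  warning — degenerate panels must not crash.
- **Strata with fewer than 2 samples per group** are skipped with a
  warning rather than producing unstable fits.
- **Ties and ordering**: all writers emit rows in lexicographic order;
  overlap-network edges are stored with $a < b$, making exports diffable
  and runs byte-identical under a fixed seed.
- **Missing Ct entries** contribute no row and are excluded listwise per
  target; the merged sample count per target is reported.
- **Seed discipline**: every generator accepts a seed, saves and restores
  the caller's RNG state, and the pipeline derives per-stage substreams by
  stable hashing of the stage name, so stage order does not affect
  stage randomness.
- **Main-effect sums of squares**: only the interaction term is formally
  tested (full-vs-additive comparison, balance-proof in 2×2); main effects
  are not reported as tests.
- **Gene identifiers** are matched case-sensitively with no alias
  resolution anywhere; identifier mapping is out of scope and should be
  done upstream.

## Problem sizes used by the test suite

The suite's simulation loops use 800-feature count matrices at the screen's
24-sample design (200 replicates for recovery, 5 for p-value uniformity),
500 single-target qPCR replicates for interaction type-I error and 200 for
power, and 100 + 100 geneset replicates for subfamily detection and its
null — sizes at which the Monte-Carlo error of each checked rate is well
below the asserted margins while the whole suite stays comfortably
interactive.

## Known limitations

- Exact reproduction of the published screen's per-miRNA fold changes and
  p-values requires the deposited raw sequencing data and is out of scope;
  the packaged table ships the printed values for fixture-level checks.
- The 456 → 24 → 17 pathway funnel of the original analysis depends on
  target-database and pathway-collection versions that are not pinned;
  the network module reproduces the *procedure* and its worked constants
  (fence rule, completeness denominator), not those counts.
- Total-count CPM remains sensitive to extreme compositional shifts; for
  data where a large fraction of reads moves between conditions, a robust
  normalization should be used upstream.
- The subfamily test's background (all pathways with count ≥ 1) is one
  defensible choice among several; it is recorded in the output metadata.
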