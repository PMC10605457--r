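---
title: "From Ct values to differentially correlated gene pairs"
author: "ctflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Ct values to differentially correlated gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctflow)
```

# The problem

Large-scale qPCR experiments — hundreds of cells or samples, dozens of
genes — record a cycle-threshold (Ct) value per sample and gene: the PCR
cycle at which fluorescence crosses detection, a log2-scale quantity
where one cycle less means roughly twice the template. Such data support
two kinds of questions. The conventional one is differential expression
between experimental groups. The one that only becomes feasible at this
scale is *differential correlation*: does a pair of genes change its
correlation structure between two conditions, suggesting a
context-dependent rewiring of their regulatory relationship? ctflow
implements the full path from raw Ct tables to both answers, headlessly
and reproducibly.

# The procedure, stage by stage

## Input and replicate handling

Ct tables arrive wide (sample, group, one column per gene) or long
(sample, group, gene, Ct), as CSV, TSV, or Excel sheets. Non-numeric Ct
cells ("Undetermined", ">40", blanks) become missing values; no
imputation is ever performed, because qPCR missingness is not missing at
random in any controllable way and imputing it would manufacture
correlation. Technical replicates — rows sharing a sample identifier and
group — are collapsed to the geometric mean of the non-missing replicate
Cts per gene. The geometric mean on the cycle scale is deliberate:
replicate disagreement is multiplicative on template quantity. More than
two replicate rows are collapsed the same way; replicates that disagree
on their group label are an error rather than a silent majority vote.

## Housekeeping stability

Normalization needs reference genes that are stable across exactly the
samples being analyzed, so candidates are scored on the data themselves
with a model-based variance decomposition in the NormFinder family
(Andersen et al. 2004, Cancer Research 64:5245), computed directly on Ct
values restricted to samples that carry a group label. Within each
group, two-way centering over genes and samples removes sample-loading
and gene-level effects; what remains per gene is an intragroup variance
$\hat\sigma^2_{ig}$, estimated from the centered residuals with an
unbiasedness correction,

$$\hat\sigma^2_{ig} = \Big(\mathrm{RV}_{ig} - \hat S_g/k^2\Big)\frac{k}{k-2},
\qquad \mathrm{RV}_{ig} = \frac{\sum_j z_{igj}^2}{n_g - 1},$$

with negative estimates truncated to zero, and an intergroup deviation
$\hat d_{ig}$ — the gene-by-group interaction of the group means,
shrunken toward zero empirically in proportion to its sampling variance
(genes with little evidence of a systematic group effect contribute
none). The stability value is the group average of
$|\tilde d_{ig}| + \sqrt{\mathrm{var}(\tilde d_{ig}) + \hat\sigma^2_{ig}/n_g}$;
lower is more stable. With a single group it reduces to $\hat\sigma$.
Pairs are scored by the same rule applied to $(\hat d_i+\hat d_j)/2$ and
$(\hat\sigma^2_i+\hat\sigma^2_j)/4$, so two genes deviating in opposite
directions can make a pair more stable than either member — the reason a
best *pair* is sought at all.

Three boundary choices are worth stating. With exactly two candidates
the correction above is undefined ($k-2 = 0$); the shared residual
variance cannot be apportioned between two genes, and each is assigned
twice its residual variance symmetrically. Missing values are handled by
keeping, within each group, only samples complete for every candidate
(the two-way centering needs a rectangular matrix); a group left with
fewer than two complete samples is dropped for all candidates, keeping
the candidate set comparable, with a warning. Ties on the minimal
stability break lexicographically.

One structural caveat: the interaction $d$ is identifiable only
relative to the candidate set. A drift shared by *all* candidates is
absorbed by the centering and invisible to this (or any) stability
score; the score compares candidates, it does not certify absolute
constancy.

## Livak normalization

The selected normalizers (a user list of one gene is honored as-is; two
or more are scored and the best pair used; no list at all scores every
gene, allowed but discouraged) are averaged arithmetically on the Ct
scale — the geometric mean of the underlying linear quantities, the
natural companion of the Livak method, which assumes near-equal primer
efficiencies. Each target gene's normalized expression is
$-\Delta Ct = -(Ct_{target} - \overline{Ct}_{hk})$, so higher means more
expressed on a log2 scale. A $-\Delta Ct$ is missing iff the target or
any normalizer Ct is missing for that sample. The whole housekeeping
candidate list leaves the target set (a candidate that lost the contest
is still a reference gene, not a biological target). Relative expression
$2^{-\Delta\Delta Ct}$ rescales one gene against a reference group by
dividing by the reference-group median of $2^{-\Delta Ct}$; centering on
the linear scale makes the reference median exactly 1 for any group
size, which subtracting a log-scale median does not guarantee for
even-sized groups.

## Group comparison and the volcano screen

Normalized qPCR data inherit variability from both the target and the
housekeeping measurements and are frequently non-normal, so medians and
nonparametric tests are the default posture. Per gene and group, a
one-sample Kolmogorov–Smirnov test against a normal law with plug-in
sample mean and SD (no Lilliefors correction — the plain form is what
the upstream R ecosystem computes) yields normality p-values; if any
involved group rejects at $\alpha = 0.05$ the Mann–Whitney test is used,
otherwise the classical equal-variance Student t-test. The user can
override the routing in either direction. Mann–Whitney p-values are
exact when the combined sample size is at most 25 with no ties, and use
the tie- and continuity-corrected normal approximation otherwise. The
fold change between groups is $2^{\mathrm{med}_A - \mathrm{med}_B}$ of
the $-\Delta Ct$ medians — a linear-scale fold consistent with the Livak
transform, antisymmetric under group swap. Significance stars follow the
fixed scheme ns ($p \ge 0.05$), \* ($p < 0.05$), \*\* ($p \le 0.01$),
\*\*\* ($p \le 0.001$), \*\*\*\* ($p \le 0.0001$), strongest label
winning at the boundaries.

The volcano screen applies one chosen test to every target gene between
two groups, adjusts the p-values with the Benjamini–Hochberg step-up
rule across the genes actually tested (missing-p genes are excluded from
the adjustment and reported unclassified), and classifies genes
against fold-change and p thresholds with *strict* inequalities — a gene
sitting exactly at a threshold is not called. Raw p-values against the
thresholds are the default; adjusted p-values are a flag away.

## Differential correlation (dR-val)

Within each group, all pairwise target-gene correlations are computed on
pairwise-complete observations — Pearson if every gene passes the
normality check in every selected group, Spearman otherwise, one method
per run so that differences compare like with like. A coefficient whose
p-value exceeds the significance threshold $\alpha$ (default 0.05) is
set to zero: a non-significant correlation is treated as no correlation
regardless of its magnitude. The differential statistic for a gene pair
between groups $a$ and $b$ is

$$\mathrm{dR\text{-}val} = |r^{gated}_a - r^{gated}_b| \in [0, 2],$$

0 meaning no change in the correlation profile and 2 a complete flip
from perfect positive to perfect negative. Only group pairs containing
the chosen reference group are reported by default (the full
$n(n-1)/2$ set is available on request). Pairs with fewer than three
complete observations in a group carry a missing dR-val and sort last.
Spearman p-values use the exact permutation null for $n \le 9$ without
ties and the t-approximation otherwise; Pearson uses the t-distribution.
dR-val is a descriptive screening statistic: the package deliberately
attaches no significance test to it (a Fisher-z or permutation FDR layer
would be a different design commitment), so top-ranked pairs are
candidates for confirmation in the scatter view, not discoveries.

# The synthetic-data generator

Every stage is testable without any external download because
`simulateCtData()` plants a known truth: per-target group means on the
$-\Delta Ct$ scale, designated gene pairs with per-group correlation
targets (induced through bivariate normal noise blocks), housekeeping
candidates with chosen SDs and intergroup shifts, a per-sample loading
common to all genes, completely-at-random missing cells, and optional
technical replicates. Signals are planted on the $-\Delta Ct$ scale and
mapped to Ct by subtracting them from fixed per-gene baselines and
adding the loading, so Livak normalization against the stable
candidates inverts the construction exactly in the noise-free limit.
Unstable candidates each drift in their *own* group: shifts collinear
across candidates would cancel in the gene-by-group interaction and be
invisible to any stability score, making the planted "stable pair"
unrecoverable in principle rather than in practice.

Default noise levels are chosen once as realistic for single-cell-scale
qPCR: target intragroup SD 0.5 on the $-\Delta Ct$ scale (1.0 in the
example emulation below, reflecting noisier single-cell material),
stable-candidate SD 0.15–0.18 Ct, unstable-candidate SDs 0.3–0.5 Ct with
0.3–0.6 Ct own-group shifts, loading SD 0.8 Ct, 2% missing cells.

`exampleCtData()` is a fully synthetic emulation of a reference study
design — 4 groups × 82 samples, 5 housekeeping candidates named A–E
among 68 genes — with planted findings to recover: B and E the stable
pair; twelve genes differentially expressed between Group1 and Group2
(TP53, CDH2, FOS, SESN2 up in Group1; SOD2, SRC, HIF1A, CMBL, PCNA,
SERPINE2, ALDH3A1, SNAI1 up in Group2, planted effects 1.6–2.6 log2
units); AKT1 raised strongly (1.5) in Group3 and modestly (0.5) in
Group4 versus Group1; and the PCNA–KDM5B pair planted at correlation
+0.43 in Group1 and −0.48 in Group3. It is synthetic data emulating a
design, not a measured dataset.

What passing tests on generated data do and do not show: the generator's
noise is Gaussian on the log scale, its missingness is completely at
random, its non-differential genes are exactly null, and its correlation
structure is confined to designated pairs. Real qPCR data have amplification
artifacts, detection-limit censoring (the ">40" cells), batch structure,
and diffuse correlation. Recovery of planted truth demonstrates that the
estimators compute what they claim under the stated model — not that
real experiments of this size will behave as cleanly.

# Worked example

```{r example, eval = FALSE}
sim <- exampleCtData(seed = 104)
x <- sim$ct

hk <- selectHousekeeping(x, c("A", "B", "C", "D", "E"))
#> best pair: B + E
norm <- deltaCt(x, hk, excludeGenes = c("A", "B", "C", "D", "E"))

vt <- classifyGenes(
    volcanoTable(norm, "Group1", "Group2", "mann-whitney"),
    fcThreshold = 2, pThreshold = 1e-4)
sum(vt$class == "significant")
#> 12

pairScatterStats(norm, "PCNA", "KDM5B", c("Group1", "Group3"), "spearman")
#>    group      r         p  n
#>   Group1  0.483 1.49e-05 73
#>   Group3 -0.476 1.23e-05 77

corrs <- lapply(c("Group1", "Group3"), function(g)
    correlationMatrix(norm, g, "spearman"))
names(corrs) <- c("Group1", "Group3")
head(drvalTable(corrs, "Group1"), 1)
#>  geneA geneB groupA groupB rGatedA rGatedB dRval
#>   PCNA KDM5B Group1 Group3   0.483  -0.476 0.959
```

# Numerical choices and problem sizes

Decimal separators are fixed to "."; `.txt` is read as tab-separated;
labels are matched case-sensitively after whitespace trimming. Ct values
are validated as finite and nonnegative. Degenerate inputs take defined
paths: a constant group in the KS check is declared non-normal (p = 0);
a zero-variance vector in a correlation yields a missing coefficient;
the t-test on two identical samples reports p = 1.

The test suite exercises the estimators at the scales the statistics
need rather than the largest scales the package supports: the
example-scale emulation (68 × 328) once per property, 100–200 seeded
replicates at n = 50–80 per group for the recovery and ranking suites,
and exhaustive enumeration oracles at n ≤ 8 (rank tests), ≤ 12 (BH), and
≤ 6 (Spearman permutation). These sizes give the binomial recovery
criteria (≥90–95%) enough resolution while keeping a full run in a few
minutes on one CPU.

# Known limitations

Pfaffl-style efficiency correction is unsupported (the Livak assumption
of matched efficiencies is the user's responsibility); there is no
imputation, no omnibus multi-group testing, no unsupervised module
(heatmaps/PCA), and no significance layer on dR-val. The stability
score is relative to the candidate set (see above). Excel input is
read-only; exports are CSV and PNG.
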