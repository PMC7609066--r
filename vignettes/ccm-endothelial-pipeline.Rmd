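---
title: "Methods: clustering, annotation and expansion statistics for CCM endothelial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, annotation and expansion statistics for CCM endothelial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

ccmEC implements the downstream analysis of droplet single-cell RNA-seq and
spot-based spatial transcriptomics of brain endothelial cells (ECs) in a
conditional *Pdcd10* (Ccm3) knockout mouse, the standard neonatal model of
cerebral cavernous malformation (CCM). The biological questions the
components answer are: which endothelial subpopulations exist (clustering +
rule-based annotation), which of them expand after *Pdcd10* deletion (a
fold-change statistic with a confidence-interval flag), how mitotic, tip-cell
and resident-progenitor phenotypes redistribute between genotypes
(threshold- and quartile-based positivity rules), which pathways are
over-represented among genotype DEGs (hypergeometric overlap), and where
proliferating lesion endothelium sits in tissue (co-expression rules on
spatial spots with a Fisher exact comparison).

Everything operates on log-normalized expression
\(v = \ln(1 + 10{,}000\, c / C)\) for count \(c\) in a cell (or spot) with
total \(C\). Natural logarithms are used throughout, including fold changes
\( \mathrm{logFC} = \ln\frac{\overline{e^{v}-1}_{\text{in}} + 1}
{\overline{e^{v}-1}_{\text{out}} + 1}\) (the +1 pseudocount prevents division
by zero and matches the convention of the droplet ecosystem the thresholds
were calibrated in).

## Quality control

Cells are dropped when their number of detected genes (genes with count
> 0) lies strictly outside mean ± 2 SD computed **within genotype** (samples
of a genotype merged first), or when mitochondrial counts exceed 5% of the
cell's total. Both rules are evaluated on the input matrix in a single pass.
The order matters — filtering mitochondrial outliers first would shift the
detected-gene mean — and the source protocol does not state an order, so the
single-pass choice is documented here and the bounds are reported in the QC
report. Cells exactly on a bound are retained ("outside of" reads as
strict). SD is the sample standard deviation, so groups need at least two
cells.

## Clustering and the resolution heuristic

After normalization, expression is regressed per gene on total molecules per
cell (nUMI; simple linear fit, residuals centred and unit-scaled), the top
variable genes are chosen by the variance-stabilizing-transform family
(degree-2 polynomial trend of log variance on log mean, standardized counts
clipped at \(\sqrt{n}\)), and cells are embedded with 30 principal
components. Clustering is Louvain modularity optimisation on a shared-
nearest-neighbour graph (k = 20, Jaccard edge weights, weak edges pruned at
1/15). No anchor-based cross-genotype integration is performed: the
synthetic world is batch-free, and a precomputed integrated embedding can be
supplied via `embedding` where real data requires one.

The working resolution is chosen from a scan (default grid 0.01–1) using a
clustering tree whose edges carry **in-proportions** — the fraction of a
cluster's cells at resolution \(r_{i+1}\) that came from a given cluster at
\(r_i\). A *stable region* is a maximal run of resolutions with a constant
cluster count and one-to-one parent–child steps; *over-clustering* begins
where a genuinely new cluster (not the main continuation of any parent)
draws at least `low_inprop` (0.1) of its cells from at least 2 distinct
parents. The selected resolution is the highest one inside a stable region
entirely below the onset. The source describes this criterion visually;
`identity_threshold = 0.9` (dominant-parent share defining "no
sub-branching") and the onset thresholds operationalize it and are exposed
as configuration. Labels are always relabelled 0, 1, 2, … by decreasing
size.

## Markers, annotation and differential expression

The test everywhere is the two-sided Wilcoxon rank-sum: tie-corrected normal
approximation with continuity correction, switching to exact permutation
enumeration when both groups have ≤ 10 cells. Conserved markers are computed
one-vs-rest **within each genotype**, the two p-values combined with the
Tippett minimum-p statistic \(1 - (1 - p_{\min})^k\), and per-genotype logFCs
averaged. Genes expressed in < 10% of the cluster in either genotype are
dropped (per-genotype, the ecosystem convention; the source does not say
whether the filter pooled genotypes). Adjusted p-values are Bonferroni
within the gene family tested per cluster; Bonferroni rather than BH is the
convention behind the "p_val_adj" thresholds the rules quote, and it is
configurable.

A cluster is annotated with a cell type when ≥ 50% of the type's key genes
pass `avg_logFC > 0` and combined p < 0.05 among the cluster's markers; the
boundary is inclusive and panel genes absent from the matrix count as
misses. Uniqueness rules: a unique marker passes `avg_logFC > 0.25`,
adjusted p < 0.05 in exactly one cluster; a unique DEG passes
|logFC| > 0.2, adjusted p < 0.05 in exactly one cluster.

## Expansion and positivity statistics

For groups (clusters or trajectory branches) with wild-type cells, fold =
ko/wt cell count. The flagging limit is the upper bound of the two-sided
95% t-interval of the mean fold, \( \bar f + t_{0.975,\,n-1}\, s/\sqrt n \),
computed on the **raw** folds (no log transform is mentioned in the source);
a group is flagged when its fold strictly exceeds the limit. Groups without
wild-type cells are excluded with a warning, and mixed/non-endothelial
clusters can be excluded from the family by configuration. Note the
statistic flags *relative to the family of folds*: with near-identical folds
the limit hugs the mean, so after a stochastic clustering step small-noise
flags can appear; with counts taken from the generator's deterministic
truth the null world yields identical folds and no flags.

Positivity rules: mitotic and tip markers use expression > 0; progenitor
markers (Bst1, Peg3, Procr, Cd200) use expression > Q1, where Q1 is the
25th percentile (type-7 linear interpolation, zeros included) computed once
over the stated reference population — all analysed cells, pooled across
genotypes — and reused for every group. Positivity fractions per group and
genotype feed the same fold + CI flagging; double positivity (e.g. Mki67
within a progenitor-positive population) is a conjunction of two rules.
Trajectory branch assignments are consumed from a table (`S0-S1`-style
names); trajectory structure learning is out of scope.

## Over-representation

Hypergeometric upper-tail p with the \(P(X \ge 0) = 1\) convention,
BH q across the collection, and "odds of overlapped genes to genes in the
gene set" implemented as fold enrichment \((k/n)/(K/N)\) (alternative
\(k/K\) selectable). Default filters: p < 0.05, q ≤ 0.25, odds ≥ 4,
overlap > 2. The source prints the q filter as "q > 0.25", which contradicts
standard usage and is presumed a typo; both directions are selectable and
the default is q ≤ 0.25. The universe is the set of genes present in the
matrix after QC — only what could have been detected is tested. The
disease-set variant reports per-cluster overlap with two-sided Fisher exact
p and display stars at 0.05/0.01.

## Spot classification

Spots are log-normalized like cells (scale 10,000; the scale the original
thresholds were applied on is not stated, so both threshold and scale are
configuration). Flags are conjunctions: EC = Cldn5 & Cdh5 & Pecam1 > 0.5;
lesion adds Klf4, Klf2, Ly6a, Thbd > 0.5; tip adds Apln & Plaur > 0.5;
proliferating variants add Mki67 > 1. Because every rule's gene set contains
the EC set, the implication hierarchy (every lesion/tip/proliferating spot
is an EC spot, etc.) holds by construction. The Fisher comparison of
proliferating proportions uses disjoint rows (EC-but-not-lesion vs lesion
EC) because the exact test requires disjoint categories; a nested variant is
available. Knockout samples are merged before counting.

## The synthetic world

The generator emulates exactly the structure the analysis assumes, no more:

* negative-binomial counts parameterized by (mean, inverse-dispersion), with
  per-gene baseline means `baseline_mean * Gamma(2, 2)`;
* planted cluster markers (default 10 per cluster at fold 8); marker genes'
  baselines are floored at `baseline_mean` so that a "canonical marker" is
  always a detectably expressed gene;
* two genotypes with **deterministic** per-cluster cell counts
  (`ko = round(wt × expansion)`), so the expansion statistic's ground truth
  is exact; default expansions mirror the studied system (4.8-fold for the
  venous cluster C9, 4.0-fold for C12, 1 elsewhere);
* a Beta-distributed mitochondrial count share per cell (default mean 2%,
  SD 1%) spread over the 13 mouse mt- genes;
* optional knockout log-fold effects per cluster and per gene;
* marker-positivity targets realised by a Bernoulli zero-inflation mask over
  a high-mean NB draw, so > 0 and > Q1 rules have exact expected fractions;
* spatial spots as Poisson mixtures of cluster mean profiles plus a
  non-endothelial background, on a grid, with lesion/proliferation/tip
  structure as elevated means of the corresponding genes and a near-zero
  floor (0.002) elsewhere.

It does **not** simulate doublets, ambient RNA, batch effects, sample-level
variability beyond the two-samples-per-genotype labels, or realistic
mean–variance trends beyond NB. A green recovery test therefore establishes
that the rules and statistics do what they claim on data satisfying their
assumptions — not that the pipeline is robust to the artifacts of real
droplet data. One granularity caveat: at typical spot depth a *single*
Mki67 count already exceeds the > 1 threshold after normalization, so any
nonzero background floor produces a small false-positive rate for the
proliferation flag; the strict null in the tests uses a zero floor.

## Numerical choices and scaling

Ties in variable-gene ranking break by gene symbol; cluster label ties by
original label; PCA signs are fixed by the largest-loading convention so
embeddings are reproducible across BLAS implementations. All randomness
funnels through one seed (per-resolution community detection uses
`seed + column index`). Exact rank-sum enumeration is capped at group sizes
of 10 (≈ 185k subsets). The multi-seed acceptance checks (20-seed expansion
recovery and null control) run the full simulate → QC → normalize → cluster
pipeline at reduced scale — 8×120 and 4×100 cells with 600/500 genes —
to stay within a desk-scale CPU budget; the single-run recovery checks use
the full 500-cells-per-cluster, fold-8, 2000-gene world. The headline
numbers of the original study depend on its deposited accession and on
reproducing its exact cluster structure; rerunning this pipeline on that
accession is supported by the same defaults but is not part of the test
suite.

## Known limitations

* Louvain community detection is order-dependent in principle; determinism
  is guaranteed only for a fixed seed and input order (permutation
  invariance holds in practice on separated data and is tested there).
* The degree-2 variance trend is a simplification of the loess fit used by
  the reference implementation; rankings can differ near the trend.
* Bonferroni adjustment is conservative; swapping in BH would enlarge DEG
  sets and is a one-line configuration change.
* The expansion CI treats the per-group folds as an i.i.d. sample; with few
  groups the interval is wide (flagging a 3× positivity increase among only
  4 groups is unreliable — the tests use 8+ groups, like the studied
  system's cluster family).
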