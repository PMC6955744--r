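---
title: "Methods: contrasting aneurysmal against occlusive aortic disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting aneurysmal against occlusive aortic disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaDE)
```

## The scientific problem

Abdominal aortic aneurysm (AAA) and aorto-iliac occlusive disease (AOD)
patients carry a very similar atherosclerotic burden and share the classic
cardiovascular risk factors, yet one aorta dilates and the other occludes.
Contrasting AAA tissue directly against AOD tissue — a case-vs-case design —
cancels expression changes driven by the shared risk profile and isolates
what is specific to aneurysm formation.  `aortaDE` implements that contrast
as a reusable pipeline: array preprocessing and sample QC, per-probe
two-group testing with signed linear fold changes, removal of sex-linked
genes (the two disease groups differ strongly in sex composition), upstream
regulator activation inference, gene-set overrepresentation, and a
two-track candidate prioritization that ends in a combined 60-gene list.

Because tissue studies of this kind are small and their raw data often
cannot be redistributed, the package ships a synthetic-data module that
generates every input with planted ground truth.  All tests and the
reproduction script run on synthetic data; no download is required.

## The statistical model, stage by stage

### Preprocessing and QC

Probe intensities arrive as a linear-scale probe × sample matrix.  Quantile
normalization forces every sample onto the common distribution given by the
row-wise mean of the per-sample sorted values (ties averaged); it is
idempotent and makes between-sample comparisons scale-free.  Values are then
log2-transformed and hybridization batches are corrected by per-gene
batch-mean centering: each batch's mean is shifted onto the gene's global
mean.  This is the minimal correction consistent with additive batch
structure; it preserves each gene's global mean exactly and, on simulated
data with planted batch offsets, removes essentially all between-batch
variance.  More elaborate corrections (empirical-Bayes shrinkage as in
ComBat) are deliberately not used: with 19 samples in 3 batches the
mean-shift model is already saturated, and the simpler form is exactly
invertible in tests.

Sample QC combines PCA on gene-centered profiles with agglomerative
clustering using distance `1 − Pearson correlation` and average linkage —
the most common expression-QC convention, fixed here for determinism.  The
dendrogram is cut into two flat clusters and every sample whose group label
disagrees with its cluster's majority label is *flagged*.  Flags are never
auto-removed: in the motivating study one case sample that clustered with
the controls was removed only after manual review, so removal stays a
caller decision (`drop_flagged = TRUE` in `run_pipeline()` reproduces that
behaviour).

### Differential expression

Per probe, a two-sample t-test (pooled variance by default, Welch by flag)
is run on log2 values; fold changes are reported on the signed linear
scale, `+r` for increases and `−r` for decreases (never inside (−1, 1)),
computed from the back-transformed linear group means.  Testing on log2 with
linear-scale fold-change reporting matches standard array practice and the
magnitude range of published tables (top fold changes above 30).  Probes are
collapsed to genes by the median: gene fold change = median of probe fold
changes on the signed scale (even counts: mean of the two central values),
and — as the symmetric convention, since the source analysis specifies the
median only for fold changes — gene p = median probe p.  The significance
filter keeps genes with `|FC| ≥ 2` **and** `p ≤ 0.05`, both inclusive.  No
multiple-testing correction enters the filter; the joint fold-change +
raw-p rule is the published criterion, and a Benjamini–Hochberg column is
emitted for information only.

### Sex-confound removal

The case group is predominantly male and the control group predominantly
female, so case-vs-control testing partly re-discovers sex.  Sex-linked
genes are therefore derived from an *external* control cohort measured on
two platforms: per platform, male vs female controls are tested and genes
with `p < 0.05` and `|FC|` above a platform-specific cut (3.5
Affymetrix-style, 2.5 Illumina-style; both strict) are kept.  The exclusion
set is the **union** across platforms — the published workflow reports one
merged list from two platform analyses, and union is the conservative
choice for confound removal — matched to the main dataset by gene symbol.
Both fold-change directions count, since the male-vs-female direction is
arbitrary for a confounder.  Removal is exact set subtraction and
idempotent.

### Upstream-regulator inference

For a regulator with signed edges to targets (`+1` activating, `−1`
inhibiting), the activation z-score over its targets present in the
significant DE list is

  z = Σₜ eₜ·dₜ / √N,

with `dₜ = sign(FCₜ)` and `N` the number of such targets.  Under the null
of random target directions z is standard normal (verified by calibration
tests); `|z| ≥ 2` with hypergeometric overlap `p ≤ 0.01` yields an
Activated/Inhibited call.  Edges are unweighted: commercial implementations
weight edges by literature confidence, but those weights are not
reproducible, and the unweighted statistic is the documented core.  The
overlap p is the one-sided hypergeometric tail with the measured-gene
universe as population — the genes present after probe collapse, matching
how the published analysis defined its upload universe.

The part-2 candidate list keeps called regulators whose *own* transcript is
upregulated with `FC ≥ +2` (upregulation, not `|FC|`, following the
published rule), ranks by z descending with deterministic tie-breaking
(overlap p, then symbol), and truncates to 30.  Only Activated regulators
qualify by default — the published list contains only Activated entries —
with `include_inhibited = TRUE` available.

### Gene-set overrepresentation

Each set is intersected with the universe and tested with the one-sided
hypergeometric tail (the right tail of Fisher's exact test), DE direction
ignored; results are ranked by p with `−log10(p)` reported, mirroring
ranked-pathway figures.  BH q-values are attached.

### Candidate prioritization (track 1) and assembly

The significant, sex-filtered table is prioritized in five steps: genes
whose normalized linear expression bins as Low (< 80) are dropped (Medium
is 80–800 inclusive on both ends, from the published interval notation;
High > 800); only upregulated genes are kept (increased expression is more
robustly detected than absence); subcellular location and molecule type are
attached; vascular-gene-set membership and regulator cross-hits are
*marked, never filtered*; and the list is ranked by fold change descending
(ties: p, then symbol) and cut at 30.  The binning statistic is the mean
normalized linear intensity across **case** samples — the published
rationale is detectability in the diseased tissue — with an all-sample
mean available by flag.  The final list concatenates both tracks: 30 + 30
rows at full quota, shared genes appearing once per track with the
cross-hit flag set.

### Clinical and qPCR statistics

Cohort characteristic tables use: two-sided Fisher's exact test by
point-probability summation for binary variables (the summation convention
reproduces the published cohort p-values 0.0095, 0.3684 and 0.6027 exactly
from the printed counts, which a conditional-odds-ratio-interval convention
would not); the pooled two-sample t-test for normal continuous variables
(reproducing the published age p = 0.001 from printed summaries — Welch
does not); and the Wilcoxon rank-sum test (exact when tie-free; the
two-group equivalent of Kruskal–Wallis) for skewed variables, summarized as
median [IQR] with type-7 linear-interpolation quartiles.  Patients with
hs-CRP strictly above 10 are excluded as acutely inflamed.

qPCR quantification uses the comparative Ct method: per sample
`ΔCt = Ct_target − mean(Ct of the two reference genes)` (the arithmetic
mean of reference Cts, i.e. the geometric mean of their linear quantities —
the published protocol names the two housekeeping genes but not the
combination rule), `ΔΔCt` is the case-minus-control difference of group
mean ΔCt, fold change `= 2^(−ΔΔCt)`, and the p-value is a two-sample
t-test on per-sample ΔCt.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 12 case vs 7 control
samples; three hybridization batches with per-gene batch offsets (SD 0.3
log2); residual probe noise SD 0.25 log2; per-gene baseline log2
intensities ~ N(8, 1.5), placing typical linear values around 256 so the
80/800 bin boundaries are live; planted disease fold changes log-uniform on
[2, 32] with random sign; 30 sex-linked genes at 4-fold; and a sex/group
confound realized deterministically as `round(p·n)` males per group with
p = 11/12 (case) and 2/7 (control).  Intensities are built on the log2
scale and exponentiated, so "normalized raw expression values" exist on
the linear scale where binning is defined.  Planted-active regulators are
drawn from the planted *upregulated* genes — so their own transcript can
satisfy the part-2 self-fold-change rule, as the published top regulators
do — and their edge signs agree with target directions with probability
`consistency`; inactive regulators get random targets and signs.

The generator does **not** emulate probe sequence effects, spatial array
artifacts, intensity-dependent variance, cross-hybridization, or correlated
gene modules beyond the planted regulator structure.  Passing tests
therefore demonstrate that the algorithms are implemented correctly and are
calibrated under idealized noise — not that the pipeline is robust to every
real-array pathology.

## Numerical conventions and degenerate inputs

* Quantile normalization delegates to `limma::normalizeQuantiles(ties =
  TRUE)`; equality of column distributions and idempotence are verified to
  1e−12.
* Zero within-group variance in a t-test yields `t = 0, p = 1` when means
  agree (and p → 0 otherwise in the ΔΔCt path); single-sample groups are
  errors.
* Fisher's point-probability comparison uses a relative tolerance of
  1e−12 when deciding which tables are "as extreme".
* A regulator with no DE targets has undefined z and is Undetermined; the
  overlap tail at k = 0 is exactly 1.
* All rankings break ties deterministically (stated per function), so
  outputs are stable under input permutation; dendrogram distances and
  merge heights are permutation-invariant.
* All simulation randomness flows through one seed per generator call
  (`withr::with_seed`); the same configuration is bit-reproducible, and
  derived generators (network, annotations) use fixed offsets of the
  config seed so the components are independently reproducible.

## Design choices on genuinely open points

* **PCA/clustering gene set**: all genes by default (an optional top-N
  variance filter exists); the source QC does not state a filter.
* **Union vs intersection** of the two platform sex-gene lists: union (see
  above).
* **Symbol vs probe matching** when subtracting sex genes: symbol, since
  the exclusion list and the DE table come from different platforms.
* **Binning statistic**: case-group mean (see above), configurable.
* **Test scale**: t-tests on log2 values with linear-scale fold-change
  reporting; the original analysis does not state the scale, and this
  combination reproduces the printed fold-change magnitudes.
* **Gene-level p**: median probe p, the symmetric partner of the stated
  median-fold-change collapse.

## Problem sizes used in the test suite

The suite exercises the pipeline end-to-end at 500–4000 genes with 1–3
probes per gene, 19 samples, 20-seed Monte-Carlo loops for calibration
properties (type-I error, fold-change recovery, sex-filter completeness,
ΔΔCt recovery), and exhaustive enumeration oracles for the exact tests
(all 2×2 tables with total ≤ 40; hypergeometric universes ≤ 30).  These
sizes give tight Monte-Carlo error on every calibrated property while
keeping the default run fast.  The full-quota two-track fixture uses 4000
genes with a ~5% DE fraction, mirroring the proportion of significant
genes in a genome-wide screen: at much smaller gene universes quantile
normalization visibly compresses the strongest planted effects at the top
of the intensity distribution, which is a property of the method, not of
the implementation.

## Known limitations

* Probe-level background correction (GC-RMA) is out of scope; the pipeline
  starts from a summarized probe × sample matrix.
* The regulator statistic is unweighted and depth-1; it will not reproduce
  literature-weighted commercial z-scores on real knowledge bases.
* The published 137-gene sex list and the published gene/regulator tables
  cannot be re-derived exactly — they depend on undeposited patient arrays
  and under-specified preprocessing of the external control dataset — so
  the package validates those stages by planted-truth recovery instead.
* `characteristics_table()` supports two groups; multi-group designs fall
  back to Kruskal–Wallis only through `rank_test_two_group()`.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_expression(cfg)
net <- simulate_regulator_network(cfg, sim$truth)
ann <- simulate_annotations(cfg, sim$truth)
sex <- derive_sex_genes(simulate_sex_reference(cfg))

bundle <- run_pipeline(
  sim$exprs, sim$samples, sim$probe_map,
  annotations = ann$annotations, vascular_set = ann$vascular_set,
  network = net$network, gene_sets = ann$gene_sets, sex_genes = sex)
bundle
head(bundle$gene_list)
```
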