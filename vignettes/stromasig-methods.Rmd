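---
title: "Methods: stability-resampled signatures for stromal transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-resampled signatures for stromal transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

# Overview

`stromasig` derives gene-expression signatures for mesenchymal stromal
cells (MSCs) and related populations from multi-batch compendia. This
vignette is the package's account of the statistics it implements: the
models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations.

# The moderated two-group model

Every contrast in the package is binary ("Cell Type I" versus "Cell
Type II", oriented A − B so positive log fold changes mean higher in
A). For gene $g$ with group sizes $n_A, n_B$:

* $\mathrm{logFC}_g = \bar{x}_{gA} - \bar{x}_{gB}$ (log2 units),
* $s_g^2$ = pooled within-group variance with
  $d_g = n_A + n_B - 2$ degrees of freedom.

The gene variances are assumed exchangeable around a scaled
inverse-chi-square prior, $s_0^2 d_0 / \chi^2_{d_0}$. The prior is fit
by method of moments on $z_g = \log s_g^2$: solve
$\operatorname{trigamma}(d_0/2) = \operatorname{var}(z) -
\operatorname{trigamma}(d_g/2)$ by Newton inversion of the trigamma
function, and recover $s_0^2$ from $\operatorname{mean}(z)$ with the
corresponding digamma corrections. When the spread of $z$ does not
exceed its pure sampling component the prior is degenerate
($d_0 = \infty$) and $s_0^2$ is the bias-corrected geometric mean. A
subtlety worth stating: for *exactly constant* $s^2$ the bias-corrected
inversion returns $s^2 \exp(\log(d_g/2) - \operatorname{digamma}(d_g/2))$,
slightly above the common value — the correction is calibrated for
variances that genuinely arise from the sampling model, and we keep it
consistent rather than special-casing ties.

Shrinkage and testing follow the standard moderated-t construction:
$\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
$t_g = \mathrm{logFC}_g / \sqrt{\tilde{s}_g^2 (1/n_A + 1/n_B)}$,
two-sided p on $t_{d_0 + d_g}$. With $d_0 = 0$ this is the ordinary
pooled t (a limit the tests assert to 1e-12); with $d_0 = \infty$ every
gene is tested against $s_0^2$. Multiple testing uses
Benjamini–Hochberg step-up FDR (delegated to `stats::p.adjust` behind
the `bh_adjust()` surface and verified against a brute-force step-up
oracle). A gene is called DE when `fdr < alpha` *strictly*, with
`alpha = 0.05` by default and **no fold-change cutoff** — significance
alone defines DE here, and `alpha` is exposed for users who want
otherwise.

# The resampling stability protocol

`resample_contrast()` repeatedly draws `k_per_group` columns per group
uniformly *with replacement* (default 7-vs-7), reruns the full
moderated pipeline on each draw — including re-estimation of
$(d_0, s_0^2)$, since each subsample is a small independent experiment
— and intersects the significant calls across iterations. Design
choices that were genuinely open:

* **Strict direction-consistent intersection.** A stable gene must be
  significant in the same direction in *every* iteration; a gene
  significant up once and down once is excluded. This is the strictest
  reading of "significant along all iterations" and gives the stable
  set its defining property: call frequency exactly 1.
* **Plateau operationalization.** The stopping criterion is stated
  qualitatively in the underlying protocol ("the DE genes become
  constant"). We operationalize it as: stop at the first iteration
  `>= min_iters` whose last `patience` cumulative stable-set sizes
  (both directions) are all equal; defaults `max_iters = 200`,
  `min_iters = 50`, `patience = 20`. Because cumulative intersections
  are monotone non-increasing and bounded, they *always* plateau
  eventually — so the interesting diagnostic for a pathological
  contrast is not the cumulative trace but the per-iteration DE-count
  trace, which `plateau_reached(..., which = "de")` checks with the
  same windowed-constancy rule. A heterogeneous group (half the
  samples carrying opposite effects) shows exactly this signature:
  per-iteration DE counts oscillate by orders of magnitude, never hold
  a constant window, and the cumulative stable set collapses to
  (almost) nothing. The test suite reproduces this behaviour.
* **Duplicate draws are used as-is.** Degrees of freedom come from the
  drawn counts ($2k - 2$); the occasional zero-variance group that
  duplicate draws can produce is absorbed by moderation.
* **Ranks over all genes.** Each iteration ranks *all* genes by FDR
  ascending with averaged ties (not only the significant ones), so the
  per-gene median rank across iterations is comparable between
  iterations with different call counts.

# Normalization with frozen references

`build_frozen_reference()` freezes two things from a *balanced*
subsample (`per_batch_n` arrays per batch, default 3 — the balanced
subset size is not prescribed anywhere, so it is exposed as
configuration): a reference quantile vector (per-rank mean of the
sorted subsampled arrays) and per-batch per-gene offset vectors (mean
residual of each batch's quantile-normalized subsample around the
across-batch mean). `apply_frozen_normalization()` maps any array onto
the reference by rank — tied values receive the mean of their tied
reference positions — and subtracts the sample's frozen batch offset.
This is an explicit, simplified gene-level stand-in for
frozen-parameter array normalization: it preserves the idea (vectors
precomputed on balanced subsets, then applied unchanged to any number
of arrays) while staying desk-scale and testable. Note the division of
labour: a batch effect *constant across genes* is removed by the
quantile step alone (ranks are unchanged, so its frozen offsets are
null), whereas *gene-specific* batch offsets survive rank mapping and
are what the frozen offset vectors capture. On synthetic data with
additive per-gene batch offsets of SD 0.8 log2 units the
between/within variance decomposition attributes > 50% less variance
to batch after normalization (the acceptance suite measures ~85–88%
reduction).

`variance_filter()` implements the companion filtering step (keep the
most variable fraction of a panel before pattern clustering) with
population variance (divisor n — irrelevant to the ordering, fixed for
reproducibility) and lexicographic gene-id tie-break.

# Signatures, enrichment, structure, growth

Signature derivation is pure set algebra with recorded provenance:
tissue-specific signatures intersect a class's up-lists against every
other stromal class; the lineage-core signature intersects the
tissue-vs-HSPC up-lists, then an (optional) meta-analysis up-list,
then an (optional) expression footprint, reporting the size after each
stage. Empty optional stages are skipped and logged rather than
treated as absorbing.

Panel enrichment is the upper-tail hypergeometric $P(X \ge k)$ via
`stats::phyper`, exact by construction (the tests verify it against
full subset enumeration for every universe up to N = 12). The universe
is an explicit argument defaulting to all genes in the analysed
matrix: published enrichment p-values in this literature are often
irreproducible precisely because the universe is left implicit, so the
package refuses to guess.

Structure analyses: PCA by SVD (`stats::prcomp`) in either
orientation, with variance fractions checked against the covariance
eigendecomposition; sample distances as Euclidean distances between
rows of the sample-correlation matrix (the samples' *correlation
profiles*, not 1 − r — two samples are close when they correlate
similarly with everyone); UPGMA clustering via `stats::hclust`.
Coexpression networks threshold the gene-gene Pearson correlation at
`r_min = 0.95`, read as *signed* positive correlation per the
published cutoff; `absolute = TRUE` is available as a variant.
Zero-variance genes are dropped with a warning; isolated genes are not
listed as nodes; exports are SIF and edge-list TSV.

Growth: `PDT = TExpan · log 2 / log(Q2/Q1)` (hours; base-invariant),
compared across classes by a Wilcoxon rank-sum test that enumerates
all assignments exactly for $n_A + n_B \le 12$ with mid-ranked ties
(so identical samples give p = 1 exactly), and otherwise uses the
normal approximation with tie and continuity corrections. The exact
path is hand-implemented because the stock test abandons exactness
under ties; it is cross-checked against `wilcox.test(exact = TRUE)` on
tie-free data.

# The synthetic generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes: per-gene baselines $N(7, 1.5^2)$ log2 units; per-gene noise
variances $s_0^2 d_0/\chi^2_{d_0}$ with $d_0 = 4$, $s_0^2 = 0.05$ (a
heavy-tailed prior, so a realistic minority of genes is genuinely
noisy); additive per-gene per-batch offsets $N(0, 0.5^2)$ assigned
round-robin across three batches — the simplest structure the frozen
normalizer can provably remove; and planted shifts of ±1.5 log2 units.
Planted sets are drawn from non-overlapping index blocks so recovery
scoring is unambiguous; a contrast side may name a *lineage* rather
than a class, which is how a shared mesenchymal core (up in every MSC
class versus HSPCs) is planted alongside tissue-exclusive blocks.
Marker panels are built with configurable overlap against the planted
genes, and `make_footprint()` builds a synthetic stand-in for an
external expressed-gene list (it contains the planted lineage genes
plus random others, as a real footprint would contain the truly
expressed core).

What the generator does **not** emulate: probe-level hybridization
noise, intensity-dependent variance, correlated gene modules beyond
the planted ones, annotation errors, or single-cell structure.
Passing recovery tests therefore demonstrate that the pipeline's
statistics behave as designed under their own model assumptions — not
that real compendia satisfy those assumptions.

# The end-to-end pipeline and problem sizes

`run_pipeline()` wires the stages in dependency order — simulate,
normalize, per-tissue moderated DE, stability resampling of the
meta-analysis contrast (BM-MSC versus HSPC), the signature cross-flow,
structure analyses, coexpression network, growth statistics — with a
hash-based manifest so unchanged stages are skipped on re-runs and a
single seed deterministically derives every stage seed. The flow
mirrors the derivation it models: tissue-level up-lists come from
single moderated DE runs, and only the meta contrast uses the
resampling protocol; applying the strict stability intersection to
*every* tissue contrast would compound the per-iteration miss
probability three times over and is not what the derivation does.

Default problem sizes are chosen as a desk-scale emulation of the
study conditions: 2,000 genes, four classes of 10 samples, three
batches, a 150-gene planted lineage core, 40-gene tissue blocks, and
the full 200-iteration resampling budget (runs plateau around 100
iterations). At these sizes the whole pipeline completes in a few
seconds; the acceptance script's additional calibration simulations
(50-replicate null, 20-replicate prior recovery, a 100-iteration
planted and null stability run at 20-vs-10) keep the total within tens
of seconds.

# Known limitations

* The normalizer is a gene-level stand-in; it does not reproduce
  probe-level frozen-parameter normalization and should not be used in
  place of it on raw array data.
* Probe-to-gene collapse uses the per-sample median over probes; the
  choice of summary for multi-probe genes is a genuine degree of
  freedom and other summaries will move values for such genes.
* The DE engine is strictly two-group with pooled variance; no
  covariates, no multi-factor designs.
* Exact rank-sum enumeration is limited to $n_A + n_B \le 12$;
  beyond that the approximation's error is bounded only empirically
  (within 0.02 of exact on 6-vs-6 in the tests).
* The stability protocol's guarantees are empirical, not analytic:
  type-I behaviour and recovery rates are established by simulation at
  the configured conditions, and will differ under other noise priors
  or sample sizes.
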