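---
title: "Methods: mixture-model survival screens and fixed-width enhancer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-model survival screens and fixed-width enhancer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataprog)
```

# Overview

`strataprog` implements two analysis arms commonly combined in tumor
regulatory genomics, plus a synthetic-data module that generates every input
they consume:

1. **Cohort arm.** Per-gene patient stratification by univariate Gaussian
   mixture models (GMMs) on log2(FPKM+1) expression, followed by
   Kaplan–Meier / multi-group log-rank comparison of the expression groups,
   orchestrated as a genome-wide screen for prognosis-associated genes.
2. **Epigenome arm.** Construction of a reproducible, fixed-width (501 bp)
   H3K27ac consensus peak set from per-sample summit calls; fragment
   counting; TMM/log-CPM normalization and a stand-in differential test;
   transcription-factor motif deviation z-scores against GC- and
   accessibility-matched background peaks; and GREAT-style
   basal-plus-extension regulatory domains that link differential peaks to
   differential genes ("enhancer–gene pairs").

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data does and does
not establish.

# The cohort arm

## Per-gene mixture model

For a single gene, patient expression values $x_1,\dots,x_n$ (log2(FPKM+1))
are modeled as a $k$-component Gaussian mixture with *component-specific*
variances (the unequal-variance family):

$$ p(x) = \sum_{j=1}^{k} w_j\, \mathcal N(x;\ \mu_j, \sigma_j^2),
   \qquad \sum_j w_j = 1 .$$

`fit_gmm_em()` fits the model by EM. Numerical choices:

* **Initialization.** The first fit uses $k$ evenly spaced sample quantiles
  as means, equal weights, and the pooled variance — deterministic, so a
  screen with `restarts = 1` is fully reproducible without random draws.
  Additional restarts start from random responsibilities.
* **Convergence.** Relative log-likelihood change below `tol = 1e-8`, at
  most `max_iter = 1000` iterations. The log-likelihood trace is retained
  and is nondecreasing (asserted in the tests at tolerance 1e-9).
* **Variance floor.** Each M-step clamps component variances at
  $10^{-6}\times$ the overall ML variance, preventing singular one-point
  components.
* **Labels.** Components are relabeled in ascending mean order, so group 1
  is always the lowest-expression group; assignments take the maximum
  posterior responsibility, ties to the lower label.
* **Degeneracy.** A fit with any weight below $2/n$ is flagged degenerate
  and discarded during model selection; all-identical input with $k \ge 2$
  raises an error.

`select_model()` chooses $k$ by BIC in the "larger is better" convention,
$\mathrm{BIC} = 2\log L - m\log n$ with $m = 3k - 1$ free parameters, ties
broken toward smaller $k$. The candidate grid defaults to $k = 1,\dots,9$.
Neither the grid, the initialization, nor the tie rule is dictated by the
underlying method — they are conventions of this package, chosen to match
common mixture-model tooling, and all are configurable.

The EM iteration itself runs in C++ (`src/gmm_em.cpp`): a genome-wide
screen fits tens of thousands of mixtures, and a compiled inner loop is
what the field's mixture packages do. A pure-R implementation of the same
updates is kept in the package and the test suite verifies the two agree
step for step.

## Survival comparison

`km_estimate()` is the standard product-limit estimator; censored subjects
tied with an event time remain at risk for that time's events (the usual
convention — the data sources this emulates do not state one).
`logrank_test()` is the $k$-sample log-rank test with the multivariate
hypergeometric variance for ties and an asymptotic $\chi^2_{k-1}$ p-value;
with $\sim$200 patients the asymptotic reference is the evident choice, so
no permutation p-value is provided. The test statistic is checked in the
suite against an independent per-event-time oracle and against
`survival::survdiff` on random tables, and its type-I error is verified to
be 0.05 within ±0.015 under a two-group exponential null.

## The screen

`run_screen()` reproduces the standard screening funnel:

1. keep genes with mean $\ge$ 0.5 **and** variance $\ge$ 0.5 (log2(FPKM+1)
   scale, variance denominator $n-1$);
2. fit the per-gene GMM and require stratification into $\ge 2$ groups;
3. require at least two groups with $\ge$ 10 patients each;
4. select genes with log-rank $p < 0.01$ on the raw p-value.

Design choices where the underlying procedure is ambiguous:

* The group-size rule is read as "at least two groups each of size ≥ 10".
  By default, groups smaller than 10 are **excluded from the survival
  comparison** rather than disqualifying the gene (`small_groups = "drop"`);
  comparing all groups is available via `small_groups = "keep"`.
* No multiple-testing correction is applied to the selection (the funnel
  selects on raw $p < 0.01$); BH q-values are reported as a non-selecting
  `logrank_q` column for the reader.
* Per-gene seeds are derived from the global seed and the gene *name*, so
  results are invariant to gene and patient reordering (verified in the
  tests).

# The synthetic cohort

`simulate_cohort()` generates the world the screen assumes:

* One latent mixture component per patient is drawn from the configured
  weights, and **all planted genes express that same latent grouping**
  (each planted gene draws from the component Gaussians given the patient's
  component). The underlying design is ambiguous about how several planted
  genes should map onto a single per-patient survival outcome; sharing one
  latent grouping is the simplest construction in which every planted gene
  is genuinely prognostic, which is what the recovery criteria quantify.
* Survival is exponential with rate
  $\lambda_i = \lambda_0 \cdot \mathrm{HR}^{(z_i - 1)}$, components ordered
  by ascending mean — i.e., log-linear proportional hazards in the group
  index, higher expression groups faring worse. Censoring is independent
  exponential with its rate solved from the mean hazard to hit the target
  censoring fraction approximately.
* Null genes are unimodal Gaussians independent of survival, with means
  drawn in [1, 4] and standard deviations in [0.9, 1.4] so that most null
  genes *pass* the expression filter and genuinely exercise the mixture and
  log-rank stages (a null panel filtered out at stage 1 would trivialize
  the false-selection rate).

Defaults (200 patients; two components at means 1 and 3.4, sd 0.8 — a
3-pooled-sd separation; hazard ratio 3; baseline hazard 0.1 events per time
unit; 30% censoring) follow the stated recovery world of the acceptance
criteria; where that world is silent (baseline hazard, censoring rate, null
gene parameters) the values are conventional choices for a tumor cohort
with a few years of follow-up, fixed once. Expression values are *not*
truncated at zero: the mixture model assumes Gaussian components, and
truncation would distort exactly the structure under test — real
log2(FPKM+1) data are nonnegative, which is one of the ways the synthetic
world is idealized.

What a green recovery test establishes: the screen detects 3-sd-separated
bimodal prognostic genes at hazard ratio 3 with high sensitivity and a
per-null false-selection rate bounded by the log-rank level. What it does
not establish: behavior under skewed/zero-inflated expression, correlated
genes, non-proportional hazards, or informative censoring — none of which
the generator produces. At this separation BIC detection is genuinely
marginal (roughly 90–98% per gene at $n = 200$), which is a property of the
stated world, not of the implementation.

# The epigenome arm

## Fixed-width consensus peaks

All coordinates are 0-based half-open (BED dialect); summits are 0-based
positions; overlap means $\ge$ 1 shared bp.

* `standardize_peaks()` extends each summit by 250 bp on both sides to a
  fixed width of 501 bp. Peaks that would run past a chromosome end are
  **dropped, not trimmed** — trimming would break the fixed-width invariant
  that per-peak score comparisons rely on.
* `filter_blacklist()` removes peaks overlapping any blacklist interval;
  a peak that merely abuts one (half-open semantics) is kept.
* `score_per_million()` normalizes each sample's peak scores:
  $\mathrm{spm}_i = s_i / (\sum_j s_j / 10^6)$, so each sample sums to one
  million and the values are invariant to rescaling the caller's scores.
  The "score" column is treated as an opaque positive significance value.
* `iterative_overlap_reduce()` is the greedy canonical reduction: keep the
  highest-ranked remaining peak, discard everything overlapping it, repeat.
  Rank ties break by (chrom, start, end), which makes the output
  independent of input order.
* `build_reproducible_set()` pools the per-sample reduced sets, reduces
  across samples ranked by spm, counts per retained peak the number of
  distinct samples contributing an overlapping original peak (the retained
  peak's own sample counts), and keeps peaks with spm $\ge$ 5 and support
  $\ge$ 2; chrY peaks are removed. Two ambiguities are exposed as flags:
  the spm threshold is applied **after** pooling on each retained peak's
  own spm by default (`spm_filter = "pre"` filters per sample first), and
  support counts *samples*, not peaks. spm is never recomputed after
  pooling.

`count_fragments()` counts, per consensus peak and sample, fragments
overlapping by $\ge$ 1 bp; a fragment spanning two disjoint peaks
increments both.

## Normalization and the stand-in differential test

`tmm_factors()` implements the published trimmed-mean-of-M-values
computation (reference sample by upper-quartile proximity; double trim of
30% on M and 5% on A; precision-weighted mean; geometric mean rescaled
to 1), and `log_cpm()` the prior-damped log2 counts-per-million with
effective libraries $L'_j = L_j f_j$ and per-sample prior
$p_j = \mathrm{prior}\cdot L'_j/\overline{L'}$. Both are verified against
edgeR to $10^{-10}$ in the test suite, and against hand computations.

The original analyses this emulates use a quasi-likelihood
negative-binomial GLM for differential calling. That machinery is
deliberately **not** reimplemented; `differential_test()` is a documented
stand-in on log-CPM that preserves the effect-size definition and the call
thresholds (genes: FDR < 0.01 and |log2FC| > 1; peaks: FDR < 0.1 and
log2FC sign). Two stand-ins are provided:

* `method = "moderated"` (default): empirical-Bayes moderated t with an
  intensity trend on the variances (limma-trend). With only two or three
  technical replicates per group — the design this package targets —
  per-feature variances are too unstable for a plain t-test: at the stated
  recovery world (NB dispersion 0.1, 3 vs 3, +2 log2FC), the Welch test
  recovers roughly 10% of planted peaks while the moderated test recovers
  essentially all of them at the nominal false-call rate. Sharing variance
  information across features is the field's standard answer to exactly
  this design, which is why it is the default.
* `method = "welch"`: a plain two-sided Welch t-test, retained for
  reference and calibration checks (its null p-values are verified to be
  approximately uniform).

`classify_differential()` applies the thresholds to any table with
`log2fc` and `fdr` columns, so externally computed statistics (e.g. from a
GLM run elsewhere) are classified identically. `bh_adjust()` is the
Benjamini–Hochberg step-up, verified against `p.adjust` and a sorted-cummin
oracle.

## Motif deviations

`compute_deviations()` follows the bias-corrected deviation construction:
for motif $m$ and sample $j$, the observed fragment total over
motif-matching peaks $X_{mj}$ is compared with the expectation
$E_{mj} = T_j \sum_{i\in m} t_i / \sum_i t_i$ (sample depth times the
motif's share of the global per-peak totals); the raw deviation
$(X-E)/E$ is exactly zero for a motif matching all peaks and is invariant
to a global rescaling of all samples. Each of `n_bg_sets = 50` background
sets substitutes, for every peak, a peak drawn from its
`n_neighbors = 50` nearest neighbors in standardized (GC fraction, mean
log-CPM accessibility) space, self excluded; the z-score ("motif score")
standardizes the raw deviation by the background mean and standard
deviation (denominator $n_{bg}-1$). Both set sizes follow the reference
method's defaults. Degenerate covariates fall back to uniform background
sampling with a warning. `delta_scores()` is the condition contrast
$\Delta_m = \bar z_{m,A} - \bar z_{m,B}$; swapping conditions negates it.

Motif *membership* is an input (as in pipelines built on precomputed PWM
annotations); no sequence scanning is performed. `compute_gc()` accepts
either raw chromosome sequences or a precomputed per-peak GC table.

## Regulatory domains and enhancer–gene pairs

`basal_regulatory_domains()` builds the basal-plus-extension domains with
the published defaults (5 kb upstream, 1 kb downstream, up to 1 Mb
extension toward the nearest neighboring basal domain, clipped to the
chromosome) — the tool this emulates is usually run with "default
settings", and those numbers are its documented defaults; all three are
parameters here. On the minus strand the basal window is the mirror image
of the plus-strand rule around the TSS base. Curated domains are not
modeled. `associate_peaks_genes()` uses **midpoint containment** in the
extended domain (the reference tool's region-to-gene convention); any-
overlap association is available via a flag. A peak may associate with
zero, one, or several genes.

`enhancer_gene_pairs()` intersects the association edges with per-contrast
downregulated gene and peak sets. The default `gene_rule = "either"`
(down in at least one knockdown contrast) follows the usual phrasing of
such analyses; `"both"` is available, and the same choice is exposed for
peaks. The operation is monotone: enlarging any input set never removes a
pair.

# Synthetic epigenome inputs

`simulate_peak_samples()` draws a shared set of summit "archetypes"
(length-weighted across chromosomes, including chrY) and lets each sample
re-observe them with jitter well under the 250 bp flank, guaranteeing
cross-sample overlap; a configurable fraction of noise summits is
sample-specific. Two archetypes are deliberately placed inside blacklist
intervals and one on chrY so the filters are always exercised.
`simulate_fragment_counts()` plants log2 fold-changes on chosen peaks in a
negative-binomial model (variance $\mu + \phi\mu^2$); the per-sample
scaling applies equally to both conditions so the planted expected ratio
is exactly $2^{\mathrm{lfc}}$. `simulate_motif_matches()` couples a few
"planted" motifs to the peaks carrying the planted condition effect.
These generators emulate the statistical structure the pipeline assumes —
they do not emulate read-level artifacts, GC-dependent coverage bias,
fragment-length distributions, or correlated motif co-occurrence.

# Known limitations

* The differential stand-in is not a negative-binomial GLM; dispersion
  estimation and designs beyond two groups are out of scope. External GLM
  output can be classified through the same thresholds.
* The screen treats survival time units as opaque and assumes independent
  censoring.
* Regulatory-domain construction is quadratic per chromosome in the number
  of genes — appropriate for the toy genomes and gene tables this package
  targets.
* The consensus builder assumes per-sample peak sets fit in memory; all
  interval work is delegated to IRanges.
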