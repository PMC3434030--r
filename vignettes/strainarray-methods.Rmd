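---
title: "Methods: strain-level transcriptome analysis with strainarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level transcriptome analysis with strainarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`strainarray` implements a complete probe-level analysis for comparing brain
gene expression among fish strains with different domestication histories on
Affymetrix 3' expression arrays: RMA-style preprocessing, detection calls and
unbiased filters, single-feature-polymorphism (SFP) screening, moderated
differential expression with strain/domestication/sex contrasts, EASE-score
category overrepresentation, behavioral phenotype scoring with nested
fixed-effects ANOVA, and qRT-PCR ANCOVA validation. A synthetic-data
generator with full planted truth makes every stage measurable: sensitivity,
false-flag rates and false-discovery behavior are computed against known
ground truth in the test suite and in `scripts/acceptance.R`.

# Study design assumed by the pipeline

The canonical design is four strains — two recently wild-derived
(Gaighatta, Nadia) and two long-domesticated (SH, TM1) — with two biological
replicate pools per sex per strain: 16 arrays. Pools (3–5 fish each) are
treated as independent units with equal weight regardless of pool size; the
metadata carries pool sizes but no weighting is applied because pooled RNA
homogenates do not scale variance in a way that simple weights capture. The
strain-to-domestication mapping is data-driven (from the samples table), so
other panels can be analyzed unchanged.

# Preprocessing

**Background correction.** Observed PM intensity is modeled as
$O = S + B$ with signal $S \sim \mathrm{Exp}(\alpha)$ and optical background
$B \sim N(\mu, \sigma^2)$. Per sample, $\mu$ is the mode of the intensity
density, $\sigma$ comes from the sub-mode spread ($\times\sqrt2$, since only
the lower half of the background normal is visible below the mode), and
$\alpha$ is the reciprocal mode of the supra-mode excess. Each intensity is
replaced by the closed-form posterior mean $E[S \mid O = o]$ with the signal
supported on $(0, o)$; the transform is strictly positive and monotone. The
closed form is checked against numerical quadrature of the posterior in the
tests.

**Quantile normalization.** Columns are forced onto the common distribution
whose $r$-th order statistic is the cross-sample mean of $r$-th order
statistics. Ties within a column receive the mean of the reference values at
their would-be ranks. For continuous intensities ties have probability zero,
and the post-condition — bitwise-identical sorted columns — is exact; with
ties the tie convention (documented above) takes precedence over exact
equality of sorted vectors.

**Summarization.** Per probe set, `log2` intensities are decomposed as
`overall + probe effect + sample effect` by alternating median sweeps (probe
sweep first, then sample sweep), stopping when the total absolute residual
changes by less than 0.01 (default) or after 10 iterations — enough for
expression estimates well below the noise floor of 16-array experiments;
tests that compare against an independent median-polish implementation
tighten the tolerance so both runs reach the common fixed point.

**Detection calls.** Discrimination scores $R_j = (PM_j - MM_j)/(PM_j +
MM_j)$ are tested against $H_0: \mathrm{median}(R) = \tau$ (one-sided,
$\tau = 0.015$) with a Wilcoxon signed-rank test: the exact null for up to 12
informative probes (full $2^n$ sign enumeration when absolute deviations tie,
the closed signed-rank distribution otherwise), a normal approximation with
continuity and tie corrections beyond. Calls use the published cutoffs
(`P` below 0.04, `A` above 0.04) and Marginal is treated as Absent
downstream. The score construction and $\tau$ follow the standard detection
algorithm for these arrays; only the two p-value cutoffs are
experiment-specific.

**Expression filter.** "Unexpressed" is operationalized as: pool the
expression values of probe sets called Absent-or-Marginal in *every* sample,
take the 99th percentile as threshold $T$, and remove probe sets whose
maximum expression across samples is below $T$. Pooling over samples is the
default reading; a per-sample variant sits behind the `pooling` flag because
the verbal definition admits both. The threshold is a property of the full
matrix, so the filtered matrix carries it as an attribute and re-application
reuses it — this is what makes the filter idempotent; re-estimating on an
already filtered matrix would chase the surviving upper tail.

**IQR filter.** Probe sets with an interquartile range of log2 expression
below 0.5 across all chips are removed, with quartiles computed by linear
interpolation (`type = 7`); the convention is configurable because it moves
counts at the boundary. The comparison is strict (`IQR < 0.5` removed,
exactly 0.5 retained).

# SFP screening

A single-feature polymorphism is a probe whose hybridization differs among
genotypes because of sequence variation under the probe rather than
expression. Residuals are computed by subtracting the probe-set expression
estimate from each probe's background-corrected, normalized log2 value:
gene-level expression differences cancel, constant probe affinities survive
as row constants (and cancel in between-strain comparisons), while a
genotype-linked affinity shift leaves a strain-associated residual pattern.

Per probe, a multiclass SAM-type score
$d_j = \sqrt{\sum_k n_k(\bar x_{jk} - \bar x_j)^2} \,/\, (s_j + s_0)$
is computed with $s_j$ the pooled within-strain standard error and $s_0$ a
fudge constant (default: the 5th percentile of the $s_j$ distribution — a
deterministic, cheap convention; the coefficient-of-variation-minimizing
grid search is available via `s0 = "grid"`). Because significance is
calibrated by permuting strain labels, any strictly monotone rescaling of
the score leaves the q-value ranking unchanged, so the exact scaling
constant is immaterial. The q-value of probe $j$ is the median over
permutations of the count of permuted scores at or above $d_j$, divided by
the count of observed scores at or above $d_j$, clipped to $[0,1]$ and made
monotone nonincreasing in $d$. Strain (four classes), not
wild/domesticated, defines the permutation groups. A probe set is flagged
when *any* member probe has $q < 0.01$ (a `min_probes` option exists for
stricter rules), and flagged probe sets are removed before model fitting.

# Differential expression

Gene-wise ordinary least squares are fit on log2 expression with two
parameterizations: a strain cell-means model (one column per strain) for the
among-strain F test and the domestication contrast, and a strain-by-sex
cell-means model for the sex contrast. The among-strain and domestication
tests deliberately use the model without sex — sex and interaction terms are
null for the vast majority of genes in this design, and removing them
returns two residual df at $n = 16$; the factorial fit is still emitted for
audit.

Residual variances are moderated empirically: the prior $(d_0, s_0^2)$ is
estimated by matching the mean and variance of $\log s^2$ to a scaled-F
(log-chi-square) distribution via digamma/trigamma identities (Newton
inversion of the trigamma), the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and t/F statistics
gain $d_0$ degrees of freedom. When the log-variances are less dispersed
than chi-square sampling noise allows, $d_0 = \infty$ and the pooled
variance (arithmetic mean, the MLE in that regime) is used. Forcing
$d_0 = 0$ reproduces classical per-gene t statistics exactly — a tested
identity, as is the agreement with the `limma` reference implementation.

The domestication contrast is
$\tfrac12(\mu_{SH} + \mu_{TM1}) - \tfrac12(\mu_{Nadia} + \mu_{Gaighatta})$
(positive = higher in domesticated), computed *within* the four-strain model
rather than by re-fitting a two-group model: the four-strain residual is the
correct error term when strains genuinely differ. P-values are adjusted by
Benjamini–Hochberg (5% FDR throughout). Fold changes are
$2^{|\Delta \bar x|}$ with a separate direction field; for among-strain
lists "2-fold or greater" means the maximum over the six pairwise strain
comparisons reaches 2, and the boundary is inclusive. Domestication
candidates additionally pass a range-overlap filter: a gene is retained only
if the wild and domesticated expression ranges overlap by at most one sample
(values equal to a group extreme count as inside). Both boundary conventions
are inclusive and documented because they change printed counts.

Control probe sets (identifier prefix `AFFX-`, e.g. transgenic reporter
features) travel through preprocessing but are excluded between SFP removal
and model fitting, so ledger counts are control-free by construction; a
`control_exclusion = "post_hoc"` flag reproduces the alternative ordering in
which controls are dropped from the final lists only.

# Overrepresentation

Categories are scored against the *expressed* background (never the whole
array — the precondition enforces this) with the EASE score: the
hypergeometric upper-tail probability recomputed after removing one gene
from the list-and-category cell. The jackknife penalizes single-gene
categories and is provably conservative relative to plain Fisher; both
properties are tested against exhaustive enumeration of the hypergeometric
pmf. BH-adjusted p-values are reported alongside the raw EASE scores, and
flagging uses EASE < 0.05. Reproducing any specific annotation database or
hierarchy-aware filtering is out of scope; annotation is a user-supplied
table.

# Behavior and qRT-PCR statistics

**Scoring.** Vertical Depth is the mean over observation periods of the mean
vertical zone within each period (1 = surface, 6 = bottom); Horizontal
Position is the proportion of recordings with the front flag set. Incomplete
periods contribute their available recordings with counts reported.

**ANOVA.** The canonical model is Sex + Domestication + Strain nested within
Domestication, all fixed. Partial (Type-III-style) sums of squares are the
default because the design is slightly imbalanced (sequential Type-I sits
behind a flag); sum-to-zero contrasts are applied and, for nested terms,
aliased columns are dropped by pivoting exactly as `lm()` does — a term
errors only when *all* of its columns are inestimable. Residual skewness,
excess kurtosis and a Shapiro–Wilk statistic are reported as a normality
check but never gate the analysis.

**qRT-PCR.** Target C$_T$ is modeled as
`ct_target ~ ct_reference + Strain * Sex`: including the reference-gene
C$_T$ as covariate normalizes input amount within the model rather than by
pre-subtraction. Covariate-adjusted strain means are evaluated at the mean
reference C$_T$, averaged over sexes. A constant reference C$_T$ drops the
covariate with a warning and reduces to the two-way ANOVA. Pairwise strain
comparisons use the studentized range (Tukey–Kramer convention for
unbalanced sizes), and grouping letters are the standard compact letter
display: letters are maximal sets of mutually non-significant groups, so two
groups share a letter exactly when some non-significant set contains both.

# The synthetic-data generator

The generator exists so that every detector can be scored against known
truth. PM intensities follow
$PM_{ji} = 2^{\mu_{g(j),s(i)} + \phi_j + \delta_{j,s(i)} + \epsilon_{ji}} + b_{ji}$:
log-additive true abundance, probe-specific affinity
$\phi_j \sim N(0, 0.8)$, Gaussian log-scale noise (sd 0.25) and additive
truncated-normal optical background (mean 100, sd 20). MM probes carry
affinity and background but no signal term (cross-hybridization only), which
is what makes the PM−MM discrimination score informative. SFPs are modeled
as affinity shifts of ±1.5 log2 on two probes of a flagged probe set, shared
by all samples of one randomly chosen strain — the standard genetic
interpretation, invisible at the probe-set mean under robust summarization.

Defaults and their rationale:

* **16 samples** (4 strains × 2 sexes × 2 pools), 11 PM/MM pairs per probe
  set, matching the assumed design.
* **45% unexpressed** probe sets (no signal term), giving an expressed
  fraction similar to what brain tissue yields on a whole-genome array.
* **Expressed baselines** $\sim N(10, 1.2)$ log2 — signal well above the
  optical background. This matters: probes whose signal sits near the
  background respond nonlinearly after background correction, which imprints
  genuine strain-dependent probe residuals on strongly differential genes
  and would be flagged by the SFP screen. That artifact is real on arrays
  but is not the planted truth being measured.
* **Planted effects**: |log2 effect| $\sim N(1.25, 0.5)$ truncated below at
  0.89, i.e. fold changes from 1.85 upward — the range the candidate lists
  of such experiments span. Strain-specific effects hit one wild and one
  domesticated strain with the same sign, keeping the planted among-strain
  signal orthogonal to the domestication contrast; domestication effects
  shift both domesticated strains; sex effects shift males.
* **Biological strain variation** (sd 0.5 log2, per gene × strain) on
  expressed genes *without* planted effects. Real strain panels show
  substantial among-population expression variation; without it the IQR
  filter would remove every non-planted gene and the filtered set would be
  an artifact of the simulation. Planted genes carry no extra wiggle so
  their recorded truth is exact.
* **Behavior**: latent depth preference per fish with
  between-fish/total latent variance ratio 0.5 — the middle of the 0.4–0.6
  repeatability range reported for this assay — discretized into zones 1–6
  with clamping; front preference is Bernoulli with a per-fish logit-normal
  deviation. Default strain depth means (4.9/4.6 wild vs 2.4/2.6
  domesticated) were set so the one-way strain F statistic lands at the
  scale printed for the real assay (tens, not thousands).
* **qPCR**: reference C$_T$ $\sim N(20, 0.2)$, target tracks it with slope 1
  plus strain means and independent noise — the design that makes the
  ANCOVA's covariate adjustment exactly recoverable.

What the generator does **not** emulate: spatial array artifacts, batch and
hybridization-date effects, RNA degradation profiles, probe-sequence (GC)
affinity structure, saturating or non-log-linear dose response beyond the
additive optical background, and correlated gene modules. Passing tests
therefore demonstrate correctness of the statistical machinery under the
model the methods themselves assume, not robustness to every failure mode of
real arrays.

# Composition of stage-level guarantees

Sensitivity of the SFP screen is a property of the screen, measured by
feeding it all expressed probe sets. In the full pipeline the IQR filter
runs first and removes low-variability genes, including some SFP carriers
whose expression happens to be flat; end-to-end recovery metrics are
therefore reported *conditionally on a probe set reaching the relevant
stage* (flagged among expressed SFP carriers; detected among analyzed
planted-DE genes). Conditioning is the only well-defined composition — a
detector cannot recover what an upstream filter removed — and the
unconditional module-level sensitivities are reported alongside.

# Numerical conventions

Quantile `type = 7` (linear interpolation) for IQR and the expression
threshold; exact signed-rank null up to $n = 12$ with $2^n$ enumeration
under ties; median-polish probe sweep before sample sweep; trigamma
inversion by Newton iterations with asymptotic endpoints; permutation seeds
mandatory for every stochastic stage, with the pipeline fully deterministic
given its configuration. Result tables are written sorted by adjusted
p-value with identifier tie-breaks at 12 significant digits, so repeated
runs produce byte-identical outputs.

Problem sizes used by the test suite and acceptance script — 2000 probe sets
for pipeline-scale runs, 1000 for replicated recovery studies, 1000
permutations for production q-values (500 in replicated loops), 10–20
replicates for calibration estimates — were chosen to put Monte-Carlo error
comfortably below the tolerances being asserted while keeping a full run in
a few minutes on one core.

# Known limitations

* Printed counts (expressed / SFP-flagged / differentially expressed) on
  synthetic data depend on the generator's variability parameters and are
  not calibrated to reproduce any particular real dataset's cascade.
* Permutation q-values are granular at small permutation counts; fewer than
  100 permutations triggers a warning.
* The EASE stage scores a user-supplied annotation; database-dependent
  category systems and annotation clustering are out of scope.
* Random-effects and duplicate-correlation modeling, surrogate-variable
  correction, and binary CEL parsing are out of scope; probe-level input is
  tab-delimited text converted externally.
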