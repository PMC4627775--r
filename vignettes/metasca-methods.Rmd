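---
title: "Decomposing longitudinal dose-response metabolomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing longitudinal dose-response metabolomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

metasca analyzes studies in which separate groups of animals, exposed to a
range of doses of a compound, are sampled at a series of ages, and each
sample is profiled by ^1^H-NMR into a fixed-width bucket vector. The central
statistical problem is that dose effects of interest are small compared with
the physiological drift of the metabolome over age, so a per-time-point
discriminant model and a design-aware variance decomposition are both needed.
This vignette explains the models the package implements, the tunable
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical conventions, so that results can be interpreted
and reproduced.

## Bucket grids and normalization

A bucket grid divides a spectral region into half-open `[lo, lo + w)`
intervals of width `w` (0.01 ppm by default). Solvent and contaminant
resonances are removed through exclusion windows. The boundary convention is
that a window removes every bucket whose *lower* edge falls strictly inside
it, so an aligned window of width `W` removes `W/w - 1` buckets and one
boundary bucket survives per window. Under this convention the conventional
serum region (δ 9.0–0.70, excluding 5.10–4.40, 3.7–3.6 and 1.25–1.10 ppm)
retains 738 buckets and the liver region (10.0–0.80, excluding 5.0–4.50)
retains 871. ppm positions are compared with a 1e-6 ppm tolerance; axes are
reported high-to-low (NMR convention) while all set arithmetic runs on
ascending edges.

Each sample's bucket vector is divided by its total (total-area
normalization) to absorb differences in sample amount. Rows with
non-positive totals are rejected by sample name. Normalization is idempotent
and invariant to per-sample positive scale factors; the package does not
implement probabilistic-quotient normalization or peak alignment.

## The ANOVA-simultaneous component decomposition

For a two-way design (Time × Dose, separate animals in every cell) the
grand-mean-centered matrix is split additively:

$$X = X_{Time} + X_{Dose} + X_{Time \times Dose} + X_{Residual}$$

Main-effect rows are the marginal factor-level means of the centered data;
interaction rows are cell means minus both main effects; the residual is the
within-cell remainder. Main effects are always estimated marginally and
subtracted *before* the cell means, so the dose block and the interaction
block are reported separately — no combined dose-plus-interaction block
exists in the output. Each block's squared Frobenius norm is expressed as a
percentage of the total centered sum of squares. With unequal cell counts
(6–10 animals per cell is typical) the blocks lose exact orthogonality; the
resulting additivity deviation is small and is reported in
`additivity_deviation` rather than hidden by renormalizing. Constant
matrices are flagged `degenerate` instead of producing undefined
percentages. Each effect block can then be analyzed by singular value
decomposition (`sca()`), yielding per-sample scores, loadings and percent
explained per component; `interaction_score_profile()` averages the
interaction scores per design cell for the classic crossing-profiles plot.

### Permutation significance

Factor significance is assessed by permuting whole data rows against the
fixed design and recomputing the tested factor's sum of squares, with
$p = (\#\{SSQ_{perm} \ge SSQ_{obs}\} + 1)/(n_{perm} + 1)$ (so $p$ can never
be smaller than $1/(n_{perm}+1)$). This scheme is exact under the global
null and has a useful property worth keeping in mind when reading results:
under permutation the expected share of a factor's block is roughly its
degrees of freedom over $n - 1$. A Time × Dose interaction on a full 5 × 5
design (16 df, ~200 samples) therefore only reaches significance when its
share clears ~8%, while on a reduced 3 × 2 subset (2 df, ~40 samples) a
share above ~5% can already be significant. This is why the subset search
below exists: interactions confined to a few cells are invisible in the full
design and detectable in the right subset.

### The subset search

`search_interaction()` enumerates every combination of `k` time points
(`k = 3..5`; at least three time points are always required) and `h` doses
(`h = 2..5`), re-decomposes the corresponding sample subset and permutation
tests its interaction. On a full 5 × 5 design this is
$(C(5,3)+C(5,4)+C(5,5)) \times (C(5,2)+C(5,3)+C(5,4)+C(5,5)) = 16 \times 26
= 416$ combinations. Combinations that lose a design cell are skipped and
logged. Raw p-values are primary (each combination is a separate hypothesis
a researcher inspects); an optional Benjamini–Hochberg column is available
via `fdr = TRUE` for readers who want a multiplicity-adjusted view.

## OSC-filtered PLS-DA

Per time point, dose groups are discriminated with partial least squares
regression on the centered one-hot class matrix (NIPALS, sequential
deflation). Before modelling, columns are mean-centered and scaled — unit
variance by default, Pareto ($\sqrt{sd}$) selectable; constant columns are
dropped with a warning. Optionally, orthogonal signal correction first
removes the dominant variation orthogonal to the class structure
(instrumental or physiological variation unrelated to treatment). The OSC
implementation iterates the candidate score between the data's leading
principal direction and its class-orthogonal complement; the final removal
weights come from a pseudo-inverse projection, which makes the removed score
orthogonal to the class matrix to machine precision and lets the stored
model reproduce the filtered training data exactly. One OSC component is the
default; the count is configurable and the variance removed per component is
logged.

Model quality is summarized by:

* `R2Y`: cumulative percent of class variance explained;
* `Q2`: cross-validated predictive ability, $1 - PRESS/SS$, from stratified
  7-fold cross-validation in which scaling statistics are re-estimated on
  each training fold. Folds are random but seeded; every class must reach
  every training fold.
* `VIP`: per-bucket variable importance, normalized so the mean squared VIP
  is exactly 1; VIP > 1 is the conventional selection threshold.

The number of components is user-set; `ncomp = "auto"` adds components while
the cross-validated Q2 gains at least 0.01. Two-dimensional score plots
carry the 95% Hotelling's T² ellipse,
$T^2_{crit} = \frac{2(n-1)}{n-2} F_{0.95}(2, n-2)$.

### Permutation validation and the two verdicts

`permutation_validate()` refits the model under `n` random label
permutations (200 by default) and regresses R² and Q² on the correlation
between the permuted and original class matrices, including the original
model at correlation 1. The intercepts estimate the performance of a purely
random model. Two verdicts are reported, deliberately distinct:

* `robust`: Q² intercept below zero — the classical permutation-plot
  criterion;
* `valid`: the full standard — R² above 50%, Q² above 0.4 *and* a negative
  Q² intercept.

The distinction matters because on signal-free data both the permuted cloud
and the original Q² are negative, so the intercept alone is negative almost
always; only the composite standard separates informative from
uninformative data. The package's own null simulations (20 signal-free
cohorts through OSC + PLS-DA + validation) hold the `valid` rate at or
below 10%.

## Discriminant metabolites

Candidate buckets are selected by VIP (or absolute loading) threshold, then
each candidate is tested across dose groups with the Kruskal–Wallis rank
test (`stats::kruskal.test`). Only when the overall test is significant
(gatekeeping at 0.05) are pairwise comparisons of each exposed group against
the reference run — Dunn's tie-corrected rank z test by default, pairwise
Mann–Whitney selectable — with Benjamini–Hochberg correction (Bonferroni and
Holm selectable) across the within-bucket family of reference comparisons,
mirroring the starred-bar presentation of dose-response figures.
Direction-of-change signs (`+`/`-` relative to the reference mean) are
reported only for significant comparisons. Bucket records are aggregated to
metabolites through a ppm-interval annotation map; resonances that disagree
in sign are flagged as conflicts, and significant buckets without an
annotation are reported as explicit "unassigned δ lo–hi" intervals rather
than dropped.

## Biomarker sub-networks

The metabolic network is a directed bipartite graph of metabolite and
reaction nodes (substrate → reaction → product arcs), read from an edge-list
TSV or minimal SBML; reversible reactions are expanded into forward and
reverse reaction nodes so a path can never enter and leave a reaction on the
same side. For every unordered pair of discriminant metabolites the package
computes the lightest connecting path (igraph Dijkstra). By default,
entering a metabolite node costs its degree in the full network — the
standard penalty that steers paths around ubiquitous cofactors — with plain
shortest paths selectable; side compounds (ATP, NADH, water, …) are
additionally excludable through an editable list rather than a hard-coded
one, because the right list is organism- and question-dependent. Ties
between equally light paths are broken lexicographically on the node-id
sequence, so results are deterministic. The union of all accepted paths is
returned with per-node provenance (which biomarker pairs use it) and can be
exported to GraphML/GML for visual mining. Unreachable pairs are reported
as values, never raised as errors.

## The synthetic-cohort generator

`simulate_cohort()` emulates the structure the analysis assumes: a 5-dose ×
5-time design with 6–10 animals per cell (unbalanced, sampled per cell),
~30 latent metabolites mapped onto 1–4 bucket resonances each, and effects
entering *additively on the log-concentration scale* — so concentrations
stay positive and noise is multiplicative, as is standard for NMR
intensities. Time trajectories are seeded linear or quadratic shapes; dose
responses are monotone or U-shaped (non-monotone dose responses being a
hallmark of endocrine disruptors); interaction patterns are double-centered
cell-specific matrices, optionally confined to a chosen
`interaction_times × interaction_doses` block (the pattern is
double-centered inside the block, hence a pure interaction in the full
design as well). Default amplitudes (time 0.4, dose 0.1, interaction 0.2 log
units; affected fractions 0.6/0.3/0.3; multiplicative σ = 0.2) produce the
variance budget typical of this kind of study — a dominant Time share, a
dose share of a few percent and a large residual.

The generator's "truth" is defined as the decomposition of the noise-free,
normalized bucket matrix. This guarantees the exact ANOVA zero-sum
constraints and additive reconstruction with a zero residual block. Because
the true residual is zero while any noisy estimate has a positive one,
recovery is assessed on percent contributions *renormalized over the three
effect blocks*; comparing raw four-block percentages would measure the noise
level, not the estimator. At σ = 0.05 the effect-block shares are recovered
within 2 percentage points on average over ten seeds.

What the generator does **not** emulate: lineshapes, chemical-shift drift,
peak overlap beyond bucket-level mixing, correlated (pathway-level)
metabolite dynamics, and litter or batch structure. Passing tests therefore
demonstrate that the estimators recover the designed structure under
realistic dimensions and noise — not that any particular biological claim
holds on real spectra.

## Numerical conventions and test-scale choices

* Reconstruction and orthogonality checks use relative tolerances of 1e-9;
  OSC orthogonality 1e-8; VIP normalization 1e-9.
* Permutation p-values carry the +1 correction and are bounded below by
  $1/(n_{perm}+1)$; at least 99 permutations are required.
* The decomposition input is the normalized, centered matrix without OSC
  (OSC belongs to the discriminant arm); an OSC-filtered matrix can be
  passed explicitly for sensitivity analysis.
* Degenerate cases (constant matrices, zero blocks, all-tied rank tests)
  return explicit flags, not errors.
* Validation suites run at reduced bucket counts (a 60-bucket grid, 12–20
  metabolites) so that the full battery — including 200 null cohorts × 199
  permutations for calibration, and the 416-combination subset search —
  completes in a few minutes; design dimensions (5 × 5, 6–10 per cell) are
  kept at study scale. The subset-search identifiability check injects its
  interaction into a balanced 8-per-cell design without a time main effect,
  because the interaction *share* metric penalizes subsets containing
  high-time-variance levels; with a dominant Time effect the same injected
  pattern is still detected, but ranking "first by share" is only a
  well-posed target without that confound.

## Known limitations

* The decomposition uses unweighted marginal means (the standard
  simultaneous-component estimator); for severely unbalanced designs a
  regression-based (general linear model) variant would be preferable and is
  out of scope here, as are multilevel variants — each animal is sampled
  once, so no within-subject structure exists.
* Whole-row permutation tests the global exchangeability null per factor;
  its power for interactions depends on the interaction share relative to
  its null expectation (see above), which is a property of the method, not
  of the implementation.
* PLS-DA results are not numerically identical to any particular commercial
  implementation (component scaling conventions differ); agreement was
  verified against an independent open-source implementation at the level of
  score and VIP correlations above 0.99.
* No xlsx writer is available; bucket tables are written as CSV/TSV (xlsx is
  read-supported).
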