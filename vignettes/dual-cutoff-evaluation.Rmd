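---
title: "Dual-cutoff evaluation of plasma AD biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-cutoff evaluation of plasma AD biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyzone)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and the numerical conventions that make results reproducible to
the bit.

## 1. The classification framework

A plasma biomarker $X$ is evaluated against amyloid-PET positivity,
defined as a Centiloid value above 20 CL. A *dual-cutoff* rule with
thresholds $\ell \le u$ maps each subject to one of three zones:

$$
Z(x) = \begin{cases}
\text{negative} & x < \ell\\
\text{intermediate} & \ell \le x \le u\\
\text{positive} & x > u
\end{cases}
$$

Boundary values fall in the intermediate zone: the closed-interval
convention is the conservative choice (a value exactly at a threshold
yields no binary call) and matters only on ties.

With three-zone counts $a,b,c$ for disease-positive subjects (positive,
intermediate, negative zone) and $d,e,f$ for disease-negative subjects,
the package reports

$$
\mathrm{PPV} = \frac{a}{a+d},\quad
\mathrm{NPV} = \frac{f}{c+f},\quad
\mathrm{PLR} = \frac{a/(a+b+c)}{d/(d+e+f)},\quad
\mathrm{NLR} = \frac{c/(a+b+c)}{f/(d+e+f)},
$$

plus the intermediate-zone likelihood ratio $\frac{b/(a+b+c)}{e/(d+e+f)}$
and the intermediate fraction $(b+e)/N$. The likelihood ratios are
*multi-level* likelihood ratios with full-class denominators. This is a
deliberate choice: with intermediate-excluded denominators the three zone
probabilities would not sum to one within a disease class and a likelihood
ratio *of the intermediate zone itself* would be incoherent. When the
intermediate zone is empty the definitions reduce exactly to the classical
binary $\mathrm{sens}/(1-\mathrm{spec})$ and
$(1-\mathrm{sens})/\mathrm{spec}$, which the test suite asserts.

Degenerate cells are never silently dropped: a metric whose denominator is
empty is reported as `NA` with a reason string, and an infinite likelihood
ratio (no false positives) is reported as `Inf`.

### Cutoff derivation

`optimize_dual_cutoffs()` minimises the intermediate fraction subject to
$\mathrm{PPV} \ge 0.90$, $\mathrm{NPV} \ge 0.90$, $\mathrm{PLR} > 5$,
$\mathrm{NLR} < 0.1$ (inclusive for predictive values, strict for
likelihood ratios — exactly as the targets are stated; all four are
user-overridable through `cutoff_constraints()`).

The search grid is the set of midpoints between consecutive order
statistics of the observed values, extended by one sentinel below the
minimum and one above the maximum. This grid is *lossless*: any threshold
between the same two observed values induces the identical partition of
the sample, so searching all $\binom{K+1}{2}$ ordered midpoint pairs is an
exhaustive search over achievable classifications. The implementation
vectorises the search with cumulative class counts; the test suite holds
it bit-identical to an independently coded brute-force enumeration on
hundreds of random instances.

Ties in the objective are broken deterministically: fewest violated
constraints, then smallest intermediate fraction, then smallest cutoff
width, then largest $\mathrm{PPV}+\mathrm{NPV}$ (undefined values counting
as zero), then smallest lower and upper cutoff. An undefined metric never
satisfies its constraint; an infinite PLR does. When no pair is feasible
the minimiser of the violation count is returned with `feasible = FALSE` —
never a silent fallback.

One property of this optimisation deserves emphasis: when the reference
labels are independent of the marker, the constraints can still be met
*vacuously* — a single extreme value gives $\mathrm{PPV} = 1$ with
essentially the whole sample pushed into the intermediate zone. Feasibility
alone is therefore not evidence of discrimination; the intermediate
fraction is part of the result, and the tests assert that exchangeable
classes never admit a feasible pair with a small indeterminate zone.

### Bootstrap

`bootstrap_dual_cutoffs()` resamples subjects with replacement
(unstratified by default; a stratified option exists), re-derives the
optimal pair on each of $B = 1000$ replicates, and aggregates:

- **cutoffs** — per-threshold medians across feasible replicates. Medians
  of dependent thresholds can in principle cross; the implementation then
  collapses the pair to their midpoint. The original-sample optimum is
  available via `point_estimate = "original"`; it is always feasible when
  any pair is, whereas the median pair can miss a constraint narrowly on
  the original sample — the result flags this rather than hiding it.
- **metrics** — the three-zone metrics of the final pair applied to the
  original sample.
- **intervals** — 2.5/97.5 percentile intervals across replicates, each
  replicate's metric evaluated at *its own* cutoffs, so the interval
  reflects cutoff-derivation uncertainty, not merely counting noise.
  Percentile (not BCa) intervals are the simplest defensible choice at
  $B = 1000$. Replicates with an undefined metric are excluded from that
  metric's interval; infinite values are handled with order-statistic
  quantiles.

The fraction of infeasible replicates is recorded; if every replicate is
infeasible the CIs are undefined and the result is flagged.

## 2. Discrimination analyses

The AUC is the Mann–Whitney concordance: the fraction of
(positive, negative) pairs ranked correctly, ties counting one half,
computed from midranks. It is identical to trapezoidal integration of the
empirical ROC curve (asserted to $10^{-12}$) and invariant under strictly
increasing score transforms.

Confidence intervals use DeLong's structural-components estimator with a
normal approximation, clipped to $[0,1]$. The choice is deliberate:
DeLong is the standard for empirical AUCs, deterministic (no resampling
seed), and its coverage is verified in the test suite by a binormal
simulation with true AUC 0.85 (coverage within $[0.93, 0.97]$ at
$n = 200/200$ over 1000 replications). The implementation is cross-checked
against the independent `pROC` implementation to $10^{-10}$.

APOE ε4 carriage enters through a logistic model
$\text{logit}\,P(\text{A}\beta^+) = \beta_0 + \beta_1 x + \beta_2
\cdot \text{carrier}$, fitted by IRLS (tolerance $10^{-8}$, 100 iteration
cap); the fitted probabilities are the combined score. Complete separation
— detected directly from its definition, a fitted linear predictor that
splits the classes perfectly — triggers a warning and a documented
fallback to the raw marker ranking, because the MLE then diverges and its
fitted probabilities are numerically arbitrary.

Markers that *fall* with disease (Aβ42) are by default reported on the
oriented scale (score negated when the raw AUC is below one half, noted in
`score_spec`), matching how ROC tables are conventionally published;
`direction = "as-is"` disables this. Records without a Centiloid value are
excluded from ROC and cutoff analyses rather than imputed — under the
default generator that leaves 238 of 262 subjects. Subgroup analyses rerun
identically within the cognitively unimpaired (CU) and impaired
(MCI + dementia) strata.

## 3. Group comparisons

- One-way ANOVA from raw data uses the classical between/within
  decomposition; an algebraically identical summary-statistics entry point
  (`anova_from_summary()`) re-tests published mean ± SD tables without
  subject-level data. When all values are identical, $F = 0$ and $p = 1$
  by convention (the decomposition is 0/0).
- Proportions are compared by Pearson chi-squared without continuity
  correction (the group-comparison tables here are $2 \times 5$ with large
  expected counts, where Yates' correction is both unnecessary and
  biased). `counts_from_percent()` reconstructs integer counts from
  printed percentages, erroring when the implied count is further from an
  integer than the tolerance; since the distance can never exceed 0.5, the
  default tolerance 0.51 only fires when the user tightens it.
- Biomarker group effects are tested by ANCOVA (`value ~ group + age +
  sex`) with a full-versus-reduced partial $F$; adjusted means are
  evaluated at covariate means via `emmeans`, and post hoc contrasts apply
  the Bonferroni rule $\min(1, p \cdot k(k-1)/2)$ to the adjusted-model
  contrast p-values — post hoc inference is tied to the covariate-adjusted
  model, not to unadjusted pairwise t-tests. Constant covariates are
  dropped with a message (the group test then equals the unadjusted
  ANOVA); rank-deficient designs error naming the collinear columns.
- APOE carrier comparisons use the Welch (unequal-variance) t-test.
  Carrier and non-carrier variances of plasma markers are grossly unequal,
  and the Welch statistic on published carrier summaries reproduces the
  published p-value, which the pooled test does not; whether the original
  analyses pooled variances is not stated, so the Welch choice is recorded
  here.

Type-I calibration of the adjusted group test is verified empirically:
under a null generator (all group moments equal) the ANCOVA rejects at
$\alpha = 0.05$ in $5\% \pm 2\%$ of 1000 cohorts of $n = 200$.

## 4. Tau-PET partial correlations

Associations between plasma markers and regional tau-PET SUVR are
residual-based partial correlations: both variables are regressed on age
and sex, and the Pearson correlation of the residuals is reported with
$p$ from $t = r\sqrt{df/(1-r^2)}$, $df = n - 2 - k$. The residual method
agrees with the textbook recursive partial-correlation formula to
$10^{-8}$ (tested), and near-zero-variance residuals are reported as
undefined rather than correlated noise.

The 15 regional variables are grouped by Braak-stage topography (mesial
temporal — Braak I–II; meta-temporal and temporo-parietal — Braak III–IV;
frontal — Braak V–VI; global composites), each as left/right/composite
variants. The exact regional definitions of the cohort study this package
emulates are not public, so the shipped mapping is an explicit synthetic
stand-in and any `region, stage_group` table can be supplied instead.
Cells use pairwise deletion with per-cell $n$ displayed, and significance
tiers (`*` < 0.05, `**` < 0.01, `***` < 0.001) are raw p-values without
multiplicity correction — the convention of the heatmaps this reproduces,
stated rather than endorsed.

## 5. The synthetic cohort generator

No subject-level data are distributable, so every analysis is exercised on
a generator calibrated, at design time, to published group summaries.

**Marginals.** Concentrations are strictly positive and right-skewed, and
one group's p-tau217 has SD ≈ mean; a normal would place ~16% of its mass
below zero. Each group × marker therefore draws from a log-normal with
$\sigma^2 = \log(1 + (s/m)^2)$, $\mu = \log m - \sigma^2/2$ — exact
moment matching on the natural scale. Ages are normal truncated at 55
years (the emulated study's inclusion age, by rejection sampling),
education at 0.

**Dependence.** Within a subject the panel is tied together by **two**
standard-normal latent factors:

- a *disease severity* factor $z$: loadings $+0.5$ (p-tau217), $-0.3$
  (Aβ42), $+0.5$ (GFAP), $+0.6$ (Centiloid);
- a shared *pre-analytical nuisance* factor $w$ (sample volume, dilution,
  assay run): loadings $+0.5$ (p-tau217), $+0.6$ (Aβ42), 0 elsewhere.

Each log-scale marker is $\mu + \sigma(\lambda_z z + \lambda_w w +
\kappa \varepsilon)$ with $\kappa$ chosen so the marginal stays exactly
standard normal — the configured moments are preserved no matter the
loadings. The two-factor structure is load-bearing: a single factor
cannot simultaneously make the p-tau217/Aβ42 ratio the best discriminator
and give Aβ42 negative tau-PET correlations. A negative Aβ42 loading on
the *same* factor as p-tau217 adds positive covariance to the log-ratio
(high p-tau and low Aβ42 co-occur), inflating its within-group variance
until the ratio *loses* to p-tau217 alone; a positive loading flips the
pooled Aβ42–tau correlation sign. Splitting the shared variation into a
nuisance factor that the ratio algebraically cancels reproduces the real
mechanism by which ratio markers outperform their numerators, and under
the default calibration the ratio beats p-tau217 on AUC and on the
minimal intermediate zone in essentially every seeded cohort (verified
over 100 seeds in the acceptance suite).

**Amyloid reference.** Centiloid is drawn per group from a normal whose
moments are the affine image ($\mathrm{CL} = 188 \cdot \mathrm{SUVR} -
96.56$, anchored so SUVR 0.62 corresponds to CL 20) of the published
global-SUVR group summaries, coupled to $z$, and truncated (by inverse-CDF
sampling, exact for arbitrarily extreme tails) to the group's amyloid
sign: the diagnostic groups of the emulated cohort are *defined by*
amyloid-PET status, so group label and CL sign agree by construction.
24 subjects (default) have their Centiloid set missing, reproducing an
imaging subsample of 238. `global_suvr` is emitted as the inverse affine
image of Centiloid.

**APOE.** Carrier probabilities per group (0.22, 0.55, 0.28, 0.55, 0.65)
are designed, not published: they give an expected 104/262 carriers
(matching the published 102) with carriers enriched in amyloid-positive
groups, so carrier-stratified biomarker shifts emerge through group
composition alone.

**Tau panel.** Regional SUVR is `baseline + loading × severity + noise`
with stage-specific parameters (loadings 0.28/0.25/0.20/0.24 from Braak
I–II to the global composites, noise SD 0.15–0.20) and per-subject
severity `group offset + z` (offsets 0, 0.8, 0.2, 1.4, 2.0 across the
five groups). The loadings were calibrated once, by construction at large
$n$, so the ratio's age/sex-adjusted partial correlation with the mesial
temporal composite lies near 0.5 and Aβ42's is negative; they were not
fitted to any data. The default subsample (24 CU + 52 impaired = 76
subjects) mirrors a tau-PET substudy.

**Unpublished moments.** The amyloid-negative MCI plasma panel copies the
amyloid-negative CU moments (both groups are amyloid-negative), and the
amyloid-positive MCI Aβ42 is set between its CU and dementia neighbours
(23.0 ± 5.0); all such entries carry `interpolated = TRUE` in the config
and are design choices, not reproductions.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: assay analytics and batch structure,
longitudinal trajectories, non-log-normal tail behaviour, missingness
mechanisms other than the Centiloid subsample, and any site or scanner
effects. Headline metrics on synthetic cohorts (AUC ≈ 0.90, minimal
intermediate zone ≈ 30% at the default calibration) are properties of the
generator, not estimates of any published cohort's values: group mean/SD
summaries alone do not pin down the overlap structure that drives a real
cohort's discrimination.

**Sampling modes.** The default `draw = "random"` is iid, which the
calibration checks require (the type-I study needs genuine sampling
noise). A `draw = "quantile"` mode rank-maps each marker's latent onto
midpoint normal quantiles; it preserves the dependence structure through
ranks while making large-sample moments nearly deterministic (worst-case
SD error 0.34% at $n = 10^4$). It exists because the natural-scale SD of
a log-normal with CV ≈ 1 has excess-kurtosis-driven sampling error of
about 3% at $n = 10^4$, so an iid draw cannot attest the *calibration* of
the moment matching at the 2% level — the quantile mode checks the math,
the random mode serves every analysis.

## 6. Reproducibility conventions

Every stochastic function takes an explicit seed and restores the caller's
RNG state. The pipeline derives deterministic per-stage sub-seeds from one
global seed, so adding a stage never perturbs earlier stages' draws; two
runs with the same configuration are byte-identical, which the test suite
asserts via file checksums. Cohorts round-trip through CSV (sex as
`F`/`M`, missing values as empty fields) with a JSON sidecar holding the
full generator parameterisation; reloading the sidecar reproduces the
cohort to JSON decimal precision.

## 7. Problem sizes used in the test suite

The suites run at sizes chosen to make each property measurable while
keeping the whole suite quick on a laptop: oracle equivalence on 200
instances of $n \le 40$ (where exhaustive enumeration is exact and cheap),
DeLong coverage and type-I calibration at 1000 replications, ordering
properties over 100 seeded cohorts of the default 262-subject
configuration, moment recovery at $n = 10{,}000$ per group, and sign
patterns of the tau model at cohorts of several thousand.

## 8. Known limitations

- The optimizer's exhaustive pair search is $O(K^2)$ in the number of
  distinct values; at cohort sizes in the hundreds this is milliseconds,
  but for $n \gg 10^4$ a monotonicity-pruned search would be preferable.
- Bootstrap aggregation by per-threshold medians does not guarantee
  original-sample feasibility of the aggregated pair (see §1); both
  aggregation modes are first-class for this reason.
- PPV and NPV are prevalence-dependent; no prevalence-adjusted or
  cost-weighted cutoff selection is provided, and no external-validation
  split — cutoffs and metrics are in-sample.
- The DeLong interval is asymptotic; at very small $n$ or AUC near 1 its
  coverage degrades (the clipped bound is a symptom, not a fix).
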