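---
title: "Methods: first-day ICP trajectory phenotypes, survival cut-points, and weighted treatment effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-day ICP trajectory phenotypes, survival cut-points, and weighted treatment effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpday)
```

## The analysis problem

Patients with aneurysmal subarachnoid hemorrhage (SAH) are monitored invasively
for intracranial pressure (ICP) during their first day in intensive care.
Which summary of that first-day signal carries prognostic information — the
daily mean, its variability, or the shape of the 24-hour trajectory — and
where a clinically actionable threshold lies, are open questions. `icpday`
implements a complete, testable version of one analysis strategy:

1. regularize irregular chart events into a 24-point hourly series per subject;
2. cluster the normalized series to find trajectory phenotypes;
3. locate the survival-optimal dichotomization threshold of the daily ICP mean
   (and variance) by minimum log-rank p-value;
4. treat the threshold-defined groups as a "treatment" and estimate ATT/ATU/ATE
   under stabilized inverse probability of treatment weighting (IPTW);
5. produce FDR-controlled baseline comparison tables, multivariable logistic
   models for ICU mortality, and fluid-balance correlations.

Because the motivating cohorts live in credentialed clinical databases that
cannot ship with software, the package carries a synthetic cohort generator
whose structure mirrors what the analysis assumes, so every stage is
exercised end to end by code anyone can run.

## Preprocessing model

Chart events are assigned to the nearest hour of the subject's first 24 ICU
hours (`round_to_hour`). Ties at half past round up; measurements at or after
23:30 are clamped into the last slot; multiple measurements in one slot are
averaged. The day anchor is ICU admission; slots are indexed 1–24.

A subject is excluded (`gap_exclude`) when no monitoring is available or the
longest run of consecutive missing hour slots — runs touching either edge of
the day included — exceeds 6 hours. "Over 6 hours" is read strictly: a
6-hour gap is retained. The rule is applied to hour slots *after* rounding,
which is the resolution at which the series exists.

Interior missing slots are filled by linear interpolation between the nearest
observed neighbours; leading and trailing gaps carry the nearest observed
value flat (`impute_series`), since linear extrapolation beyond the last
observation is undefined and a flat carry adds no artificial trend.
`ICP_mean` and `ICP_variance` are the mean and sample variance (denominator
23) of the completed series; the variance denominator is a convention choice
and is documented rather than load-bearing.

The cohort matrix is normalized per time point (`normalize_matrix`):
each hourly column is z-scored across subjects, so that clustering responds
to trajectory *shape* relative to the cohort rather than absolute level
alone. Min–max scaling per column is available as an alternative
(`method = "minmax"`); z-score is the default because column-standardized
Euclidean geometry is the conventional input for distance-based clustering.
Degenerate columns map to zeros. The transform stores its affine parameters
and is exactly invertible, which the tests exploit.

## Trajectory clustering

`kmedoids` partitions the normalized rows around medoids (PAM build + swap,
Euclidean distance) via `cluster::pam`; the deterministic BUILD
initialisation makes results reproducible without seeding. `select_k` scans
k = 2..7 and picks the partition minimizing the Davies–Bouldin index
(`davies_bouldin`): the average over clusters of the worst-case
(dispersion-sum / centre-separation) ratio, lower better, with ties broken
toward smaller k for parsimony. The classical centroid-based dispersion is
the default even though the partition is medoid-based; a medoid-based
variant is selectable (`center = "medoid"`). Two clusters with identical
centres make the index undefined and raise an error rather than returning a
silent infinity.

Euclidean distance on the normalized series is an explicit modelling choice:
no time-warping or representation learning is attempted, because the series
are already aligned on the clock and only 24 points long.

## Survival cut-point search

`scan_cutpoints` implements the X-tile-style optimal dichotomization: the
candidates are the distinct integer-rounded marker values; each candidate
splits the cohort into `marker <= c` vs `marker > c` (boundary values go
low, matching the convention that a "14 mmHg" threshold means the group
*above* 14); candidates leaving less than `min_group_frac = 0.05` of the
cohort on either side are inadmissible. For each admissible candidate a
two-group log-rank test is computed — implemented directly from the
hypergeometric observed-minus-expected construction so the scan stays cheap —
and the candidate with the smallest p-value wins.

The minimum of many correlated p-values is anti-conservative. The package
therefore reports, alongside the raw minimum p, a Šidák-style minimum-p
correction `1 − (1 − p_min)^m` over the m candidates. The raw minimum still
drives cut selection (that *is* the procedure being modelled); the corrected
value quantifies the multiplicity honestly, and a property-based test
verifies that under a null marker the corrected rejection rate stays near
nominal while the raw one inflates.

Survival time is hours from ICU admission to ICU death, censored at ICU
discharge. Kaplan–Meier estimation wraps `survival::survfit`; the in-package
log-rank statistic is cross-checked against `survival::survdiff` and a
20,000-draw permutation null in the tests.

## Confounder screening and stabilized IPTW

The threshold-defined high-ICP group is treated as the exposure. Candidate
confounders (age, gender, minimum GCS, APS III, OASIS, SOFA) are screened
(`screen_confounders`): a covariate enters the propensity model when its
univariable association with the outcome has p < 0.1 (likelihood-ratio
test) *or* adding it to the outcome-on-treatment model moves the treatment
coefficient by more than 10% in relative terms. The 10% is read as a
relative change, the common epidemiological convention for
"change-in-estimate" criteria.

Propensity scores come from a logistic model; with `smooth = TRUE`
continuous covariates get penalized spline terms (`mgcv::gam`), shrinking
to the linear fit when the truth is linear. Scores are clipped to
[0.01, 0.99] — a pragmatic positivity guard, configurable. Apparent
separation triggers a ridge-penalized logistic fallback with a warning.

`stabilized_weights` implements: ATE — treated `P(T=1)/ps`, controls
`P(T=0)/(1−ps)`; ATT — treated 1, controls `ps/(1−ps)`; ATU — treated
`(1−ps)/ps`, controls 1. When the score is the marginal prevalence
(intercept-only model), all three estimands coincide exactly, which the
tests assert.

Effects are odds ratios from weighted logistic regression of outcome on
treatment (for the saturated model this equals the weighted 2×2 odds
ratio). The published effect scale in this literature is often unlabeled;
the odds ratio is this package's interpretation and is documented as such.
Confidence intervals are percentile bootstrap (default 1,000 resamples;
500 in the pipeline default), with the propensity model refit inside every
resample so the interval reflects design as well as outcome uncertainty.
The p-value is a normal approximation on the bootstrap log-OR spread. Zero
events in an arm fall back to a continuity-corrected (+0.5) odds ratio with
a warning.

## Cohort statistics

`compare_groups` builds a Table-1-style comparison: continuous variables are
gated per group through a Lilliefors-corrected Kolmogorov–Smirnov normality
test (estimated parameters; plain KS against a fixed normal would be
miscalibrated), then t-test/ANOVA or Wilcoxon/Kruskal–Wallis; categorical
variables use chi-square without continuity correction, switching to
Fisher's exact test when any expected cell is below 5. Benjamini–Hochberg
step-up flags are applied across all rows at q = 0.05; summaries print as
mean ± sd or n (%) with one decimal. `multivariate_logistic` feeds a
univariable p < 0.1 screen into a joint logistic model (age always
retained as a conventional forced covariate), reporting Wald CIs on the OR
scale. `fluid_icp_correlation` reports Pearson r, R² and the two-sided
p per outcome stratum.

## The synthetic cohort generator

The generator (`sim_config`, `simulate_cohort`) emulates the *structure* the
analysis assumes, with four trajectory archetypes:

| archetype | share | mean (mmHg) | profile | fluctuation sd (mmHg) |
|---|---|---|---|---|
| I | 0.62 | 9 | flat | 1 |
| II | 0.03 | 19 | large sinusoid (amplitude 15) | 2.5 |
| III | 0.10 | 19 | flat | 1 |
| IV | 0.25 | 9 | moderate sinusoid (amplitude 9) | 1 |

Each subject's latent trajectory is archetype mean + per-subject level
jitter + the archetype's deterministic 24-h profile + a smooth random drift
(three low-order sinusoid components) + i.i.d. noise. The deterministic
profile term is a deliberate design decision: archetypes that differ only in
noise scale are not identifiable by any distance-based clustering, and a
small high-variance group whose variability is pure noise can always be
absorbed by a neighbouring cluster under internal validity indices. Giving
each archetype a coherent shape — which is also what distinct trajectory
phenotypes mean clinically — makes the planted structure recoverable, and
the recovery study then genuinely tests the clustering stack rather than the
generator. Archetype II remains the high-variance phenotype by a wide
margin (within-day variance ≈ 120 mmHg² vs ≈ 1 for the flat archetypes).

Sampling is Poisson-irregular at 1.2 measurements/hour; 15% of subjects
lose one contiguous block of 2–9 hours, so the over-6-hour exclusion rule is
exercised at realistic rates (~8% excluded). ICU death follows a logistic
model in the latent daily mean, age and minimum GCS (defaults give ~20–25%
mortality, rising with ICP); GCS is generated to decrease with ICP, making
it a genuine confounder; fluid balance increases with ICP. An optional
log-odds jump at a configurable threshold plants a recoverable cut-point.
Death times are uniform over follow-up and survivors are censored at
discharge — deliberately *not* a hazard model, since the downstream use is
dichotomous-group log-rank comparison only.

What the generator does **not** emulate: pulse/respiratory ICP waveform
components, multi-day dynamics, informative censoring, treatment feedback
(ICP-lowering interventions responding to the signal), or realistic
covariate joint distributions (covariates are independent draws with
plausible locations). Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and calibrated, not that the clinical
findings replicate in real cohorts.

## Validation study sizes and numerical choices

The shipped studies use: n = 400 for archetype recovery (selected k = 4 and
adjusted Rand index > 0.9 against the planted labels), n = 1000 for
recovering a planted 14 mmHg mortality threshold (±1 mmHg), n = 2000 for
IPTW recovery of a planted conditional odds ratio of 3 (relative bias
< 15%, interval covering the truth), and 200 replicates at n = 2000 for the
null coverage of the bootstrap interval (observed ≈ 95–97%). The log-rank
implementation is checked against `survival::survdiff` to 1e-8 and against a
20,000-draw permutation null; PAM is checked against exhaustive medoid
enumeration for n ≤ 8; the BH step-up is checked against a brute-force
enumeration over 10,000 random p-vectors.

Other numerical conventions: nearest-hour ties round up; candidate cuts are
rounded to integers before scanning; cut-scan ties break toward larger
chi-square then smaller cut; Davies–Bouldin ties break toward smaller k;
sample variance uses n − 1; propensity clipping at [0.01, 0.99]; bootstrap
resamples that lose a treatment arm are dropped from the interval.

## Known limitations

- The min-p cut-point and the subsequent group comparisons reuse the same
  data; the reported corrected p mitigates but does not remove the circularity.
- IPTW assumes no unmeasured confounding and positivity; the generator
  satisfies both by construction, real data need not.
- The odds-ratio effect scale is an interpretation where the source
  literature leaves the scale unlabeled; a risk-ratio variant would require
  only a different link in the outcome stage.
- Single-day, single-ICU-stay scope; no competing risks (ICU discharge is
  treated as censoring, not a competing event).
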