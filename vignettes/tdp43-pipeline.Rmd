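---
title: "Classifying TDP-43 neuropathology in multicenter autopsy data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TDP-43 neuropathology in multicenter autopsy data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdpengine)
```

## The problem

Multicenter autopsy registries code TDP-43 proteinopathy through several
partially overlapping variables: tri-state regional assessments (spinal
cord, amygdala, hippocampus, EC/ITC, neocortex), a categorical
FTLD-TDP designation, a motor-neuron-inclusion type (TDP-43, FUS, SOD1,
other, none), hippocampal sclerosis of aging with laterality, and the
antibody used for staining. Three properties of these data drive the
design of this package:

1. **"Not assessed" is not "absent".** A region without a TDP-43 stain
   carries no information; conflating it with a negative finding biases
   both category frequencies and regional-distribution estimates. Every
   tri-state field therefore keeps `not_assessed` as a first-class
   value, and all category assignment is restricted to *complete cases*:
   records with all four brain regions, the FTLD-TDP designation, the
   motor-neuron assessment, and HS-A assessed. Spinal cord assessment is
   deliberately not required, because the categories are defined on brain
   TDP-43 and the spinal measure is far less available.
2. **Availability is structured, not random.** Assessment rates vary by
   calendar year (uptake of newer forms), by center (different staining
   practice), and — critically — conditionally on findings: after the
   introduction of the LATE-NC staging scheme, a hippocampus-negative
   case may not receive the neocortical stain at all. Such
   outcome-conditional missingness is exactly what a naive
   missing-at-random analysis gets wrong, so the package both *models* it
   (in the generator) and *detects* it (the era-split conditional
   availability test).
3. **Centers are a clustering unit.** Referral patterns differ sharply
   between centers, so association models come in single-level and
   center-varying-intercept (multilevel) versions.

## The classification rules

Categories are assigned by a fixed top-down cascade; the first matching
rule wins, and each record keeps an ordered trace of what fired:

| Rule | Condition | Category |
|---|---|---|
| 1 | FTLD-TDP designated, or motor neuron inclusions of TDP-43 type | ALS/FTLD-TDP |
| 2 | No TDP-43 in any brain region | No TDP-43 |
| 3 | Exclusionary pathology (CBD, CTE, acute/chronic TBI, Huntington, Guam/Kii) or FTD-related/ADAD mutation | Other TDP-43 |
| 4 | Neocortical TDP-43 without both amygdala and hippocampal TDP-43 | Other TDP-43 |
| 5 | otherwise | LATE-NC, staged |

Design points that were genuinely open and how they were decided:

- **Spinal-cord-only TDP-43** without a designation is No TDP-43,
  because the groups are defined on brain TDP-43; the finding is kept in
  the rule trace rather than discarded.
- **Designated ALS/FTLD-TDP with no TDP-43 anywhere** keeps its category
  (the designation is authoritative) but receives a `qc_no_regional`
  flag, since the combination may be a data-entry error.
- In rule 4, "without" means *assessed and absent*: the rule runs after
  the complete-case restriction, so a missing region can never trigger
  it.
- An EC/ITC + neocortex pattern (amygdala and hippocampus absent) falls
  under rule 4 and is traced explicitly rather than silently absorbed.
- Mutations recorded at a visit and at autopsy are treated identically;
  the data do not support distinguishing them.

LATE-NC stages are nested: stage 3 (amygdala + hippocampus + neocortex)
implies the stage-2 condition (amygdala + hippocampus); every other
eligible limbic distribution — amygdala, hippocampus, or EC/ITC in any
combination short of amygdala + hippocampus — is stage 1. The stager
requires at least one of the three limbic regions to be involved; calling
it on a neocortex-only pattern is a contract error, because such a record
can never be LATE-NC.

## Statistical engines

- **Rank-sum test**: exact enumeration of the null distribution when both
  samples have ≤ 8 observations and no ties; otherwise the normal
  approximation with tie correction and *no* continuity correction, so
  two identical samples give p = 1 exactly. When every observation is
  tied the tie-corrected variance is zero and p is defined as 1.
- **Chi-square**: Pearson without continuity correction by default; a
  `yates` switch exists for parity with software that defaults to the
  correction. The choice matters only in small strata.
- **2×2 odds ratios**: cross-product ratio with Wald intervals on the
  log scale. A single zero cell triggers the Haldane–Anscombe 0.5
  correction (documented in the output); a zero margin makes the
  statistic non-estimable and it is reported as `NA`, never fabricated.
- **Adjusted logistic regressions**: maximum likelihood (`glm`), outcome
  dichotomizations fixed as: ADNC none/low vs intermediate/high; CAA,
  atherosclerosis, arteriolosclerosis, and the atrophy measures none/mild
  vs moderate/severe; Lewy bodies present in any region; dementia vs
  normal/MCI; clinical AD vs not-AD/no-impairment. Covariates: age at
  death (years), sex, education (years), last-visit-to-death interval
  (years). Complete cases per outcome, with `n_used` reported so that
  `n_used + missing` always equals the cohort size. Coefficients with
  |log OR| > 15 are flagged as (quasi-)separated and non-estimable.
- **Multilevel variants**: `lme4::glmer` with a varying intercept per
  center. A single-center input degenerates, by design, to the
  single-level fit and says so. Convergence messages are surfaced in a
  `converged` column, never swallowed.
- **Post-hoc contrasts**: Wald tests on coefficient differences using
  the fit's covariance matrix (fixed effects only for multilevel fits —
  the covariance treatment was an open choice and this is the documented
  decision). Because adjustment covariates are shared, a coefficient
  difference *is* the log odds ratio between two categories, and the
  contrast is exactly reproducible by refitting with the other category
  as reference — a property the test suite checks to 1e-8. P-values are
  unadjusted for multiplicity throughout, matching the reporting
  convention of the analyses this package supports.
- **Rounding** is applied only at render time: percentages to the
  nearest whole percent (half away from zero, `pct_half_up()`), odds
  ratios to one decimal. All stored tables keep exact counts and
  proportions.

## The synthetic-cohort generator

The generator exists so that every stage — parsing, profiling,
classification, modeling — can be exercised and verified without access
to restricted registry data. Its defaults are the study conditions the
package is built around: category prevalences 62 / 27 / 9 / 2 % (No
TDP-43 / LATE-NC / ALS-FTLD-TDP / Other), subtype split 79 / 16 / 5 %
(FTLD-only / both / ALS-only), truncated-normal ages on [40, 110] years
with means (SD) of 78.9 (12.1), 84.0 (9.5), 71.5 (11.0), and 81.0 (12.3)
years for No TDP-43, LATE-NC, ALS/FTLD-TDP, and Other respectively,
APOE4 carriage of 58% in LATE-NC vs 32–39% elsewhere, and per-category
regional pattern tables in which 78% of ALS/FTLD-TDP records carry
TDP-43 in all four regions and the amygdala+hippocampus+EC/ITC pattern
is the LATE-NC mode at 46% (stage totals ≈ 35 / 53 / 12 %). Where a
quantity had no stated value (e.g. the laterality split within HS-A, the
diagnosis-label noise), a single realistic choice was made once and is
documented in `tdpengine:::default_generator_params()`; every value is
overridable through `generator_config()`.

Structural consistency is enforced at two levels. The configuration
validator rejects pattern tables that put mass on patterns inconsistent
with their category (a LATE-NC pattern may not show neocortical TDP-43
without both amygdala and hippocampus) and rejects nonzero LATE-NC
mutation rates, since mutation carriers are by definition not LATE-NC.
And by construction, classifying a generated record recovers its ground
truth: `round_trip_check()` verifies 100% category and stage agreement
on complete cases, which is the central internal-consistency property of
the whole pipeline.

Missingness is generated in three mechanisms:

1. a **staining workup** factor per record — a logistic trend in year of
   death plus a normal center intercept (SD 0.4 on the log-odds scale) —
   that gates all regional assessments and most FTLD-TDP designations.
   Gating regions on a shared factor, rather than drawing them
   independently, reproduces the strong cross-region availability
   correlation of real centers (regions tend to be available together or
   not at all);
2. independent logistic year-trends for the ALS and HS-A assessments,
   which do not require a TDP-43-specific stain and are therefore widely
   available throughout;
3. the **conditional neocortex skip**: for deaths in or after the split
   year (default 2019) with an assessed, TDP-43-negative hippocampus,
   the neocortical value is set to `not_assessed` with probability
   `p_skip_neocortex_if_hipp_negative` (default 0.15, sized to produce
   an availability gap of the magnitude seen in practice). The antibody
   is listed only when some TDP-43 stain was performed.

Random substreams are allocated per center, so enlarging one center
leaves the others' records bit-identical; the whole generator is
deterministic given the seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: longitudinal visit histories; correlated
co-pathologies beyond their category-conditional rates (e.g. no
ADNC–CAA dependence within a category); free-text diagnosis labels
beyond the configured label set; center-specific case-mix beyond the
random intercepts; and measurement error in the assessments themselves.
Tests on synthetic data demonstrate the *software* recovers what was
planted, not that the planted model is true of any registry.

## Verification strategy and problem sizes

The suite pairs every operation with an independent oracle: an
exhaustively enumerated truth table for the classifier (all region ×
designation × exclusion combinations), exact rank enumeration for the
rank-sum test, a hand-coded Newton maximizer of the logistic likelihood
(agreement to 1e-6 on a 12-row fixture), brute-force membership recounts
for all pattern tabulations, and reference-switch reparameterization for
the contrasts (1e-8). Stochastic properties use fixed seeds and
conservative bounds: 3 binomial standard errors for rate recovery at
n = 20,000; 95%-interval coverage of planted odds ratios in at least 18
of 20 replicates at n = 5,000; multilevel–single-level agreement within
2% at n = 10,000 with zero between-center variance; and detection of the
neocortex-skip mechanism at n = 10,000. These sizes keep the full suite
under a minute while leaving comfortable statistical margins.

## Limitations

- The classifier is only defined on complete cases; it deliberately
  refuses to classify partially assessed records rather than guess.
  Roughly half of realistic registry records are excluded by that
  restriction, and the retained subset is not a random half — analyses
  inherit whatever selectivity drives assessment.
- FTLD-TDP harmonized subtypes (A/B/C), CTE staging, and inclusion
  morphology are not representable in the coded fields this package
  reads.
- The "Other TDP-43" category is heterogeneous by design; it exists to
  protect the LATE-NC definition, not to characterize its members.
- Wald intervals and tests are used throughout; in very small strata
  profile-likelihood or exact methods would be preferable.
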