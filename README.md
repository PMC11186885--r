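# tdpengine

Classification and analysis of TDP-43 neuropathology in coded multicenter
autopsy registries.

TDP-43 proteinopathy spans clinically and demographically distinct
conditions: amyotrophic lateral sclerosis and frontotemporal lobar
degeneration with TDP-43 pathology (ALS/FTLD-TDP), limbic-predominant
age-related TDP-43 encephalopathy neuropathologic change (LATE-NC), and a
heterogeneous set of other TDP-43-associated pathologies (CBD, CTE,
traumatic brain injury, Huntington disease, Guam/Kii parkinsonism, and
mutation carriers). Registry data record these through coded fields:
tri-state regional TDP-43 assessments (spinal cord, amygdala, hippocampus,
entorhinal/inferior temporal cortex, neocortex — each *present*, *absent*,
or *not assessed*), an FTLD-TDP designation, a motor-neuron-inclusion
type, hippocampal sclerosis of aging (HS-A), and the antibody used.
`tdpengine` is for neuropathology and epidemiology researchers who work
with such tables and need the category assignment, the missing-data
accounting, and the association models to be explicit, deterministic, and
testable.

## What it does

**Classification.** Each record with complete TDP-43 assessment is
assigned one of four mutually exclusive categories by a fixed rule
cascade:

1. ALS-TDP or FTLD-TDP designation → **ALS/FTLD-TDP** (irrespective of
   co-pathologies), with subtype `ftld_only` / `als_only` / `both`;
2. no brain TDP-43 → **No TDP-43** (spinal-cord-only TDP-43 stays here,
   noted in the trace);
3. an exclusionary pathology or an FTD-related/ADAD mutation →
   **Other TDP-43**;
4. neocortical TDP-43 without both amygdala and hippocampal TDP-43 →
   **Other TDP-43** (not a permissible LATE-NC distribution);
5. otherwise → **LATE-NC**, staged 1–3: stage 2 requires amygdala +
   hippocampus, stage 3 adds neocortex, any other eligible limbic
   pattern is stage 1.

Every assignment carries a human-readable rule trace and QC flags.

**Availability analytics.** Per-measure assessed-vs-not profiles,
availability-by-year-of-death curves, Venn-style pattern counts across
measures and across brain regions, and a two-era chi-square comparison of
neocortical availability by hippocampal TDP-43 status (the signature of
pathologists skipping the neocortical stain in hippocampus-negative
cases after the LATE-NC staging scheme appeared).

**Associations.** Table-1-style group summaries (Wilcoxon rank-sum /
Pearson chi-square), adjusted logistic regressions of clinical diagnoses
and co-pathologies on TDP-43 category (odds ratios with Wald 95% CIs,
adjusted for age at death, sex, education, and last-visit-to-death
interval), multilevel variants with a varying intercept per center
(`lme4`), and Wald post-hoc contrasts between categories.

**Synthetic cohorts.** A fully seeded generator of multicenter cohorts
with ground truth: configurable category prevalences, category-specific
demographics and co-pathology rates, regional inclusion-pattern tables,
and structured missingness (logistic year trends, center intercepts, and
an outcome-conditional neocortex-skip mechanism). Every pipeline stage is
testable without access to restricted registry data.

## Worked example

```r
library(tdpengine)

cfg <- generator_config(n = 2000, n_centers = 25, seed = 20140101)
bundle <- run_pipeline(
  pipeline_config(generator = cfg, outcomes = c("dementia", "hs_a", "adnc")),
  "demo-output")
render_summary(bundle)
```

```
== TDP-43 pipeline summary ==
Records in cohort: 2000
Complete TDP-43 assessment: 861
  no_tdp43         503 (58%)
  late_nc          254 (30%)
  als_ftld_tdp      77 (9%)
  other_tdp43       27 (3%)
ALS/FTLD-TDP subtypes (n = 77):
  ftld_only     60 (78%)
  als_only       5 (6%)
  both          12 (16%)
LATE-NC stages (n = 254):
  stage 1    91 (36%)
  stage 2   135 (53%)
  stage 3    28 (11%)
Adjusted odds ratios (single-level):
  dementia           late_nc vs no_tdp43          OR 4.4 [2.9, 6.8]
  ...
```

Of 2,000 simulated autopsies, 861 (43%) have every TDP-43 assessment
performed and enter the complete-case analyses. Among them LATE-NC is the
most common TDP-43 pathology (30%), ALS/FTLD-TDP is enriched far beyond
its population prevalence (9%, as expected of referral-based registries),
and the adjusted models recover the planted associations — e.g. LATE-NC
carries about four-fold odds of dementia relative to records without
TDP-43. All tables are also written as CSV into `demo-output/`, together
with a JSON-lines run log that accounts for every record at every stage.

To classify your own coded CSV instead, pass `input =` (and optionally a
custom code dialect; see `inst/extdata/dialect.yaml`):

```r
bundle <- run_pipeline(pipeline_config(input = "cohort.csv"), "out")
```

A command-line wrapper with subcommands `simulate`, `classify`,
`availability`, `associations`, `all` is installed at
`inst/cli/tdpengine.R`.

## Package layout

- `R/` — dialect/parser, availability profiling, classifier and stager,
  Part-I availability analytics, statistical engines, Table-1 summaries,
  pattern/overlap tabulations, synthetic-cohort generator, pipeline.
- `vignettes/tdp43-pipeline.Rmd` — the methods vignette: model,
  assumptions, parameter choices, and limitations.
- `tests/testthat/` — unit, property, and acceptance suites with
  independent oracles (exhaustive truth tables, rank enumeration, Newton
  likelihood maximization, brute-force recounts).
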