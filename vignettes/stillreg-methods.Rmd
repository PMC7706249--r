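---
title: "Methods: registry stillbirth analysis in stillreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry stillbirth analysis in stillreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillreg)
```

# The problem

Prospective, population-based pregnancy registries in low-resource
settings enroll all pregnant women in defined geographic clusters
(catchment areas of roughly 300–500 annual births, grouped into research
sites) and record demographics, antenatal and delivery care, and birth
outcomes. `stillreg` implements the analysis layer for such a registry:
which fetal deaths count as stillbirths, how causes are attributed, how
rates and risk factors are estimated in the presence of within-cluster
outcome correlation — and a synthetic registry generator so that the whole
pipeline can be exercised and validated without access to any study data.

# Outcome classification

A delivery is a **stillbirth** under a modified WHO criterion: a fetal
death at ≥ 20 completed weeks of gestation, or — only when gestational age
is unavailable — birthweight ≥ 500 g. When both fields are present the
gestational-age criterion decides alone: a fetal death at 20 weeks and
400 g is a stillbirth, a fetal death at 19 weeks and 900 g is a
miscarriage. This "GA-first" reading follows the definition's own phrasing
("for those without gestational age available"), and keeps the rule a
deterministic partition: every record maps to exactly one of
stillbirth / live birth / miscarriage / termination / missing.

Some reports describe the denominator as births "> 500 g"; the inclusion
rule above (≥, GA-or-weight) is used for numerator and denominator alike
for internal consistency. A `strict_gt_500g` switch in
`outcome_thresholds()` restores the strict reading for sensitivity
analyses; it is off by default.

The analysis set excludes miscarriages, terminations and missing
outcomes, and `build_analysis_set()` reports the full enrollment
accounting (screened → enrolled → excluded by reason → included) so the
counts can be audited against an enrollment diagram.

# The cause-of-stillbirth hierarchy

Each stillbirth receives exactly one primary cause by walking a fixed
six-level hierarchy and stopping at the first level satisfied:

1. **trauma** — fetal trauma / accident;
2. **congenital anomaly** — a major, *visible* anomaly (no routine
   ultrasound is assumed);
3. **infection** — signs of maternal or fetal infection;
4. **asphyxia** — any maternal or fetal condition associated with
   intrauterine asphyxia; the default condition set is hypertensive
   disease (pre-eclampsia/eclampsia), antepartum hemorrhage,
   obstructed/prolonged labor, plus a generic other-condition flag;
5. **prematurity** — gestational age below 32 completed weeks;
6. **unknown**.

Three design choices deserve note:

* **Unknown flags count as absent.** Condition flags are tri-state
  (true/false/unknown); the classifier treats unknown as false but the
  original value is preserved for reporting.
* **Missing gestational age can never yield prematurity.** "Below 32
  weeks" is unverifiable without a GA, so such records fall through to
  unknown.
* **The asphyxia set is configurable** because the source definition is
  explicitly non-exhaustive. Breech/transverse lie is *not* in the
  default set: it appears in condition-level reporting but not in the
  stated algorithm. Passing
  `asphyxia_conditions = c(default_asphyxia_conditions(),
  "breech_transverse")` reproduces the alternative reading.

The classifier is validated against an exhaustive brute-force oracle over
all $2^9$ flag combinations crossed with GA ∈ {missing, 20, …, 40}, and by
property tests (first-match dominance; monotonicity in trauma).

Report tables ("other/unknown" column) are represented by the single
`unknown` cause: the stated algorithm has no separate "other" branch.
Percentages are rounded half-up to one decimal, matching report style
(base R's round-half-to-even would differ in edge cases).

# Rates and trends

Rates are stillbirths per 1000 births (live + still). Two interval
methods are provided, with `ci_method` always recorded in the output:

* **Wilson score interval** (default) on the binomial proportion, scaled
  to per-1000. The source reports intervals without stating a method;
  Wilson is a well-behaved default at both small counts and boundaries.
* **Cluster-robust interval**: the ratio-estimator between-cluster
  variance $\widehat{var}(R) = \frac{G}{G-1}\sum_g (x_g - R n_g)^2 /
  (\sum_g n_g)^2$ with a normal approximation, acknowledging that
  outcomes are correlated within cluster. With identical cluster rates it
  degenerates to the point estimate; with fewer than two clusters it
  falls back to Wilson with a warning.

Yearly trend series can be restricted to **continuing clusters** — those
contributing at least one included birth in *every* calendar year of the
span — because sites changed their cluster sets over time and a trend on
a shifting denominator would be confounded by cluster composition. A
`min_births_per_year` option strengthens the restriction if desired. No
formal trend test is fitted (the source assessed trends visually); the
series is the deliverable.

# Relative risks under cluster correlation

Risk factors are estimated one exposure at a time (univariable), matching
the per-row presentation of registry risk-factor tables; no adjustment
set is defined. The model is a log-link binomial marginal model, so
coefficients exponentiate to relative risks. Variance comes from the
cluster-level sandwich (GEE) estimator; the working correlation is

* **independence** (default): the point estimate then coincides with the
  crude RR from the pooled 2×2 counts, which keeps it interpretable as
  the marginal RR, while the sandwich still delivers cluster-robust
  standard errors;
* **exchangeable**: a common within-cluster correlation α estimated by
  the usual moment estimator; the working-correlation inverse is applied
  in closed form, so fitting stays linear in the number of records.

No GEE library is assumed: the estimating equations are solved by Fisher
scoring with step-halving that keeps all fitted risks below 1 (the
log-binomial boundary). If the fit still fails to converge the documented
fallback is a log-link Poisson model with the same sandwich variance —
standard RR-estimation practice — flagged as `fallback = TRUE` in the
output. Exposure levels with zero cases in either arm (separation under
the log link) are flagged and returned without an estimate; a 0.5
continuity correction is available in `crude_rr()` but off by default.

The default clustering unit is the geographic cluster; `cluster_unit =
"site"` is offered because some table footnotes describe clustering at
site level. Both are first-class and labelled in output metadata. The
printed, clustering-adjusted RRs of the source are *not* reproduction
targets: the crude preterm RR computed from the printed counts (≈ 9.5)
differs materially from the printed 8.6, showing that the published
adjustment is not recoverable from printed counts alone. The estimator is
therefore validated by properties: collapse to the crude RR, algebraic
chain identities, invariance to cluster relabelling, and a Monte-Carlo
coverage study (500 replicates, 50 clusters × 500 births, true RR 2.0:
bias ≤ 5 %, CI coverage within 90–98 %).

# The synthetic registry: a stated world

`generate_registry()` draws one record per enrolled pregnancy:

* **Structure.** Each site has `n_clusters` clusters enrolling a fixed
  `births_per_cluster_year`; the bundled `gn2018_config()` uses seven
  sites (one Latin-American, three African, three Asian) with 10–24
  clusters each and site totals near the reported study sizes, first-year
  rates between ~20 and 56 per 1000, declining trends for the
  Pakistan-like and Nagpur-like sites (multiplicative factors 0.971 and
  0.922 per year, chosen to connect the reported 2010 and 2018 rates) and
  mild declines (0.995) elsewhere.
* **Risk model.** Stillbirth is Bernoulli with risk combined
  multiplicatively (log link): site baseline × yearly trend ×
  exp(cluster random effect) × per-covariate RRs. The baseline is
  calibrated by dividing by the analytic expectation of the covariate
  multiplier and the random-effect mean, so the configured site rate is
  the *marginal* rate — the exact estimand of the rate pipeline — and
  each configured covariate RR is the exact marginal RR (covariates are
  independent, and a shared multiplicative cluster effect cancels from
  marginal risk ratios).
* **Bounded effects.** The full set of printed marginal RRs cannot be
  combined multiplicatively at the highest-rate site: the worst covariate
  combination would imply risk > 1, which the generator rejects by
  contract (such configs are invalid worlds). The bundled default
  therefore carries risk through a bounded subset spanning the printed
  range — ANC visits (3.5 / 2.2), birth attendant (2.1 / 0.6 / 0.5), fetal
  sex (1.2) — and keeps the remaining covariates descriptive (RR 1).
  Preterm- and birthweight-linked risk emerges instead from the
  outcome-conditional gestational-age model below.
* **Gestational age and birthweight.** GA is a rounded, clamped normal:
  mean 38.8 (SD 1.9) weeks for live births, 35.5 (SD 4.5) for
  stillbirths, giving preterm fractions near 12 % and 60 % respectively.
  Birthweight is linear in GA (170 g/week from 3250 g at 40 weeks, −150 g
  for stillbirths, SD 350 g). A stillbirth with missing GA is forced to
  ≥ 520 g so its truth label stays consistent with the 500 g fallback.
* **Conditions, maceration, exclusions.** Condition flags are sampled
  conditionally on outcome, with stillbirth-conditional probabilities
  chosen once so the hierarchy lands near an asphyxia-dominated mix
  (~44 % asphyxia, ~22 % infection); maceration status is drawn per site
  (overall ≈ 29 % macerated / 63 % non-macerated / 8 % unknown);
  enrolled pregnancies become miscarriage / termination / missing with
  probabilities 2.8 % / 0.2 % / 0.6 %, so ~96 % of enrolled are included,
  as in large registries.
* **Truth ledger.** Every latent is recorded: analysis class, true
  stillbirth flag, per-record risk, cluster effect, and the intended
  cause (computed by an independent inline re-derivation of the
  hierarchy), plus cluster continuity labels and expected site-year
  rates. `truth_report()` adds analytic expectations, including the
  expected cause mix by full enumeration of flag combinations with the
  prematurity branch weighted by $P(\text{GA observed} < 32)$.

What a green round-trip test establishes: the estimators recover the
configured marginal rates, trends, cause mix and RRs at stated
Monte-Carlo tolerances. What it does not: the generator samples
covariates independently, so real-world covariate correlation (education
× site × ANC), twin correlation, enrollment drift and measurement
improvement over time are all outside the stated world.

# Numerical choices

* Displayed rates and percentages round half-up to one decimal; machine
  outputs keep full precision.
* GEE convergence: max |Δβ| < 1e−9 or score sup-norm < 1e−10, 60
  iterations, step-halving against the η ≥ 0 boundary; exchangeable α
  clamped to [0, 0.95].
* Degenerate inputs: zero-birth strata are flagged `undefined` rather
  than dropped; empty cross-tab columns report zero percentages without
  division errors; empty input yields empty output with zero counts.
* Determinism: one global seed; identical seed + config gives
  byte-identical CSV output.

# Known limitations

* The CI method behind published rate intervals is unstated; both offered
  methods are approximations and are labelled in every output row.
* The published clustering-adjusted RRs cannot be reproduced from printed
  counts (see above); only properties of the estimator are claimed.
* The cause classifier consumes clinical flags as given; it cannot model
  under-ascertainment of infection or subtle anomalies.
* Whether macerated stillbirths were barred from the prematurity cause in
  the original system is unknowable from the stated algorithm (published
  tables show zero macerated-prematurity cells); no such rule is encoded.
* Cluster ids are unique within site only; all joins are on (site,
  cluster).

# Worked example

```{r example, eval = FALSE}
cfg <- gn2018_config(scale = 0.05)          # ~5% of full size, fast
bundle <- run_pipeline(config = cfg, out_dir = tempfile("report"),
                       seed = 42, exposures = c("preterm", "anc_group"))
bundle$site_rates
bundle$cause_by_site
bundle$risks
```
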