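---
title: "Modelling the prognostic impact of MRI-era reclassification in prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the prognostic impact of MRI-era reclassification in prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progshift)
library(dplyr)
```

## The problem

Pre-treatment risk and prognostic groups — the three-tier EAU system, the
four-tier AUA system and the five-tier Cambridge Prognostic Group (CPG)
model adopted by NICE — drive management decisions in non-metastatic
prostate cancer. All of them were developed before pre-biopsy MRI became
standard. MRI changes the inputs those models see, through two routes:
radiological T staging can upstage tumours relative to digital rectal
examination (DRE), and image-targeted biopsies can re-grade tumours
relative to systematic cores alone (including finding cancers whose
systematic cores were benign).

`progshift` models the downstream consequences in three stages:

1. **Reclassification.** Classify every patient of a diagnostic cohort
   twice — once from clinical attributes (DRE stage, systematic-biopsy
   Grade Group), once from MRI-enhanced attributes (radiological stage,
   combined-biopsy Grade Group) — and tabulate the marginal shifts.
2. **Redistribution.** Retrofit the observed percentage-point shifts onto
   a grouped historical population cohort with long-term prostate-cancer
   mortality, reassigning deaths to the resized groups at each group's
   original death rate.
3. **Evaluation.** Measure what the redistribution does to each model's
   discrimination (Harrell's C) and effect sizes (Cox hazard ratios) on
   simulated individual-level survival data.

## Risk classifiers

All three systems are driven by (Grade Group, PSA, T group). The package
operationalises them on **whole T groups only**: T2 substages are ignored
(the 2017 TNM revision abandoned them), which makes the EAU and AUA tiers
exact collapses of the CPG tiers:

| CPG  | condition                                                  | EAU          | AUA                        |
|------|------------------------------------------------------------|--------------|----------------------------|
| CPG1 | GG1, PSA < 10, T1–T2                                       | low          | low                        |
| CPG2 | T1–T2, exactly one of {GG2, PSA 10–20}                     | intermediate | favourable intermediate    |
| CPG3 | T1–T2 and (GG2 ∧ PSA 10–20, or GG3 ∧ PSA ≤ 20)            | intermediate | unfavourable intermediate  |
| CPG4 | exactly one of {GG4, PSA > 20, T3} (GG < 5)                | high         | high                       |
| CPG5 | ≥ 2 of {GG4, PSA > 20, T3}, or GG5, or T4                  | high         | high                       |

The collapse property is asserted by exhaustive enumeration in the test
suite, together with totality (every (GG, PSA band, T) cell receives
exactly one label per system) and monotonicity (worsening one feature
never improves a label). PSA banding uses the conventional inclusive
10–20 ng/ml intermediate band; both boundary values fall in the band.

Two deliberate simplifications, both visible in the classifier code:

* **AUA percent-positive-core criteria are not applied** to the
  favourable/unfavourable split. The cohort margins this package is built
  to reproduce are identical for AUA favourable/unfavourable and
  CPG2/CPG3, which is only possible if core counts played no role; the
  package adopts that operationalisation.
* **Radiological staging** follows the fixed rule: biopsy-proven but
  MRI-invisible lesions are rT1, visible organ-confined lesions rT2,
  extracapsular extension rT3a and seminal vesicle invasion rT3b; rT4 is
  never produced. Substage detail (T3a/T3b) is display-only.

## Shift tables and rounding

`stage_shift()`, `grade_shift()` and `risk_shift()` report, per category,
counts and percentages under each characterisation and the
percentage-point delta. Percentages are rounded to 1 decimal place,
half away from zero.

Denominators follow the cohort structure rather than being forced equal:
stage and grade tables cover **all** biopsied patients (n = 370 in the
default cohort), while risk tables use cancers-only denominators — the
clinical side excludes the 16 patients whose systematic biopsies were
benign (n = 354) because a benign biopsy has no risk group, whereas the
MRI side covers all 370 combined-biopsy cancers.

The delta is computed by a single rule with two regimes:

* equal denominators (stage, grade): the delta is the exact net-count
  percentage `100 * (n_mri − n_clinical) / N`, rounded once — e.g. the
  stage shift 29/370 = +7.8 pp;
* unequal denominators (risk tables): there is no common count scale, so
  the delta is the difference of the two 1-dp percentages as reported.

This distinction is not cosmetic: with a 354 vs 370 split, the
full-precision difference and the difference of reported percentages can
disagree by 0.1 pp (the CPG4 shift is 4.353 pp at full precision but
+4.3 as the difference of the reported 22.4% and 18.1%). The package
prints deltas that are consistent with its own printed percentages.

`risk_crosstab()` exposes the per-patient transition matrix (including a
`benign` clinical row) for anyone who needs per-patient shift rates; the
shift tables themselves are net marginal comparisons. No statistical test
of marginal homogeneity is attached — the shifts are descriptive.

## The synthetic diagnostic cohort

Published diagnostic cohorts of this design report *margins*: stage,
grade and risk distributions under each characterisation. The joint
clinical-by-MRI transition structure is not published. The default
generator (`gen_diagnostic_cohort()`, driven by
`build_default_joint_table()`) therefore ships a **minimal-movement
feasible joint table**: stage changes are upgrades only (T1–T2 → T3),
grade changes are upgrades plus benign→cancer transitions for the 16
systematic-benign cases, and cell counts were chosen so that *every*
published margin is reproduced exactly — 107 vs 136 T3 assignments,
systematic grades 101/123/60/13/57 (+16 benign) vs combined
96/133/63/17/61, and risk-group counts 67/86/69/64/68 (n = 354) vs
66/78/65/83/78 (n = 370) under the classifiers above.

Within that structure, covariates are filled deterministically: PSA on an
even grid inside each record's band (spanning the published 1.2–108
ng/ml range), ages on 45–80, volumes on 17.9–191 ml, and the published
Likert margin (17 negative MRIs — the rT1 records — then 29/79/193
scored 3/4/5 with 52 unrecorded). A multinomial mode resamples cells with
a seeded RNG for uncertainty exploration; its margins converge to the
deterministic ones as n grows.

What the generator does **not** emulate: any real correlation between
PSA level and grade beyond the joint table's band structure, reader- or
lesion-level MRI detail, and the true (unpublished) per-patient
transition pattern — the crosstab of the synthetic cohort is *a* feasible
realisation, not an observation. Tests that pass on this cohort certify
the pipeline's arithmetic and the margin structure, not any per-patient
claim about real data.

## Redistribution simulation

`redistribute()` applies a model's percentage-point shifts to a grouped
allocation (per risk group: alive and prostate-cancer-death counts):

* **Sizes** (`redistribute_sizes()`): the target size of group *g* is
  `N × (original proportion + shift/100)`; fractional targets are
  integerised by largest-remainder rounding so the population total is
  conserved exactly. Because reported shift vectors can carry ±0.1 pp of
  rounding drift, targets are rescaled to the population total before
  integerising.
* **Deaths** (`assign_events()`): each resized group receives
  `new_size × orig_dead/(orig_alive + orig_dead)` deaths — the group's
  original death rate applied to its new size — rounded half-to-even in
  expected mode, or drawn as a seeded binomial in stochastic mode.

Two properties deserve emphasis. First, **total deaths are not
conserved**, by construction: net movement into high-rate groups at their
original rates increases the total (with the default cohort's shifts the
EAU total rises from 789 to ~846), and the published redistributed
tables show exactly the same behaviour. Second, the published
redistributed group sizes come from a *stochastic* block-assignment run
in the source analysis and differ from the deterministic expectation by
a handful of subjects; the package therefore never asserts equality with
printed sizes, only closeness, while the printed *death* counts are
reproduced exactly when `assign_events()` is evaluated at the printed
sizes. The stochastic mode here keeps the deterministic target sizes and
randomises the death draws only — the exact block scheme of the original
analysis is not published, and inventing one would add noise without
information. Net size movement is interpreted as flow between adjacent
groups (a modelling convention; only margins matter downstream).

## Population cohort simulation

The population side needs individual-level censored survival times, which
were never published. `population_config()` fixes the emulation:

* entry uniform over a 10-year accrual window, administrative censoring
  2 years after accrual ends — potential follow-up uniform on 2–12
  years, chosen to match the published cohort's accrual (2000–2010,
  follow-up to 2012) and its 6.9-year median follow-up;
* two competing exponential hazards per subject: a per-group
  prostate-cancer hazard and a shared other-cause hazard (0.02/year by
  default, a modest rate for a mostly 60–75-year-old cohort);
* the prostate-cancer hazard of each group is **calibrated by root
  finding** (`calibrate_pc_hazard()`) so the expected number of
  *observed* prostate-cancer deaths — net of other-cause deaths and
  censoring — equals the group's published death count.

Follow-up is summarised by `median_followup()`, whose default is the
reverse Kaplan-Meier estimator (deaths censored, censoring as event),
the standard way "median follow-up" is reported; under the default
configuration it lands at ≈ 7.0–7.1 years.

Two generators share this machinery. `gen_population_cohort()` draws
everything randomly: per-group death counts are then binomial around the
targets (tests check the mean over replicates against the targets within
3 binomial standard errors). `expand_allocation()` instead reproduces the
allocation *exactly* — every group gets exactly its alive and dead
counts, with death times drawn from the calibrated hazard truncated to
each subject's follow-up — and uses stratified quantile-grid draws with a
seeded pairing, so the represented distributions carry minimal Monte
Carlo noise. That makes paired contrasts (original vs redistributed
allocation expanded under the same seed) isolate the effect of the
allocation itself, which is how the discrimination-degradation analysis
is run.

The exponential form is the simplest calibratable choice; nothing in the
published material constrains the shape of the hazard, and the
configuration object is the hook for richer families if needed. C and
hazard-ratio *orderings* are insensitive to this choice at the cohort's
event rates; absolute C values are not, which is one reason the package
treats its simulated C values as descriptive.

## Survival evaluation

* **Kaplan-Meier** (`km_estimate()`) and **Cox** (`cox_fit()`) go through
  the survival package. Cox models use group indicators with the
  best-prognosis tier as reference, Breslow handling of tied event times
  (the default of the statistical software used for the original
  analysis), and Wald 95% intervals. Other-cause deaths are censored:
  the endpoint is prostate-cancer-specific mortality throughout, and no
  competing-risks (Fine–Gray) model is fitted. A group without events
  makes hazard ratios inestimable and raises an explicit error rather
  than returning a boundary fit.
* **Harrell's C** (`harrell_c()`, `concordance_index()`) is implemented
  in the package with the exact pinned definition: a pair is usable when
  the observed times differ strictly and the subject with the shorter
  time has an event; the pair is concordant when that subject also has
  the higher score; score ties count ½; pairs tied on time are excluded.
  Grouped predictors are scored by the tier's ordinal rank — no
  within-tier ordering is invented. The implementation sweeps event
  times in O(n log n + nk); the test suite proves it equal to an
  exhaustive all-pairs oracle on hundreds of random instances, and the
  Cox fits equal a brute-force Breslow partial-likelihood optimiser to
  10⁻³ on small instances. Confidence intervals for C use a seeded
  nonparametric bootstrap over subjects (percentile method, 1000
  replicates by default) — the original analysis does not state its CI
  method, so a method-agnostic reproducible choice was preferred.

Evaluating all three models on the *same* CPG-generated records (EAU and
AUA labels derived by collapse) makes the discrimination ordering an
almost-sure consequence of the data: merging CPG4/CPG5 into AUA "high"
turns informative cross-tier pairs into ties, and the merged tiers have
clearly different death rates, so C(CPG) > C(AUA) ≥ C(EAU) on any
realistically sized cohort. Redistribution inflates the high-rate tiers
(more score-tied pairs, fewer informative cross-tier pairs), which drags
every model's C towards 0.5 — the degradation the pipeline is built to
quantify.

## Problem sizes and numerical choices

The shipped analyses and tests use the full published scale where it is
cheap (10,139-subject expansions, 370-patient cohorts) and replicate
counts chosen for stable Monte Carlo summaries: 100 paired seeds for the
ordering/degradation analysis, 1000 replicates for generator calibration
checks, 200 random instances for the concordance oracle and 20–25 for the
Cox oracle. Root finding uses `uniroot` to 10⁻¹² on a bracketed hazard;
largest-remainder rounding breaks remainder ties by group order;
`round()`'s half-to-even is used for expected death counts and is
documented in `assign_events()`.

## Known limitations

* The joint transition table and all survival times are synthetic; only
  the published margins constrain them. Conclusions about *orderings and
  directions* are robust to that; absolute C values and hazard ratios
  are descriptive.
* The redistribution transports group margins, not individual
  covariates; it assumes redistributed groups keep the original groups'
  death rates, exactly as the source analysis did — if MRI-upstaged
  patients have systematically different mortality than their new
  group's historical members, both the original analysis and this
  simulation would mis-estimate the impact.
* The individualised-prediction contrast (overall survival under an
  external prognostic algorithm) is out of scope; a documented hook
  (`individual_predictions()`) marks the interface.
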