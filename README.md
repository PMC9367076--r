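# progshift

Quantify how MRI-era prostate cancer diagnostics shift pre-treatment
risk-group assignment, and simulate what that shift does to prognostic
model performance on long-term population outcomes.

Modern diagnostic pathways characterise a newly diagnosed prostate cancer
twice: clinically (digital rectal examination stage + systematic biopsy
Grade Group) and with MRI-enhanced information (radiological stage +
combined targeted/systematic biopsy Grade Group). The risk models used to
counsel patients — EAU (3 tiers), AUA (4 tiers) and the NICE Cambridge
Prognostic Groups, CPG (5 tiers) — all predate pre-biopsy MRI.
`progshift` implements the full analysis pipeline for asking what MRI
does to them:

1. **Classify** both characterisations of every patient. All three
   systems are deterministic functions of (Grade Group *GG*, PSA, whole
   T group); on whole T groups the coarser systems collapse from CPG:
   CPG1 = {GG1, PSA < 10 ng/ml, T1–2}; CPG2/CPG3 split the
   intermediate tier by whether one or both of {GG2, PSA 10–20} are
   present (plus GG3 ≤ 20 in CPG3); CPG4 has exactly one adverse
   feature of {GG4, PSA > 20, T3}; CPG5 has two or more, or GG5.
2. **Tabulate shifts**: per-category counts, 1-dp percentages and
   percentage-point deltas for stage (T1–T2 vs T3), Grade Group
   (GG1–GG5 + benign) and each risk model, with the cancers-only
   denominator convention on the clinical side.
3. **Redistribute** a grouped population cohort (per risk group: alive
   and prostate-cancer-death counts) by the observed shifts:
   `new_size_g = N(p_g + shift_g/100)` with largest-remainder rounding,
   then `deaths_g = round(new_size_g × d_g/n_g)` — each group's original
   death rate applied to its new size.
4. **Evaluate** discrimination on simulated individual-level survival:
   Kaplan–Meier curves, Cox proportional-hazards hazard ratios (Breslow
   ties, best tier as reference) and Harrell's concordance index
   `C = (concordant + ½ tied) / usable pairs` with bootstrap CIs.

Synthetic generators reproduce the published marginal structure of a
370-man diagnostic cohort and a 10,139-man population cohort (789
prostate-cancer deaths, median follow-up ≈ 6.9 y), so everything is
testable without patient data. See the vignette
(`vignettes/reclassification-impact.Rmd`) for the modelling detail.

## Worked example

```r
library(progshift)
library(dplyr)

cohort <- gen_diagnostic_cohort()        # 370 patients, paired characterisations
risk_shift(cohort, "cpg")
#> Shift table (CPG): clinical n = 354, MRI-enhanced n = 370
#>   category n_clinical pct_clinical n_mri pct_mri delta_pp
#> 1 CPG1             67         18.9    66    17.8     -1.1
#> 2 CPG2             86         24.3    78    21.1     -3.2
#> 3 CPG3             69         19.5    65    17.6     -1.9
#> 4 CPG4             64         18.1    83    22.4      4.3
#> 5 CPG5             68         19.2    78    21.1      1.9
```

MRI-enhanced characterisation moves 4.3 and 1.9 percentage points of
patients into the two worst prognostic tiers (high and very high risk).
Retrofit those shifts onto the population cohort and re-evaluate:

```r
redis <- redistribute(table3_allocation("cpg"), risk_shift(cohort, "cpg"))
redis
#>   model group n_alive n_dead n_total n_total_orig n_dead_orig size_change
#> 1 cpg   CPG1     1597     31    1628         1740          33        -112
#> 2 cpg   CPG2     1701     53    1754         2078          63        -324
#> 3 cpg   CPG3     1363     81    1444         1637          92        -193
#> 4 cpg   CPG4     3182    306    3488         3052         268         436
#> 5 cpg   CPG5     1453    372    1825         1632         333         193

pop  <- expand_allocation(table3_allocation("cpg"), seed = 1)
pop2 <- expand_allocation(redis[, 1:5], seed = 1)
tibble(model = c("cpg", "aua", "eau"),
       c_original      = sapply(c("cpg","aua","eau"), \(m) harrell_c(pop,  m, boot = 0)$c_index),
       c_redistributed = sapply(c("cpg","aua","eau"), \(m) harrell_c(pop2, m, boot = 0)$c_index))
#>   model c_original c_redistributed
#> 1 cpg        0.707           0.701
#> 2 aua        0.670           0.656
#> 3 eau        0.664           0.652
```

The finer five-tier CPG model discriminates best before and after, and
every model loses discrimination after redistribution — the high-risk
tiers absorb more patients at unchanged death rates, diluting the
cohort's risk separation. Hazard ratios and KM curves come from
`cox_fit()` / `km_estimate()` (with `tidy()`, `glance()` and
`autoplot()` methods), and `run_pipeline()` orchestrates the whole
sequence from one seeded configuration.

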