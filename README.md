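# metabosurv

Survival modelling of paired serum metabolite fold changes.

`metabosurv` is an R package for relating changes in serum metabolite
profiles — quantified by NMR before and after a systemic treatment such as
neoadjuvant chemotherapy — to time-to-event outcomes (disease-free and
overall survival). It is aimed at biostatisticians and metabolomics
analysts who need a multivariate, collinearity-aware alternative to
one-metabolite-at-a-time survival testing.

## The method

For patient *i* and metabolite *m*, concentrations are sum-normalized per
sample and the covariate is the paired natural-log fold change
`logFC[i,m] = ln(after[i,m]) − ln(before[i,m])`. The analysis core is:

1. **Multivariate Cox model with recursive VIF elimination.** A Cox
   proportional hazards model (Efron ties, Newton–Raphson) is built over
   all metabolite fold changes plus forced clinical covariates (HER-2,
   hormonal receptor). The variance inflation factor
   `VIF_j = 1/(1 − R²_j)` is computed over the design; the metabolite with
   the highest VIF ≥ 3 is removed and the scan repeats until every
   remaining covariate has VIF < 3. Forced covariates are never removed.
2. **Metabolite-related survival score (MRSS).** Metabolites with Wald
   p < 0.10 in the final model define
   `MRSS_i = Σ_m β̂_m · logFC[i,m]`.
3. **Maximally selected rank cutpoint.** The score is dichotomized at the
   cutpoint maximizing the absolute standardized two-sample log-rank
   statistic over all splits leaving ≥ 10% of patients on each side,
   yielding low-/high-risk strata.
4. **Downstream reporting.** Kaplan–Meier curves and log-rank tests
   (overall and within stage I–II / III–IV), Cox models adjusted for age
   and stage, and cohort-characteristics tables with chi-square/Fisher
   association tests.

A synthetic-cohort generator (`generate_cohort()`) produces paired
concentration tables with planted fold-change collinearity and
proportional-hazards outcomes with known coefficients, so the entire
pipeline is testable without patient data. See the methods vignette
(`vignettes/metabosurv-methods.Rmd`) for the model, assumptions, and
design decisions.

## Worked example

```r
library(metabosurv)

cohort <- generate_cohort(cohort_config(seed = 1))   # 80 patients, 35 metabolites
bundle <- run_pipeline(cohort, pipeline_config(output_dir = "results"))

bundle$selection
#>      metabolite       beta          hr            p
#> 1       Choline  1.4906224  4.43985823 0.0781393187
#> 2 Phenylalanine -2.8474530  0.05799184 0.0001475162
#> 3        Serine  2.5583976 12.91510493 0.0001378063
#> 4          Urea  0.4441626  1.55918404 0.0749949141

bundle$mrss
#> <mrss_result> 80 patients scored on 4 metabolites
#> cutpoint = 0.44045 -> 64 low / 16 high risk

bundle$logrank$DFS
#> Two-sample log-rank test
#>   chi-square = 43.827 on 1 df, p = 3.588e-11
#>   group 'low': observed 18, expected 29.532

subset(bundle$adjusted$table, factor == "mrss_high")
#>   endpoint    factor       hr ci_lower ci_upper            p
#> 3      DFS mrss_high 7.818065 3.797344 16.09603 2.384175e-08
#> 6       OS mrss_high 6.545437 2.905410 14.74585 5.791111e-06
```

Reading the output: the simulated cohort (seed 1) has 33 relapses and 25
deaths among 80 patients. The VIF recursion removed 20 collinear
metabolites (logged per cycle), the final multivariate model selected four
metabolites at p < 0.10 — including Serine, one of the planted signal
metabolites — and the resulting score split the cohort 64/16. High-risk
patients relapse markedly faster (log-rank p ≈ 4e-11); after adjustment
for age and disease stage the high-risk stratum keeps a DFS hazard ratio
of 7.8 (95% CI 3.8–16.1). Because the cutpoint is chosen to maximize
separation, these in-sample p-values are optimistic; see the vignette.

All artifacts (fold changes, VIF trace, final model, scores, cutpoint,
KM exports, characteristic tables, run manifest) are written to
`output_dir` as CSV/JSON and are byte-identical across repeated runs.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/metabosurv.R simulate --out cohort_dir/
Rscript inst/cli/metabosurv.R run --before cohort_dir/before.csv \
  --after cohort_dir/after.csv --clinical cohort_dir/clinical.csv \
  --outcomes cohort_dir/outcomes.csv --out results/
```

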