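# trecscreen

Simulation and evaluation of TREC-based newborn screening for severe
combined immunodeficiency (SCID).

National screening programmes detect SCID from dried blood spots by
multiplex qPCR of T cell receptor excision circles (TREC, a proxy for
thymic output), the B cell analogue KREC, and beta-actin (ACTB, a
DNA-sufficiency control), all in copies per well. A card is referred to a
specialist centre when its mean TREC over replicate PCRs is ≤ 6
copies/well; cards just above that pass through an epoch-dependent
reanalysis band (initial TREC ≤ 15 copies/well, lowered to ≤ 10 on
1 April 2020); cards whose replicates are uniformly low TREC with
ACTB < 1000 copies/well are inconclusive and trigger a new-card request.

`trecscreen` is for screening-laboratory statisticians and methods
researchers who want to study this decision algorithm quantitatively. It
provides:

* **Synthetic cohorts** — `simulate_cohort()` generates screened children
  whose per-gestational-age TREC/KREC distributions reproduce the published
  reference table (lognormal per stratum, calibrated by median and IQR:
  μ = ln median, σ = ln(q3/q1)/(2·z₀.₇₅)), with injected SCID /
  lymphopenia / false-positive / technical-failure cases matching the
  published per-case profiles.
* **qPCR plate model** — `simulate_plate()`, `fit_standard_curve()`,
  `quantify()` (copies = 10^((Ct − intercept)/slope)), `accept_plate()`
  with internal-control patterns and blank checks.
* **The decision algorithm** — `classify_initial()`,
  `replicate_consensus()` (extreme-variability outlier rule),
  `screen_child()`, `run_programme()`.
* **Clinical performance** — Wilson score intervals (`wilson_ci()`),
  exact Poisson incidence intervals (`exact_poisson_ci()`), confusion
  metrics, stratified referral rates, post hoc referral cut-off sweeps
  (`cutoff_sweep()`), and a pure-arithmetic report from the published
  first-year aggregate counts (`first_year_report()`).

## Worked example

Simulate a 20,000-newborn cohort with injected cases, run the screening
programme, and evaluate it against the ground truth:

```r
library(trecscreen)
cfg <- pipeline_config(
  cohort = cohort_config(n_newborns = 20000, n_non_newborns = 100,
                         case_rates = c(SCID = 5/20000,
                                        lymphopenia_non_SCID = 10/20000,
                                        FP_low_trec = 12/20000,
                                        technical_failure = 8/20000)),
  seed = 2026)
res <- run_pipeline(cfg)
print(res$run)
#> Screening run: 20100 children
#>   reanalysed: 61 (0.30%)   referred: 32 (0.159%)
#>   inconclusive: 10   lost to follow-up: 3
print(res$performance$confusion$SCID)
#> Confusion table (outcome: SCID), n = 20,100
#>   TP 5   FP 27   TN 20,065   FN 0   excluded 3
print(res$performance$incidence)
#> 5 cases / 20,000: 1 in 4,000 (95% CI 1 in 12,319 - 1 in 1,714)
```

All five injected SCID cases are referred (sensitivity 1, FN 0): every
SCID card carries TREC < 1 copy/well on all spots, and the replicate
consensus rule is constructed so that uniformly low cards can never have
replicates excluded. The 27 false positives are the injected low-TREC FP
and lymphopenia children plus the rare healthy preterm tail. The
inconclusive cards are collection failures (ACTB < 1000 on every punch);
responders resolve on a second card, the rest are lost to follow-up and
excluded from the negative count. The post hoc sweep then shows what a
lower referral cut-off would have done:

```r
res$sweep[res$sweep$cutoff %in% c(6, 4),
          c("cutoff", "referred_total", "tp_scid", "tp_lymphopenia",
            "ppv_lymphopenia", "sensitivity_scid")]
#>   cutoff referred_total tp_scid tp_lymphopenia ppv_lymphopenia sensitivity_scid
#> 1      6             32       5             14       0.4375000                1
#> 3      4             17       5             10       0.5882353                1
```

The published-counts path needs no simulation at all:

```r
print(first_year_report())
#> Outcome SCID:
#>   sensitivity  100.00% (43.85-100.00)
#>   specificity   99.94% (99.92-99.95)
#>   ppv            4.11% (1.41-11.40)
#>   npv          100.00% (100.00-100.00)
#> Outcome T_cell_lymphopenia:
#>   ppv           28.77% (19.65-40.01)
#> ...
#> SCID incidence: 3 cases / 115,216: 1 in 38,405 (95% CI 1 in 186,231 - 1 in 13,142)
#> At referral cut-off 4 copies/well: 53 referred, PPV(lymphopenia) 34.0% (22.7-47.4),
#> SCID sensitivity retained 100%
```

## Package layout

| Layer | Functions |
|---|---|
| cohort | `cohort_config()`, `simulate_cohort()`, `inject_case()`, `ga_reference_strata()` |
| qPCR | `fit_standard_curve()`, `quantify()`, `simulate_plate()`, `quantify_plate()`, `accept_plate()`, `analytical_limits()` |
| screening | `screening_policy()`, `classify_initial()`, `replicate_consensus()`, `screen_child()`, `run_programme()` |
| evaluation | `wilson_ci()`, `exact_poisson_ci()`, `confusion_table()`, `confusion_metrics()`, `referral_rates()`, `cutoff_sweep()`, `percentile_equivalence()`, `summarise_distribution()`, `evaluate_performance()` |
| reporting / IO | `first_year_counts()`, `first_year_report()`, `true_positive_cases()`, `run_pipeline()`, CSV/YAML/JSON readers and writers |

See `vignettes/trec-screening-methods.Rmd` for the model, its assumptions,
every tunable parameter, and known limitations.
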