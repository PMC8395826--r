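---
title: "Modelling TREC-based newborn screening for SCID: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TREC-based newborn screening for SCID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trecscreen)
```

## The screening problem

Severe combined immunodeficiency (SCID) is a group of inborn errors of the
adaptive immune system in which T lymphocytes are absent or non-functional.
Untreated it is fatal in infancy; treated before infections take hold
(hematopoietic cell transplantation, enzyme replacement, or gene therapy)
survival is excellent. Population newborn screening detects SCID from dried
blood spots (DBS, Guthrie cards) by quantifying T cell receptor excision
circles (TREC) — episomal DNA by-products of T cell receptor gene
rearrangement that track recent thymic output — together with the B cell
analogue KREC and beta-actin (ACTB) as a DNA-sufficiency control, all by
multiplex qPCR in copies per well.

This package models the complete analysis chain of a national TREC/KREC
screening programme: the screened population, the qPCR measurement, the
decision algorithm, and the clinical-performance statistics. Real screening
data cannot be shared, so the package couples two evidence paths:

1. a **pure-arithmetic path** (`first_year_counts()`,
   `first_year_report()`) that computes every performance statistic directly
   from the programme's published aggregate counts, with no simulation; and
2. a **simulation path** (`simulate_cohort()` → `run_programme()` →
   `evaluate_performance()`) whose generator is calibrated to the published
   reference distributions, so the decision algorithm and the evaluation
   machinery can be exercised end to end on data with known ground truth.

## The synthetic cohort

### Per-stratum lognormal calibration

TREC levels rise with gestational age. The published reference table gives,
for seven 3-week gestational-age strata from week 22, the stratum size and
the median and quartiles of TREC and KREC copies/well. Copy-number
distributions are strictly positive and right-skewed, so each stratum is
modelled as a lognormal. Only the median and IQR are published, which
identifies the two parameters exactly:

$$\mu = \ln(\mathrm{median}), \qquad
  \sigma = \frac{\ln(q_3/q_1)}{2\,z_{0.75}}, \quad z_{0.75} = 0.6745.$$

A point worth being precise about: this calibration reproduces the median
*exactly* and the quartile **ratio** $q_3/q_1$ exactly. A lognormal is
geometrically symmetric about its median, so when the published quartiles
are not ($110/79 \ne 79/55$ for the whole-population summary) the
individual quartiles are matched only approximately — e.g. (79, 55, 110)
yields quartiles $79/\sqrt 2 = 55.9$ and $79\sqrt 2 = 111.7$. Tests
therefore check the median and the quartile ratio, which is what the family
can represent.

```{r}
unlist(lognormal_from_median_iqr(79, 55, 110))
```

The default gestational-age mixture uses the reference strata's own sizes
as proportions (93.7% term). Simulating 50,000 newborns and taking the
median recovers the published population median of 79 copies/well:

```{r}
coh <- simulate_cohort(cohort_config(n_newborns = 50000, n_non_newborns = 0,
                                     spots_per_child = 1L, seed = 1))
median(coh$trec)
```

### Children, spots, and conditions

Each child carries up to four blood spots. Spot-level truths are the
child's level times multiplicative lognormal noise with a 10% coefficient
of variation (median-preserving, `meanlog = 0`). Intra-card replicate
variance is not published for real cards; 10% is a conventional qPCR
figure and is a configurable stand-in (`spot_cv`).

Non-healthy conditions are injected at the rates observed in the first
programme year (per child: SCID 3/115,216; non-SCID T cell lymphopenia
18/115,216; low-TREC false positives 52/115,786; technical failures
27/115,786), with analyte profiles taken from the published per-case table:

* **SCID** — TREC below 1 copy/well on every spot; KREC split by genotype
  (ADA-like cases also lose B cells, KREC ≈ 1; JAK3-like cases keep normal
  KREC ≈ 125); CD3+ T cells far below the lymphopenia threshold.
* **Non-SCID T cell lymphopenia** — TREC drawn in 0–6 copies/well
  (the printed case range), CD3 < 2 × 10⁹ cells/L.
* **False positive** — TREC in 0–6.4 copies/well (the printed
  false-positive range) with normal CD3 ≥ 2 × 10⁹ cells/L.
* **Technical failure** — ACTB below 1000 copies/well on every spot, with
  *healthy underlying* TREC/KREC (the failure is in sample collection, not
  biology).

Non-newborns (screened between one month and two years) draw from separate
reference distributions, most prominently a right-shifted KREC
(median 180, IQR 126–258). Age trends *within* the non-newborn group are
not modelled; the source data describe them only qualitatively. Sampling
age is lognormal (median 57.1 h, quartile ratio 73.0/49.9), truncated at
24 h.

What passing tests on this cohort do **not** show: real screening data have
heavier and more structured tails (sick preterm neonates, TPN, transfusion,
seasonal batch effects), and the real preterm low tail is dominated by
zero-TREC cards in a way the case-injection model only approximates. The
generator is a calibration target and a test harness, not a population
model.

## The measurement model

### Standard curves and quantification

Quantification inverts a 5-point standard curve (TREC/KREC 10–10⁵,
ACTB 10²–10⁶ copies/well), fit by ordinary least squares of Ct on
log₁₀ copies — the kit's own fitting procedure is proprietary, and OLS is
the standard choice. Efficiency derives from the slope,
$E = 10^{-1/\mathrm{slope}} - 1$. The forward model is the exact inverse
(Ct = intercept + slope·log₁₀ truth + Gaussian Ct noise), so at zero noise
quantification round-trips truths to six significant digits across
1–10⁶ copies/well — a property the tests enforce.

Detection near the analytical limits is a step model: truths below the
limit of blank (TREC 0.32, KREC 0.38 copies/well) never amplify; truths
between the limit of blank and the limit of detection (TREC 3.41,
KREC 3.13) amplify with probability 0.5 (configurable, `p_mid`); truths
above always amplify. Only the limits themselves are published; the step
probabilities are a deliberate simplification of a smooth hit-rate curve.
"No amplification" quantifies as 0 copies/well.

Plate acceptance mirrors routine qPCR QC: every curve needs r² ≥ 0.98 and
efficiency within 90–110%, the three internal DBS controls must reproduce
their low/high patterns (low ≤ 6, high ≥ 15 copies/well, i.e. on the
correct sides of the decision cut-offs), and the blank must not amplify.
The kit's true acceptance rules are unpublished, so all thresholds are
parameters.

### Amplification failure

A punch whose measured ACTB falls below the quality minimum carries too
little DNA for *any* analyte to amplify reliably, so the programme-level
measurement layer reads TREC and KREC on such punches as 0. This is what
makes the inconclusive branch reachable: a collection-failure card shows
uniformly low TREC *and* low ACTB and triggers a new-card request rather
than a referral. In `"truth"` mode (the default) measurement is otherwise
deterministic — spot truths censored at the limit of blank — which keeps
the decision path exactly reproducible; `"plate"` mode routes every
reanalysed card through the qPCR forward model instead.

## The decision algorithm

Per card, with all concentrations in copies/well:

1. **Quality gate** — acceptable amplification profile and
   ACTB ≥ 1000; failures go to full reanalysis.
2. **Triage** — initial TREC above the reanalysis cut-off: directly
   negative. The reanalysis cut-off is epoch-dependent: 15 until
   31 March 2020, 10 from 1 April 2020 (the card's laboratory arrival date
   decides). Between referral and reanalysis cut-offs: duplicate
   reanalysis from different spots. At or below the referral cut-off
   (TREC ≤ 6, inclusive at exactly 6.0): quadruplicate, or all spots where
   fewer than four are available.
3. **Consensus** — the referral decision uses the mean TREC over all
   replicate PCRs of the card. We read "all replicates" as the initial PCR
   plus the reanalysis punches. Under extreme variability, individual
   replicates with particularly low TREC are excluded: concretely, the
   retained minimum is dropped (iteratively) while the retained max/min
   ratio exceeds 10 *and* the remaining mean lies above the referral
   cut-off. The published description is qualitative; this rule is one
   admissible quantitative reading, and the ratio is configurable. The
   second condition encodes the stated rationale — SCID cards yield
   uniformly low replicates — and makes it a theorem that a card with every
   replicate below 1 copy/well and sufficient ACTB is referred under
   *every* policy configuration (the tests sweep this exhaustively).
4. **Verdicts** — mean ≤ 6: positive referral. All replicates below 6 with
   all ACTB below 1000: inconclusive, one new card is requested
   (non-responders become lost to follow-up; the response probability
   defaults to the observed 20/27). Otherwise negative after reanalysis.
   KREC is carried and reported with referrals but never enters the
   decision. An optional clinician-discretion margin above 6 exists and
   defaults to off.

Lowering the reanalysis cut-off from 15 to 10 cannot change any referral
verdict — it only removes cards from the reanalysis workload — because a
card that is directly negative at either cut-off has initial TREC > 10 > 6,
and identical replicates then yield a consensus mean above the referral
cut-off. The tests verify this on a 0–20 grid in 0.1 steps at both epochs.

## Performance statistics

Proportions (PPV, NPV, sensitivity, specificity, rates) carry Wilson score
intervals; the score bounds are exact 0/1 at the boundary outcomes. Exact
enumeration shows the score interval's well-known coverage oscillation:
for $n \le 30$ the exact coverage at $p = k/n$ dips to 0.875
(at $n = 4, k = 2$) though its mean stays near nominal — the package
documents this rather than papering over it, and cross-checks the interval
against `stats::prop.test(correct = FALSE)`.

Incidence uses the exact Poisson interval via the chi-squared relation
(bounds $\tfrac12\chi^2_{\alpha/2, 2k}$ and
$\tfrac12\chi^2_{1-\alpha/2, 2k+2}$ over the denominator; newborns only in
the denominator), cross-checked against `stats::poisson.test()`:

```{r}
exact_poisson_ci(3, 115216)
```

Confusion tables define TN as screening-negative children minus
outcome-positive cases, excluding the children without a final outcome
(lost to follow-up and opt-outs), which reproduces the published negative
count of 115,704. One known discrepancy is recorded rather than resolved:
the published specificity cells (99.937 / 99.953) do not equal
TN/(TN+FP) under any natural reading of the printed counts (which give
99.940 / 99.955); the package reports its documented formula and treats
the two-decimal PPV/sensitivity/NPV cells as the comparison surface.

The post hoc cut-off sweep recomputes referred counts, TPs, PPVs and SCID
sensitivity over candidate referral cut-offs among the actually referred
children (counts are non-decreasing in the cut-off by construction). The
matched-percentile device maps a term-population cut-off onto the preterm
distribution through the left-continuous inverse empirical CDF (type-1
quantile), flagging collapse into the undetectable range (< 1 copy/well).
On real data this collapse lands exactly at 0; in simulation it depends on
the injected-case tail, so the tests assert the robust version (the
matched cut-off falls deep into the case-driven lower tail) plus an exact
collapse check on a zero-inflated example.

## Numerical choices and problem sizes

* Percentages are reported from unrounded fractions; rounding happens only
  in display.
* Referral comparison at the cut-off is inclusive (≤ 6.0); so is the
  candidate-cut-off comparison in sweeps.
* Replicate exclusion breaks ties by index (the first minimum); with a
  zero minimum and a positive maximum the ratio is treated as infinite,
  and an all-zero card excludes nothing.
* Calibration tests simulate 50,000-child cohorts (20 seeds) for the
  population median and one 150,000-child cohort for per-stratum bootstrap
  recovery; these sizes put Monte-Carlo error well inside the asserted
  bands while keeping the default test run in tens of seconds.
* Cohort generation is vectorised; only the ~1% of cards needing
  reanalysis pass through the per-card state machine.

## Limitations

* The generator does not model seasonality, maternal immunosuppression,
  transfusion, vaccination, or within-non-newborn age trends.
* The outlier-exclusion rule and the plate-acceptance thresholds are
  explicit interpretations of qualitative descriptions; both are
  configurable and all conclusions that depend on them are property-tested
  across settings.
* Epoch-dependent reanalysis *rates* (1.55% / 0.68%) depend on the real
  per-sample TREC distribution near the cut-offs and on real amplification
  QC failures; the simulation reports its own rates but they are not a
  reproduction of the published ones.
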