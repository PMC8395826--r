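test_that("Wilson intervals reproduce the programme's printed CIs", {
  # PPV for SCID: 3 of 73 referrals
  ci <- wilson_ci(3, 73)
  expect_equal(ci$estimate, 3 / 73, tolerance = 1e-12)
  expect_equal(round(100 * ci$lower, 2), 1.41)
  expect_equal(round(100 * ci$upper, 2), 11.40)
  # sensitivity 3/3
  ci2 <- wilson_ci(3, 3)
  expect_equal(round(100 * ci2$lower, 2), 43.85)
  expect_equal(ci2$upper, 1)
  # PPV for lymphopenia: 21 of 73
  ci3 <- wilson_ci(21, 73)
  expect_equal(round(100 * ci3$lower, 2), 19.65)
  expect_equal(round(100 * ci3$upper, 2), 40.01)
  # boundary behaviour
  expect_equal(wilson_ci(0, 10)$lower, 0)
  expect_equal(wilson_ci(10, 10)$upper, 1)
  expect_error(wilson_ci(3, 0), "positive")
  expect_error(wilson_ci(5, 3), "0 <= k <= n")
})

test_that("Wilson interval matches the score-test inversion in prop.test", {
  # independent oracle: prop.test without continuity correction inverts the
  # same score test
  for (kn in list(c(3, 73), c(21, 73), c(18, 53), c(1, 115216), c(7, 12))) {
    ci <- wilson_ci(kn[1], kn[2])
    ref <- prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(ci$lower, ref[1], tolerance = 1e-9)
    expect_equal(ci$upper, ref[2], tolerance = 1e-9)
  }
  # symmetry in the complement
  ci <- wilson_ci(5, 19)
  cc <- wilson_ci(14, 19)
  expect_equal(ci$lower, 1 - cc$upper, tolerance = 1e-12)
  expect_equal(ci$upper, 1 - cc$lower, tolerance = 1e-12)
})

test_that("Wilson coverage is near-nominal for all n up to 30", {
  # exact (enumerated) coverage of the true proportion p = k/n; the score
  # interval's coverage oscillates around the nominal level, with a known
  # worst case of 1 - 2/16 = 0.875 at n = 4, p = 1/2
  covs <- numeric(0)
  for (n in c(4, 5, 10, 17, 30)) {
    x <- 0:n
    bounds <- vapply(x, function(xx) {
      ci <- wilson_ci(xx, n)
      c(ci$lower, ci$upper)
    }, numeric(2))
    for (k in 0:n) {
      p <- k / n
      covs <- c(covs, sum(dbinom(x, n, p) *
                            (bounds[1, ] <= p & p <= bounds[2, ])))
    }
  }
  expect_true(all(covs >= 0.875))
  expect_gte(mean(covs), 0.94)
  # degenerate truths p = 0 and p = 1 are always covered: the score bounds
  # reach the boundary exactly
  x <- 0:10
  b <- vapply(x, function(xx) {
    ci <- wilson_ci(xx, 10)
    c(ci$lower, ci$upper)
  }, numeric(2))
  expect_equal(sum(dbinom(x, 10, 0) * (b[1, ] <= 0 & 0 <= b[2, ])), 1)
  expect_equal(sum(dbinom(x, 10, 1) * (b[1, ] <= 1 & 1 <= b[2, ])), 1)
})

test_that("exact Poisson incidence matches the chi-squared oracle", {
  inc <- exact_poisson_ci(3, 115216)
  expect_equal(inc$one_in, 115216 / 3, tolerance = 1e-12)     # 1 in 38,405
  expect_equal(round(inc$one_in), 38405)
  expect_equal(inc$lower, qchisq(0.025, 6) / 2 / 115216, tolerance = 1e-12)
  expect_equal(inc$upper, qchisq(0.975, 8) / 2 / 115216, tolerance = 1e-12)
  expect_equal(round(inc$one_in_lower), 186231)
  expect_equal(round(inc$one_in_upper), 13142)
  # independent oracle: poisson.test inverts the same exact relation
  ref <- poisson.test(3, 115216)$conf.int
  expect_equal(c(inc$lower, inc$upper), as.numeric(ref), tolerance = 1e-9)
  # zero cases: lower bound collapses to 0
  inc0 <- exact_poisson_ci(0, 1000)
  expect_equal(inc0$lower, 0)
  expect_equal(inc0$upper, qchisq(0.975, 2) / 2 / 1000, tolerance = 1e-12)
  # identity denominator
  expect_equal(exact_poisson_ci(1, 1)$rate, 1)
  expect_error(exact_poisson_ci(-1, 10), "invalid input")
})

test_that("confusion metrics reproduce the first-year performance table", {
  scid <- confusion_table(tp = 3, fp = 70, tn = 115704, fn = 0,
                          outcome = "SCID", n_excluded = 9)
  expect_equal(scid$n_total, 115786)
  m <- confusion_metrics(scid)
  get <- function(mm) m[m$metric == mm, ]
  expect_equal(get("ppv")$estimate, 3 / 73, tolerance = 1e-12)
  expect_equal(round(100 * get("ppv")$estimate, 2), 4.11)
  expect_equal(get("sensitivity")$estimate, 1)
  expect_equal(round(100 * get("sensitivity")$lower, 2), 43.85)
  expect_equal(get("npv")$estimate, 1)
  expect_equal(round(100 * get("npv")$lower, 2), 100)
  expect_equal(round(100 * get("specificity")$estimate, 2), 99.94)

  lymph <- confusion_table(tp = 21, fp = 52, tn = 115704, fn = 0,
                           outcome = "T_cell_lymphopenia", n_excluded = 9)
  ml <- confusion_metrics(lymph)
  expect_equal(round(100 * ml[ml$metric == "ppv", "estimate"], 2), 28.77)
  expect_equal(round(100 * ml[ml$metric == "ppv", "lower"], 2), 19.65)
  expect_equal(round(100 * ml[ml$metric == "ppv", "upper"], 2), 40.01)

  # degenerate: a perfect test
  perf <- confusion_metrics(confusion_table(5, 0, 100, 0))
  expect_true(all(perf$estimate == 1))
  # undefined metrics are NA, not errors
  und <- confusion_metrics(confusion_table(0, 0, 100, 0))
  expect_true(is.na(und[und$metric == "ppv", "estimate"]))
  expect_error(confusion_table(-1, 0, 0, 0), "non-negative")
})

test_that("referral rates from printed counts match the reported percentages", {
  r <- first_year_report()$rates
  get <- function(s) r$pct[r$stratum == s]
  expect_equal(round(get("overall"), 3), 0.063)
  expect_equal(round(get("preterm"), 2), 0.52)
  expect_equal(round(get("term"), 2), 0.03)
  expect_equal(round(get("non_newborn"), 2), 0.88)
  expect_equal(round(get("undetectable_trec"), 3), 0.016)
  expect_equal(round(get("repeat_card"), 3), 0.023)
})

test_that("referral_rates stratifies a simulated run correctly", {
  coh <- small_cohort(n = 1500, seed = 121, cases = c(SCID = 0.01))
  run <- run_programme(coh, seed = 2)
  rr <- referral_rates(run$outcomes, coh)
  overall <- rr[rr$stratum == "overall", ]
  expect_equal(overall$referred, run$log$n_referred)
  expect_equal(overall$rate, run$log$referral_rate)
  # strata partition the newborn cohort
  expect_equal(rr$n[rr$stratum == "term"] + rr$n[rr$stratum == "preterm"],
               1500 - sum(is.na(coh$ga_weeks[!duplicated(coh$child_id)])))
  # zero referrals give rate zero, empty stratum gives NA
  healthy <- small_cohort(n = 50, seed = 122)
  run0 <- run_programme(healthy, seed = 2)
  rr0 <- referral_rates(run0$outcomes, healthy)
  expect_equal(rr0$rate[rr0$stratum == "overall"], 0)
  expect_true(is.na(rr0$rate[rr0$stratum == "non_newborn"]))
})

test_that("cut-off sweep on first-year referrals reproduces the post hoc analysis", {
  # reconstruct the 73 referred children from printed aggregates: at a
  # cut-off of 4, 53 remain (3 SCID TP, 18 lymphopenia TP)
  c4 <- first_year_counts()$cutoff4
  referred <- data.frame(
    mean_trec = c(rep(0, 3),                                  # SCID cases
                  rep(2, c4$tp_lymphopenia - 3),              # lymphopenia kept at 4
                  rep(5, 21 - c4$tp_lymphopenia),             # lymphopenia lost at 4
                  rep(2, c4$referred - c4$tp_lymphopenia),    # FP kept at 4
                  rep(5, (73 - 21) - (c4$referred - c4$tp_lymphopenia))),
    scid = c(rep(TRUE, 3), rep(FALSE, 70)),
    lymphopenia = c(rep(TRUE, 21), rep(FALSE, 52)))
  sw <- cutoff_sweep(referred, cutoffs = c(6, 4))
  r6 <- sw[sw$cutoff == 6, ]
  expect_equal(r6$referred_total, 73)
  expect_equal(round(100 * r6$ppv_scid, 2), 4.11)
  expect_equal(round(100 * r6$ppv_lymphopenia, 2), 28.77)
  r4 <- sw[sw$cutoff == 4, ]
  expect_equal(r4$referred_total, 53)
  expect_equal(round(100 * r4$ppv_lymphopenia, 1), 34.0)
  expect_equal(round(100 * r4$ppv_lymphopenia_lower, 1), 22.7)
  expect_equal(round(100 * r4$ppv_lymphopenia_upper, 1), 47.4)
  expect_equal(r4$sensitivity_scid, 1)
})

test_that("sweep counts are monotone in the cut-off", {
  set.seed(131)
  referred <- data.frame(mean_trec = runif(80, 0, 6),
                         scid = runif(80) < 0.1,
                         lymphopenia = runif(80) < 0.3,
                         preterm = runif(80) < 0.4)
  referred$lymphopenia <- referred$lymphopenia | referred$scid
  sw <- cutoff_sweep(referred, cutoffs = seq(0, 6, by = 0.25))
  o <- order(sw$cutoff)
  expect_true(all(diff(sw$referred_total[o]) >= 0))
  expect_true(all(diff(sw$referred_total[o] - sw$tp_lymphopenia[o]) >= 0))
  expect_true(all(diff(sw$sensitivity_scid[o]) >= 0))
  expect_true(all(sw$referred_term + sw$referred_preterm ==
                    sw$referred_total))
})

test_that("percentile equivalence matches quantiles across populations", {
  set.seed(141)
  term <- rlnorm(1e5, log(80), 0.5)
  # identical distributions return the cut-off itself
  pe <- percentile_equivalence(term, term, term_cutoff = sort(term)[50])
  expect_equal(pe$matched_cutoff, sort(term)[50])
  # a population scaled down by a constant factor scales the cut-off
  pe2 <- percentile_equivalence(term, term / 4, term_cutoff = sort(term)[50])
  expect_equal(pe2$matched_cutoff, sort(term)[50] / 4, tolerance = 1e-12)
  expect_error(percentile_equivalence(numeric(0), term, 4), "non-empty")
})

test_that("term-equivalent preterm cut-off lands in the extreme lower tail", {
  # a cut-off of 4 copies/well is a rare event among term newborns; the
  # matched percentile in the preterm population maps deep into its
  # case-and-censoring-driven lower tail, far below the preterm bulk
  # (median ~69 copies/well)
  coh <- simulate_cohort(cohort_config(n_newborns = 100000,
                                       n_non_newborns = 0,
                                       spots_per_child = 1L, seed = 151))
  lim <- analytical_limits()
  child <- coh[!duplicated(coh$child_id), ]
  child$measured <- ifelse(child$trec < lim$lob_trec, 0, child$trec)
  term <- child$measured[!is.na(child$ga_weeks) & child$ga_weeks >= 37]
  pre <- child$measured[!is.na(child$ga_weeks) & child$ga_weeks < 37]
  pe <- percentile_equivalence(term, pre, term_cutoff = 4)
  expect_lt(pe$percentile, 0.002)   # a rare event among term newborns
  expect_lt(pe$matched_cutoff, 10)
  # when the low tail is dominated by undetectable (censored-to-zero) cards,
  # the matched cut-off collapses to zero and is flagged
  pre0 <- c(rep(0, 50), rlnorm(5000, log(69), 0.55))
  pe0 <- percentile_equivalence(term, pre0, term_cutoff = 4)
  expect_true(pe0$collapsed)
  expect_equal(pe0$matched_cutoff, 0)
})

test_that("distribution summaries report median, IQR and tail shares", {
  s <- summarise_distribution(c(5, 5, 5))
  expect_equal(s$median, 5)
  expect_equal(s$q1, 5)
  expect_equal(s$q3, 5)
  coh <- stratum_cohort("22-24", 20000, seed = 161)
  s2 <- summarise_distribution(per_child_mean(coh))
  expect_equal(s2$median, 25, tolerance = 0.05)
  # stratified summaries drop NA strata
  vals <- c(1, 2, 3, 4)
  by <- c("a", "a", NA, "b")
  s3 <- summarise_distribution(vals, by)
  expect_equal(sort(s3$stratum), c("a", "b"))
  expect_equal(sum(s3$n), 3)
  expect_error(summarise_distribution(numeric(0)), "non-empty")
})

test_that("a full simulated-population TREC summary matches the reference shape", {
  coh <- simulate_cohort(cohort_config(n_newborns = 50000, n_non_newborns = 0,
                                       spots_per_child = 1L, seed = 171))
  s <- summarise_distribution(per_child_mean(coh))
  expect_equal(s$median, 79, tolerance = 0.03)
  expect_equal(s$q1, 55, tolerance = 0.05)
  expect_equal(s$q3, 110, tolerance = 0.05)
})

test_that("end-to-end evaluation recovers injected case rates", {
  rates <- c(SCID = 0.004, lymphopenia_non_SCID = 0.008, FP_low_trec = 0.008,
             technical_failure = 0.002)
  coh <- simulate_cohort(cohort_config(n_newborns = 8000, n_non_newborns = 0,
                                       case_rates = rates, seed = 181))
  run <- run_programme(coh, seed = 19)
  perf <- evaluate_performance(run, coh)
  scid <- perf$confusion$SCID
  # all SCID cases detected
  expect_equal(scid$fn, 0)
  n_scid <- sum(coh$condition[!duplicated(coh$child_id)] == "SCID")
  expect_equal(scid$tp, n_scid)
  # configured PPV: SCID / (SCID + lymphopenia + referred FPs); most FP and
  # lymphopenia truths fall below the cut-off, so PPV_scid is roughly
  # 0.004 / 0.02 = 0.2; allow generous Monte-Carlo slack
  ppv <- perf$metrics[perf$metrics$outcome == "SCID" &
                        perf$metrics$metric == "ppv", "estimate"]
  expect_gt(ppv, 0.1)
  expect_lt(ppv, 0.4)
  expect_equal(perf$incidence$cases, n_scid)
})
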