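#' Wilson score confidence interval for a binomial proportion
#'
#' The score-test inversion interval: with `z` the normal quantile at
#' `(1 + level)/2` and `p = k/n`,
#' `centre = (p + z^2/2n) / (1 + z^2/n)` and half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Unlike the Wald interval it
#' behaves at the boundaries (`k = 0` gives a lower bound of exactly 0,
#' `k = n` an upper bound of exactly 1) and is the interval used for all
#' proportion summaries in this package.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @return An object of class `proportion_ci`: `estimate`, `lower`, `upper`,
#'   `level`, `method = "wilson"`, `k`, `n`.
#' @examples
#' wilson_ci(3, 73)   # PPV of 3 true positives among 73 referrals
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (length(n) != 1 || is.na(n) || n <= 0) {
    stop("invalid input: n must be a positive count", call. = FALSE)
  }
  if (k < 0 || k > n) {
    stop("invalid input: need 0 <= k <= n", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the score bounds are exactly 0 at k = 0 and 1 at k = n; enforce despite
  # floating-point cancellation in centre - half
  lower <- if (k == 0) 0 else max(0, centre - half)
  upper <- if (k == n) 1 else min(1, centre + half)
  structure(list(estimate = p, lower = lower, upper = upper, level = level,
                 method = "wilson", k = k, n = n),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%g/%g = %.*f, %g%% CI (%s) [%.*f, %.*f]\n",
              x$k, x$n, digits, x$estimate, 100 * x$level, x$method,
              digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Exact Poisson confidence interval for an incidence rate
#'
#' Treats the case count as Poisson and inverts via the chi-squared/gamma
#' relation: with `k` cases the rate bounds are
#' `qchisq(alpha/2, 2k)/2` and `qchisq(1 - alpha/2, 2k + 2)/2` divided by the
#' denominator; for `k = 0` the lower bound is 0. The point estimate is
#' `k/denominator`. Rates are also expressed in the "1 in N" form customary
#' for birth-prevalence reporting.
#'
#' @param cases Observed case count (>= 0).
#' @param denominator Population size (> 0), e.g. screened newborns.
#' @param level Confidence level, default 0.95.
#' @return An object of class `incidence_estimate`: `cases`, `denominator`,
#'   `rate`, `lower`, `upper` (rates), and `one_in`, `one_in_lower`,
#'   `one_in_upper` ("1 in N" denominators; `one_in_lower` is the larger N,
#'   i.e. the rarer bound).
#' @examples
#' exact_poisson_ci(3, 115216)  # SCID incidence, first screening year
#' @export
exact_poisson_ci <- function(cases, denominator, level = 0.95) {
  stopifnot(length(cases) == 1, length(denominator) == 1)
  if (cases < 0 || denominator <= 0) {
    stop("invalid input: cases >= 0 and denominator > 0 required",
         call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (cases == 0) 0 else stats::qchisq(alpha / 2, 2 * cases) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * cases + 2) / 2
  rate <- cases / denominator
  structure(list(cases = cases, denominator = denominator,
                 rate = rate, lower = lower / denominator,
                 upper = upper / denominator, level = level,
                 one_in = if (cases > 0) denominator / cases else Inf,
                 one_in_lower = if (lower > 0) denominator / lower else Inf,
                 one_in_upper = denominator / upper),
            class = "incidence_estimate")
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat(sprintf("%d cases / %s: 1 in %s (%g%% CI 1 in %s - 1 in %s)\n",
              x$cases, format(x$denominator, big.mark = ","),
              format(round(x$one_in), big.mark = ","), 100 * x$level,
              format(round(x$one_in_lower), big.mark = ","),
              format(round(x$one_in_upper), big.mark = ",")))
  invisible(x)
}

#' Confusion table for a screening outcome definition
#'
#' @param tp,fp,tn,fn Counts of true/false positives/negatives.
#' @param outcome Outcome definition the counts refer to (`"SCID"` or
#'   `"T_cell_lymphopenia"`).
#' @param n_excluded Children without a final outcome (documented
#'   exclusions, e.g. lost to follow-up), so that
#'   `tp + fp + tn + fn + n_excluded = n_total`.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn,
                            outcome = c("SCID", "T_cell_lymphopenia"),
                            n_excluded = 0L) {
  outcome <- match.arg(outcome)
  if (any(c(tp, fp, tn, fn, n_excluded) < 0)) {
    stop("invalid input: counts must be non-negative", call. = FALSE)
  }
  structure(list(outcome = outcome, tp = tp, fp = fp, tn = tn, fn = fn,
                 n_excluded = n_excluded,
                 n_total = tp + fp + tn + fn + n_excluded),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table (outcome: %s), n = %s\n", x$outcome,
              format(x$n_total, big.mark = ",")))
  cat(sprintf("  TP %d   FP %d   TN %s   FN %d   excluded %d\n",
              x$tp, x$fp, format(x$tn, big.mark = ","), x$fn, x$n_excluded))
  invisible(x)
}

#' Clinical-performance metrics with Wilson intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`, each with a
#' Wilson score interval. A metric whose denominator is zero is reported as
#' `NA` (undefined), not an error.
#'
#' @param table A [confusion_table()].
#' @param level Confidence level.
#' @return A data.frame with one row per metric: `metric`, `k`, `n`,
#'   `estimate`, `lower`, `upper` (fractions).
#' @examples
#' confusion_metrics(confusion_table(tp = 3, fp = 70, tn = 115704, fn = 0))
#' @export
confusion_metrics <- function(table, level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  defs <- list(sensitivity = c(table$tp, table$tp + table$fn),
               specificity = c(table$tn, table$tn + table$fp),
               ppv = c(table$tp, table$tp + table$fp),
               npv = c(table$tn, table$tn + table$fn))
  rows <- lapply(names(defs), function(m) {
    k <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) {
      data.frame(metric = m, k = k, n = n, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_, stringsAsFactors = FALSE)
    } else {
      ci <- wilson_ci(k, n, level)
      data.frame(metric = m, k = k, n = n, estimate = ci$estimate,
                 lower = ci$lower, upper = ci$upper, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Stratified referral rates of a screening run
#'
#' Referral rate (referred / stratum size) overall and for term newborns
#' (gestational age >= 37 weeks), preterm newborns (< 37 weeks),
#' non-newborns, plus the rate of cards with undetectable TREC
#' (mean TREC < 1 copy/well). An empty stratum yields an `NA` rate.
#'
#' @param outcomes Outcome data.frame of [run_programme()].
#' @param cohort The cohort the outcomes came from (for the strata).
#' @return A data.frame: `stratum`, `n`, `referred`, `rate` (fraction).
#' @export
referral_rates <- function(outcomes, cohort) {
  child <- cohort[!duplicated(cohort$child_id),
                  c("child_id", "ga_weeks", "is_newborn")]
  m <- merge(outcomes, child, by = "child_id", all.x = TRUE)
  referred <- m$status == "positive_referral"
  strata <- list(
    overall = rep(TRUE, nrow(m)),
    term = m$is_newborn & !is.na(m$ga_weeks) & m$ga_weeks >= 37,
    preterm = m$is_newborn & !is.na(m$ga_weeks) & m$ga_weeks < 37,
    non_newborn = !m$is_newborn
  )
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    data.frame(stratum = s, n = sum(sel), referred = sum(referred & sel),
               rate = if (sum(sel) > 0) sum(referred & sel) / sum(sel)
                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  undet <- m$mean_trec < 1
  rows <- c(rows, list(data.frame(stratum = "undetectable_trec", n = nrow(m),
                                  referred = sum(undet),
                                  rate = mean(undet),
                                  stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Post hoc referral cut-off sweep
#'
#' Recomputes, for each candidate referral cut-off, how many of the
#' *actually referred* children would still have been referred (mean TREC at
#' or below the candidate), the true positives retained for both outcome
#' definitions, the PPVs with Wilson intervals, and whether SCID sensitivity
#' would have been lost. Term/preterm stratified counts are included when a
#' `preterm` flag is supplied.
#'
#' @param referred A data.frame of referred children with columns
#'   `mean_trec`, `scid` (logical), `lymphopenia` (logical; includes the
#'   SCID cases), and optionally `preterm` (logical; `NA` for non-newborns).
#' @param cutoffs Candidate referral cut-offs (copies/well).
#' @param level Confidence level for the PPV intervals.
#' @return A data.frame with one row per cut-off: referred and TP counts
#'   (overall and by term/preterm), `ppv_scid`, `ppv_lymphopenia` with CI
#'   bounds, and `sensitivity_scid` (fraction of the input's SCID cases
#'   retained).
#' @export
cutoff_sweep <- function(referred, cutoffs = seq(6, 0, by = -0.5),
                         level = 0.95) {
  stopifnot(all(c("mean_trec", "scid", "lymphopenia") %in% names(referred)))
  has_strata <- "preterm" %in% names(referred)
  n_scid <- sum(referred$scid)
  rows <- lapply(cutoffs, function(cc) {
    inc <- referred$mean_trec <= cc
    tp_s <- sum(inc & referred$scid)
    tp_l <- sum(inc & referred$lymphopenia)
    n_ref <- sum(inc)
    ppv_s <- if (n_ref > 0) wilson_ci(tp_s, n_ref, level) else NULL
    ppv_l <- if (n_ref > 0) wilson_ci(tp_l, n_ref, level) else NULL
    out <- data.frame(
      cutoff = cc, referred_total = n_ref,
      tp_scid = tp_s, tp_lymphopenia = tp_l,
      ppv_scid = if (n_ref > 0) ppv_s$estimate else NA_real_,
      ppv_scid_lower = if (n_ref > 0) ppv_s$lower else NA_real_,
      ppv_scid_upper = if (n_ref > 0) ppv_s$upper else NA_real_,
      ppv_lymphopenia = if (n_ref > 0) ppv_l$estimate else NA_real_,
      ppv_lymphopenia_lower = if (n_ref > 0) ppv_l$lower else NA_real_,
      ppv_lymphopenia_upper = if (n_ref > 0) ppv_l$upper else NA_real_,
      sensitivity_scid = if (n_scid > 0) tp_s / n_scid else NA_real_,
      stringsAsFactors = FALSE
    )
    if (has_strata) {
      out$referred_term <- sum(inc & !referred$preterm, na.rm = TRUE)
      out$referred_preterm <- sum(inc & referred$preterm, na.rm = TRUE)
      out$tp_term <- sum(inc & referred$lymphopenia & !referred$preterm,
                         na.rm = TRUE)
      out$tp_preterm <- sum(inc & referred$lymphopenia & referred$preterm,
                            na.rm = TRUE)
    }
    out
  })
  do.call(rbind, rows)
}

#' Matched-percentile cut-off between two populations
#'
#' Finds the cut-off in a second population (e.g. preterm newborns) that
#' sits at the same cumulative probability as a given cut-off in a first
#' population (e.g. term newborns). Uses the left-continuous inverse of the
#' empirical distribution function (type-1 quantile), so the result is
#' always an observed value; with heavy mass at 0 it collapses to
#' (effectively) zero, which the result flags.
#'
#' @param term_trecs,preterm_trecs Non-empty numeric vectors of per-child
#'   mean TREC copies/well.
#' @param term_cutoff Cut-off (copies/well) applied to the first population.
#' @return A list: `percentile` (cumulative probability of `term_cutoff` in
#'   the first population), `matched_cutoff` (the second population's
#'   quantile at that probability), and `collapsed` (`TRUE` when the matched
#'   cut-off falls below 1 copy/well, i.e. only children with undetectable
#'   TREC would be referred).
#' @export
percentile_equivalence <- function(term_trecs, preterm_trecs, term_cutoff) {
  if (length(term_trecs) == 0 || length(preterm_trecs) == 0) {
    stop("invalid input: both populations must be non-empty", call. = FALSE)
  }
  p <- mean(term_trecs <= term_cutoff)
  q <- unname(stats::quantile(preterm_trecs, probs = p, type = 1))
  list(percentile = p, matched_cutoff = q, collapsed = q < 1)
}

#' Median, quartiles, and density summary of analyte values
#'
#' @param values Numeric vector of copies/well.
#' @param by Optional stratification factor (e.g. gestational-age stratum);
#'   `NA` strata are dropped.
#' @param cap Display cap (copies/well); the share of values above it is
#'   reported, mirroring density plots truncated at 400 copies/well.
#' @return A data.frame: `stratum`, `n`, `median`, `q1`, `q3`, `p95`,
#'   `share_above_cap`.
#' @export
summarise_distribution <- function(values, by = NULL, cap = 400) {
  if (length(values) == 0) {
    stop("invalid input: values must be non-empty", call. = FALSE)
  }
  one <- function(v, label) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(stratum = label, n = length(v), median = q[2], q1 = q[1],
               q3 = q[3], p95 = q[4], share_above_cap = mean(v > cap),
               stringsAsFactors = FALSE)
  }
  if (is.null(by)) {
    return(one(values, "all"))
  }
  keep <- !is.na(by)
  groups <- split(values[keep], by[keep])
  do.call(rbind, lapply(names(groups), function(g) one(groups[[g]], g)))
}

#' Evaluate a screening run against the cohort truth
#'
#' Joins outcomes to the cohort's condition labels and builds confusion
#' tables and metrics for both outcome definitions (SCID; T cell
#' lymphopenia, which includes the SCID cases), stratified referral rates,
#' and the SCID incidence among newborns. Children without a final outcome
#' (lost to follow-up or still inconclusive) are excluded from the negative
#' counts, and their number is carried in the tables' `n_excluded`.
#'
#' @param run A [run_programme()] result (or its `outcomes` data.frame).
#' @param cohort The cohort screened.
#' @param level Confidence level.
#' @return A list of class `performance_report`: `confusion` (both tables),
#'   `metrics` (data.frame, both outcomes), `rates` ([referral_rates()]),
#'   `incidence` ([exact_poisson_ci()]), `referred` (per-child data.frame
#'   ready for [cutoff_sweep()]).
#' @export
evaluate_performance <- function(run, cohort, level = 0.95) {
  outcomes <- if (inherits(run, "screening_run")) run$outcomes else run
  child <- cohort[!duplicated(cohort$child_id),
                  c("child_id", "condition", "ga_weeks", "is_newborn")]
  m <- merge(outcomes, child, by = "child_id")
  referred <- m$status == "positive_referral"
  no_final <- m$status %in% c("inconclusive_new_card", "lost_to_followup")
  is_scid <- m$condition == "SCID"
  is_lymph <- m$condition %in% c("SCID", "lymphopenia_non_SCID")

  tab <- function(pos, outcome) {
    confusion_table(tp = sum(referred & pos),
                    fp = sum(referred & !pos),
                    tn = sum(!referred & !no_final & !pos),
                    fn = sum(!referred & !no_final & pos),
                    outcome = outcome, n_excluded = sum(no_final))
  }
  conf <- list(SCID = tab(is_scid, "SCID"),
               T_cell_lymphopenia = tab(is_lymph, "T_cell_lymphopenia"))
  metrics <- do.call(rbind, lapply(names(conf), function(o) {
    cbind(outcome = o, confusion_metrics(conf[[o]], level))
  }))
  referred_df <- data.frame(child_id = m$child_id[referred],
                            mean_trec = m$mean_trec[referred],
                            scid = is_scid[referred],
                            lymphopenia = is_lymph[referred],
                            preterm = ifelse(m$is_newborn[referred],
                                             m$ga_weeks[referred] < 37, NA),
                            stringsAsFactors = FALSE)
  structure(list(
    confusion = conf, metrics = metrics,
    rates = referral_rates(outcomes, cohort),
    incidence = exact_poisson_ci(sum(referred & is_scid & m$is_newborn),
                                 sum(m$is_newborn), level),
    referred = referred_df
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  for (tb in x$confusion) print(tb)
  cat("\nMetrics (fractions):\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat("\nReferral rates:\n")
  print(x$rates, row.names = FALSE, digits = 3)
  cat("\nSCID incidence: ")
  print(x$incidence)
  invisible(x)
}
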