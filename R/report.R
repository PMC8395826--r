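#' Clinical-performance report from the programme's published counts
#'
#' Pure-arithmetic reporting path: takes the aggregate counts of the first
#' national screening year ([first_year_counts()]) and reproduces the
#' programme's clinical-performance statistics without any simulation or
#' random number generation — confusion tables and metrics for both outcome
#' definitions, stratified referral rates, the SCID incidence with its exact
#' Poisson interval, and the post hoc cut-off analysis at 4 copies/well.
#'
#' For the outcome SCID there were 3 true positives among 73 referrals and
#' no known missed case; the negative count (115,704) excludes the 9
#' children without a final screening outcome (7 lost to follow-up after an
#' inconclusive card, 2 opt-outs).
#'
#' @param counts A counts list in the shape of [first_year_counts()].
#' @param level Confidence level.
#' @return A list of class `counts_report`: `confusion`, `metrics` (with
#'   percentage columns), `rates` (percentages), `incidence`, `sweep`
#'   (the cut-off-4 row), `counts`.
#' @examples
#' rep <- first_year_report()
#' subset(rep$metrics, metric == "ppv")
#' @export
first_year_report <- function(counts = first_year_counts(), level = 0.95) {
  conf <- list(
    SCID = confusion_table(
      tp = counts$tp_scid, fp = counts$n_referred - counts$tp_scid,
      tn = counts$n_negative, fn = 0L, outcome = "SCID",
      n_excluded = counts$n_screened - counts$n_negative - counts$n_referred),
    T_cell_lymphopenia = confusion_table(
      tp = counts$tp_lymphopenia,
      fp = counts$n_referred - counts$tp_lymphopenia,
      tn = counts$n_negative, fn = 0L, outcome = "T_cell_lymphopenia",
      n_excluded = counts$n_screened - counts$n_negative - counts$n_referred)
  )
  metrics <- do.call(rbind, lapply(names(conf), function(o) {
    cbind(outcome = o, confusion_metrics(conf[[o]], level))
  }))
  metrics$pct <- 100 * metrics$estimate
  metrics$pct_lower <- 100 * metrics$lower
  metrics$pct_upper <- 100 * metrics$upper

  rates <- data.frame(
    stratum = c("overall", "term", "preterm", "non_newborn",
                "undetectable_trec", "repeat_card"),
    referred = c(counts$n_referred, counts$referred_term,
                 counts$referred_preterm, counts$referred_non_newborn,
                 counts$n_undetectable, counts$n_repeat_cards),
    n = c(counts$n_screened, counts$n_term, counts$n_preterm,
          counts$n_non_newborns, counts$n_screened, counts$n_screened),
    stringsAsFactors = FALSE
  )
  rates$rate <- rates$referred / rates$n
  rates$pct <- 100 * rates$rate

  c4 <- counts$cutoff4
  ppv_s <- wilson_ci(c4$tp_scid, c4$referred, level)
  ppv_l <- wilson_ci(c4$tp_lymphopenia, c4$referred, level)
  sweep <- data.frame(
    cutoff = 4, referred_total = c4$referred,
    tp_scid = c4$tp_scid, tp_lymphopenia = c4$tp_lymphopenia,
    ppv_scid = ppv_s$estimate, ppv_scid_lower = ppv_s$lower,
    ppv_scid_upper = ppv_s$upper,
    ppv_lymphopenia = ppv_l$estimate,
    ppv_lymphopenia_lower = ppv_l$lower,
    ppv_lymphopenia_upper = ppv_l$upper,
    sensitivity_scid = c4$tp_scid / counts$tp_scid,
    stringsAsFactors = FALSE
  )

  structure(list(
    confusion = conf, metrics = metrics, rates = rates,
    incidence = exact_poisson_ci(counts$tp_scid, counts$n_newborns, level),
    sweep = sweep, counts = counts
  ), class = "counts_report")
}

#' @export
print.counts_report <- function(x, ...) {
  cat("Screening performance from published first-year counts\n\n")
  m <- x$metrics
  for (o in unique(m$outcome)) {
    cat(sprintf("Outcome %s:\n", o))
    mo <- m[m$outcome == o, ]
    for (i in seq_len(nrow(mo))) {
      if (is.na(mo$estimate[i])) next
      cat(sprintf("  %-12s %6.2f%% (%.2f-%.2f)\n", mo$metric[i], mo$pct[i],
                  mo$pct_lower[i], mo$pct_upper[i]))
    }
  }
  cat("\nReferral rates (%):\n")
  print(x$rates[, c("stratum", "referred", "n", "pct")], row.names = FALSE,
        digits = 3)
  cat("\nSCID incidence: ")
  print(x$incidence)
  s <- x$sweep
  cat(sprintf("\nAt referral cut-off %g copies/well: %d referred, PPV(lymphopenia) %.1f%% (%.1f-%.1f), SCID sensitivity retained %.0f%%\n",
              s$cutoff, s$referred_total, 100 * s$ppv_lymphopenia,
              100 * s$ppv_lymphopenia_lower, 100 * s$ppv_lymphopenia_upper,
              100 * s$sensitivity_scid))
  invisible(x)
}
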