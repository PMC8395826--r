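#' Gestational-age-stratified TREC/KREC reference distributions
#'
#' Published reference summary of the Swedish national screening population
#' (first programme year, 115,189 newborns with known gestational age),
#' subdivided into 3-week gestational-age blocks from week 22. For each
#' stratum the table carries the number of newborns and the median and
#' quartiles of TREC and KREC copies/well. These summaries are what the
#' synthetic-cohort generator is calibrated against: stratum sizes give the
#' default gestational-age mixture and median/IQR give the per-stratum
#' lognormal parameters (see [lognormal_from_median_iqr()]).
#'
#' @return A data.frame with one row per gestational-age stratum: `label`,
#'   `week_lo`, `week_hi`, `n_reference`, `trec_median`, `trec_q1`, `trec_q3`,
#'   `krec_median`, `krec_q1`, `krec_q3`, and `proportion` (stratum share of
#'   the reference population).
#' @export
ga_reference_strata <- function() {
  x <- data.frame(
    label       = c("22-24", "25-27", "28-30", "31-33", "34-36", "37-39", "40-43"),
    week_lo     = c(22L, 25L, 28L, 31L, 34L, 37L, 40L),
    week_hi     = c(24L, 27L, 30L, 33L, 36L, 39L, 43L),
    n_reference = c(109L, 232L, 430L, 1088L, 4819L, 52839L, 55672L),
    trec_median = c(25, 41, 56, 67, 69, 78, 81),
    trec_q1     = c(14, 25, 36, 44, 47, 55, 56),
    trec_q3     = c(47, 60, 86, 96, 98, 108, 112),
    krec_median = c(49, 47, 46, 50, 50, 53, 49),
    krec_q1     = c(29, 29, 28, 31, 32, 35, 33),
    krec_q3     = c(85, 74, 66, 77, 73, 78, 72),
    stringsAsFactors = FALSE
  )
  stopifnot(all(x$trec_q1 <= x$trec_median), all(x$trec_median <= x$trec_q3),
            all(x$krec_q1 <= x$krec_median), all(x$krec_median <= x$krec_q3))
  x$proportion <- x$n_reference / sum(x$n_reference)
  x
}

#' Reference TREC/KREC distributions for screened non-newborns
#'
#' Children screened between one month and two years of age (immigrant
#' screening) show a right-shifted, wider KREC distribution and a slightly
#' higher TREC median than term newborns. Summaries are medians and IQRs in
#' copies/well.
#'
#' @return A list with `trec` and `krec` components, each holding `median`,
#'   `q1`, `q3` (copies/well).
#' @export
non_newborn_reference <- function() {
  list(
    trec = list(median = 104, q1 = 64, q3 = 151),
    krec = list(median = 180, q1 = 126, q3 = 258)
  )
}

#' Aggregate counts from the first year of Swedish national SCID screening
#'
#' The published aggregate results of the first programme year
#' (August 2019 - August 2020): cohort composition, referral and outcome
#' counts, and the post hoc counts at the hypothetical referral cut-off of
#' 4 TREC copies/well. These counts are the inputs for the pure-arithmetic
#' reporting path ([first_year_report()]), which reproduces the programme's
#' clinical-performance statistics without any simulation.
#'
#' @return A named list of counts; `cutoff4` is a nested list with the
#'   post hoc counts at a referral cut-off of 4 copies/well.
#' @export
first_year_counts <- function() {
  list(
    n_screened        = 115786L,  # all cards received
    n_newborns        = 115216L,
    n_non_newborns    = 570L,
    n_term            = 108524L,  # born >= week 37
    n_preterm         = 6687L,    # 5704 moderate + 642 very + 341 extremely
    n_ga_unknown      = 5L,
    n_negative        = 115704L,  # screening-negative cards with a final outcome
    n_referred        = 73L,
    referred_term     = 33L,
    referred_preterm  = 35L,
    referred_non_newborn = 5L,
    tp_scid           = 3L,
    tp_lymphopenia    = 21L,      # includes the 3 SCID cases
    n_undetectable    = 19L,      # cards with mean TREC < 1 copy/well
    n_repeat_cards    = 27L,      # inconclusive quality, new card requested
    n_lost_to_followup = 7L,
    cutoff4 = list(referred = 53L, tp_scid = 3L, tp_lymphopenia = 18L,
                   referred_term = 25L, tp_term = 12L,
                   referred_preterm = 23L, tp_preterm = 6L)
  )
}

#' Per-case screening results of the true-positive children
#'
#' Average TREC and KREC copies/well of the first and (where sampled) second
#' screening card, total lymphocyte and CD3+ T cell counts, and clinical
#' diagnosis for the 21 true-positive children (T cell lymphopenia, of whom 3
#' had SCID) detected in the first programme year. Stored as a plain-text
#' fixture so the decision algorithm can be exercised against real printed
#' card values with zero simulation.
#'
#' @return A data.frame with one row per case.
#' @export
true_positive_cases <- function() {
  path <- system.file("extdata", "true_positive_cards.csv",
                      package = "trecscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
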