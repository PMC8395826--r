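# Shared fixtures: small cohorts and curves built in code at test time.

small_cohort <- function(n = 500, seed = 11, cases = NULL, spots = 4L) {
  rates <- c(SCID = 0, lymphopenia_non_SCID = 0, FP_low_trec = 0,
             technical_failure = 0)
  if (!is.null(cases)) rates[names(cases)] <- cases
  simulate_cohort(cohort_config(n_newborns = n, n_non_newborns = 0,
                                case_rates = rates, spots_per_child = spots,
                                seed = seed))
}

# a cohort consisting only of one gestational-age stratum
stratum_cohort <- function(label, n, seed = 3, spots = 1L) {
  mix <- ga_reference_strata()
  mix <- mix[mix$label == label, ]
  mix$proportion <- 1
  simulate_cohort(cohort_config(
    n_newborns = n, n_non_newborns = 0, ga_mixture = mix,
    case_rates = c(SCID = 0, lymphopenia_non_SCID = 0, FP_low_trec = 0,
                   technical_failure = 0),
    p_ga_unknown = 0, spots_per_child = spots, seed = seed))
}

per_child_mean <- function(cohort, col = "trec") {
  tapply(cohort[[col]], cohort$child_id, mean)
}
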