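#' Configuration for the synthetic screened cohort
#'
#' Bundles every parameter of the cohort generator. Defaults reproduce the
#' composition of the Swedish national programme's first screening year:
#' 115,216 newborns with the gestational-age mixture of
#' [ga_reference_strata()], 570 non-newborn children (screened between one
#' month and two years of age), case rates matching the counts observed in
#' that year, and the reported sampling-age distribution (median 57.1 h,
#' IQR 49.9-73.0).
#'
#' @param n_newborns,n_non_newborns Cohort sizes.
#' @param ga_mixture A data.frame in the shape of [ga_reference_strata()]
#'   (columns `label`, `week_lo`, `week_hi`, `trec_*`, `krec_*`,
#'   `proportion`); proportions must sum to 1.
#' @param case_rates Named probabilities per child for the non-healthy
#'   conditions `SCID`, `lymphopenia_non_SCID`, `FP_low_trec`, and
#'   `technical_failure`. The residual probability is `healthy`.
#' @param p_ga_unknown Probability that a newborn's gestational age was not
#'   recorded (such children draw term-like analyte truths but carry
#'   `ga_weeks = NA` and are excluded from stratified summaries).
#' @param sampling_age A list with `median`, `q1`, `q3` (hours) for the
#'   newborn sampling-age lognormal, plus `min` (truncation, hours).
#' @param spots_per_child Dried blood spots per card (1-4).
#' @param spot_cv Multiplicative spot-to-spot coefficient of variation of the
#'   analyte truths around the child's level. The programme's source data do
#'   not report intra-card replicate variance; 10% is a stand-in and is fully
#'   configurable.
#' @param actb A list with `median` and `sigma` (lognormal, copies/well) for
#'   sample-quality ACTB levels of non-failed cards; draws are floored at
#'   1000 copies/well so only `technical_failure` children fail the DNA
#'   sufficiency gate.
#' @param period Character vector of two dates (card arrival window).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return An object of class `cohort_config` (a named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_newborns = 115216L,
                          n_non_newborns = 570L,
                          ga_mixture = ga_reference_strata(),
                          case_rates = c(SCID = 3 / 115216,
                                         lymphopenia_non_SCID = 18 / 115216,
                                         FP_low_trec = 52 / 115786,
                                         technical_failure = 27 / 115786),
                          p_ga_unknown = 5 / 115216,
                          sampling_age = list(median = 57.1, q1 = 49.9,
                                              q3 = 73.0, min = 24),
                          spots_per_child = 4L,
                          spot_cv = 0.10,
                          actb = list(median = 3500, sigma = 0.35),
                          period = c("2019-08-05", "2020-08-04"),
                          seed = 1L) {
  stopifnot(n_newborns >= 0, n_non_newborns >= 0,
            spots_per_child >= 1, spots_per_child <= 4,
            spot_cv >= 0)
  rates <- case_rates[c("SCID", "lymphopenia_non_SCID", "FP_low_trec",
                        "technical_failure")]
  rates[is.na(rates)] <- 0
  names(rates) <- c("SCID", "lymphopenia_non_SCID", "FP_low_trec",
                    "technical_failure")
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("case rates must lie in [0, 1] and sum to at most 1", call. = FALSE)
  }
  if (abs(sum(ga_mixture$proportion) - 1) > 1e-9) {
    stop("gestational-age mixture proportions must sum to 1", call. = FALSE)
  }
  structure(list(n_newborns = as.integer(n_newborns),
                 n_non_newborns = as.integer(n_non_newborns),
                 ga_mixture = ga_mixture, case_rates = rates,
                 p_ga_unknown = p_ga_unknown, sampling_age = sampling_age,
                 spots_per_child = as.integer(spots_per_child),
                 spot_cv = spot_cv, actb = actb,
                 period = as.Date(period), seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Screened-cohort configuration\n")
  cat(sprintf("  newborns: %d   non-newborns: %d   spots/card: %d\n",
              x$n_newborns, x$n_non_newborns, x$spots_per_child))
  cat(sprintf("  case rates: %s\n",
              paste(sprintf("%s=%.3g", names(x$case_rates), x$case_rates),
                    collapse = ", ")))
  cat(sprintf("  spot CV: %.0f%%   seed: %d\n", 100 * x$spot_cv, x$seed))
  invisible(x)
}

conditions_enum <- function() {
  c("healthy", "SCID", "lymphopenia_non_SCID", "FP_low_trec",
    "technical_failure")
}

# multiplicative lognormal noise with median 1 and coefficient of variation cv
spot_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

# Condition-specific analyte truths for n children x spots spots.
# Values follow the per-case profiles observed in the programme's first year:
# SCID cards have TREC < 1 copy/well on every spot with genotype-dependent
# KREC (ADA-like cases lose B cells too, JAK3-like cases keep normal KREC);
# non-SCID T cell lymphopenia cards ran 0-6 copies/well; false-positive
# referrals ranged 0-6.4 copies/well with normal CD3; technical failures have
# insufficient DNA (ACTB < 1000 copies/well) on all spots.
draw_case_truths <- function(n, condition, spots, cv) {
  out <- list(trec = NULL, krec = NULL, actb = NULL, cd3 = NULL)
  if (n == 0) {
    return(out)
  }
  rmat <- function(child_level, clamp_hi = Inf, clamp_lo = 0) {
    m <- matrix(child_level, nrow = n, ncol = spots) *
      matrix(spot_noise(n * spots, cv), nrow = n)
    pmin(pmax(m, clamp_lo), clamp_hi)
  }
  if (condition == "SCID") {
    # genotype split: ~1/3 ADA-like (low KREC), ~2/3 JAK3-like (normal KREC)
    ada <- stats::runif(n) < 1 / 3
    out$trec <- matrix(stats::runif(n * spots, 0, 0.9), nrow = n)
    krec_child <- ifelse(ada, stats::runif(n, 0.3, 2),
                         stats::rlnorm(n, log(125), 0.3))
    out$krec <- rmat(krec_child)
    out$cd3 <- stats::runif(n, 0.005, 0.2)
  } else if (condition == "lymphopenia_non_SCID") {
    out$trec <- rmat(stats::runif(n, 0, 6), clamp_hi = 6.4)
    out$cd3 <- stats::runif(n, 0.05, 1.9)
  } else if (condition == "FP_low_trec") {
    out$trec <- rmat(stats::runif(n, 0, 6.4), clamp_hi = 6.4)
    out$cd3 <- stats::runif(n, 2.0, 6.5)
  } else if (condition == "technical_failure") {
    out$actb <- matrix(stats::runif(n * spots, 100, 999), nrow = n)
  } else {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  out
}

#' Overwrite a child's analyte truths with a condition-specific profile
#'
#' Takes the spot-level rows of a single child (as produced by
#' [simulate_cohort()]) and redraws the analyte truths to match the requested
#' condition, leaving demographics untouched. This is the same draw the cohort
#' generator applies internally, exposed for targeted construction of test
#' cases.
#'
#' @param child A data.frame of 1-4 spot rows for one child.
#' @param condition One of `"SCID"`, `"lymphopenia_non_SCID"`,
#'   `"FP_low_trec"`, `"technical_failure"`.
#' @param spot_cv Spot-to-spot coefficient of variation.
#' @return The modified spot rows with `condition` relabelled.
#' @export
inject_case <- function(child, condition, spot_cv = 0.10) {
  if (!condition %in% setdiff(conditions_enum(), "healthy")) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  stopifnot(is.data.frame(child), nrow(child) >= 1, nrow(child) <= 4,
            length(unique(child$child_id)) == 1)
  spots <- nrow(child)
  d <- draw_case_truths(1L, condition, spots, spot_cv)
  if (!is.null(d$trec)) child$trec <- d$trec[1, ]
  if (!is.null(d$krec)) child$krec <- d$krec[1, ]
  if (!is.null(d$actb)) child$actb <- d$actb[1, ]
  if (!is.null(d$cd3)) child$cd3 <- d$cd3[1]
  child$condition <- condition
  child
}

#' Simulate a screened newborn cohort
#'
#' Generates a cohort of screened children whose analyte truths reproduce the
#' published gestational-age-stratified TREC/KREC reference distributions.
#' Each child receives a gestational-age stratum (newborns) or the
#' non-newborn reference distributions, child-level TREC/KREC truths from the
#' stratum's median/IQR-calibrated lognormal, per-spot truths with
#' multiplicative noise, a sampling age, a card arrival date, and a condition
#' label. Children drawn as SCID / lymphopenia / false-positive /
#' technical-failure cases have their truths overwritten with the
#' condition-specific profiles of [inject_case()]. SCID and non-SCID
#' lymphopenia children carry CD3+ T cell counts below 2 x 10^9 cells/L;
#' false positives carry normal CD3.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per (child, spot): `child_id`, `sex`,
#'   `ga_weeks`, `ga_stratum`, `is_newborn`, `sampling_age_h`, `arrival_date`,
#'   `condition`, `spot`, `trec`, `krec`, `actb` (copies/well truths), `cd3`
#'   (10^9 cells/L). Deterministic given `config$seed`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_newborns = 200, n_non_newborns = 5))
#' aggregate(trec ~ ga_stratum, data = coh, FUN = median)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_nb <- config$n_newborns
  n_on <- config$n_non_newborns
  n <- n_nb + n_on
  if (n == 0) {
    return(empty_cohort())
  }
  mix <- config$ga_mixture
  spots <- config$spots_per_child
  is_newborn <- rep(c(TRUE, FALSE), c(n_nb, n_on))

  # demographics ------------------------------------------------------------
  sex <- sample(c("F", "M", "unknown"), n, replace = TRUE,
                prob = c(0.4818, 0.5181, 0.0001))
  stratum_idx <- rep(NA_integer_, n)
  if (n_nb > 0) {
    stratum_idx[1:n_nb] <- sample.int(nrow(mix), n_nb, replace = TRUE,
                                      prob = mix$proportion)
  }
  ga_weeks <- ifelse(is.na(stratum_idx), NA_integer_, {
    lo <- mix$week_lo[stratum_idx]
    hi <- mix$week_hi[stratum_idx]
    lo + floor(stats::runif(n) * (hi - lo + 1))
  })
  ga_unknown <- is_newborn & stats::runif(n) < config$p_ga_unknown
  ga_weeks[ga_unknown] <- NA_integer_

  sa <- config$sampling_age
  sa_par <- lognormal_from_median_iqr(sa$median, sa$q1, sa$q3)
  sampling_age_h <- pmax(sa$min, stats::rlnorm(n, sa_par$mu, sa_par$sigma))
  # non-newborns: 28 days to 2 years, in hours
  if (n_on > 0) {
    sampling_age_h[!is_newborn] <- stats::runif(n_on, 28, 730) * 24
  }
  arrival_date <- config$period[1] +
    sample.int(as.integer(diff(config$period)) + 1L, n, replace = TRUE) - 1L

  # conditions --------------------------------------------------------------
  rates <- config$case_rates
  u <- stats::runif(n)
  breaks <- cumsum(c(rates, healthy = 1 - sum(rates)))
  condition <- names(breaks)[findInterval(u, c(0, breaks),
                                          rightmost.closed = TRUE)]
  # SCID / non-SCID lymphopenia only arise among newborns in this model
  condition[!is_newborn &
              condition %in% c("SCID", "lymphopenia_non_SCID")] <- "healthy"

  # child-level analyte truths ----------------------------------------------
  trec_child <- numeric(n)
  krec_child <- numeric(n)
  if (n_nb > 0) {
    idx <- stratum_idx[1:n_nb]
    tp <- lognormal_from_median_iqr(mix$trec_median, mix$trec_q1, mix$trec_q3)
    kp <- lognormal_from_median_iqr(mix$krec_median, mix$krec_q1, mix$krec_q3)
    trec_child[1:n_nb] <- stats::rlnorm(n_nb, tp$mu[idx], tp$sigma[idx])
    krec_child[1:n_nb] <- stats::rlnorm(n_nb, kp$mu[idx], kp$sigma[idx])
  }
  if (n_on > 0) {
    ref <- non_newborn_reference()
    tp <- lognormal_from_median_iqr(ref$trec$median, ref$trec$q1, ref$trec$q3)
    kp <- lognormal_from_median_iqr(ref$krec$median, ref$krec$q1, ref$krec$q3)
    trec_child[!is_newborn] <- stats::rlnorm(n_on, tp$mu, tp$sigma)
    krec_child[!is_newborn] <- stats::rlnorm(n_on, kp$mu, kp$sigma)
  }
  cd3 <- stats::runif(n, 2.2, 6.5)  # healthy newborn CD3+ counts

  # spot-level truths (children x spots matrices) ----------------------------
  trec <- matrix(trec_child, n, spots) *
    matrix(spot_noise(n * spots, config$spot_cv), n, spots)
  krec <- matrix(krec_child, n, spots) *
    matrix(spot_noise(n * spots, config$spot_cv), n, spots)
  actb <- matrix(pmax(1000, stats::rlnorm(n * spots,
                                          log(config$actb$median),
                                          config$actb$sigma)), n, spots)

  # condition-specific overrides --------------------------------------------
  for (cond in setdiff(conditions_enum(), "healthy")) {
    sel <- which(condition == cond)
    if (length(sel) == 0) next
    d <- draw_case_truths(length(sel), cond, spots, config$spot_cv)
    if (!is.null(d$trec)) trec[sel, ] <- d$trec
    if (!is.null(d$krec)) krec[sel, ] <- d$krec
    if (!is.null(d$actb)) actb[sel, ] <- d$actb
    if (!is.null(d$cd3)) cd3[sel] <- d$cd3
  }

  out <- data.frame(
    child_id = rep(sprintf("C%06d", seq_len(n)), each = spots),
    sex = rep(sex, each = spots),
    ga_weeks = rep(ga_weeks, each = spots),
    ga_stratum = rep(ifelse(is.na(stratum_idx), NA_character_,
                            mix$label[stratum_idx]), each = spots),
    is_newborn = rep(is_newborn, each = spots),
    sampling_age_h = rep(sampling_age_h, each = spots),
    arrival_date = rep(arrival_date, each = spots),
    condition = rep(condition, each = spots),
    spot = rep(seq_len(spots), times = n),
    trec = as.vector(t(trec)),
    krec = as.vector(t(krec)),
    actb = as.vector(t(actb)),
    cd3 = rep(cd3, each = spots),
    stringsAsFactors = FALSE
  )
  out
}

empty_cohort <- function() {
  data.frame(child_id = character(), sex = character(),
             ga_weeks = integer(), ga_stratum = character(),
             is_newborn = logical(), sampling_age_h = numeric(),
             arrival_date = as.Date(character()), condition = character(),
             spot = integer(), trec = numeric(), krec = numeric(),
             actb = numeric(), cd3 = numeric(), stringsAsFactors = FALSE)
}
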