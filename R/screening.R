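#' Screening policy: cut-offs, quality gate, and replicate rules
#'
#' Encodes the decision algorithm's parameters. A card is directly negative
#' when its initial TREC lies above the reanalysis cut-off; the reanalysis
#' cut-off was 15 copies/well during the programme's first eight months
#' (epoch 1) and was lowered to 10 copies/well on 1 April 2020 (epoch 2).
#' The referral cut-off, mean TREC <= 6 copies/well over all replicate PCRs,
#' was constant throughout; the comparison at exactly 6.0 is inclusive.
#' Sample quality requires ACTB >= 1000 copies/well and an acceptable
#' amplification profile.
#'
#' @param reanalysis_cutoff_epoch1,reanalysis_cutoff_epoch2 Reanalysis
#'   cut-offs (copies/well) before/after the switch date.
#' @param referral_cutoff Referral cut-off (copies/well), compared inclusively.
#' @param actb_min Minimum ACTB copies/well for sufficient sample quality.
#' @param epoch_switch_date Date the reanalysis cut-off changed.
#' @param outlier_ratio Replicate-exclusion rule: the minimum replicate is
#'   dropped only when max/min exceeds this ratio *and* the remaining mean
#'   lies above the referral cut-off (SCID cards yield uniformly low TREC, so
#'   the rule can never remove a true case's replicates).
#' @param discretionary_margin Optional clinician-discretion band: when > 0,
#'   consensus means in `(referral_cutoff, referral_cutoff + margin]` are
#'   also referred. Default off.
#' @param repeat_card Whether inconclusive cards trigger a second-card
#'   request.
#' @param followup_response_rate Probability that a requested second card is
#'   actually received (non-responders become lost to follow-up).
#' @return An object of class `screening_policy`.
#' @export
screening_policy <- function(reanalysis_cutoff_epoch1 = 15,
                             reanalysis_cutoff_epoch2 = 10,
                             referral_cutoff = 6,
                             actb_min = 1000,
                             epoch_switch_date = as.Date("2020-04-01"),
                             outlier_ratio = 10,
                             discretionary_margin = 0,
                             repeat_card = TRUE,
                             followup_response_rate = 20 / 27) {
  stopifnot(referral_cutoff <= reanalysis_cutoff_epoch1,
            referral_cutoff <= reanalysis_cutoff_epoch2,
            actb_min > 0, outlier_ratio > 1,
            discretionary_margin >= 0,
            followup_response_rate >= 0, followup_response_rate <= 1)
  structure(list(reanalysis_cutoff_epoch1 = reanalysis_cutoff_epoch1,
                 reanalysis_cutoff_epoch2 = reanalysis_cutoff_epoch2,
                 referral_cutoff = referral_cutoff,
                 actb_min = actb_min,
                 epoch_switch_date = as.Date(epoch_switch_date),
                 outlier_ratio = outlier_ratio,
                 discretionary_margin = discretionary_margin,
                 repeat_card = repeat_card,
                 followup_response_rate = followup_response_rate),
            class = "screening_policy")
}

#' @export
print.screening_policy <- function(x, ...) {
  cat("Screening policy\n")
  cat(sprintf("  reanalysis cut-off: %g (epoch 1) / %g (epoch 2, from %s) copies/well\n",
              x$reanalysis_cutoff_epoch1, x$reanalysis_cutoff_epoch2,
              format(x$epoch_switch_date)))
  cat(sprintf("  referral cut-off: mean TREC <= %g copies/well; ACTB >= %g\n",
              x$referral_cutoff, x$actb_min))
  cat(sprintf("  replicate outlier rule: drop minimum if max/min > %g and remaining mean > cut-off\n",
              x$outlier_ratio))
  invisible(x)
}

#' Epoch of a card arrival date
#'
#' @param date Date (or coercible) of card arrival at the laboratory.
#' @param policy A [screening_policy()].
#' @return Integer vector of 1s and 2s.
#' @export
policy_epoch <- function(date, policy = screening_policy()) {
  ifelse(as.Date(date) < policy$epoch_switch_date, 1L, 2L)
}

reanalysis_cutoff_for <- function(policy, date) {
  ifelse(policy_epoch(date, policy) == 1L,
         policy$reanalysis_cutoff_epoch1, policy$reanalysis_cutoff_epoch2)
}

#' Triage a card's initial PCR result
#'
#' First step of the decision algorithm: the quality gate (amplification
#' profile acceptable and ACTB >= 1000 copies/well), then the epoch's
#' reanalysis cut-off. Cards above the reanalysis cut-off are directly
#' negative; results between the referral and reanalysis cut-offs are
#' reanalysed in duplicate from different blood spots; results at or below
#' the referral cut-off are reanalysed in quadruplicate (or from all
#' available spots).
#'
#' @param trec,actb Initial quantified copies/well (vectorised).
#' @param amplification_ok Logical; the visually-inspected amplification
#'   profile abstracted to a flag.
#' @param policy A [screening_policy()].
#' @param date Card arrival date (determines the epoch).
#' @return Character vector in `{"negative", "reanalyse_duplicate",
#'   "reanalyse_quadruplicate", "quality_fail"}`.
#' @export
classify_initial <- function(trec, actb, amplification_ok = TRUE,
                             policy = screening_policy(),
                             date = policy$epoch_switch_date) {
  if (any(trec < 0, na.rm = TRUE) || any(actb < 0, na.rm = TRUE)) {
    stop("invalid input: analyte concentrations must be non-negative",
         call. = FALSE)
  }
  rc <- reanalysis_cutoff_for(policy, date)
  ifelse(!amplification_ok | actb < policy$actb_min, "quality_fail",
         ifelse(trec > rc, "negative",
                ifelse(trec > policy$referral_cutoff, "reanalyse_duplicate",
                       "reanalyse_quadruplicate")))
}

#' Replicate consensus mean with extreme-variability exclusion
#'
#' The referral decision uses the mean TREC over all replicate PCRs of a
#' card. Under extreme variability, individual replicates with particularly
#' low TREC are excluded as technical outliers, on the rationale that true
#' SCID cards yield uniformly low replicates. Concretely, the retained
#' minimum is dropped (iteratively) while (a) the retained max/min ratio
#' exceeds `policy$outlier_ratio` and (b) the mean of the remaining
#' replicates lies above the referral cut-off. Condition (b) guarantees the
#' rule can never lift a uniformly-low card above the cut-off.
#'
#' @param trecs Numeric vector of replicate TREC copies/well (>= 1 value).
#' @param policy A [screening_policy()].
#' @return A list: `mean_trec` (consensus mean), `excluded` (integer indices
#'   into `trecs`), `used` (retained indices).
#' @examples
#' replicate_consensus(c(8, 9, 10, 0.4))  # drops the 0.4 outlier
#' replicate_consensus(c(0, 0, 0, 0))     # uniform: nothing excluded
#' @export
replicate_consensus <- function(trecs, policy = screening_policy()) {
  if (length(trecs) == 0) {
    stop("invalid input: at least one replicate required", call. = FALSE)
  }
  if (any(trecs < 0)) {
    stop("invalid input: replicate TREC must be non-negative", call. = FALSE)
  }
  keep <- seq_along(trecs)
  while (length(keep) > 1) {
    v <- trecs[keep]
    i_min <- keep[which.min(v)]
    ratio <- if (min(v) == 0) {
      if (max(v) == 0) 1 else Inf
    } else {
      max(v) / min(v)
    }
    rest <- setdiff(keep, i_min)
    if (ratio > policy$outlier_ratio &&
        mean(trecs[rest]) > policy$referral_cutoff) {
      keep <- rest
    } else {
      break
    }
  }
  list(mean_trec = mean(trecs[keep]),
       excluded = setdiff(seq_along(trecs), keep),
       used = keep)
}

# indices of the reanalysis punches for a card with n_spots available spots
reanalysis_spots <- function(action, n_spots) {
  if (action == "reanalyse_duplicate") {
    # duplicate from different blood spots; with a single spot, re-punch it
    if (n_spots >= 3) c(2L, 3L) else rep(seq_len(n_spots), length.out = 2L)
  } else {
    # quadruplicate, or all blood spots where fewer than four are available
    seq_len(min(n_spots, 4L))
  }
}

#' Screen one child's card through the full decision algorithm
#'
#' Runs the triage of [classify_initial()] on the first spot, then, where
#' required, the replicate stage: duplicate reanalysis for results in the
#' reanalysis band, quadruplicate (all available spots) for results at or
#' below the referral cut-off or failed quality. The consensus set is the
#' initial PCR plus the reanalysis punches. A card is referred when the
#' consensus mean TREC is at or below the referral cut-off; it is
#' inconclusive (new card requested) when every replicate is below the
#' referral cut-off while every replicate ACTB is below the quality minimum
#' (amplification failure). KREC is carried through and reported but never
#' enters the decision.
#'
#' @param trecs,krecs,actbs Measured copies/well per available spot (1-4
#'   values each; first value = the initial PCR's spot).
#' @param policy A [screening_policy()].
#' @param date Card arrival date.
#' @param amplification_ok Amplification-profile flag for the initial PCR.
#' @return A one-row data.frame: `status` (one of `negative`,
#'   `negative_after_reanalysis`, `positive_referral`,
#'   `inconclusive_new_card`), `mean_trec`, `mean_krec`, `replicates_used`,
#'   `replicates_excluded`, `epoch`, `initial_action`.
#' @export
screen_child <- function(trecs, krecs = rep(NA_real_, length(trecs)), actbs,
                         policy = screening_policy(),
                         date = policy$epoch_switch_date,
                         amplification_ok = TRUE) {
  n_spots <- length(trecs)
  stopifnot(n_spots >= 1, n_spots <= 4, length(actbs) == n_spots,
            length(krecs) == n_spots)
  action <- classify_initial(trecs[1], actbs[1], amplification_ok, policy, date)
  epoch <- policy_epoch(date, policy)
  if (action == "negative") {
    return(data.frame(status = "negative", mean_trec = trecs[1],
                      mean_krec = krecs[1], replicates_used = 1L,
                      replicates_excluded = 0L, epoch = epoch,
                      initial_action = action, stringsAsFactors = FALSE))
  }
  rep_idx <- reanalysis_spots(action, n_spots)
  v_trec <- c(trecs[1], trecs[rep_idx])
  v_krec <- c(krecs[1], krecs[rep_idx])
  v_actb <- c(actbs[1], actbs[rep_idx])

  if (all(v_trec < policy$referral_cutoff) && all(v_actb < policy$actb_min)) {
    return(data.frame(status = "inconclusive_new_card",
                      mean_trec = mean(v_trec), mean_krec = mean(v_krec),
                      replicates_used = length(v_trec),
                      replicates_excluded = 0L, epoch = epoch,
                      initial_action = action, stringsAsFactors = FALSE))
  }
  cons <- replicate_consensus(v_trec, policy)
  referred <- cons$mean_trec <= policy$referral_cutoff ||
    (policy$discretionary_margin > 0 &&
       cons$mean_trec <= policy$referral_cutoff + policy$discretionary_margin)
  data.frame(status = if (referred) "positive_referral"
                      else "negative_after_reanalysis",
             mean_trec = cons$mean_trec,
             mean_krec = mean(v_krec[cons$used]),
             replicates_used = length(cons$used),
             replicates_excluded = length(cons$excluded),
             epoch = epoch, initial_action = action,
             stringsAsFactors = FALSE)
}

#' Run the screening programme over a cohort
#'
#' Applies the decision algorithm to every child of a simulated cohort and
#' aggregates the programme log. In `"truth"` mode the measured copies/well
#' are the cohort's spot truths censored at the assay's limit of blank
#' (truths below the limit of blank report as 0 copies/well, the
#' "no amplification" convention); in `"plate"` mode the spots of children
#' needing reanalysis are run through the qPCR forward model and quantified
#' from the standard curves. Children with inconclusive cards receive one
#' second-card request: responders are rescreened on a fresh card (sample
#' collection failure resolved), non-responders are lost to follow-up.
#'
#' In both modes, a spot whose measured ACTB falls below the policy's
#' quality minimum is treated as a failed amplification: insufficient DNA on
#' the punch means no analyte amplifies reliably, so TREC and KREC on that
#' spot are measured as 0. This is what routes collection failures into the
#' inconclusive branch (all replicates below the referral cut-off with
#' ACTB below the minimum) instead of the referral branch.
#'
#' @param cohort A [simulate_cohort()] data.frame.
#' @param policy A [screening_policy()].
#' @param mode `"truth"` (deterministic censored truths) or `"plate"` (qPCR
#'   forward model with Ct noise).
#' @param seed Integer seed for the second-card lottery and plate noise.
#' @param limits [analytical_limits()] used for censoring/detection.
#' @param curves,noise_sd Plate-mode parameters, see [simulate_plate()].
#' @return A list of class `screening_run`: `outcomes` (one row per child:
#'   `child_id`, `status`, `mean_trec`, `mean_krec`, `replicates_used`,
#'   `replicates_excluded`, `epoch`) and `log` (aggregate counters:
#'   reanalysis/referral/inconclusive rates, per-epoch reanalysis rates,
#'   second-card resolution).
#' @export
run_programme <- function(cohort, policy = screening_policy(),
                          mode = c("truth", "plate"), seed = 1L,
                          limits = analytical_limits(),
                          curves = default_standard_curves(),
                          noise_sd = 0.15) {
  mode <- match.arg(mode)
  if (nrow(cohort) == 0) {
    return(structure(list(outcomes = empty_outcomes(), log = list(n_children = 0L)),
                     class = "screening_run"))
  }
  set.seed(seed)
  # per-child measured values, spot-major
  cohort <- cohort[order(cohort$child_id, cohort$spot), ]
  if (mode == "plate") {
    measured <- quantify_spots_by_plate(cohort, curves, noise_sd, limits)
  } else {
    measured <- cohort
    measured$trec <- ifelse(cohort$trec < limits$lob_trec, 0, cohort$trec)
    measured$krec <- ifelse(cohort$krec < limits$lob_krec, 0, cohort$krec)
  }
  # insufficient DNA on a punch fails amplification of every analyte
  dna_fail <- measured$actb < policy$actb_min
  measured$trec[dna_fail] <- 0
  measured$krec[dna_fail] <- 0

  first <- measured[measured$spot == 1, ]
  action <- classify_initial(first$trec, first$actb, TRUE, policy,
                             first$arrival_date)
  epoch <- policy_epoch(first$arrival_date, policy)

  outcomes <- data.frame(child_id = first$child_id, status = "negative",
                         mean_trec = first$trec, mean_krec = first$krec,
                         replicates_used = 1L, replicates_excluded = 0L,
                         epoch = epoch, stringsAsFactors = FALSE)
  redo <- which(action != "negative")
  by_child <- split(measured[measured$child_id %in% first$child_id[redo], ],
                    measured$child_id[measured$child_id %in% first$child_id[redo]])
  for (i in redo) {
    ch <- by_child[[first$child_id[i]]]
    res <- screen_child(ch$trec, ch$krec, ch$actb, policy,
                        first$arrival_date[i])
    outcomes[i, c("status", "mean_trec", "mean_krec", "replicates_used",
                  "replicates_excluded")] <-
      res[, c("status", "mean_trec", "mean_krec", "replicates_used",
              "replicates_excluded")]
  }

  # second-card handling for inconclusive cards
  inconclusive_idx <- which(outcomes$status == "inconclusive_new_card")
  n_inconclusive <- length(inconclusive_idx)
  n_lost <- 0L
  if (policy$repeat_card && n_inconclusive > 0) {
    responded <- stats::runif(n_inconclusive) < policy$followup_response_rate
    raw_by_child <- split(cohort[cohort$child_id %in%
                                   first$child_id[inconclusive_idx], ],
                          cohort$child_id[cohort$child_id %in%
                                            first$child_id[inconclusive_idx]])
    for (j in seq_along(inconclusive_idx)) {
      i <- inconclusive_idx[j]
      if (!responded[j]) {
        outcomes$status[i] <- "lost_to_followup"
        n_lost <- n_lost + 1L
        next
      }
      # fresh card: collection failure resolved, so the new punches measure
      # the child's underlying analyte levels with sufficient DNA
      ch <- raw_by_child[[first$child_id[i]]]
      trec2 <- ifelse(ch$trec < limits$lob_trec, 0, ch$trec)
      krec2 <- ifelse(ch$krec < limits$lob_krec, 0, ch$krec)
      actb2 <- pmax(1000, stats::rlnorm(nrow(ch), log(3500), 0.35))
      res <- screen_child(trec2, krec2, actb2, policy,
                          first$arrival_date[i])
      outcomes[i, c("status", "mean_trec", "mean_krec", "replicates_used",
                    "replicates_excluded")] <-
        res[, c("status", "mean_trec", "mean_krec", "replicates_used",
                "replicates_excluded")]
    }
  }

  n <- nrow(outcomes)
  reanalysed <- action != "negative"
  log <- list(
    n_children = n,
    n_direct_negative = sum(action == "negative"),
    n_reanalysed = sum(reanalysed),
    reanalysis_rate = mean(reanalysed),
    reanalysis_rate_epoch1 = if (any(epoch == 1L)) mean(reanalysed[epoch == 1L]) else NA_real_,
    reanalysis_rate_epoch2 = if (any(epoch == 2L)) mean(reanalysed[epoch == 2L]) else NA_real_,
    n_referred = sum(outcomes$status == "positive_referral"),
    referral_rate = mean(outcomes$status == "positive_referral"),
    n_inconclusive = n_inconclusive,
    repeat_rate = n_inconclusive / n,
    n_lost_to_followup = n_lost,
    n_excluded_replicates = sum(outcomes$replicates_excluded)
  )
  structure(list(outcomes = outcomes, log = log), class = "screening_run")
}

empty_outcomes <- function() {
  data.frame(child_id = character(), status = character(),
             mean_trec = numeric(), mean_krec = numeric(),
             replicates_used = integer(), replicates_excluded = integer(),
             epoch = integer(), stringsAsFactors = FALSE)
}

#' @export
print.screening_run <- function(x, ...) {
  l <- x$log
  cat(sprintf("Screening run: %d children\n", l$n_children))
  if (l$n_children > 0) {
    cat(sprintf("  reanalysed: %d (%.2f%%)   referred: %d (%.3f%%)\n",
                l$n_reanalysed, 100 * l$reanalysis_rate,
                l$n_referred, 100 * l$referral_rate))
    cat(sprintf("  inconclusive: %d   lost to follow-up: %d\n",
                l$n_inconclusive, l$n_lost_to_followup))
  }
  invisible(x)
}

# plate-mode quantification: batch all spots into 92-well plates, simulate,
# quantify, and return the cohort with measured copies/well substituted
quantify_spots_by_plate <- function(cohort, curves, noise_sd, limits) {
  n <- nrow(cohort)
  batches <- split(seq_len(n), (seq_len(n) - 1) %/% 92)
  measured <- cohort
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    plate <- simulate_plate(cohort[idx, ], curves = curves,
                            noise_sd = noise_sd, limits = limits,
                            plate_id = sprintf("P%04d", b))
    w <- quantify_plate(plate)
    w <- w[w$role == "sample", ]
    key <- paste0(cohort$child_id[idx], ":", cohort$spot[idx])
    for (a in c("TREC", "KREC", "ACTB")) {
      wa <- w[w$analyte == a, ]
      m <- match(key, wa$sample_ref)
      col <- c(TREC = "trec", KREC = "krec", ACTB = "actb")[[a]]
      measured[[col]][idx] <- wa$copies[m]
    }
  }
  measured
}
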