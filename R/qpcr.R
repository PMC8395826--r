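#' Analytical limits of the screening qPCR assay
#'
#' Manufacturer-reported limits of detection and blank, in copies/well.
#' Truths below the limit of blank never amplify; truths between the limit of
#' blank and the limit of detection amplify stochastically (see
#' [simulate_plate()]).
#'
#' @param lod_trec,lod_krec Limits of detection.
#' @param lob_trec,lob_krec Limits of blank.
#' @return A named list of the four limits.
#' @export
analytical_limits <- function(lod_trec = 3.41, lod_krec = 3.13,
                              lob_trec = 0.32, lob_krec = 0.38) {
  stopifnot(lob_trec < lod_trec, lob_krec < lod_krec)
  list(lod_trec = lod_trec, lod_krec = lod_krec,
       lob_trec = lob_trec, lob_krec = lob_krec)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 nominal copies/well, the standard
#' quantification geometry: `Ct = intercept + slope * log10(copies)`.
#' Amplification efficiency derives from the slope as
#' `10^(-1/slope) - 1` (a slope of -3.32 is 100% efficiency).
#'
#' @param points A data.frame with columns `copies` (> 0) and `ct`; at least
#'   two distinct concentrations are required.
#' @param analyte Label (`"TREC"`, `"KREC"`, `"ACTB"`).
#' @return An object of class `standard_curve` with `slope` (Ct per decade),
#'   `intercept` (Ct at 1 copy/well), `r_squared`, `efficiency`, and the
#'   calibration `points`.
#' @examples
#' pts <- data.frame(copies = 10^(1:5), ct = 38.5 - 3.321928 * (1:5))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points, analyte = "TREC") {
  if (!is.data.frame(points) || !all(c("copies", "ct") %in% names(points))) {
    stop("invalid curve: points must have columns 'copies' and 'ct'",
         call. = FALSE)
  }
  if (any(points$copies <= 0)) {
    stop("invalid curve: non-positive nominal concentration", call. = FALSE)
  }
  if (length(unique(points$copies)) < 2) {
    stop("invalid curve: need at least 2 distinct concentrations",
         call. = FALSE)
  }
  x <- log10(points$copies)
  ct <- points$ct
  slope <- stats::cov(x, ct) / stats::var(x)
  intercept <- mean(ct) - slope * mean(x)
  tss <- sum((ct - mean(ct))^2)
  rss <- sum((ct - (intercept + slope * x))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(list(analyte = analyte, points = points,
                 slope = slope, intercept = intercept,
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("%s standard curve: Ct = %.3f %+.4f * log10(copies)\n",
              x$analyte, x$intercept, x$slope))
  cat(sprintf("  efficiency %.1f%%, r^2 = %.4f, %d points (%g-%g copies/well)\n",
              100 * x$efficiency, x$r_squared, nrow(x$points),
              min(x$points$copies), max(x$points$copies)))
  invisible(x)
}

#' Ideal 5-point standard curves for the three assay analytes
#'
#' TREC and KREC curves span 10 to 100,000 copies/well, ACTB spans 100 to
#' 1,000,000 copies/well, mirroring the kit's calibrator series. The default
#' geometry is 100% efficiency (slope `-1/log10(2)` = -3.3219) with
#' analyte-specific intercepts.
#'
#' @param intercepts Named Ct values at 1 copy/well.
#' @param slope Ct change per decade of template.
#' @return A named list of [fit_standard_curve()] objects.
#' @export
default_standard_curves <- function(intercepts = c(TREC = 38.5, KREC = 38.8,
                                                   ACTB = 40.2),
                                    slope = -1 / log10(2)) {
  ranges <- list(TREC = 10^(1:5), KREC = 10^(1:5), ACTB = 10^(2:6))
  curves <- lapply(names(ranges), function(a) {
    pts <- data.frame(copies = ranges[[a]],
                      ct = intercepts[[a]] + slope * log10(ranges[[a]]))
    fit_standard_curve(pts, analyte = a)
  })
  names(curves) <- names(ranges)
  curves
}

#' Quantify copies/well from a Ct value
#'
#' Inverts the fitted standard curve: `copies = 10^((ct - intercept)/slope)`.
#' Missing Ct (`NA`, the "no amplification" convention) quantifies to 0
#' copies/well. The result carries an `extrapolated` attribute flagging
#' quantities outside the curve's calibrated range.
#'
#' @param ct Numeric vector of Ct values (`NA` = no amplification).
#' @param curve A [fit_standard_curve()] object.
#' @return Numeric vector of copies/well.
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- ifelse(is.na(ct), 0, 10^((ct - curve$intercept) / curve$slope))
  rng <- range(curve$points$copies)
  attr(copies, "extrapolated") <- !is.na(ct) &
    (copies < rng[1] | copies > rng[2])
  copies
}

# detection probability of a template given the analytical limits:
# 0 below the limit of blank, p_mid between blank and detection, 1 above
detection_prob <- function(truth, lob, lod, p_mid = 0.5) {
  ifelse(truth < lob, 0, ifelse(truth < lod, p_mid, 1))
}

#' Simulate a 96-well screening plate
#'
#' Forward model inverse to [quantify()]: each sample well receives
#' `Ct = intercept + slope * log10(truth) + N(0, noise_sd)` per analyte, with
#' stochastic amplification failure near the analytical limits. Each plate
#' carries the three internal dried-blood-spot controls
#' (low-TREC/high-KREC, low-KREC/high-TREC, low-TREC/low-TREC-and-KREC
#' patterns) and one blank PCR, leaving capacity for 92 samples.
#'
#' @param samples Spot-level data.frame (rows of a [simulate_cohort()]
#'   cohort); at most 92 rows.
#' @param curves Standard curves as from [default_standard_curves()].
#' @param noise_sd Ct noise standard deviation.
#' @param limits [analytical_limits()].
#' @param p_mid Amplification probability for truths between the limit of
#'   blank and the limit of detection.
#' @param plate_id Plate label.
#' @param seed Optional integer; when given, makes the plate reproducible.
#' @return An object of class `plate_record`: `plate_id`, `curves`, and a
#'   `wells` data.frame (one row per well x analyte: `well`, `sample_ref`,
#'   `role`, `analyte`, `ct`, `amplification_ok`).
#' @export
simulate_plate <- function(samples, curves = default_standard_curves(),
                           noise_sd = 0.15, limits = analytical_limits(),
                           p_mid = 0.5, plate_id = "P001", seed = NULL) {
  if (nrow(samples) > 92) {
    stop("plate capacity exceeded: at most 92 samples per 96-well plate",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  control_truths <- data.frame(
    sample_ref = c("ctrl_lowT_highK", "ctrl_lowK_highT", "ctrl_lowT_lowK",
                   "blank"),
    role = c("control", "control", "control", "blank"),
    trec = c(2, 150, 2, 0), krec = c(150, 2, 2, 0),
    actb = c(5000, 5000, 5000, 0),
    stringsAsFactors = FALSE
  )
  truths <- rbind(
    data.frame(sample_ref = paste0(samples$child_id, ":", samples$spot),
               role = "sample", trec = samples$trec, krec = samples$krec,
               actb = samples$actb, stringsAsFactors = FALSE),
    control_truths
  )
  wells96 <- paste0(rep(LETTERS[1:8], each = 12), sprintf("%02d", 1:12))
  truths$well <- wells96[seq_len(nrow(truths))]

  lims <- list(TREC = c(limits$lob_trec, limits$lod_trec),
               KREC = c(limits$lob_krec, limits$lod_krec),
               ACTB = c(1, 1))  # ACTB has no reported limits; detect above 1
  rows <- lapply(c("TREC", "KREC", "ACTB"), function(a) {
    tr <- truths[[tolower(a)]]
    p <- detection_prob(tr, lims[[a]][1], lims[[a]][2], p_mid)
    amp <- stats::runif(length(tr)) < p
    ct <- ifelse(amp,
                 curves[[a]]$intercept + curves[[a]]$slope * log10(pmax(tr, 1e-12)) +
                   (if (noise_sd > 0) stats::rnorm(length(tr), 0, noise_sd) else 0),
                 NA_real_)
    data.frame(well = truths$well, sample_ref = truths$sample_ref,
               role = truths$role, analyte = a, ct = ct,
               amplification_ok = amp, stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, rows)
  wells <- wells[order(match(wells$well, wells96)), ]
  rownames(wells) <- NULL
  structure(list(plate_id = plate_id, curves = curves, wells = wells),
            class = "plate_record")
}

#' @export
print.plate_record <- function(x, ...) {
  n_samp <- length(unique(x$wells$sample_ref[x$wells$role == "sample"]))
  cat(sprintf("qPCR plate %s: %d sample wells, 3 internal controls, 1 blank\n",
              x$plate_id, n_samp))
  invisible(x)
}

#' Quantify every well of a plate
#'
#' @param plate A [simulate_plate()] record.
#' @return The plate's `wells` data.frame with an added `copies` column.
#' @export
quantify_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_record"))
  w <- plate$wells
  w$copies <- NA_real_
  for (a in names(plate$curves)) {
    sel <- w$analyte == a
    w$copies[sel] <- as.numeric(quantify(w$ct[sel], plate$curves[[a]]))
  }
  w
}

#' Plate acceptance verdict
#'
#' A plate is accepted when every standard curve meets the linearity and
#' efficiency requirements, the three internal dried-blood-spot controls
#' reproduce their expected low/high analyte patterns, and the blank shows no
#' amplification. The kit's own acceptance thresholds are unpublished;
#' defaults follow common qPCR practice (r^2 >= 0.98, efficiency 90-110%)
#' and the screening cut-off geometry (a "low" control must quantify below
#' the referral region, a "high" control above the reanalysis cut-off).
#'
#' @param plate A [simulate_plate()] record.
#' @param r2_min Minimum standard-curve r-squared.
#' @param efficiency_range Acceptable efficiency window (fractions).
#' @param low_max Maximum copies/well for a "low" control pattern.
#' @param high_min Minimum copies/well for a "high" control pattern.
#' @return A list of class `plate_verdict`: `accepted` flag and a character
#'   vector of `reasons` (empty when accepted).
#' @export
accept_plate <- function(plate, r2_min = 0.98, efficiency_range = c(0.9, 1.1),
                         low_max = 6, high_min = 15) {
  stopifnot(inherits(plate, "plate_record"))
  reasons <- character()
  for (a in names(plate$curves)) {
    cv <- plate$curves[[a]]
    if (cv$r_squared < r2_min) {
      reasons <- c(reasons, sprintf("standard curve %s: r^2 %.4f < %.2f",
                                    a, cv$r_squared, r2_min))
    }
    if (cv$efficiency < efficiency_range[1] ||
        cv$efficiency > efficiency_range[2]) {
      reasons <- c(reasons, sprintf("standard curve %s: efficiency %.2f outside [%.2f, %.2f]",
                                    a, cv$efficiency, efficiency_range[1],
                                    efficiency_range[2]))
    }
  }
  w <- quantify_plate(plate)
  ctrl <- function(ref, analyte) w$copies[w$sample_ref == ref & w$analyte == analyte]
  expected <- list(
    ctrl_lowT_highK = c(TREC = "low", KREC = "high"),
    ctrl_lowK_highT = c(TREC = "high", KREC = "low"),
    ctrl_lowT_lowK  = c(TREC = "low", KREC = "low")
  )
  for (ref in names(expected)) {
    for (a in names(expected[[ref]])) {
      val <- ctrl(ref, a)
      want <- expected[[ref]][[a]]
      ok <- if (want == "low") length(val) == 1 && val <= low_max
            else length(val) == 1 && val >= high_min
      if (!ok) {
        reasons <- c(reasons, sprintf("control pattern: %s %s expected %s, got %.2f copies/well",
                                      ref, a, want, if (length(val)) val else NA))
      }
    }
  }
  blank_amp <- w$amplification_ok[w$sample_ref == "blank"]
  if (any(blank_amp)) {
    reasons <- c(reasons, "blank contamination: amplification in blank well")
  }
  structure(list(accepted = length(reasons) == 0, reasons = reasons),
            class = "plate_verdict")
}

#' @export
print.plate_verdict <- function(x, ...) {
  if (x$accepted) {
    cat("Plate accepted\n")
  } else {
    cat("Plate rejected:\n")
    for (r in x$reasons) cat("  -", r, "\n")
  }
  invisible(x)
}
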