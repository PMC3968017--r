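# Unit conversion, detection gating and dilution-series analysis.

#' Convert a net OD rate to a raw molar activity
#'
#' Beer-Lambert conversion of a background-corrected rate of absorbance loss
#' into moles of 4-NTP degraded per minute in the well:
#' rate(OD/min) / epsilon gives mol L^-1 min^-1, times the reaction volume
#' gives mol/min, reported in pmol/min. With 1:1 thiamine:4-NTP
#' stoichiometry this equals pmol thiamine degraded per minute. Sign is
#' preserved (negative net rates stay negative).
#'
#' @param net Net velocity, mOD/min (experimental minus control mean vmax).
#' @param constants An [assay_constants()].
#' @return Raw activity in pmol/min.
#' @examples
#' od_rate_to_raw_activity(0.66)  # ~4.8 pmol/min, the detection floor
#' @export
od_rate_to_raw_activity <- function(net, constants = assay_constants()) {
  stopifnot(inherits(constants, "assay_constants"))
  (net / 1000) / constants$epsilon * constants$reaction_volume * 1e12
}

#' Inverse of [od_rate_to_raw_activity()]
#'
#' @param raw Raw activity, pmol/min.
#' @param constants An [assay_constants()].
#' @return Net velocity in mOD/min.
#' @examples
#' raw_activity_to_od_rate(4.8) * 10  # mOD lost over one 10-min window
#' @export
raw_activity_to_od_rate <- function(raw, constants = assay_constants()) {
  stopifnot(inherits(constants, "assay_constants"))
  raw * 1e-12 / constants$reaction_volume * constants$epsilon * 1000
}

#' Apply the two-tier detection gate to a raw activity
#'
#' Gate outcomes, in order of increasing activity:
#' \describe{
#'   \item{negative_net}{raw <= 0; reported 0 (activity is physically
#'     non-negative).}
#'   \item{below_floor}{0 < raw <= floor; reported 0 (below the assay's
#'     detection limit).}
#'   \item{tested_pass / tested_fail}{floor < raw <= band upper: an unpaired
#'     two-sided t-test compares per-well maximum velocities of the
#'     experimental and control arms; the activity is reported only if
#'     p < alpha.}
#'   \item{untestable}{raw in the test band but an arm has fewer than 2
#'     wells; reported 0 with a warning.}
#'   \item{above_band}{raw > band upper; reported without a test.}
#' }
#'
#' @param raw Raw activity, pmol/min, computed from the same wells.
#' @param exp_vmax,ctrl_vmax Per-well maximum velocities (mOD/min) of the
#'   experimental and control arms; non-empty numeric vectors.
#' @param policy A [gating_policy()].
#' @return A one-row tibble: `raw_activity`, `gate`, `p_value` (NA unless
#'   tested), `reported_raw`.
#' @examples
#' gate_activity(30, c(4.1, 4.0, 3.9, 4.2), c(0.2, 0.25, 0.22, 0.18))
#' @export
gate_activity <- function(raw, exp_vmax, ctrl_vmax,
                          policy = gating_policy()) {
  stopifnot(inherits(policy, "gating_policy"))
  if (length(exp_vmax) == 0 || length(ctrl_vmax) == 0) {
    stop_domain("experimental and control vmax lists must be non-empty")
  }
  gate <- NULL
  p <- NA_real_
  reported <- 0
  if (raw <= 0) {
    gate <- "negative_net"
  } else if (raw <= policy$floor) {
    gate <- "below_floor"
  } else if (raw <= policy$ttest_band_upper) {
    if (length(exp_vmax) < 2 || length(ctrl_vmax) < 2) {
      warning(sprintf(
        "raw activity %.3g pmol/min is in the t-test band but an arm has < 2 wells; gated untestable",
        raw))
      gate <- "untestable"
    } else {
      # degenerate arms (both essentially constant) break t.test; a nonzero
      # mean difference with zero spread is unambiguous evidence
      p <- tryCatch(
        unname(stats::t.test(exp_vmax, ctrl_vmax,
                             alternative = "two.sided",
                             var.equal = policy$test_variant == "student")$p.value),
        error = function(e) {
          if (grepl("constant", conditionMessage(e))) {
            if (mean(exp_vmax) != mean(ctrl_vmax)) 0 else 1
          } else {
            stop(e)
          }
        })
      if (p < policy$alpha) {
        gate <- "tested_pass"
        reported <- raw
      } else {
        gate <- "tested_fail"
      }
    }
  } else {
    gate <- "above_band"
    reported <- raw
  }
  tibble::tibble(raw_activity = raw, gate = gate, p_value = p,
                 reported_raw = reported)
}

#' Convert a reported raw activity to specific activity
#'
#' For tissue extracts: the raw activity is divided by the mass fraction of
#' sample in the extract (sample mass over sample-plus-buffer mass, with
#' 1 ml buffer = 1 g) times the aliquot mass added to the well, i.e.
#' multiplied by `((mass + buffer)/mass) / aliquot`, then scaled by the
#' dilution factor; units nmol min^-1 g^-1. For culture supernatant the
#' conversion is simply `1 / aliquot` (per ml of culture); units
#' nmol min^-1 ml^-1. With the standard prep (1 g tissue + 2.5 ml buffer,
#' 3 µl per well) the tissue factor is (1/3.5 x 0.003)^-1.
#'
#' @param reported_raw Gated raw activity, pmol/min (0 if gated out).
#' @param spec A [sample_spec()].
#' @return Specific activity in nmol/min per g (tissue) or per ml
#'   (supernatant).
#' @examples
#' s <- sample_spec("sup", "supernatant")
#' to_specific_activity(4.8, s)  # 1.6 nmol/min/ml
#' @export
to_specific_activity <- function(reported_raw, spec) {
  stopifnot(inherits(spec, "sample_spec"))
  factor <- if (spec$category == "tissue") {
    (spec$sample_mass + spec$buffer_volume) / spec$sample_mass / spec$aliquot
  } else {
    1 / spec$aliquot
  }
  reported_raw * factor * spec$dilution_factor / 1000  # pmol -> nmol
}

#' Analyse a serial-dilution series for linear range and detection limit
#'
#' Fits log2(activity) on log2(dilution fraction) by OLS over the detectable
#' points (activity above `detection_floor`); a proportional series has
#' slope 1. A point is proportional when its activity deviates from the
#' fitted line by at most `tolerance` (relative, on the activity scale). The
#' detection limit is the activity at the deepest detectable dilution.
#'
#' @param points Data frame with columns `dilution` (fraction <= 1, distinct)
#'   and `activity` (volumetric or specific activity, same units as
#'   `detection_floor`).
#' @param detection_floor Activity below which a point is undetectable.
#'   Default 1.6, the volumetric equivalent (nmol min^-1 ml^-1) of the
#'   4.8 pmol/min raw floor with a 3 µl aliquot.
#' @param tolerance Maximum relative deviation from the fit for a point to
#'   count as proportional. Default 0.3.
#' @return An object of class `dilution_fit`: `points` (tibble with fitted
#'   values, deviations, `detectable` and `proportional` flags), `slope`,
#'   `intercept` (log2 scale), `last_proportional_dilution`,
#'   `detection_limit_activity`.
#' @examples
#' pts <- data.frame(dilution = 2^-(0:8), activity = 534 * 2^-(0:8))
#' analyze_dilution_series(pts)
#' @export
analyze_dilution_series <- function(points, detection_floor = 1.6,
                                    tolerance = 0.3) {
  points <- tibble::as_tibble(points)
  if (!all(c("dilution", "activity") %in% names(points))) {
    stop_domain("points need columns 'dilution' and 'activity'")
  }
  if (anyDuplicated(points$dilution)) {
    stop_domain("dilution fractions must be distinct")
  }
  if (any(points$dilution <= 0 | points$dilution > 1)) {
    stop_domain("dilution fractions must lie in (0, 1]")
  }
  points <- points[order(-points$dilution), ]
  points$detectable <- points$activity > detection_floor
  n_det <- sum(points$detectable)
  if (n_det < 3) {
    stop_domain(sprintf(
      "series too short: %d detectable points (need >= 3)", n_det))
  }
  det <- points[points$detectable, ]
  fit <- stats::lm(log2(activity) ~ log2(dilution), data = det)
  coefs <- stats::coef(fit)
  intercept <- unname(coefs[1])
  slope <- unname(coefs[2])
  fitted_act <- 2^(intercept + slope * log2(points$dilution))
  points$fitted <- fitted_act
  points$deviation <- abs(points$activity - fitted_act) / fitted_act
  points$proportional <- points$detectable & points$deviation <= tolerance
  structure(
    list(points = points,
         slope = slope,
         intercept = intercept,
         last_proportional_dilution =
           if (any(points$proportional))
             min(points$dilution[points$proportional]) else NA_real_,
         detection_limit_activity =
           points$activity[points$detectable][
             which.min(points$dilution[points$detectable])]),
    class = "dilution_fit"
  )
}

#' Type-I error calibration of the gate t-test on null samples
#'
#' Simulates samples with identical generative parameters in both arms (no
#' enzymatic activity anywhere, shared background decay and noise), computes
#' per-well maximum velocities, and gates each sample with a raw activity
#' fixed inside the t-test band, so the gate outcome is decided purely by
#' the t-test on null well values. The long-run `tested_pass` fraction
#' estimates the gate's false-detection rate and should match `alpha`.
#'
#' @param n_samples Number of null samples to simulate.
#' @param n_replicates Wells per arm. Default 4 (the 12-sample format).
#' @param raw_in_band Raw activity handed to the gate, pmol/min; must lie in
#'   `(floor, ttest_band_upper]`. Default 10.
#' @param k_bg,noise_sd,c0 Generative parameters shared by every well.
#' @param seed Master seed.
#' @param constants,policy Assay configuration.
#' @return A tibble with one row per null sample: `sample`, `gate`,
#'   `p_value`.
#' @export
null_gate_calibration <- function(n_samples = 2000, n_replicates = 4,
                                  raw_in_band = 10,
                                  k_bg = 0.001, noise_sd = 0.002,
                                  c0 = 200e-6, seed = 1,
                                  constants = assay_constants(),
                                  policy = gating_policy()) {
  if (raw_in_band <= policy$floor || raw_in_band > policy$ttest_band_upper) {
    stop_domain("raw_in_band must lie inside the t-test band")
  }
  set.seed(seed)
  well_seeds <- sample.int(2147483646L, n_samples * 2 * n_replicates)
  dim(well_seeds) <- c(n_samples, 2 * n_replicates)
  base <- sim_spec(v_enz = 0, k_bg = k_bg, c0 = c0, noise_sd = noise_sd)
  gates <- character(n_samples)
  pvals <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    vm <- vapply(seq_len(2 * n_replicates), function(j) {
      s <- base
      s$seed <- well_seeds[i, j]
      tr <- simulate_trace(s, constants)
      max_velocity(tr$time_min, tr$od411, constants$window_length)$vmax
    }, numeric(1))
    g <- gate_activity(raw_in_band, vm[seq_len(n_replicates)],
                       vm[n_replicates + seq_len(n_replicates)], policy)
    gates[i] <- g$gate
    pvals[i] <- g$p_value
  }
  tibble::tibble(sample = seq_len(n_samples), gate = gates, p_value = pvals)
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf(
    "<dilution_fit> %d points (%d detectable), log2-log2 slope %.3f\n",
    nrow(x$points), sum(x$points$detectable), x$slope))
  cat(sprintf("  proportional down to 1/%s; detection limit activity %.3g\n",
              format(1 / x$last_proportional_dilution, digits = 4),
              x$detection_limit_activity))
  invisible(x)
}
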