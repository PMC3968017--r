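#' Assay constants for the 4-NTP thiaminase I assay
#'
#' Physical and geometric constants of the colorimetric assay. Defaults are
#' the standard assay conditions: 4-NTP extinction coefficient in TCEP buffer
#' of 13,650 M\eqn{^{-1}}cm\eqn{^{-1}} at 411 nm, a 100 µl reaction
#' (\eqn{10^{-4}} L: 97 µl solution + 3 µl sample), a 10-min analysis window,
#' 200 µM initial 4-NTP and 400 µM thiamine in experimental wells.
#'
#' @param epsilon Molar extinction coefficient of 4-NTP, M^-1 cm^-1.
#' @param reaction_volume Well reaction volume in litres.
#' @param window_length Sliding-window length in minutes used for maximum
#'   velocity estimation.
#' @param ntp_initial Initial 4-NTP concentration, mol/L.
#' @param thiamine_initial Initial thiamine concentration in experimental
#'   wells, mol/L (metadata; thiamine is in large excess and not tracked).
#' @param wavelength Read wavelength in nm (metadata only).
#'
#' @return An object of class `assay_constants` (a validated list).
#' @examples
#' assay_constants()
#' @export
assay_constants <- function(epsilon = 13650,
                            reaction_volume = 1e-4,
                            window_length = 10,
                            ntp_initial = 200e-6,
                            thiamine_initial = 400e-6,
                            wavelength = 411) {
  num <- c(epsilon = epsilon, reaction_volume = reaction_volume,
           window_length = window_length, ntp_initial = ntp_initial,
           thiamine_initial = thiamine_initial, wavelength = wavelength)
  if (!all(is.finite(num)) || any(num <= 0)) {
    stop_domain("all assay constants must be finite and strictly positive")
  }
  structure(
    list(epsilon = epsilon, reaction_volume = reaction_volume,
         window_length = window_length, ntp_initial = ntp_initial,
         thiamine_initial = thiamine_initial, wavelength = wavelength),
    class = "assay_constants"
  )
}

#' Detection-gating policy
#'
#' Two-tier gate applied to background-corrected raw activities (pmol 4-NTP
#' degraded per minute per well). Activities at or below `floor` are reported
#' as zero; activities in the band `(floor, ttest_band_upper]` must be
#' substantiated by an unpaired two-sided t-test comparing per-well maximum
#' velocities of experimental and control wells at level `alpha`; activities
#' above the band are accepted without a test.
#'
#' @param floor Minimum detectable raw activity, pmol/min. Default 4.8.
#' @param ttest_band_upper Upper edge of the t-test band, pmol/min. Default 25.
#' @param alpha Significance level for the gate t-test. Default 0.05.
#' @param test_variant `"welch"` (unequal variances, default) or `"student"`.
#' @return An object of class `gating_policy`.
#' @examples
#' gating_policy()
#' @export
gating_policy <- function(floor = 4.8,
                          ttest_band_upper = 25,
                          alpha = 0.05,
                          test_variant = c("welch", "student")) {
  test_variant <- match.arg(test_variant)
  if (!is.finite(floor) || !is.finite(ttest_band_upper) ||
      floor <= 0 || ttest_band_upper <= floor) {
    stop_domain("need 0 < floor < ttest_band_upper")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_domain("alpha must lie strictly between 0 and 1")
  }
  structure(
    list(floor = floor, ttest_band_upper = ttest_band_upper,
         alpha = alpha, test_variant = test_variant, sides = "two"),
    class = "gating_policy"
  )
}
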