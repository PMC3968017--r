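# Synthetic plates with known ground truth.
#
# Generative model per well: 4-NTP concentration follows
#   dC/dt = -k_bg * C - v_enz   while C > 0,  C(0) = c0,
# i.e. zero-order enzymatic consumption (thiamine is in large excess) plus
# first-order non-enzymatic decay shared by experimental and control wells,
# with a hard floor at zero. OD = epsilon * path_length * C + baseline,
# plus i.i.d. Gaussian read noise. Control wells have v_enz = 0.

#' Simulation parameters for one well
#'
#' @param v_enz Enzymatic 4-NTP consumption rate, mol L^-1 min^-1 (0 in
#'   control wells). A raw activity of `r` pmol/min in a 1e-4 L well
#'   corresponds to `v_enz = r * 1e-12 / 1e-4`.
#' @param k_bg First-order non-enzymatic decay rate, min^-1.
#' @param c0 Initial 4-NTP concentration, mol/L. Default 200e-6 (200 µM).
#' @param baseline Additive OD offset.
#' @param noise_sd Read-noise standard deviation in OD units. Default 0.002
#'   (2 mOD, a typical plate-reader read-noise scale).
#' @param path_length Optical path length in cm. Default 1.
#' @param duration Run length, minutes. Default 60.
#' @param cadence Read interval, minutes. Default 1.
#' @param seed Integer seed; identical seeds give bit-identical traces.
#'   `NULL` uses the current RNG state.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(v_enz = 0, k_bg = 0, c0 = 200e-6, baseline = 0,
                     noise_sd = 0.002, path_length = 1,
                     duration = 60, cadence = 1, seed = NULL) {
  if (v_enz < 0 || k_bg < 0 || noise_sd < 0) {
    stop_domain("v_enz, k_bg and noise_sd must be >= 0")
  }
  if (c0 <= 0 || path_length <= 0 || duration <= 0 || cadence <= 0) {
    stop_domain("c0, path_length, duration and cadence must be > 0")
  }
  structure(
    list(v_enz = v_enz, k_bg = k_bg, c0 = c0, baseline = baseline,
         noise_sd = noise_sd, path_length = path_length,
         duration = duration, cadence = cadence, seed = seed),
    class = "sim_spec"
  )
}

# exact per-step integral of dC/dt = -k*C - v with floor at 0
step_concentration <- function(c, dt, v, k) {
  if (c <= 0) return(0)
  cn <- if (k > 0) {
    (c + v / k) * exp(-k * dt) - v / k
  } else {
    c - v * dt
  }
  max(cn, 0)
}

#' Simulate one well's kinetic trace
#'
#' Integrates the concentration model on the read grid (exact step solution
#' with a floor at zero) and converts to OD via the Beer-Lambert law.
#' Deterministic when `noise_sd = 0`; otherwise additive i.i.d. Gaussian
#' noise from the seeded generator.
#'
#' @param spec A [sim_spec()].
#' @param constants An [assay_constants()] supplying the extinction
#'   coefficient.
#' @return A tibble with columns `time_min`, `od411`.
#' @examples
#' simulate_trace(sim_spec(noise_sd = 0))  # constant OD 2.73
#' @export
simulate_trace <- function(spec, constants = assay_constants()) {
  stopifnot(inherits(spec, "sim_spec"), inherits(constants, "assay_constants"))
  times <- seq(0, spec$duration, by = spec$cadence)
  conc <- numeric(length(times))
  conc[1] <- spec$c0
  for (i in seq_along(times)[-1]) {
    conc[i] <- step_concentration(conc[i - 1], times[i] - times[i - 1],
                                  spec$v_enz, spec$k_bg)
  }
  od <- constants$epsilon * spec$path_length * conc + spec$baseline
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    od <- od + stats::rnorm(length(od), sd = spec$noise_sd)
  }
  tibble::tibble(time_min = times, od411 = od)
}

#' Design a synthetic plate
#'
#' Lays out samples in the standard formats: `"12-sample"` gives 4
#' experimental + 4 control wells per sample (one column each, rows A-D
#' experimental, E-H control); `"24-sample"` gives 2 + 2 (half columns).
#' Control wells share `k_bg`, `c0`, `baseline` and `noise_sd` with their
#' experimental counterparts and have zero enzymatic rate.
#'
#' @param samples Data frame with columns `sample_id` and
#'   `true_raw_pmol_per_min` (per-well enzymatic activity), plus optional
#'   [sample_spec()] columns (`category`, `sample_mass`, `buffer_volume`,
#'   `aliquot`, `dilution_factor`).
#' @param template `"12-sample"` or `"24-sample"`.
#' @param k_bg,c0,baseline,noise_sd Shared generative parameters, see
#'   [sim_spec()].
#' @param duration,cadence Read schedule in minutes.
#' @return An object of class `plate_design`.
#' @export
plate_design <- function(samples, template = c("12-sample", "24-sample"),
                         k_bg = 0, c0 = 200e-6, baseline = 0,
                         noise_sd = 0.002, duration = 60, cadence = 1) {
  template <- match.arg(template)
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "true_raw_pmol_per_min") %in% names(samples))) {
    stop_domain("samples need columns sample_id and true_raw_pmol_per_min")
  }
  if (anyDuplicated(samples$sample_id)) stop_domain("duplicate sample_id")
  if (any(samples$true_raw_pmol_per_min < 0)) {
    stop_domain("true_raw_pmol_per_min must be >= 0")
  }
  capacity <- if (template == "12-sample") 12L else 24L
  if (nrow(samples) > capacity) {
    stop_domain(sprintf("%s template holds at most %d samples (96 wells)",
                        template, capacity))
  }
  defaults <- list(category = "supernatant", sample_mass = 1,
                   buffer_volume = 0, aliquot = 0.003, dilution_factor = 1)
  for (f in names(defaults)) {
    if (!f %in% names(samples)) samples[[f]] <- defaults[[f]]
  }
  structure(
    list(samples = samples, template = template, k_bg = k_bg, c0 = c0,
         baseline = baseline, noise_sd = noise_sd,
         duration = duration, cadence = cadence),
    class = "plate_design"
  )
}

template_wells <- function(template, n_samples, replicates_each) {
  rows <- LETTERS[1:8]
  lapply(seq_len(n_samples), function(i) {
    if (template == "12-sample") {
      col <- i
      list(exp = paste0(rows[1:4], col), ctrl = paste0(rows[5:8], col))
    } else {
      col <- ceiling(i / 2)
      half <- if (i %% 2 == 1) 1:4 else 5:8
      list(exp = paste0(rows[half[1:2]], col),
           ctrl = paste0(rows[half[3:4]], col))
    }
  })
}

#' Simulate a full plate with known ground truth
#'
#' Places each sample's wells deterministically from the template, derives
#' one RNG substream seed per well from the master seed, simulates every
#' trace, and returns the plate alongside its layout and a ground-truth
#' table. The same seed always reproduces the same plate bit-for-bit.
#'
#' @param design A [plate_design()].
#' @param seed Master integer seed.
#' @param constants An [assay_constants()].
#' @return A list: `series` ([plate_timeseries()]), `layout`
#'   ([plate_layout()]), `truth` (tibble: `sample_id`,
#'   `true_raw_pmol_per_min`, `true_specific_activity`).
#' @export
simulate_plate <- function(design, seed = 1, constants = assay_constants()) {
  stopifnot(inherits(design, "plate_design"))
  n <- nrow(design$samples)
  placement <- template_wells(design$template, n)
  set.seed(seed)
  # independent substream seed per well, derived once from the master seed
  all_wells <- unlist(placement)
  well_seeds <- sample.int(2147483646L, length(all_wells))
  names(well_seeds) <- all_wells

  assignments <- list()
  traces <- list()
  specs <- list()
  for (i in seq_len(n)) {
    s <- design$samples[i, ]
    v_enz <- s$true_raw_pmol_per_min * 1e-12 / constants$reaction_volume
    for (role in c("exp", "ctrl")) {
      wells <- placement[[i]][[role]]
      for (w in wells) {
        ts <- simulate_trace(sim_spec(
          v_enz = if (role == "exp") v_enz else 0,
          k_bg = design$k_bg, c0 = design$c0, baseline = design$baseline,
          noise_sd = design$noise_sd, duration = design$duration,
          cadence = design$cadence, seed = well_seeds[[w]]), constants)
        traces[[w]] <- ts$od411
      }
      assignments[[length(assignments) + 1]] <- data.frame(
        well = wells, sample_id = s$sample_id,
        role = if (role == "exp") "experimental" else "control",
        stringsAsFactors = FALSE)
    }
    specs[[s$sample_id]] <- sample_spec(
      s$sample_id, category = s$category, sample_mass = s$sample_mass,
      buffer_volume = s$buffer_volume, aliquot = s$aliquot,
      dilution_factor = s$dilution_factor)
  }
  times <- seq(0, design$duration, by = design$cadence)
  m <- do.call(rbind, traces)
  rownames(m) <- names(traces)
  series <- plate_timeseries(m, times,
                             plate_id = sprintf("sim_seed%d", seed),
                             pathlength_corrected = TRUE)
  layout <- plate_layout(do.call(rbind, assignments), specs)
  truth <- tibble::tibble(
    sample_id = design$samples$sample_id,
    true_raw_pmol_per_min = design$samples$true_raw_pmol_per_min,
    true_specific_activity = vapply(
      seq_len(n),
      function(i) to_specific_activity(
        design$samples$true_raw_pmol_per_min[i],
        specs[[design$samples$sample_id[i]]]),
      numeric(1))
  )
  list(series = series, layout = layout, truth = truth)
}

#' Specs for a 1:1 serial-dilution series
#'
#' Scales the enzymatic rate of a base condition by `ratio^-k` for
#' k = 1..`n_dilutions`, matching a serial dilution that starts at the first
#' 1:1 dilution of the undiluted material. True raw activity scales with the
#' dilution fraction.
#'
#' @param base A [sim_spec()] describing the undiluted material's well.
#' @param n_dilutions Number of dilution steps. Default 9.
#' @param ratio Dilution ratio per step. Default 2 (1:1 with buffer).
#' @return A tibble with columns `step`, `dilution` (fraction) and a
#'   list column `spec` of [sim_spec()] objects.
#' @export
simulate_dilution_series <- function(base, n_dilutions = 9, ratio = 2) {
  stopifnot(inherits(base, "sim_spec"))
  if (ratio < 1) stop_domain("ratio must be >= 1")
  if (ratio == 1) warning("ratio 1 gives a degenerate series (no dilution)")
  k <- seq_len(n_dilutions)
  frac <- ratio^-k
  specs <- lapply(frac, function(f) {
    s <- base
    s$v_enz <- base$v_enz * f
    s
  })
  tibble::tibble(step = k, dilution = frac, spec = specs)
}
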