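# Sliding-window maximum-velocity estimation.
#
# 4-NTP disappears as thiaminase I consumes it, so the signed OD slope is
# negative where the enzyme is active; the assay's "maximum velocity" is the
# largest rate of OD decrease over any full window (default 10 min) of the
# kinetic read, i.e. minus the most negative windowed slope, in mOD/min.

TIME_EPS <- 1e-9

#' Windowed slopes of one well's kinetic trace
#'
#' Enumerates every window of length `window_length` whose closed interval
#' `[t0, t0 + window_length]` fits inside the run, one window per observed
#' time point `t0`, and returns the slope of OD on time over the readings in
#' that interval.
#'
#' @param time Read times, minutes, strictly increasing.
#' @param od Absorbance readings, same length as `time`.
#' @param window_length Window length in minutes (default 10).
#' @param method Slope estimator: `"ols"` (least-squares over all readings in
#'   the window, default) or `"endpoint"` (two-point difference between the
#'   window's first and last readings).
#' @return A tibble with one row per eligible window: `window_start`,
#'   `slope` (signed, OD/min) and `n_points`.
#' @examples
#' window_slopes(0:60, 1 - 0.001 * (0:60))
#' @export
window_slopes <- function(time, od, window_length = 10,
                          method = c("ols", "endpoint")) {
  method <- match.arg(method)
  time <- as.numeric(time)
  od <- as.numeric(od)
  if (length(time) != length(od) || length(time) < 2) {
    stop_domain("trace needs matching time/od vectors with >= 2 readings")
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop_domain("trace times must be strictly increasing")
  }
  if (!is.finite(window_length) || window_length <= 0) {
    stop_domain("window_length must be > 0")
  }
  t_max <- time[length(time)]
  starts <- time[time + window_length <= t_max + TIME_EPS]

  # fast path: evenly spaced grid with the window an exact multiple of the
  # cadence -- every window holds the same k+1 readings
  dt <- diff(time)
  if (method == "ols" && length(starts) > 0 &&
      max(dt) - min(dt) < TIME_EPS) {
    k <- round(window_length / dt[1])
    if (abs(k * dt[1] - window_length) < TIME_EPS && k >= 1 &&
        k + 1 <= length(time)) {
      tc <- (seq_len(k + 1) - 1 - k / 2) * dt[1]
      # stats::embed row i holds od[i+k], od[i+k-1], ..., od[i]
      slopes <- drop(stats::embed(od, k + 1) %*% rev(tc)) / sum(tc * tc)
      return(tibble::tibble(window_start = time[seq_along(slopes)],
                            slope = slopes,
                            n_points = rep(k + 1L, length(slopes))))
    }
  }

  # a full window also needs >= 2 readings actually spanning it
  keep <- logical(length(starts))
  slope <- numeric(length(starts))
  npts <- integer(length(starts))
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    idx <- which(time >= t0 - TIME_EPS & time <= t0 + window_length + TIME_EPS)
    if (length(idx) < 2) next
    keep[i] <- TRUE
    npts[i] <- length(idx)
    tt <- time[idx]
    yy <- od[idx]
    slope[i] <- if (method == "ols") {
      tc <- tt - mean(tt)
      sum(tc * yy) / sum(tc * tc)
    } else {
      (yy[length(yy)] - yy[1]) / (tt[length(tt)] - tt[1])
    }
  }
  if (!any(keep)) {
    stop_domain(sprintf(
      "no full %g-min window fits in the %g-min run", window_length,
      t_max - time[1]))
  }
  tibble::tibble(window_start = starts[keep], slope = slope[keep],
                 n_points = npts[keep])
}

#' Maximum 4-NTP degradation velocity of one trace
#'
#' The velocity of 4-NTP degradation is the negative of the signed OD slope,
#' so the maximum velocity corresponds to the most negative windowed slope.
#' Ties are broken in favour of the earliest window start (the largest rates
#' are typically seen early in the run). A monotonically rising trace yields
#' a negative `vmax`.
#'
#' @inheritParams window_slopes
#' @return A one-row tibble: `vmax` (mOD/min, = -1000 x winning slope),
#'   `window_start` (min), `window_slope_raw` (signed OD/min), `n_points`.
#' @examples
#' max_velocity(0:60, 1 - 6.6e-4 * (0:60))  # vmax 0.66 mOD/min
#' @export
max_velocity <- function(time, od, window_length = 10,
                         method = c("ols", "endpoint")) {
  ws <- window_slopes(time, od, window_length, method)
  m <- min(ws$slope)
  tol <- max(1e-12, abs(m) * 1e-9)
  i <- which(ws$slope <= m + tol)[[1]]
  tibble::tibble(
    vmax = -1000 * ws$slope[i],
    window_start = ws$window_start[i],
    window_slope_raw = ws$slope[i],
    n_points = ws$n_points[i]
  )
}

#' Flag likely substrate depletion
#'
#' Wells that consume most of their 4-NTP during the run violate the
#' assay's near-linear-phase assumption; such samples should be re-assayed
#' at higher dilution. The flag fires when the fractional OD loss over the
#' whole run reaches `depletion_fraction`.
#'
#' @param od Absorbance trace (time order).
#' @param depletion_fraction Fractional loss threshold, default 0.8.
#' @return Logical scalar.
#' @export
flag_substrate_depletion <- function(od, depletion_fraction = 0.8) {
  od <- as.numeric(od)
  if (length(od) == 0) stop_domain("empty trace")
  (od[1] - od[length(od)]) / max(od[1], .Machine$double.eps) >=
    depletion_fraction
}

#' Per-well maximum velocities for a whole plate
#'
#' @param series A [plate_timeseries()].
#' @param window_length Window length in minutes.
#' @param method Slope estimator, see [window_slopes()].
#' @param depletion_fraction Threshold for [flag_substrate_depletion()].
#' @return A tibble with one row per well: `well`, `vmax_mOD_per_min`,
#'   `window_start_min`, `window_slope_raw`, `n_points`, `depletion_flag`.
#' @export
well_velocities <- function(series, window_length = 10,
                            method = c("ols", "endpoint"),
                            depletion_fraction = 0.8) {
  stopifnot(inherits(series, "plate_ts"))
  method <- match.arg(method)
  rows <- lapply(series$wells, function(w) {
    od <- series$absorbance[w, ]
    mv <- max_velocity(series$times, od, window_length, method)
    tibble::tibble(
      well = w,
      vmax_mOD_per_min = mv$vmax,
      window_start_min = mv$window_start,
      window_slope_raw = mv$window_slope_raw,
      n_points = mv$n_points,
      depletion_flag = flag_substrate_depletion(od, depletion_fraction)
    )
  })
  dplyr::bind_rows(rows)
}

#' Group per-well velocities by sample and form net velocities
#'
#' Averages maximum velocities over replicate wells within each arm, then
#' subtracts the control-well mean (non-enzymatic 4-NTP decay) from the
#' experimental-well mean. Negative net velocities are retained here;
#' clipping to zero happens at gating.
#'
#' @param well_tbl Output of [well_velocities()] (or any tibble with columns
#'   `well`, `vmax_mOD_per_min`, `depletion_flag`).
#' @param layout A [plate_layout()]; every assigned well must appear in
#'   `well_tbl`.
#' @return A tibble ordered by `sample_id`, one row per sample:
#'   `n_exp`, `n_ctrl`, `mean_exp`, `mean_ctrl`, `net_mOD_per_min`,
#'   `depletion_flagged` (any experimental well flagged), and list columns
#'   `exp_vmax`, `ctrl_vmax` holding the per-well values for gating.
#' @export
group_velocities <- function(well_tbl, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  missing <- setdiff(layout$assignments$well, well_tbl$well)
  if (length(missing) > 0) {
    stop_consistency(sprintf(
      "assigned well %s has no velocity estimate", missing[[1]]))
  }
  joined <- dplyr::inner_join(layout$assignments, well_tbl, by = "well")
  rows <- lapply(sort(unique(joined$sample_id)), function(sid) {
    g <- joined[joined$sample_id == sid, ]
    ev <- g$vmax_mOD_per_min[g$role == "experimental"]
    cv <- g$vmax_mOD_per_min[g$role == "control"]
    tibble::tibble(
      sample_id = sid,
      n_exp = length(ev),
      n_ctrl = length(cv),
      mean_exp = mean(ev),
      mean_ctrl = mean(cv),
      net_mOD_per_min = mean(ev) - mean(cv),
      depletion_flagged = any(g$depletion_flag[g$role == "experimental"]),
      exp_vmax = list(ev),
      ctrl_vmax = list(cv)
    )
  })
  dplyr::bind_rows(rows)
}
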