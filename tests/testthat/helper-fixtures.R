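# Shared fixtures and independent oracles, all built in code.

# Brute-force maximum-velocity oracle: enumerate every observed time point
# admitting a full closed window and fit a textbook OLS slope with stats::lm.
# Independent of the package's windowing/slope code path.
oracle_max_velocity <- function(time, od, window_length) {
  t_max <- max(time)
  starts <- time[time + window_length <= t_max + 1e-9]
  best <- NULL
  for (t0 in starts) {
    idx <- which(time >= t0 - 1e-9 & time <= t0 + window_length + 1e-9)
    if (length(idx) < 2) next
    sl <- unname(stats::coef(
      stats::lm(y ~ t, data.frame(t = time[idx], y = od[idx])))[2])
    if (is.null(best) || sl < best$slope - 1e-15) {
      best <- list(slope = sl, start = t0, n = length(idx))
    }
  }
  list(vmax = -1000 * best$slope, window_start = best$start,
       n_points = best$n)
}

# random kinetic-looking trace (drifting walk around a decaying baseline)
random_trace <- function(n = 31, cadence = 1, irregular = FALSE) {
  time <- seq(0, by = cadence, length.out = n)
  if (irregular) {
    time <- sort(sample(seq(0, 3 * n), n))
  }
  od <- 2.7 * exp(-0.003 * time) - 0.002 * time +
    cumsum(stats::rnorm(n, 0, 0.01))
  list(time = time, od = od)
}

# minimal 1-sample layout: wells A1..A4 experimental, B1..B4 control
mini_layout <- function(spec = sample_spec("S1", "supernatant"),
                        n = 4) {
  plate_layout(
    data.frame(
      well = c(paste0("A", 1:n), paste0("B", 1:n)),
      sample_id = "S1",
      role = rep(c("experimental", "control"), each = n)),
    list(S1 = spec))
}

# small deterministic plate: two wells, linear decline vs constant
mini_series <- function(slope_mOD = 2, times = 0:60) {
  m <- rbind(
    A1 = 2.73 - slope_mOD / 1000 * times,
    B1 = rep(2.73, length(times)))
  plate_timeseries(m, times, plate_id = "mini", pathlength_corrected = TRUE)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
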