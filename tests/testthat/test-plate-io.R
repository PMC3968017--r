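test_that("long dialect parses a constant table and preserves every reading", {
  f <- write_lines_tmp(c(
    "well\ttime_min\tod411",
    paste(rep(c("A1", "A2"), each = 3), rep(0:2, 2), 0.5, sep = "\t")))
  ts <- read_plate_timeseries(f, "long", quiet = TRUE)
  expect_setequal(ts$wells, c("A1", "A2"))
  expect_equal(ts$times, c(0, 1, 2))
  expect_equal(as.vector(ts$absorbance), rep(0.5, 6))
})

test_that("wide dialect handles the standard 61-read, multi-well export", {
  wells <- paste0(LETTERS[1:8], 1)
  lines <- c(paste(c("time_min", wells), collapse = ","),
             sapply(0:60, function(t)
               paste(c(t, round(2.7 - 0.001 * t + seq_len(8) / 100, 6)),
                     collapse = ",")))
  ts <- read_plate_timeseries(write_lines_tmp(lines, ".csv"), "wide",
                              quiet = TRUE)
  expect_length(ts$times, 61)
  expect_length(ts$wells, 8)
  expect_equal(unname(ts$absorbance["C1", 1]), 2.73)
})

test_that("ragged grids and malformed values raise structured parse errors", {
  lines <- c("well\ttime_min\tod411",
             paste("A1", c(0, 1, 3), 0.5, sep = "\t"),   # missing t = 2
             paste("A2", 0:3, 0.5, sep = "\t"))
  expect_error(read_plate_timeseries(write_lines_tmp(lines), "long",
                                     quiet = TRUE),
               "A1.*time 2", class = "ntp_parse_error")

  dup <- c("well\ttime_min\tod411", "A1\t0\t0.5", "A1\t0\t0.6",
           "A1\t1\t0.5")
  expect_error(read_plate_timeseries(write_lines_tmp(dup), "long",
                                     quiet = TRUE),
               "duplicate", class = "ntp_parse_error")

  bad <- c("well\ttime_min\tod411", "A1\t0\t0.5", "A1\t1\toops")
  expect_error(read_plate_timeseries(write_lines_tmp(bad), "long",
                                     quiet = TRUE),
               "non-numeric.*row 2", class = "ntp_parse_error")
})

test_that("well addresses are normalised and validated", {
  f <- write_lines_tmp(c("well\ttime_min\tod411",
                         "a1\t0\t0.5", "a1\t1\t0.5"))
  expect_equal(read_plate_timeseries(f, "long", quiet = TRUE)$wells, "A1")
  f2 <- write_lines_tmp(c("well\ttime_min\tod411", "Z1\t0\t0.5"))
  expect_error(read_plate_timeseries(f2, "long", quiet = TRUE),
               "invalid well", class = "ntp_parse_error")
})

test_that("negative readings are permitted but counted", {
  m <- rbind(A1 = c(0.1, -0.02, 0.05))
  ts <- plate_timeseries(m, 0:2)
  expect_equal(ts$n_negative, 1)
})

test_that("write-then-read round trip is bit-exact in both dialects", {
  set.seed(42)
  des <- plate_design(
    data.frame(sample_id = c("A", "B"),
               true_raw_pmol_per_min = c(50, 7)),
    noise_sd = 0.002)
  sim <- simulate_plate(des, seed = 42)
  for (dialect in c("wide", "long")) {
    f <- tempfile()
    write_plate_timeseries(sim$series, f, dialect)
    back <- read_plate_timeseries(f, dialect, quiet = TRUE)
    expect_identical(back$absorbance, sim$series$absorbance)
    expect_identical(back$times, sim$series$times)
  }
})

test_that("the same plate serialised wide and long parses identically", {
  set.seed(7)
  m <- matrix(rnorm(5 * 13, 2, 0.5), nrow = 5,
              dimnames = list(c("A1", "B2", "C3", "D4", "H12"), NULL))
  ts <- plate_timeseries(m, seq(0, 24, by = 2))
  fw <- tempfile(); fl <- tempfile()
  write_plate_timeseries(ts, fw, "wide")
  write_plate_timeseries(ts, fl, "long")
  w <- read_plate_timeseries(fw, "wide", quiet = TRUE)
  l <- read_plate_timeseries(fl, "long", quiet = TRUE)
  expect_identical(w$absorbance, l$absorbance)
  expect_identical(w$times, l$times)
})

test_that("path-length correction divides by the factor exactly once", {
  m <- rbind(A1 = c(0.29, 0.58), B1 = c(1, 2))
  ts <- plate_timeseries(m, 0:1, pathlength_corrected = FALSE)

  id <- apply_pathlength_correction(ts, 1.0)
  expect_identical(id$absorbance, ts$absorbance)
  expect_true(id$pathlength_corrected)

  corr <- apply_pathlength_correction(ts, 0.29)
  expect_equal(unname(corr$absorbance["A1", 1]), 1.0)
  expect_equal(corr$absorbance, ts$absorbance / 0.29)

  expect_error(apply_pathlength_correction(corr, 0.29),
               "already", class = "ntp_state_error")
  expect_error(apply_pathlength_correction(ts, 0),
               class = "ntp_domain_error")
  expect_error(apply_pathlength_correction(ts, -1),
               class = "ntp_domain_error")
})

test_that("per-well path lengths are matched by well name", {
  m <- rbind(A1 = c(1, 1), B1 = c(1, 1))
  ts <- plate_timeseries(m, 0:1, pathlength_corrected = FALSE)
  corr <- apply_pathlength_correction(ts, c(B1 = 0.5, A1 = 2))
  expect_equal(unname(corr$absorbance["A1", ]), c(0.5, 0.5))
  expect_equal(unname(corr$absorbance["B1", ]), c(2, 2))
  expect_error(apply_pathlength_correction(ts, c(A1 = 1)),
               class = "ntp_domain_error")
})
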