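test_that("a quiescent well sits at the Beer-Lambert plateau OD 2.73", {
  tr <- simulate_trace(sim_spec(v_enz = 0, k_bg = 0, noise_sd = 0))
  expect_equal(tr$od411, rep(13650 * 200e-6, 61))   # = 2.73
  expect_equal(tr$time_min, as.numeric(0:60))
})

test_that("zero-order enzymatic consumption declines at the floor-equivalent rate", {
  # 4.84e-8 M/min in 1e-4 L is 4.84 pmol/min
  tr <- simulate_trace(sim_spec(v_enz = 4.84e-8, noise_sd = 0))
  mv <- max_velocity(tr$time_min, tr$od411, 10)
  expect_equal(mv$vmax, 0.6607, tolerance = 1e-3)   # 13650 * 4.84e-8 * 1000
  slopes <- diff(tr$od411)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)  # linear
})

test_that("pure background decay is exponential with its steepest window first", {
  tr <- simulate_trace(sim_spec(v_enz = 0, k_bg = 0.01, noise_sd = 0))
  expect_equal(tr$od411, 2.73 * exp(-0.01 * tr$time_min), tolerance = 1e-9)
  mv <- max_velocity(tr$time_min, tr$od411, 10)
  expect_equal(mv$window_start, 0)
})

test_that("concentration floors at zero once the substrate is exhausted", {
  tr <- simulate_trace(sim_spec(v_enz = 1e-5, noise_sd = 0))  # gone by ~20 min
  expect_equal(tr$od411[61], 0)
  expect_true(all(tr$od411 >= 0))
  expect_true(flag_substrate_depletion(tr$od411))
})

test_that("the same seed reproduces a trace and a plate bit-for-bit", {
  s <- sim_spec(v_enz = 2e-8, k_bg = 0.002, noise_sd = 0.002, seed = 99)
  expect_identical(simulate_trace(s), simulate_trace(s))

  des <- plate_design(
    data.frame(sample_id = c("A", "B"), true_raw_pmol_per_min = c(10, 100)))
  p1 <- simulate_plate(des, seed = 7)
  p2 <- simulate_plate(des, seed = 7)
  expect_identical(p1$series$absorbance, p2$series$absorbance)
  expect_identical(p1$layout$assignments, p2$layout$assignments)
  p3 <- simulate_plate(des, seed = 8)
  expect_false(identical(p1$series$absorbance, p3$series$absorbance))
  expect_identical(p1$layout$assignments, p3$layout$assignments)
})

test_that("the 12-sample template fills 96 wells with 4+4 replicates", {
  des <- plate_design(
    data.frame(sample_id = sprintf("S%02d", 1:12),
               true_raw_pmol_per_min = seq(0, 110, by = 10)),
    template = "12-sample")
  sim <- simulate_plate(des, seed = 1)
  expect_length(sim$series$wells, 96)
  counts <- table(sim$layout$assignments$sample_id,
                  sim$layout$assignments$role)
  expect_true(all(counts[, "experimental"] == 4))
  expect_true(all(counts[, "control"] == 4))
})

test_that("the 24-sample template provides duplicates of each arm", {
  des <- plate_design(
    data.frame(sample_id = sprintf("S%02d", 1:24),
               true_raw_pmol_per_min = rep(50, 24)),
    template = "24-sample")
  sim <- simulate_plate(des, seed = 1)
  expect_length(sim$series$wells, 96)
  counts <- table(sim$layout$assignments$sample_id,
                  sim$layout$assignments$role)
  expect_true(all(counts == 2))
})

test_that("requesting more samples than the plate holds is a capacity error", {
  expect_error(plate_design(
    data.frame(sample_id = paste0("S", 1:13),
               true_raw_pmol_per_min = rep(1, 13)),
    template = "12-sample"),
    "at most", class = "ntp_domain_error")
})

test_that("serial dilution specs scale the enzymatic rate geometrically", {
  base <- sim_spec(v_enz = 1e-6)
  ser <- simulate_dilution_series(base, n_dilutions = 9, ratio = 2)
  expect_equal(ser$dilution, 2^-(1:9))   # 1/2 .. 1/512
  v <- vapply(ser$spec, function(s) s$v_enz, numeric(1))
  expect_equal(v, 1e-6 * 2^-(1:9))
  expect_warning(simulate_dilution_series(base, 3, ratio = 1), "degenerate")
})

test_that("noiseless plates recover true raw activity to well under 0.5%", {
  des <- plate_design(
    data.frame(sample_id = c("lo", "mid", "hi"),
               true_raw_pmol_per_min = c(30, 120, 480)),
    noise_sd = 0)
  sim <- simulate_plate(des, seed = 3)
  run <- run_assay(sim$series, sim$layout)
  merged <- merge(run$samples, sim$truth, by = "sample_id")
  rel <- abs(merged$raw_pmol_per_min - merged$true_raw_pmol_per_min) /
    merged$true_raw_pmol_per_min
  expect_true(all(rel <= 0.005))
})

test_that("matched background decay cancels in the net velocity", {
  # v_enz = 0 in both arms, shared k_bg: expected net is 0; check the
  # empirical mean over many seeded replicates against its standard error
  n <- 500
  set.seed(2024)
  seeds <- sample.int(2147483646L, n * 4)
  dim(seeds) <- c(n, 4)
  base <- sim_spec(v_enz = 0, k_bg = 0.002, noise_sd = 0.002)
  nets <- vapply(seq_len(n), function(i) {
    vm <- vapply(1:4, function(j) {
      s <- base; s$seed <- seeds[i, j]
      tr <- simulate_trace(s)
      max_velocity(tr$time_min, tr$od411, 10)$vmax
    }, numeric(1))
    mean(vm[1:2]) - mean(vm[3:4])
  }, numeric(1))
  se <- stats::sd(nets) / sqrt(n)
  expect_lt(abs(mean(nets)), 3 * se)
})

test_that("substrate exhaustion flags depletion and understates true activity", {
  # true raw 5000 pmol/min empties 200 uM in 4 min: far into depletion
  des <- plate_design(
    data.frame(sample_id = "hot", true_raw_pmol_per_min = 5000),
    noise_sd = 0)
  sim <- simulate_plate(des, seed = 2)
  run <- run_assay(sim$series, sim$layout)
  expect_true(run$samples$depletion_flag)
  expect_lt(run$samples$raw_pmol_per_min,
            sim$truth$true_raw_pmol_per_min)
})
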