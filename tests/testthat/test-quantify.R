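test_that("Beer-Lambert conversion maps mOD rates to pmol/min and back", {
  expect_equal(od_rate_to_raw_activity(0.66), 4.8352, tolerance = 1e-4)
  expect_equal(od_rate_to_raw_activity(0), 0)
  # hand arithmetic: 0.073 OD/min / 13650 * 1e-4 L = 534.8 pmol/min
  expect_equal(od_rate_to_raw_activity(73.0), 534.8, tolerance = 1e-3)
  # sign preserved
  expect_lt(od_rate_to_raw_activity(-0.5), 0)
})

test_that("conversion and its inverse compose to the identity", {
  set.seed(5)
  x <- c(0, runif(50, -10, 600))
  expect_equal(raw_activity_to_od_rate(od_rate_to_raw_activity(x)), x,
               tolerance = 1e-12)
  consts <- assay_constants(epsilon = 9000, reaction_volume = 2e-4)
  expect_equal(
    od_rate_to_raw_activity(raw_activity_to_od_rate(x, consts), consts), x,
    tolerance = 1e-12)
})

test_that("the gate routes activities through floor, test band and accept tiers", {
  ev <- c(0.9, 0.95, 1.0, 0.92)
  cv <- c(0.88, 0.93, 0.99, 0.90)

  below <- gate_activity(4.0, ev, cv)
  expect_equal(below$gate, "below_floor")
  expect_equal(below$reported_raw, 0)
  expect_true(is.na(below$p_value))

  neg <- gate_activity(-2, ev, cv)
  expect_equal(neg$gate, "negative_net")
  expect_equal(neg$reported_raw, 0)

  # overlapping arms: Welch oracle confirms no significant difference
  p_oracle <- stats::t.test(ev, cv)$p.value
  expect_gt(p_oracle, 0.05)
  tested <- gate_activity(10.0, ev, cv)
  expect_equal(tested$gate, "tested_fail")
  expect_equal(tested$reported_raw, 0)
  expect_equal(tested$p_value, p_oracle)

  # clearly separated arms pass
  sep <- gate_activity(10.0, ev + 1.5, cv)
  expect_equal(sep$gate, "tested_pass")
  expect_equal(sep$reported_raw, 10.0)

  above <- gate_activity(30.0, ev, cv)
  expect_equal(above$gate, "above_band")
  expect_equal(above$reported_raw, 30.0)
  expect_true(is.na(above$p_value))
})

test_that("student variant uses the pooled-variance test", {
  ev <- c(1.2, 1.4, 1.1, 1.3); cv <- c(0.2, 0.4, 0.3, 0.25)
  g <- gate_activity(10, ev, cv, gating_policy(test_variant = "student"))
  expect_equal(g$p_value, stats::t.test(ev, cv, var.equal = TRUE)$p.value)
})

test_that("in-band samples with singleton arms are untestable and reported zero", {
  expect_warning(g <- gate_activity(10, 1.0, c(0.2, 0.3)), "untestable")
  expect_equal(g$gate, "untestable")
  expect_equal(g$reported_raw, 0)
  # outside the band, singleton arms are fine
  expect_silent(expect_equal(gate_activity(30, 1.0, 0.2)$gate, "above_band"))
})

test_that("increasing raw activity never flips a reported value back to zero", {
  ev <- c(1.2, 1.4, 1.1, 1.3); cv <- c(0.2, 0.4, 0.3, 0.25)  # passes the test
  raws <- c(0.5, 2, 4.8, 4.81, 10, 25, 25.1, 100)
  rep_seq <- vapply(raws, function(r)
    gate_activity(r, ev, cv)$reported_raw, numeric(1))
  reported <- rep_seq > 0
  expect_true(all(diff(reported) >= 0))    # once reported, stays reported
  # with failing wells the band reports zero but above_band still accepts
  ev2 <- c(0.9, 0.95, 1.0, 0.92); cv2 <- c(0.88, 0.93, 0.99, 0.90)
  rep2 <- vapply(raws, function(r)
    gate_activity(r, ev2, cv2)$reported_raw, numeric(1))
  expect_equal(rep2[raws <= 25], rep(0, sum(raws <= 25)))
  expect_equal(rep2[raws > 25], raws[raws > 25])
})

test_that("specific activity reproduces the printed conversion factors", {
  sup <- sample_spec("sup", "supernatant")
  expect_equal(to_specific_activity(4.8, sup), 1.6)   # (0.003 ml)^-1
  tis <- sample_spec("t", "tissue", sample_mass = 1, buffer_volume = 2.5)
  expect_equal(to_specific_activity(4.8, tis), 5.6)   # ([1/3.5] * 0.003)^-1
  expect_equal(to_specific_activity(0, tis), 0)
  expect_equal(to_specific_activity(0, sup), 0)
})

test_that("specific activity is exactly linear in raw activity and dilution factor", {
  tis <- sample_spec("t", "tissue", sample_mass = 0.7, buffer_volume = 1.4)
  base <- to_specific_activity(10, tis)
  expect_equal(to_specific_activity(30, tis), 3 * base)
  tis16 <- sample_spec("t", "tissue", sample_mass = 0.7, buffer_volume = 1.4,
                       dilution_factor = 16)
  expect_equal(to_specific_activity(10, tis16), 16 * base)
})

test_that("a noiseless proportional dilution series fits with slope exactly 1", {
  pts <- data.frame(dilution = 2^-(0:8), activity = 534 * 2^-(0:8))
  fit <- analyze_dilution_series(pts)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_true(all(fit$points$proportional))
  expect_equal(fit$last_proportional_dilution, 1 / 256)
  expect_equal(fit$detection_limit_activity, 534 / 256)
})

test_that("points below the volumetric floor are excluded as undetectable", {
  pts <- data.frame(dilution = 2^-(0:9), activity = 534 * 2^-(0:9))
  fit <- analyze_dilution_series(pts)
  # 534/512 = 1.04 < 1.6: nominal activity below the detection floor
  expect_false(fit$points$detectable[fit$points$dilution == 2^-9])
  expect_equal(sum(fit$points$detectable), 9)
  expect_equal(fit$last_proportional_dilution, 1 / 256)
})

test_that("a perturbed point falls outside tolerance without breaking the fit", {
  act <- 534 * 2^-(0:8)
  act[5] <- act[5] * 1.5
  fit <- analyze_dilution_series(
    data.frame(dilution = 2^-(0:8), activity = act))
  expect_false(fit$points$proportional[5])
  expect_true(all(fit$points$proportional[-5]))
  expect_equal(fit$slope, 1, tolerance = 0.1)
})

test_that("dilution series need at least three detectable points", {
  expect_error(
    analyze_dilution_series(
      data.frame(dilution = c(1, 0.5, 0.25), activity = c(10, 1, 0.1))),
    "too short", class = "ntp_domain_error")
  expect_error(
    analyze_dilution_series(
      data.frame(dilution = c(1, 1, 0.5), activity = c(10, 10, 5))),
    "distinct", class = "ntp_domain_error")
})
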