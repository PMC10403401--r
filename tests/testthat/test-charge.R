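# Ohm's law, charge integration, cutoff rule, calibration

test_that("current_from_voltage is Ohm's law", {
  expect_equal(current_from_voltage(0.5, 100), 0.005)
  expect_equal(current_from_voltage(0, 100), 0)
  expect_equal(current_from_voltage(2 * 0.37, 100),
               2 * current_from_voltage(0.37, 100))
  expect_error(current_from_voltage(1, 0), "must be > 0")
})

test_that("integrate_charge reproduces closed forms", {
  # constant 0.1 V for 1 h at 100 ohm: 1 mA * 3600 s = 3.6 C, rule-independent
  v_const <- rep(0.1, 13)
  expect_equal(integrate_charge(v_const, 100)$charge, 3.6)
  expect_equal(integrate_charge(v_const, 100, rule = "left_rectangle")$charge,
               3.6)
  # linear ramp 0.1 -> 0 V over 1 h: triangle area 1.8 C under the trapezoid
  v_ramp <- seq(0.1, 0, length.out = 13)
  expect_equal(integrate_charge(v_ramp, 100)$charge, 1.8)
  expect_warning(q0 <- integrate_charge(numeric(0), 100), "empty")
  expect_equal(q0$charge, 0)
  expect_error(integrate_charge(c(0.1, -0.1), 100), "negative")
})

test_that("charge is monotone in the voltage curve", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    lo <- runif(n, 0, 0.3)
    hi <- lo + runif(n, 0, 0.2)
    expect_gte(integrate_charge(hi, 100)$charge,
               integrate_charge(lo, 100)$charge)
  }
})

test_that("trailing zero-padding perturbs charge by at most one trapezoid", {
  set.seed(8)
  v <- runif(50, 0.05, 0.4)
  q <- integrate_charge(v, 100)$charge
  q_pad <- integrate_charge(c(v, rep(0, 200)), 100)$charge
  # only the junction trapezoid (last sample down to zero) can differ
  expect_lte(abs(q_pad - q), v[50] / 100 * 300 / 2 + 1e-12)
})

test_that("assemble_full_curve validates the length pairing", {
  full <- assemble_full_curve(rep(0.1, 289), rep(0.05, 1222))
  expect_length(full, 1511)
  expect_identical(full[1:289], rep(0.1, 289))  # observed passed through
  expect_length(assemble_full_curve(rep(0.1, 25), rep(0, 1486)), 1511)
  expect_error(assemble_full_curve(rep(0.1, 289), rep(0, 100)), "invalid")
  expect_error(assemble_full_curve(rep(0.1, 10), rep(0, 1501)), "invalid")
})

test_that("prediction cutoff discards from the first sub-threshold predicted sample", {
  n1 <- 289L
  curve <- c(rep(0.3, n1), rep(0.05, 1218), 0.02, 0.009, 0.05, 0.04)
  res <- apply_prediction_cutoff(curve, n1)
  expect_identical(res$cutoff_index, n1 + 1218L + 2L)
  expect_length(res$values, n1 + 1218L + 1L)      # trailing 0.05 discarded too
  # nothing below threshold: untouched
  res2 <- apply_prediction_cutoff(rep(0.3, 1511), n1)
  expect_identical(res2$cutoff_index, NA_integer_)
  expect_length(res2$values, 1511)
  # sub-threshold observed samples are never discarded
  curve3 <- c(rep(0.005, n1), rep(0.5, 1511 - n1))
  res3 <- apply_prediction_cutoff(curve3, n1)
  expect_identical(res3$cutoff_index, NA_integer_)
  # rise-phase low voltages never fire the cutoff: the curve must have
  # passed the 0.02 V depletion level first
  rise <- c(seq(0, 0.009, length.out = 400), seq(0.01, 0.5, length.out = 600),
            seq(0.5, 0.011, length.out = 511))
  res4 <- apply_prediction_cutoff(rise, n1)
  expect_identical(res4$cutoff_index, NA_integer_)
  fall <- c(seq(0, 0.009, length.out = 400), seq(0.01, 0.5, length.out = 600),
            seq(0.5, 0.005, length.out = 511))
  res5 <- apply_prediction_cutoff(fall, n1)
  expect_identical(res5$cutoff_index, 1000L + which(fall[1001:1511] < 0.01)[1])
})

test_that("fit_calibration solves exact lines and rejects degeneracy", {
  cal <- fit_calibration(c(1, 2, 3), c(10, 20, 30))
  expect_equal(cal$slope, 10)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$fit_r2, 1)
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(1, 1), "at least 2")
})

test_that("bod_from_charge applies the line and clamps at zero", {
  cal <- fit_calibration(c(1, 2, 3), c(10, 20, 30))
  expect_equal(bod_from_charge(2, cal), 20)
  expect_equal(bod_from_charge(0, cal), 0)
  cal_neg <- fit_calibration(c(1, 2), c(5, 1))     # negative slope
  expect_equal(bod_from_charge(10, cal_neg), 0)    # clamped
})

test_that("oracle-continuation identity: true continuation gives calibrated truth", {
  set0 <- noiseless_set()
  train_ids <- set_ids(set0, "train")
  test_ids <- set_ids(set0, "test")
  q_tr <- vapply(set0$traces[train_ids], trace_charge, numeric(1))
  cal <- fit_calibration(q_tr, set_masses(set0, "train"))
  for (h in c(2, 24)) {
    w <- window_spec(h)
    for (id in test_ids) {
      cv <- pad_to_canonical(set0$traces[[id]])
      est <- indirect_bod(
        matrix(truncate_window(cv, w), 1),
        matrix(continuation_target(cv, w), 1), cal)
      truth <- set0$traces[[id]]$bod5_mass
      expect_lt(abs(est$bod5_mg / truth - 1), 0.02)
    }
  }
})
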