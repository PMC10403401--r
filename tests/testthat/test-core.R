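# Canonical geometry, traces, and windows

test_that("hours_to_samples reproduces the window table and is affine", {
  hours <- c(24, 16, 12, 8, 6, 2)
  expect_identical(hours_to_samples(hours),
                   c(289L, 193L, 145L, 97L, 73L, 25L))
  expect_identical(hours_to_samples(0), 1L)
  expect_error(hours_to_samples(-1), "non-negative")
  # affine: f(a + b) = f(a) + 12 b
  for (a in c(0L, 3L, 7L)) for (b in c(0L, 2L, 10L)) {
    expect_identical(hours_to_samples(a + b), hours_to_samples(a) + 12L * b)
  }
})

test_that("window_spec derives the (n_input, n_output) table", {
  tab <- list(c(2, 25, 1486), c(6, 73, 1438), c(8, 97, 1414),
              c(12, 145, 1366), c(16, 193, 1318), c(24, 289, 1222))
  for (row in tab) {
    w <- window_spec(row[1])
    expect_identical(c(w$hours, w$n_input, w$n_output), as.integer(row))
  }
  expect_error(window_spec(5), "must be one of")
})

test_that("pad_to_canonical fills the 1511-sample frame with exact zeros", {
  v <- runif(600, 0.05, 0.5)
  tr <- voltage_trace("e1", v, bod5_mass = 10)
  cv <- pad_to_canonical(tr)
  expect_length(cv$values, 1511)
  expect_identical(cv$values[1:600], v)       # bit-exact copy
  expect_true(all(cv$values[601:1511] == 0))
  expect_identical(cv$n_observed, 600L)
  # identity case: full-length trace
  vfull <- runif(1511, 0.05, 0.5)
  cvfull <- pad_to_canonical(voltage_trace("e2", vfull, 5))
  expect_identical(cvfull$values, vfull)
  expect_identical(cvfull$n_observed, 1511L)
})

test_that("voltage_trace rejects invalid series", {
  expect_error(voltage_trace("e", numeric(0), 1), "empty")
  expect_error(voltage_trace("e", rep(0.1, 1512), 1), "at most")
  expect_error(voltage_trace("e", c(0.1, -0.1), 1), "negative")
  expect_error(voltage_trace("e", c(0.1, NA), 1), "non-finite")
  expect_error(voltage_trace("e", 0.1, -1), "non-negative")
})

test_that("truncate/continuation partition every canonical vector exactly", {
  set.seed(42)
  for (rep in 1:5) {
    v <- random_canonical(sample(30:1511, 1))
    for (h in WINDOW_HOURS) {
      w <- window_spec(h)
      head <- truncate_window(v, w)
      tail_ <- continuation_target(v, w)
      expect_length(head, w$n_input)
      expect_length(tail_, w$n_output)
      expect_identical(c(head, tail_), v$values)
    }
  }
})

test_that("detect_termination fires only after the peak", {
  expect_identical(detect_termination(c(0.5, 0.3, 0.1, 0.015, 0.01)), 4L)
  expect_identical(detect_termination(c(0.5, 0.3, 0.1)), NA_integer_)
  # pre-peak low voltages must not terminate
  expect_identical(detect_termination(c(0.01, 0.4, 0.25, 0.019)), 4L)
})

test_that("detect_termination agrees with a brute-force scan", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(10:200, 1)
    tp <- sample(2:(n - 1), 1)
    v <- c(seq(0, runif(1, 0.1, 0.6), length.out = tp),
           pmax(runif(n - tp, 0, 0.3) * exp(-seq_len(n - tp) / 20), 0))
    expect_identical(detect_termination(v), brute_termination(v))
  }
})

test_that("mass_to_concentration converts mg in mL to mg/L", {
  expect_equal(round(mass_to_concentration(46.84, 60)), 781)
  expect_equal(round(mass_to_concentration(4.13, 60)), 69)
  expect_equal(mass_to_concentration(0, 60), 0)
  expect_error(mass_to_concentration(1, 0), "volume")
})

test_that("experiment_set enforces unique ids and role bookkeeping", {
  t1 <- voltage_trace("a", c(0.1, 0.2), 1)
  t2 <- voltage_trace("b", c(0.1, 0.2), 2)
  s <- experiment_set(list(t1, t2), c("train", "test"))
  expect_identical(set_ids(s, "test"), "b")
  expect_identical(unname(set_masses(s, "train")), 1)
  expect_error(experiment_set(list(t1, t1)), "duplicate")
  m <- canonical_matrix(s)
  expect_identical(dim(m), c(2L, 1511L))
  expect_identical(rownames(m), c("a", "b"))
})

test_that("minmax scaling round-trips and validates limits", {
  x <- runif(20)
  expect_equal(minmax_unscale(minmax_scale(x, 0.02, 0.55), 0.02, 0.55), x)
  expect_error(minmax_scale(x, 0.5, 0.5), "exceed")
})
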