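# Synthetic MFC discharge curves ----------------------------------------------
#
# A gamma pulse V(t) = A * (t/tp)^k * exp(k * (1 - t/tp)) reproduces the
# asymmetric fast-rise / slow-decay shape of real MFC batch experiments with
# two shape parameters (peak time tp, sharpness k). The amplitude A is solved
# so that the coulombic charge of the terminated trace equals
# charge_intercept + charge_per_mg * bod5_mass: charge-BOD5 linearity holds
# by construction, which makes the downstream calibration testable against a
# known ground truth.

#' Parameters of the synthetic discharge-curve family
#'
#' @param v_peak nominal peak voltage (V) before amplitude rescaling; must
#'   exceed the 0.02 V termination threshold.
#' @param t_peak time of the voltage peak (min).
#' @param shape sharpness of rise/decay (> 0); larger is spikier.
#' @param noise_sd additive Gaussian voltage noise sd (V), clipped at 0.
#' @param charge_per_mg true calibration slope (C per mg BOD5).
#' @param charge_intercept true calibration intercept (C).
#' @return object of class `curve_params`.
#' @export
curve_params <- function(v_peak = 0.45, t_peak = 900, shape = 2.5,
                         noise_sd = 0.005, charge_per_mg = 9,
                         charge_intercept = 10) {
  if (v_peak <= 0.02) stop("`v_peak` must exceed the 0.02 V termination threshold")
  if (t_peak <= 0) stop("`t_peak` must be > 0")
  if (shape <= 0) stop("`shape` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (charge_per_mg <= 0) stop("`charge_per_mg` must be > 0")
  structure(
    list(v_peak = v_peak, t_peak = t_peak, shape = shape,
         noise_sd = noise_sd, charge_per_mg = charge_per_mg,
         charge_intercept = charge_intercept),
    class = "curve_params"
  )
}

#' Unit-peak gamma pulse
#'
#' `gamma_pulse(t_peak, ...) == 1`; 0 at t = 0; decays to 0 as t grows.
#'
#' @param t_min time (min), vectorised.
#' @param t_peak peak time (min).
#' @param shape sharpness (> 0).
#' @export
gamma_pulse <- function(t_min, t_peak, shape) {
  u <- t_min / t_peak
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(shape * (log(u[pos]) + 1 - u[pos]))
  out
}

# Solve the amplitude so that the trapezoid charge of the terminated grid
# curve matches the target. Termination moves (weakly) with amplitude, so a
# short fixed-point iteration is used.
solve_amplitude <- function(q_target, t_peak, shape, resistance,
                            term_threshold = 0.02) {
  t_grid <- seq(0, by = GRID_DT_MIN, length.out = CANONICAL_LENGTH)
  g <- gamma_pulse(t_grid, t_peak, shape)
  # analytic integral of the unit pulse over [0, Inf):
  # tp_sec * e^k * Gamma(k + 1) / k^(k + 1)
  full <- t_peak * 60 * exp(shape + lgamma(shape + 1) - (shape + 1) * log(shape))
  amp <- q_target * resistance / full
  for (iter in 1:50) {
    v <- amp * g
    term <- detect_termination(v, term_threshold)
    n_keep <- if (is.na(term)) CANONICAL_LENGTH else term
    q <- trapezoid_charge(v[seq_len(n_keep)], resistance, GRID_DT_MIN * 60)
    if (q <= 0) stop("degenerate synthetic curve: zero charge")
    ratio <- q_target / q
    amp <- amp * ratio
    if (abs(ratio - 1) < 1e-12) break
  }
  list(amplitude = amp, n_keep = n_keep, t_grid = t_grid, g = g)
}

#' Generate one synthetic MFC voltage trace
#'
#' The noiseless curve is an amplitude-rescaled gamma pulse whose integrated
#' charge (trapezoid rule on the 5-min grid, over the terminated support)
#' equals `charge_intercept + charge_per_mg * bod5_mass`. Gaussian noise is
#' then added, clipped at 0 V, and the trace is cut at the first post-peak
#' sample below 0.02 V (that sample is kept: it is the measurement that
#' triggers termination). If the curve does not terminate within the
#' canonical frame, `t_peak` is compressed by 10% steps with a warning.
#'
#' @param bod5_mass BOD5 mass (mg) of the virtual sample, > 0.
#' @param params a [curve_params()].
#' @param seed integer seed; identical calls are bit-identical.
#' @param experiment_id id for the resulting trace.
#' @param water_type label stored on the trace.
#' @param resistance external load (ohm).
#' @return a [voltage_trace()] carrying a `curve` attribute with the realised
#'   amplitude, `t_peak`, and `shape` (for oracle checks).
#' @export
generate_trace <- function(bod5_mass, params = curve_params(), seed = 1L,
                           experiment_id = "synthetic-1",
                           water_type = "synthetic", resistance = 100) {
  stopifnot(inherits(params, "curve_params"))
  if (bod5_mass <= 0) stop("`bod5_mass` must be > 0")
  q_target <- params$charge_intercept + params$charge_per_mg * bod5_mass
  if (q_target <= 0) stop("target charge must be > 0")

  t_peak <- params$t_peak
  repeat {
    sol <- solve_amplitude(q_target, t_peak, params$shape, resistance)
    if (sol$n_keep < CANONICAL_LENGTH) break
    warning("synthetic curve for ", experiment_id,
            " does not terminate within the canonical frame; ",
            "compressing t_peak")
    t_peak <- 0.9 * t_peak
  }
  if (sol$amplitude <= 0.02) {
    stop("realised peak voltage ", signif(sol$amplitude, 3),
         " V is below the termination threshold; the requested charge is ",
         "too small for this curve family")
  }

  v <- sol$amplitude * sol$g
  if (params$noise_sd > 0) {
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(length(v), sd = params$noise_sd)
    v <- pmax(v, 0)
  }
  term <- detect_termination(v, 0.02)
  n_keep <- if (is.na(term)) length(v) else term
  tr <- voltage_trace(experiment_id, v[seq_len(n_keep)], bod5_mass,
                      external_resistance = resistance,
                      water_type = water_type)
  attr(tr, "curve") <- list(amplitude = sol$amplitude, t_peak = t_peak,
                            shape = params$shape, q_target = q_target)
  tr
}

#' Generate a synthetic experiment set
#'
#' Masses are uniform over `mass_range`. A fraction `brewery_frac` of the
#' experiments are "brewery-like" (shorter peak time, hence taller curves at
#' a given charge); the remainder are "domestic-like" (slower). The train /
#' test split is deterministic and stratified by water type.
#'
#' @param n number of experiments (>= 2), default 56.
#' @param mass_range BOD5 mass interval (mg), default `c(4.13, 46.84)`.
#' @param brewery_frac proportion of brewery-like experiments.
#' @param n_test number of held-out test experiments (default 16).
#' @param noise_sd voltage noise sd (V).
#' @param charge_per_mg,charge_intercept true calibration line (C/mg, C).
#' @param seed master seed; all randomness derives from it.
#' @return an [experiment_set()].
#' @export
generate_dataset <- function(n = 56, mass_range = c(4.13, 46.84),
                             brewery_frac = 0.5, n_test = 16,
                             noise_sd = 0.005, charge_per_mg = 9,
                             charge_intercept = 10, seed = 1L) {
  if (n < 2) stop("`n` must be >= 2")
  if (length(mass_range) != 2L || mass_range[1] <= 0 ||
      mass_range[2] < mass_range[1]) {
    stop("`mass_range` must be a positive non-empty interval")
  }
  if (n_test < 0 || n_test >= n) stop("`n_test` must be in [0, n)")
  set.seed(as.integer(seed))
  masses <- stats::runif(n, mass_range[1], mass_range[2])
  n_brew <- round(brewery_frac * n)
  types <- sample(rep(c("brewery", "domestic"), c(n_brew, n - n_brew)))
  t_peaks <- ifelse(types == "brewery",
                    stats::runif(n, 300, 600), stats::runif(n, 600, 1100))
  shapes <- stats::runif(n, 2.2, 3.0)
  trace_seeds <- sample.int(.Machine$integer.max - 1L, n)

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- curve_params(t_peak = t_peaks[i], shape = shapes[i],
                      noise_sd = noise_sd, charge_per_mg = charge_per_mg,
                      charge_intercept = charge_intercept)
    traces[[i]] <- generate_trace(
      masses[i], p, seed = trace_seeds[i],
      experiment_id = sprintf("exp%02d", i), water_type = types[i])
  }

  roles <- rep("train", n)
  if (n_test > 0) {
    # deterministic stratified hold-out: round-robin across water types
    test_idx <- integer(0)
    for (ty in unique(types)) {
      idx <- which(types == ty)
      k <- round(n_test * length(idx) / n)
      test_idx <- c(test_idx, idx[seq_len(min(k, length(idx)))])
    }
    # top up / trim to exactly n_test
    extra <- setdiff(seq_len(n), test_idx)
    while (length(test_idx) < n_test) {
      test_idx <- c(test_idx, extra[1]); extra <- extra[-1]
    }
    test_idx <- sort(test_idx[seq_len(n_test)])
    roles[test_idx] <- "test"
  }
  set <- experiment_set(traces, roles)
  attr(set, "truth") <- list(charge_per_mg = charge_per_mg,
                             charge_intercept = charge_intercept,
                             noise_sd = noise_sd, seed = seed)
  set
}
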