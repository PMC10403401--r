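# Charge integration and linear calibration -----------------------------------
#
# The indirect route's physics stage: I = V / R (Ohm's law at the external
# load), Q = integral of I dt over the experiment, and an ordinary
# least-squares line mapping charge (C) to BOD5 mass (mg).

#' Current through the external load from the cell voltage
#'
#' @param v voltage (V), vectorised.
#' @param r external resistance (ohm), > 0.
#' @return current (A).
#' @export
current_from_voltage <- function(v, r) {
  if (any(r <= 0)) stop("`r` must be > 0")
  v / r
}

# trapezoid rule on a uniform grid; dt in seconds
trapezoid_charge <- function(v, resistance, dt) {
  n <- length(v)
  if (n < 2L) return(0)
  sum((v[-1] + v[-n]) / 2) * dt / resistance
}

left_rectangle_charge <- function(v, resistance, dt) {
  n <- length(v)
  if (n < 2L) return(0)
  sum(v[-n]) * dt / resistance
}

#' Integrate coulombic charge from a voltage series
#'
#' Converts voltage to current by Ohm's law and integrates numerically over
#' the uniform sample grid. Trapezoid rule is the default; a left-rectangle
#' rule is provided for sensitivity checks.
#'
#' @param voltages non-negative voltages (V) on a uniform grid.
#' @param resistance external resistance (ohm), > 0.
#' @param dt sample spacing (s), default 300 (5 min).
#' @param rule `"trapezoid"` (default) or `"left_rectangle"`.
#' @param cutoff_index optional bookkeeping: 1-based index of the first
#'   discarded sample when a cutoff was applied upstream.
#' @return object of class `charge_result` with fields `charge` (C),
#'   `cutoff_index`, `integration_rule`.
#' @export
integrate_charge <- function(voltages, resistance = 100, dt = 300,
                             rule = c("trapezoid", "left_rectangle"),
                             cutoff_index = NA_integer_) {
  rule <- match.arg(rule)
  if (resistance <= 0) stop("`resistance` must be > 0")
  if (dt <= 0) stop("`dt` must be > 0")
  voltages <- as.double(voltages)
  if (length(voltages) == 0L) {
    warning("empty voltage sequence: charge is 0 C")
    q <- 0
  } else {
    if (any(!is.finite(voltages))) stop("non-finite voltage")
    if (any(voltages < 0)) stop("negative voltage in charge integration")
    q <- switch(rule,
                trapezoid = trapezoid_charge(voltages, resistance, dt),
                left_rectangle = left_rectangle_charge(voltages, resistance, dt))
  }
  structure(list(charge = q, cutoff_index = cutoff_index,
                 integration_rule = rule),
            class = "charge_result")
}

#' @export
print.charge_result <- function(x, ...) {
  cat(sprintf("<charge_result> %.4f C (%s)\n", x$charge, x$integration_rule))
  invisible(x)
}

#' Concatenate an observed window with a predicted continuation
#'
#' @param observed the `n_input` measured samples.
#' @param predicted the `n_output` network-predicted samples.
#' @return numeric vector of length 1511.
#' @export
assemble_full_curve <- function(observed, predicted) {
  n1 <- length(observed)
  n2 <- length(predicted)
  valid <- hours_to_samples(WINDOW_HOURS)
  if (!(n1 %in% valid) || n2 != CANONICAL_LENGTH - n1) {
    stop("invalid (n_input, n_output) pair: (", n1, ", ", n2, ")")
  }
  c(as.double(observed), as.double(predicted))
}

#' Discard the predicted tail of an assembled curve below a cutoff voltage
#'
#' Zero-padding forces predicted continuations toward zero; samples below the
#' regression cutoff would only add noise to the charge. The rule applies to
#' predicted samples only, and only once the curve has already passed the
#' substrate-depletion level (`term_level`, 0.02 V): all samples from the
#' first predicted value strictly below `threshold` onwards are then
#' discarded. Low voltages on the rise phase of a slow curve (which has not
#' yet reached 0.02 V) never trigger the cutoff, and observed samples
#' (indices `<= n_input`) are always retained.
#'
#' @param curve assembled curve of length 1511.
#' @param n_input number of leading observed samples.
#' @param threshold cutoff voltage (V), default 0.01.
#' @param term_level termination level (V) the curve must have reached
#'   before the cutoff can fire, default 0.02.
#' @return list with `values` (the retained prefix) and `cutoff_index`
#'   (1-based index of the first discarded sample, or `NA_integer_`).
#' @export
apply_prediction_cutoff <- function(curve, n_input, threshold = 0.01,
                                    term_level = 0.02) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  curve <- as.double(curve)
  if (length(curve) != CANONICAL_LENGTH) {
    stop("`curve` must have ", CANONICAL_LENGTH, " samples")
  }
  idx <- which(curve < threshold & cummax(curve) >= term_level)
  idx <- idx[idx > n_input]
  if (length(idx) == 0L) {
    list(values = curve, cutoff_index = NA_integer_)
  } else {
    cut <- idx[1L]
    list(values = curve[seq_len(cut - 1L)], cutoff_index = cut)
  }
}

#' Fit the linear BOD5-vs-charge calibration
#'
#' Ordinary least squares of `mass = slope * charge + intercept`, fitted on
#' training experiments' true (observed, untruncated) charges.
#'
#' @param charges charges (C), >= 2 distinct values.
#' @param bod_masses reference BOD5 masses (mg), same length.
#' @return object of class `bod_calibration` with `slope` (mg/C),
#'   `intercept` (mg), `fit_r2`, `n`.
#' @export
fit_calibration <- function(charges, bod_masses) {
  charges <- as.double(charges)
  bod_masses <- as.double(bod_masses)
  if (length(charges) != length(bod_masses)) stop("length mismatch")
  if (length(charges) < 2L) stop("calibration needs at least 2 points")
  if (stats::sd(charges) == 0) {
    stop("degenerate calibration design: all charges identical")
  }
  fit <- stats::lm.fit(cbind(1, charges), bod_masses)
  pred <- bod_masses - fit$residuals
  ss_tot <- sum((bod_masses - mean(bod_masses))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 fit_r2 = r2, n = length(charges)),
            class = "bod_calibration")
}

#' @export
print.bod_calibration <- function(x, ...) {
  cat(sprintf("<bod_calibration> mass = %.4f mg/C * Q + %.4f mg (R2 %.4f, n = %d)\n",
              x$slope, x$intercept, x$fit_r2, x$n))
  invisible(x)
}

#' Map a charge to a BOD5 mass through a calibration
#'
#' @param q charge (C), vectorised.
#' @param cal a [fit_calibration()] result.
#' @return BOD5 mass (mg), clamped at 0.
#' @export
bod_from_charge <- function(q, cal) {
  stopifnot(inherits(cal, "bod_calibration"))
  pmax(0, cal$slope * q + cal$intercept)
}

#' True charge of a trace (observed samples, no padding, no cutoff)
#'
#' @param trace a [voltage_trace()].
#' @param rule integration rule, see [integrate_charge()].
#' @return charge (C).
#' @export
trace_charge <- function(trace, rule = "trapezoid") {
  stopifnot(inherits(trace, "voltage_trace"))
  integrate_charge(trace$voltages, trace$external_resistance,
                   dt = GRID_DT_MIN * 60, rule = rule)$charge
}
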