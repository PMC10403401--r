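# Canonical time geometry -----------------------------------------------------
#
# All experiments live on a uniform 5-min grid starting at injection (t = 0).
# The longest experiment spans 7550 min, so every trace is zero-padded into a
# fixed 1511-sample frame (7550 / 5 + 1, inclusive of t = 0).

#' Canonical frame length (samples)
#'
#' The universal model I/O frame: 1511 samples on the 5-minute grid, i.e.
#' 7550 minutes inclusive of the t = 0 sample.
#' @export
CANONICAL_LENGTH <- 1511L

#' Sampling interval of the voltage grid, in minutes
#' @export
GRID_DT_MIN <- 5

#' Supported input-window horizons (hours)
#' @export
WINDOW_HOURS <- c(2L, 6L, 8L, 12L, 16L, 24L)

#' Convert a measurement horizon in hours to a sample count
#'
#' Samples are taken every 5 minutes inclusive of t = 0, so `h` hours span
#' `12 * h + 1` samples (24 h -> 289, 2 h -> 25).
#'
#' @param hours non-negative number of hours (vectorised).
#' @return integer sample counts.
#' @export
#' @examples
#' hours_to_samples(24) # 289
hours_to_samples <- function(hours) {
  if (!is.numeric(hours) || any(!is.finite(hours))) {
    stop("`hours` must be finite numeric")
  }
  if (any(hours < 0)) stop("`hours` must be non-negative")
  as.integer(round(12 * hours + 1))
}

#' Input-window specification
#'
#' Bundles an input horizon with the derived model dimensions: `n_input`
#' observed samples feed the network and, for curve completion, `n_output =
#' 1511 - n_input` samples are predicted.
#'
#' @param hours one of 2, 6, 8, 12, 16, 24.
#' @return an object of class `window_spec` with fields `hours`, `n_input`,
#'   `n_output`.
#' @export
window_spec <- function(hours) {
  hours <- as.integer(hours)
  if (length(hours) != 1L || !hours %in% WINDOW_HOURS) {
    stop("`hours` must be one of ", paste(WINDOW_HOURS, collapse = ", "))
  }
  n_input <- hours_to_samples(hours)
  structure(
    list(hours = hours, n_input = n_input,
         n_output = CANONICAL_LENGTH - n_input),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d h: n_input = %d, n_output = %d\n",
              x$hours, x$n_input, x$n_output))
  invisible(x)
}

# Voltage traces ---------------------------------------------------------------

#' One MFC experiment: a voltage series plus metadata
#'
#' @param experiment_id character scalar, unique within a dataset.
#' @param voltages finite non-negative voltages (V) on the 5-min grid,
#'   first sample at t = 0; at most 1511 samples.
#' @param bod5_mass reference BOD5 mass (mg) of the injected sample.
#' @param sample_volume injected sample volume (mL), default 60.
#' @param external_resistance load resistance (ohm), default 100.
#' @param water_type one of `"domestic"`, `"brewery"`, `"synthetic"`.
#' @return an object of class `voltage_trace`.
#' @export
voltage_trace <- function(experiment_id, voltages, bod5_mass,
                          sample_volume = 60, external_resistance = 100,
                          water_type = c("domestic", "brewery", "synthetic")) {
  water_type <- match.arg(water_type)
  if (!is.character(experiment_id) || length(experiment_id) != 1L ||
      is.na(experiment_id) || !nzchar(experiment_id)) {
    stop("`experiment_id` must be a non-empty string")
  }
  voltages <- as.double(voltages)
  n <- length(voltages)
  if (n < 1L) stop("empty voltage series for experiment ", experiment_id)
  if (n > CANONICAL_LENGTH) {
    stop("voltage series of ", experiment_id, " has ", n,
         " samples; at most ", CANONICAL_LENGTH, " fit the canonical frame")
  }
  if (any(!is.finite(voltages))) {
    stop("non-finite voltage in experiment ", experiment_id)
  }
  if (any(voltages < 0)) {
    stop("negative voltage in experiment ", experiment_id)
  }
  if (!is.numeric(bod5_mass) || length(bod5_mass) != 1L || bod5_mass < 0) {
    stop("`bod5_mass` must be a single non-negative number")
  }
  if (sample_volume <= 0) stop("`sample_volume` must be > 0")
  if (external_resistance <= 0) stop("`external_resistance` must be > 0")
  structure(
    list(experiment_id = experiment_id, voltages = voltages,
         bod5_mass = as.double(bod5_mass),
         sample_volume = as.double(sample_volume),
         external_resistance = as.double(external_resistance),
         water_type = water_type),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %s: %d samples (%.0f min), peak %.3f V, BOD5 %.2f mg, %s\n",
    x$experiment_id, length(x$voltages),
    (length(x$voltages) - 1) * GRID_DT_MIN,
    max(x$voltages), x$bod5_mass, x$water_type))
  invisible(x)
}

#' Zero-pad a trace into the canonical 1511-sample frame
#'
#' Observed samples are copied bit-exactly; the remainder of the frame is
#' exactly 0.
#'
#' @param trace a [voltage_trace()].
#' @return an object of class `canonical_vector` with fields `values`
#'   (length 1511) and `n_observed` (number of observed samples).
#' @export
pad_to_canonical <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"))
  n <- length(trace$voltages)
  values <- c(trace$voltages, rep(0, CANONICAL_LENGTH - n))
  canonical_vector(values, n_observed = n)
}

#' Construct/validate a canonical 1511-sample vector
#'
#' @param values numeric vector of length 1511.
#' @param n_observed number of leading observed samples; entries beyond it
#'   must be exactly 0.
#' @export
canonical_vector <- function(values, n_observed = CANONICAL_LENGTH) {
  values <- as.double(values)
  if (length(values) != CANONICAL_LENGTH) {
    stop("canonical vector must have exactly ", CANONICAL_LENGTH,
         " samples, got ", length(values))
  }
  n_observed <- as.integer(n_observed)
  if (n_observed < 1L || n_observed > CANONICAL_LENGTH) {
    stop("`n_observed` out of range")
  }
  if (n_observed < CANONICAL_LENGTH &&
      any(values[(n_observed + 1L):CANONICAL_LENGTH] != 0)) {
    stop("padding region beyond `n_observed` must be exactly zero")
  }
  structure(list(values = values, n_observed = n_observed),
            class = "canonical_vector")
}

#' First `n_input` samples of a canonical vector (the model input window)
#'
#' @param v a [canonical_vector()].
#' @param w a [window_spec()].
#' @return numeric vector of length `w$n_input`.
#' @export
truncate_window <- function(v, w) {
  stopifnot(inherits(v, "canonical_vector"), inherits(w, "window_spec"))
  v$values[seq_len(w$n_input)]
}

#' Remaining samples of a canonical vector (the curve-completion target)
#'
#' Complements [truncate_window()]: concatenating window and continuation
#' reconstructs the canonical vector exactly.
#'
#' @inheritParams truncate_window
#' @return numeric vector of length `w$n_output`.
#' @export
continuation_target <- function(v, w) {
  stopifnot(inherits(v, "canonical_vector"), inherits(w, "window_spec"))
  v$values[(w$n_input + 1L):CANONICAL_LENGTH]
}

#' Detect substrate depletion in a discharge curve
#'
#' A real experiment ends when the voltage drops below the termination
#' threshold *after* the discharge peak; the rise phase also passes through
#' low voltages and must not terminate the experiment.
#'
#' @param trace a [voltage_trace()] or a bare numeric voltage vector.
#' @param threshold termination voltage (V), default 0.02.
#' @return 1-based index of the first post-peak sample strictly below
#'   `threshold`, or `NA_integer_` if the curve never drops below it.
#' @export
detect_termination <- function(trace, threshold = 0.02) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  v <- if (inherits(trace, "voltage_trace")) trace$voltages else as.double(trace)
  peak <- which.max(v)
  idx <- which(v < threshold)
  idx <- idx[idx > peak]
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

#' Convert an injected BOD5 mass to a concentration
#'
#' @param mass BOD5 mass (mg).
#' @param volume sample volume (mL); must be > 0.
#' @return concentration in mg/L.
#' @export
#' @examples
#' mass_to_concentration(46.84, 60) # ~781 mg/L
mass_to_concentration <- function(mass, volume = 60) {
  if (any(volume <= 0)) stop("`volume` must be > 0")
  mass / (volume / 1000)
}

# Experiment sets --------------------------------------------------------------

#' A labelled collection of voltage traces
#'
#' @param traces list of [voltage_trace()] objects with unique ids.
#' @param roles character vector (`"train"`/`"test"`), one per trace.
#' @return object of class `experiment_set`.
#' @export
experiment_set <- function(traces, roles = rep("train", length(traces))) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  ok <- vapply(traces, inherits, logical(1), "voltage_trace")
  if (!all(ok)) stop("all elements of `traces` must be voltage_trace objects")
  ids <- vapply(traces, `[[`, character(1), "experiment_id")
  if (anyDuplicated(ids)) {
    stop("duplicate experiment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  roles <- match.arg(roles, c("train", "test"), several.ok = TRUE)
  if (length(roles) != length(traces)) {
    stop("`roles` must have one entry per trace")
  }
  names(traces) <- ids
  names(roles) <- ids
  structure(list(traces = traces, roles = roles), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> %d experiments (%d train / %d test)\n",
              length(x$traces), sum(x$roles == "train"),
              sum(x$roles == "test")))
  invisible(x)
}

#' @export
length.experiment_set <- function(x) length(x$traces)

#' Experiment ids of a set, optionally filtered by role
#' @param set an [experiment_set()].
#' @param role `NULL` (all), `"train"`, or `"test"`.
#' @export
set_ids <- function(set, role = NULL) {
  stopifnot(inherits(set, "experiment_set"))
  ids <- names(set$traces)
  if (is.null(role)) ids else ids[set$roles == role]
}

#' BOD5 masses (mg) of a set as a named vector
#' @inheritParams set_ids
#' @export
set_masses <- function(set, role = NULL) {
  ids <- set_ids(set, role)
  vapply(set$traces[ids], `[[`, numeric(1), "bod5_mass")
}

#' Canonical voltage matrix of a set (experiments as rows)
#'
#' @inheritParams set_ids
#' @return numeric matrix, one row per experiment, 1511 columns, rownames =
#'   experiment ids.
#' @export
canonical_matrix <- function(set, role = NULL) {
  ids <- set_ids(set, role)
  m <- t(vapply(set$traces[ids],
                function(tr) pad_to_canonical(tr)$values,
                numeric(CANONICAL_LENGTH)))
  rownames(m) <- ids
  m
}

# Optional mini-max normalization ---------------------------------------------

#' Mini-max scale voltages with expert-supplied limits
#'
#' Rescales to `(x - v_min) / (v_max - v_min)`. The limits are supplied
#' explicitly (expert values for the full curve); they are never inferred
#' from a truncated window, where the peak may not have been reached yet.
#' Off by default throughout the package.
#'
#' @param x numeric vector.
#' @param v_min,v_max expert minimum / maximum (V), `v_max > v_min`.
#' @export
minmax_scale <- function(x, v_min, v_max) {
  if (!(v_max > v_min)) stop("`v_max` must exceed `v_min`")
  (x - v_min) / (v_max - v_min)
}

#' Invert [minmax_scale()]
#' @inheritParams minmax_scale
#' @export
minmax_unscale <- function(x, v_min, v_max) {
  if (!(v_max > v_min)) stop("`v_max` must exceed `v_min`")
  x * (v_max - v_min) + v_min
}
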