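---
title: "Rapid BOD5 estimation from MFC voltage traces: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid BOD5 estimation from MFC voltage traces: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcbod5)
```

## The measurement problem

The 5-day biochemical oxygen demand (BOD5) is the standard measure of
biodegradable organic load in water, but the reference respirometric assay
takes five days. A microbial-fuel-cell (MFC) biosensor shortens this: a
sample is injected into the anode chamber, exoelectrogenic bacteria oxidise
its organics and deliver electrons to the external circuit, and the voltage
across a 100-ohm load is logged every 5 minutes. The curve rises quickly
while readily biodegradable substrate is consumed, peaks, and decays; when
the voltage falls below 0.02 V the substrate is considered depleted and the
experiment ends. The coulombic charge

$$Q = \int_{t_s}^{t_e} I\,dt, \qquad I = V/R,$$

is, to good approximation, linear in the BOD5 mass of the injected sample —
that is the physical basis of the sensor. This package asks the follow-up
question: how much of the curve do you actually need? It predicts BOD5 from
only the first 2–24 h of the voltage trace, by two routes:

* **direct** — a multilayer perceptron (MLP) maps the truncated window
  straight to one BOD5 mass;
* **indirect** — an MLP predicts the *remainder* of the voltage curve; the
  assembled curve is integrated to a charge, and a linear calibration maps
  charge to BOD5.

## Canonical geometry

Every experiment lives on the 5-minute grid starting at injection. The
longest experiment spans 7550 min, so all traces are zero-padded into a
fixed frame of $7550/5 + 1 = 1511$ samples. An input horizon of $h$ hours
covers $n_1 = 12h + 1$ samples (inclusive of $t=0$): 289, 193, 145, 97, 73,
25 for 24, 16, 12, 8, 6, 2 h. The curve-completion target is the remaining
$n_2 = 1511 - n_1$ samples. Padding uses exact zeros, so window +
continuation always reconstructs the frame bit for bit — a property the
tests exercise on random vectors.

Sample $i$ (1-based in R) represents time $t = 5(i-1)$ min. Termination
detection (`detect_termination`) only fires *after* the curve's peak: the
rise phase also passes through low voltages and must not end an experiment.

## The networks

Twelve MLPs are registered (6 windows × 2 routes), each with three ReLU
hidden layers drawn from widths {64, 96, 128}, per-layer dropout from
{10, 20, 25, 30, 40, 50}%, and a linear output (width 1 for direct, $n_2$
for indirect). Training minimises mean squared error — over experiments for
the direct route, over experiments × time points for the indirect route —
by full-batch Adam (learning rate 0.001 direct / 0.0001 indirect; the other
Adam constants at the Keras defaults $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-7}$). With only tens of training experiments, full-batch
gradients in base-R matrix algebra are fast and make runs bit-reproducible
under a seed; dropout masks are drawn from the same seeded stream and are
active only during training.

Choices the source left open, fixed here:

* **Weight initialisation**: uniform with fan-in scaling
  $\pm\sqrt{6/\mathrm{fan_{in}}}$, seeded.
* **Batch size**: full batch (40 training rows).
* **Negative direct predictions** are clamped to 0 mg — BOD is a mass.
* **Epoch counts** are not part of the registry tables; they are tunables
  selected by block 5-fold cross-validation (`cross_validate` records the
  per-epoch validation loss in every fold, averages across folds, and picks
  the argmin). The shipped defaults — 600 epochs direct, 400 indirect —
  were fixed once from CV curves on synthetic development data: the direct
  24-h CV minimum sat near 680, while the indirect voltage loss keeps
  creeping down past 400 without improving the downstream BOD error (and
  mildly overfits by 2000). `run_pipeline(do_cv = TRUE)` reselects epochs
  per model instead of using the defaults.
* **Cross-validation scope**: the source is ambiguous about whether
  architecture was also reselected per fold; the default here fixes the
  registry architectures and selects epochs only, but `cross_validate`
  accepts a list of candidate configurations if a wider search is wanted.

Mini-max voltage normalization is available (`minmax_scale`) but **off by
default**, matching the configuration the reported results used. When used,
the per-experiment maximum/minimum must be supplied as expert values for
the full curve — never inferred from a truncated window, where the peak may
not have been reached.

## Charge integration and calibration

The indirect route converts the assembled curve (measured window +
predicted continuation; the measured window is included in the integral,
since the charge must cover the whole experiment) to current by Ohm's law
and integrates with the trapezoid rule on the 5-min grid (left-rectangle
available for sensitivity checks). Two thresholds with distinct roles:

* **0.02 V — termination**: a real experiment ends below this level.
* **0.01 V — regression cutoff**: predicted voltages decay toward the zero
  padding rather than stopping at 0.02 V exactly, so predicted samples are
  discarded from the first value below 0.01 V onwards — but only once the
  curve has already passed the 0.02 V depletion level. Without that guard,
  a slow experiment whose continuation starts on the low-voltage rise phase
  would lose its entire curve to the cutoff; with it, the rule touches only
  the decaying tail. Observed samples are never discarded. The cutoff is
  strict (`< 0.01`), applied to predicted samples only.

The calibration `mass = slope * Q + intercept` is fitted by ordinary least
squares on the *training* experiments' true charges (observed, untruncated
traces); its coefficients are not taken from any published table.
`bod_from_charge` clamps at 0 mg.

## The synthetic world

No measured dataset ships with the package, so a generator emulates its
structure. The noiseless curve family is a gamma pulse

$$V(t) = A\,(t/t_p)^k\,e^{k(1 - t/t_p)},$$

which reproduces the asymmetric fast-rise/slow-decay shape of MFC batch
curves with two parameters (peak time $t_p$, sharpness $k$). The amplitude
$A$ is solved (short fixed-point iteration) so that the trapezoid charge of
the terminated grid curve equals $Q = 10\,\mathrm{C} + 9\,\mathrm{C/mg}
\times \mathrm{BOD5}$ — charge linearity holds *by construction*, giving the
calibration stage a known ground truth. Gaussian noise (sd 0.005 V, a few
percent of a typical peak) is added and clipped at 0, and the trace is cut
at the first post-peak sample below 0.02 V.

Defaults state the emulated world once: 56 experiments, masses uniform on
[4.13, 46.84] mg in 60 mL (≈69–781 mg/L), 100-ohm load, 40/16 train/test
split stratified by water type; "brewery-like" experiments draw
$t_p \sim U(300, 600)$ min and "domestic-like" $t_p \sim U(600, 1100)$ min
(at a fixed charge a shorter pulse is taller, so brewery curves peak higher
and earlier, as in real data), $k \sim U(2.2, 3.0)$. The slope 9 C/mg and
intercept 10 C give charges of ~47–430 C and peaks of ~0.05–0.55 V,
plausible for a 230-mL air-cathode cell on a 100-ohm load.

What the generator does **not** emulate: inter-experiment correlation from
parallel cells sharing a biofilm history, drift and electrode ageing,
diauxic/multi-peak curves, and real deviations from exact charge–BOD
linearity. A green pipeline test therefore establishes that the machinery
is correct and that information content increases with window length — it
does not certify the error figures attainable on real wastewater data.

## Numerical choices and degenerate inputs

* Trapezoid rule, $dt = 300$ s; quadrature error on these smooth pulses is
  well under 1% (tested against 1-s quadrature of the closed form).
* Trailing zero-padding changes a terminated curve's charge by at most one
  junction trapezoid (property-tested).
* Traces shorter than a requested window are handled automatically by the
  zero-padded frame (a brewery-like curve can terminate before 24 h).
* Empty voltage input to the integrator yields 0 C with a warning; negative
  voltages are data errors.
* MAPE refuses zero true values; $R^2$ refuses zero-variance truth;
  classification scores with an empty reference class are `NA`, never 0.
* `fold_plan` requires the training size to be divisible by the fold count
  (blocks are contiguous in dataset order, mirroring block CV on 40 = 5×8).

## Limitations

The error tables of the motivating study are not reproducible here without
its deposited dataset; the acceptance machinery instead checks exact
geometry identities, closed-form charges, oracle-continuation identity
(≤2%), calibration parameter recovery (≤1%), metric brute-force agreement,
and the qualitative trend that 24-h models beat 2-h models on held-out
synthetic data. Real-data performance must be established on real data via
`read_dataset()` + `run_pipeline()`.
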