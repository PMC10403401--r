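# mfcbod5

Rapid estimation of 5-day biochemical oxygen demand (BOD5) from the first
2–24 hours of a microbial-fuel-cell (MFC) voltage discharge experiment.

A single-chamber air-cathode MFC turns biodegradable organics into current:
exoelectrogenic bacteria oxidise the injected sample and deliver electrons
across a 100-Ω load, and the logged voltage rises, peaks, and decays until
the substrate is depleted (V < 0.02 V). The coulombic charge

    Q = ∫ I dt,   I = V/R,

is linear in the BOD5 mass of the sample — so an MFC is a BOD sensor, but a
full experiment still takes days. This package predicts BOD5 from only a
truncated measurement window (2, 6, 8, 12, 16, or 24 h on the 5-min grid;
n₁ = 12h + 1 samples out of the canonical 1511-sample / 7550-min frame) by
two routes:

* **direct** — a multilayer perceptron (3 ReLU hidden layers + dropout,
  full-batch Adam, lr 0.001) maps the window to one BOD5 mass (mg);
* **indirect** — an MLP (lr 0.0001) predicts the remaining n₂ = 1511 − n₁
  voltage samples; the assembled curve is integrated (trapezoid, Ohm's law,
  with a 0.01 V regression cutoff applied to the predicted tail once the
  curve has passed the 0.02 V depletion level) and mapped to BOD5 through a
  linear charge calibration fitted on training experiments.

Twelve fixed network architectures (6 windows × 2 routes) are registered;
epoch counts are selected by block 5-fold cross-validation. A synthetic
discharge-curve generator (gamma pulses with charge exactly linear in BOD5
mass by construction) makes the whole pipeline testable end to end without
any measured dataset. See `vignettes/mfcbod5-methods.Rmd` for the model,
its assumptions, and what the synthetic world does and does not emulate.

## Worked example

```r
library(mfcbod5)

# a 56-experiment synthetic world: masses uniform on [4.13, 46.84] mg in
# 60 mL (~69-781 mg/L), brewery-like and domestic-like curves, 40/16 split
set <- generate_dataset(n = 56, seed = 1)
print(set)
#> <experiment_set> 56 experiments (40 train / 16 test)

res <- run_pipeline(set, windows = c(2, 24), approach = "both", seed = 1,
                    epochs = c(direct = 600, indirect = 400))
print(res$calibration)
#> <bod_calibration> mass = 0.1110 mg/C * Q + -0.8994 mg (R2 0.9999, n = 40)
print(res$metrics, digits = 3)
#>   window_h approach epochs mape_pct max_abs_error_mg      r2 n_test
#> 1        2   direct    600     50.3            23.83 -0.0414     16
#> 2        2 indirect    400     77.9            40.19 -3.2413     16
#> 3       24   direct    600      4.6             4.26  0.9752     16
#> 4       24 indirect    400     15.0            17.79  0.6717     16
```

The calibration recovers the generator's imposed line (9 C/mg + 10 C ⇒
mass = (Q − 10)/9 ≈ 0.111·Q − 1.11) from noisy training charges. The
metrics table reads: with a full 24-h window the direct model predicts
held-out BOD5 masses within ~5% on average (R² 0.98), while a 2-h window —
mostly pre-peak voltage — carries far less information (MAPE ~50%/78%).
`res$predictions` holds per-experiment true and predicted masses and, for
the indirect route, the integrated charge in coulombs.

Omitting `epochs` runs block 5-fold cross-validation per model and selects
the epoch count minimising the mean validation loss
(`res$cv[[...]]$best_epoch`).

## Command line

```sh
Rscript -e 'mfcbod5::mfc_cli()' simulate --out data --n 56 --seed 1
Rscript -e 'mfcbod5::mfc_cli()' charge   --matrix data/voltages.csv \
        --metadata data/metadata.csv --out charges.csv
Rscript -e 'mfcbod5::mfc_cli()' run-all  --matrix data/voltages.csv \
        --metadata data/metadata.csv --out results --seed 1 --windows 12,24
Rscript -e 'mfcbod5::mfc_cli()' evaluate --predictions results/predictions.csv \
        --out metrics.csv
```

The voltage CSV is the canonical 1511-row matrix (experiments as columns,
header of experiment ids, trailing zeros = padding); the metadata CSV has
columns `experiment_id, bod5_mg, volume_ml, resistance_ohm, water_type,
role`.

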