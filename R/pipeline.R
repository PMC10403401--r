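# End-to-end pipeline ----------------------------------------------------------

#' Build the model design matrices for a window and approach
#'
#' @param set an [experiment_set()].
#' @param window a [window_spec()] or hours value.
#' @param approach `"direct"` or `"indirect"`.
#' @param role `"train"`, `"test"`, or `NULL` for all experiments.
#' @return list with `inputs` (experiments x `n_input`, rownames = ids) and
#'   `targets` (experiments x 1 BOD5 masses for direct; experiments x
#'   `n_output` continuations for indirect).
#' @export
build_design <- function(set, window, approach = c("direct", "indirect"),
                         role = NULL) {
  approach <- match.arg(approach)
  w <- if (inherits(window, "window_spec")) window else window_spec(window)
  cm <- canonical_matrix(set, role)
  inputs <- cm[, seq_len(w$n_input), drop = FALSE]
  targets <- if (approach == "direct") {
    matrix(set_masses(set, role), ncol = 1,
           dimnames = list(rownames(cm), "bod5_mg"))
  } else {
    cm[, (w$n_input + 1L):CANONICAL_LENGTH, drop = FALSE]
  }
  list(inputs = inputs, targets = targets, window = w, approach = approach)
}

#' Indirect BOD5 estimates from predicted continuations
#'
#' Assembles observed window + predicted continuation, applies the 0.01 V
#' regression cutoff to the predicted part, integrates the charge, and maps
#' it through the calibration.
#'
#' @param observed matrix of observed windows (experiments x `n_input`).
#' @param predicted matrix of predicted continuations.
#' @param cal a [fit_calibration()].
#' @param resistance external resistance (ohm).
#' @param rule integration rule.
#' @param cutoff regression cutoff voltage (V).
#' @return data.frame with `charge_C`, `bod5_mg`, `cutoff_index` per row.
#' @export
indirect_bod <- function(observed, predicted, cal, resistance = 100,
                         rule = "trapezoid", cutoff = 0.01) {
  observed <- as.matrix(observed); predicted <- as.matrix(predicted)
  stopifnot(nrow(observed) == nrow(predicted))
  n1 <- ncol(observed)
  out <- lapply(seq_len(nrow(observed)), function(i) {
    full <- assemble_full_curve(observed[i, ], pmax(predicted[i, ], 0))
    cutres <- apply_prediction_cutoff(full, n1, cutoff)
    q <- integrate_charge(cutres$values, resistance, dt = GRID_DT_MIN * 60,
                          rule = rule, cutoff_index = cutres$cutoff_index)
    data.frame(charge_C = q$charge, bod5_mg = bod_from_charge(q$charge, cal),
               cutoff_index = if (is.na(cutres$cutoff_index)) NA_integer_
                              else cutres$cutoff_index)
  })
  res <- do.call(rbind, out)
  rownames(res) <- rownames(observed)
  res
}

#' Run the full train/evaluate pipeline on an experiment set
#'
#' For every requested window and approach: optionally selects the epoch
#' count by block 5-fold cross-validation on the training experiments, fits
#' the final model on all training experiments, predicts the held-out test
#' experiments, and (indirect route) integrates charge and applies the
#' charge calibration fitted on the training experiments' true charges.
#' All randomness derives from `seed`, split deterministically per model.
#'
#' @param set an [experiment_set()] with train and test roles.
#' @param windows hours values, subset of `{2, 6, 8, 12, 16, 24}`.
#' @param approach `"direct"`, `"indirect"`, or `"both"`.
#' @param seed master seed.
#' @param epochs optional epoch override (skips cross-validation); a single
#'   value or a named vector `c(direct =, indirect =)`.
#' @param do_cv run epoch-selecting cross-validation (default: only when
#'   `epochs` is `NULL`).
#' @param cv_max_epochs epoch horizon explored by cross-validation.
#' @param rule charge-integration rule.
#' @param cutoff regression cutoff voltage (V).
#' @param pollution_threshold optional mg/L threshold; when given,
#'   classification scores are added per model.
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `predictions.csv`, per-model checkpoints, and a manifest.
#' @return (invisibly when writing) list with `metrics` (one row per window
#'   x approach), `predictions` (one row per test experiment x model),
#'   `models`, `calibration`, `cv`.
#' @export
run_pipeline <- function(set, windows = WINDOW_HOURS,
                         approach = c("both", "direct", "indirect"),
                         seed = 1L, epochs = NULL, do_cv = is.null(epochs),
                         cv_max_epochs = 800L, rule = "trapezoid",
                         cutoff = 0.01, pollution_threshold = NULL,
                         out_dir = NULL) {
  approach <- match.arg(approach)
  approaches <- if (approach == "both") c("direct", "indirect") else approach
  stopifnot(inherits(set, "experiment_set"))
  train_ids <- set_ids(set, "train")
  test_ids <- set_ids(set, "test")
  if (length(test_ids) == 0L) stop("the experiment set has no test role")

  # calibration from training experiments' true (observed) charges
  train_charges <- vapply(set$traces[train_ids], trace_charge, numeric(1),
                          rule = rule)
  cal <- fit_calibration(train_charges, set_masses(set, "train"))
  true_test <- set_masses(set, "test")

  metrics <- list(); predictions <- list(); models <- list(); cv_out <- list()
  for (wi in seq_along(windows)) {
    w <- window_spec(windows[wi])
    for (ap in approaches) {
      model_seed <- as.integer(seed) + 1013L * wi +
        if (ap == "direct") 0L else 503L
      des_tr <- build_design(set, w, ap, role = "train")
      des_te <- build_design(set, w, ap, role = "test")
      cfg <- registry_config(w, ap, seed = model_seed)
      ep_override <- if (is.null(epochs)) NULL
                     else if (!is.null(names(epochs))) epochs[[ap]]
                     else epochs
      key <- sprintf("%dh_%s", w$hours, ap)

      if (do_cv) {
        plan <- fold_plan(train_ids, 5L)
        cv <- cross_validate(cfg, des_tr$inputs, des_tr$targets, plan,
                             max_epochs = cv_max_epochs, seed = model_seed)
        cfg <- cv$config
        cv_out[[key]] <- cv
      } else if (!is.null(ep_override)) {
        cfg$epochs <- as.integer(ep_override)
      }

      fit <- train_mlp(cfg, des_tr$inputs, des_tr$targets, seed = model_seed)
      models[[key]] <- fit

      if (ap == "direct") {
        pred <- predict_direct(fit, des_te$inputs)
        pred_df <- data.frame(experiment_id = test_ids,
                              window_h = w$hours, approach = ap,
                              true_bod5_mg = unname(true_test),
                              pred_bod5_mg = pred, charge_C = NA_real_)
      } else {
        cont <- predict_continuation(fit, des_te$inputs)
        ib <- indirect_bod(des_te$inputs, cont, cal,
                           resistance = set$traces[[test_ids[1]]]$external_resistance,
                           rule = rule, cutoff = cutoff)
        pred <- ib$bod5_mg
        pred_df <- data.frame(experiment_id = test_ids,
                              window_h = w$hours, approach = ap,
                              true_bod5_mg = unname(true_test),
                              pred_bod5_mg = pred, charge_C = ib$charge_C)
      }
      rep <- metrics_report(unname(true_test), pred)
      mrow <- data.frame(window_h = w$hours, approach = ap,
                         epochs = cfg$epochs, mape_pct = rep$mape,
                         max_abs_error_mg = rep$max_abs_error, r2 = rep$r2,
                         n_test = rep$n)
      if (!is.null(pollution_threshold)) {
        vol <- vapply(set$traces[test_ids], `[[`, numeric(1), "sample_volume")
        cls <- classify_and_score(
          mass_to_concentration(unname(true_test), vol),
          mass_to_concentration(pred, vol), pollution_threshold)
        mrow$sensitivity <- cls$sensitivity
        mrow$specificity <- cls$specificity
        mrow$accuracy <- cls$accuracy
      }
      metrics[[key]] <- mrow
      predictions[[key]] <- pred_df
    }
  }

  res <- list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
              predictions = do.call(rbind, c(predictions,
                                             make.row.names = FALSE)),
              models = models, calibration = cal, cv = cv_out)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    model_dir <- file.path(out_dir, "models")
    dir.create(model_dir, showWarnings = FALSE)
    for (key in names(models)) {
      saveRDS(models[[key]], file.path(model_dir, paste0(key, ".rds")))
    }
    manifest <- c(
      sprintf("package: mfcbod5 %s",
              as.character(utils::packageVersion("mfcbod5"))),
      sprintf("seed: %d", as.integer(seed)),
      sprintf("windows: %s", paste(windows, collapse = ",")),
      sprintf("approach: %s", approach),
      sprintf("rule: %s; cutoff: %g V", rule, cutoff),
      sprintf("n_train: %d; n_test: %d", length(train_ids), length(test_ids)),
      sprintf("calibration: slope %.6g mg/C, intercept %.6g mg",
              cal$slope, cal$intercept))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
    return(invisible(res))
  }
  res
}
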