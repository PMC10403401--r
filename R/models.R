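# Multilayer perceptrons ------------------------------------------------------
#
# Twelve fixed architectures (6 input windows x {direct, indirect}) with
# three ReLU hidden layers, per-layer dropout, a linear output layer, and
# full-batch Adam. The training set is tiny (tens of experiments), so plain
# BLAS-backed matrix algebra in R is fast enough; no deep-learning framework
# is needed and reproducibility is exact under a seed.

# Table rows: hidden widths, dropout rates, and learning rates for each
# window. Direct nets emit one BOD5 value (lr 0.001); indirect nets emit the
# voltage continuation (lr 0.0001).
.mlp_registry <- list(
  direct = list(
    `2`  = list(hidden = c(128, 128, 64),  dropout = c(0.30, 0.30, 0.50)),
    `6`  = list(hidden = c(128, 128, 64),  dropout = c(0.10, 0.50, 0.50)),
    `8`  = list(hidden = c(128, 64, 64),   dropout = c(0.10, 0.30, 0.50)),
    `12` = list(hidden = c(96, 96, 64),    dropout = c(0.10, 0.10, 0.40)),
    `16` = list(hidden = c(128, 128, 128), dropout = c(0.10, 0.30, 0.30)),
    `24` = list(hidden = c(128, 128, 64),  dropout = c(0.10, 0.10, 0.30))
  ),
  indirect = list(
    `2`  = list(hidden = c(128, 128, 64), dropout = c(0.30, 0.30, 0.50)),
    `6`  = list(hidden = c(128, 64, 64),  dropout = c(0.20, 0.50, 0.50)),
    `8`  = list(hidden = c(128, 128, 64), dropout = c(0.25, 0.50, 0.50)),
    `12` = list(hidden = c(128, 64, 64),  dropout = c(0.10, 0.30, 0.50)),
    `16` = list(hidden = c(128, 64, 64),  dropout = c(0.10, 0.10, 0.50)),
    `24` = list(hidden = c(128, 128, 64), dropout = c(0.10, 0.20, 0.50))
  )
)

# Default epoch counts: the registry tables do not fix them; these were
# chosen once by block cross-validation on synthetic development data and
# can be overridden everywhere an epoch argument is exposed.
.default_epochs <- c(direct = 600L, indirect = 400L)

#' MLP configuration
#'
#' @param n_input input width (observed samples).
#' @param hidden three hidden-layer widths.
#' @param dropout three per-layer dropout rates in `[0, 1)`.
#' @param n_output output width (1 for direct, `1511 - n_input` for
#'   indirect).
#' @param learning_rate Adam step size.
#' @param loss `"mse_direct"` or `"mse_indirect"` (both are mean squared
#'   error over all output elements; the label records the route).
#' @param epochs number of full-batch epochs.
#' @param seed default training seed.
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(n_input, hidden, dropout, n_output,
                       learning_rate = 0.001,
                       loss = c("mse_direct", "mse_indirect"),
                       epochs = 600L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(length(hidden) == 3L, length(dropout) == 3L,
            all(hidden >= 1), all(dropout >= 0), all(dropout < 1),
            n_input >= 1, n_output >= 1, learning_rate > 0, epochs >= 0)
  structure(
    list(n_input = as.integer(n_input), hidden = as.integer(hidden),
         dropout = as.double(dropout), n_output = as.integer(n_output),
         learning_rate = learning_rate, loss = loss,
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "mlp_config"
  )
}

#' @export
print.mlp_config <- function(x, ...) {
  cat(sprintf(
    "<mlp_config> %s: %d -> %s -> %d, dropout (%s), lr %g, %d epochs\n",
    x$loss, x$n_input, paste(x$hidden, collapse = "-"), x$n_output,
    paste(sprintf("%.0f%%", 100 * x$dropout), collapse = ", "),
    x$learning_rate, x$epochs))
  invisible(x)
}

#' Look up the registered architecture for a window and approach
#'
#' Returns the fixed architecture row for that input size: hidden widths
#' drawn from {64, 96, 128}, dropout from {10, 20, 25, 30, 40, 50}%,
#' learning rate 0.001 (direct) or 0.0001 (indirect).
#'
#' @param window a [window_spec()] or an hours value in
#'   `{2, 6, 8, 12, 16, 24}`.
#' @param approach `"direct"` or `"indirect"`.
#' @param epochs optional epoch override; defaults to the registry default
#'   for the approach.
#' @param seed default training seed stored on the config.
#' @return an [mlp_config()].
#' @export
registry_config <- function(window, approach = c("direct", "indirect"),
                            epochs = NULL, seed = 1L) {
  approach <- match.arg(approach)
  w <- if (inherits(window, "window_spec")) window else window_spec(window)
  row <- .mlp_registry[[approach]][[as.character(w$hours)]]
  if (is.null(row)) stop("no registry entry for window ", w$hours, " h")
  mlp_config(
    n_input = w$n_input, hidden = row$hidden, dropout = row$dropout,
    n_output = if (approach == "direct") 1L else w$n_output,
    learning_rate = if (approach == "direct") 0.001 else 0.0001,
    loss = if (approach == "direct") "mse_direct" else "mse_indirect",
    epochs = if (is.null(epochs)) .default_epochs[[approach]] else epochs,
    seed = seed
  )
}

# weight init: uniform with fan-in scaling (He-style bound for ReLU nets)
init_weights <- function(config) {
  dims <- c(config$n_input, config$hidden, config$n_output)
  W <- vector("list", 4L)
  b <- vector("list", 4L)
  for (l in 1:4) {
    bound <- sqrt(6 / dims[l])
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -bound, bound),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

add_bias <- function(Z, b) sweep(Z, 2, b, `+`)

# forward pass; when `masks` is given, applies inverted dropout after each
# hidden ReLU (training mode)
mlp_forward <- function(weights, X, masks = NULL) {
  A <- X
  act <- vector("list", 4L)
  pre <- vector("list", 4L)
  for (l in 1:3) {
    Z <- add_bias(A %*% weights$W[[l]], weights$b[[l]])
    H <- pmax(Z, 0)
    if (!is.null(masks)) H <- H * masks[[l]]
    pre[[l]] <- Z
    act[[l]] <- H
    A <- H
  }
  out <- add_bias(A %*% weights$W[[4]], weights$b[[4]])
  list(output = out, pre = pre, act = act, input = X)
}

mlp_backward <- function(weights, fwd, Y, masks = NULL) {
  n_el <- length(Y)
  d <- 2 * (fwd$output - Y) / n_el     # d(mean sq err)/d(output)
  gW <- vector("list", 4L)
  gb <- vector("list", 4L)
  gW[[4]] <- crossprod(fwd$act[[3]], d)
  gb[[4]] <- colSums(d)
  for (l in 3:1) {
    d <- d %*% t(weights$W[[l + 1]])
    if (!is.null(masks)) d <- d * masks[[l]]
    d <- d * (fwd$pre[[l]] > 0)
    A_prev <- if (l == 1) fwd$input else fwd$act[[l - 1]]
    gW[[l]] <- crossprod(A_prev, d)
    gb[[l]] <- colSums(d)
  }
  list(W = gW, b = gb)
}

#' Train an MLP by full-batch Adam
#'
#' Minimises mean squared error over all output elements (the direct loss
#' averages over experiments; the indirect loss over experiments times time
#' points — identical arithmetic, different shapes). Dropout is active only
#' here; inference is deterministic. The run is bit-reproducible for a given
#' seed.
#'
#' @param config an [mlp_config()].
#' @param inputs numeric matrix, experiments x `n_input`.
#' @param targets numeric matrix (or vector for direct), experiments x
#'   `n_output`.
#' @param seed training seed; defaults to `config$seed`.
#' @param epochs override of `config$epochs`.
#' @param validation optional `list(inputs =, targets =)`; when supplied the
#'   training log records per-epoch validation loss (dropout off).
#' @param dropout_off set `TRUE` to disable dropout (capacity checks).
#' @return object of class `trained_mlp` with `config`, `weights`,
#'   `training_log` (data.frame epoch/train_loss/val_loss).
#' @export
train_mlp <- function(config, inputs, targets, seed = config$seed,
                      epochs = config$epochs, validation = NULL,
                      dropout_off = FALSE) {
  stopifnot(inherits(config, "mlp_config"))
  X <- as.matrix(inputs)
  Y <- as.matrix(targets)
  if (nrow(X) != nrow(Y)) stop("row count mismatch between inputs and targets")
  if (ncol(X) != config$n_input) {
    stop("inputs have ", ncol(X), " columns; config expects ", config$n_input)
  }
  if (ncol(Y) != config$n_output) {
    stop("targets have ", ncol(Y), " columns; config expects ", config$n_output)
  }
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite training data")

  drop_p <- if (dropout_off) rep(0, 3) else config$dropout
  set.seed(as.integer(seed))
  weights <- init_weights(config)

  # Adam state (Keras-style defaults beyond the learning rate)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  mW <- lapply(weights$W, function(w) w * 0); vW <- mW
  mb <- lapply(weights$b, function(b) b * 0); vb <- mb

  has_val <- !is.null(validation)
  if (has_val) {
    Xv <- as.matrix(validation$inputs)
    Yv <- as.matrix(validation$targets)
  }
  log_train <- numeric(epochs)
  log_val <- if (has_val) numeric(epochs) else NULL
  n <- nrow(X)

  for (ep in seq_len(epochs)) {
    masks <- lapply(1:3, function(l) {
      p <- drop_p[l]
      if (p == 0) {
        matrix(1, n, config$hidden[l])
      } else {
        matrix(stats::rbinom(n * config$hidden[l], 1, 1 - p) / (1 - p),
               n, config$hidden[l])
      }
    })
    fwd <- mlp_forward(weights, X, masks)
    grad <- mlp_backward(weights, fwd, Y, masks)
    for (l in 1:4) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * grad$W[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * grad$W[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * grad$b[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * grad$b[[l]]^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
      weights$W[[l]] <- weights$W[[l]] -
        config$learning_rate * mhW / (sqrt(vhW) + eps)
      weights$b[[l]] <- weights$b[[l]] -
        config$learning_rate * mhb / (sqrt(vhb) + eps)
    }
    log_train[ep] <- mean((mlp_forward(weights, X)$output - Y)^2)
    if (has_val) {
      log_val[ep] <- mean((mlp_forward(weights, Xv)$output - Yv)^2)
    }
  }

  log <- data.frame(epoch = seq_len(epochs), train_loss = log_train)
  if (has_val) log$val_loss <- log_val
  structure(list(config = config, weights = weights, training_log = log),
            class = "trained_mlp")
}

#' @export
print.trained_mlp <- function(x, ...) {
  last <- if (nrow(x$training_log)) utils::tail(x$training_log$train_loss, 1) else NA
  cat(sprintf("<trained_mlp> %s, %d epochs trained, final train MSE %.4g\n",
              x$config$loss, nrow(x$training_log), last))
  invisible(x)
}

mlp_predict_matrix <- function(model, X) {
  stopifnot(inherits(model, "trained_mlp"))
  X <- as.matrix(X)
  if (ncol(X) != model$config$n_input) {
    stop("input has ", ncol(X), " columns; model expects ",
         model$config$n_input)
  }
  mlp_forward(model$weights, X)$output
}

#' Predict BOD5 mass from an input window (direct route)
#'
#' @param model a direct [train_mlp()] model (`n_output == 1`).
#' @param window_input one window (vector of `n_input` voltages) or a matrix
#'   of windows (experiments as rows).
#' @return BOD5 estimate(s) in mg, clamped at 0.
#' @export
predict_direct <- function(model, window_input) {
  if (model$config$n_output != 1L) stop("not a direct model")
  X <- if (is.matrix(window_input)) window_input else
    matrix(window_input, nrow = 1)
  pmax(0, as.vector(mlp_predict_matrix(model, X)))
}

#' Predict the voltage continuation from an input window (indirect route)
#'
#' @param model an indirect [train_mlp()] model.
#' @param window_input one window (vector) or a matrix of windows.
#' @return continuation matrix (rows = experiments, `n_output` columns); a
#'   vector when a single window was supplied.
#' @export
predict_continuation <- function(model, window_input) {
  if (model$config$n_output == 1L) stop("not an indirect model")
  single <- !is.matrix(window_input)
  X <- if (single) matrix(window_input, nrow = 1) else window_input
  out <- mlp_predict_matrix(model, X)
  if (single) as.vector(out) else out
}

# Block cross-validation -------------------------------------------------------

#' Partition experiment ids into contiguous equal blocks
#'
#' @param ids experiment ids in dataset order.
#' @param k number of blocks, default 5.
#' @return object of class `fold_plan`: a list of k id vectors.
#' @export
fold_plan <- function(ids, k = 5L) {
  n <- length(ids)
  if (n %% k != 0) {
    stop(n, " experiments cannot be partitioned into ", k, " equal blocks")
  }
  blocks <- split(ids, rep(seq_len(k), each = n / k))
  structure(unname(blocks), class = "fold_plan", k = k)
}

#' Block k-fold cross-validation with epoch selection
#'
#' For each candidate configuration, trains on k-1 blocks and records the
#' validation loss on the held-out block at every epoch, rotating through
#' all blocks. The per-epoch validation losses are averaged over blocks and
#' the epoch minimising the mean is selected; across candidates, the
#' configuration with the smallest minimum mean validation loss wins.
#'
#' @param configs one [mlp_config()] or a list of candidates.
#' @param inputs,targets training design (rows named by experiment id).
#' @param plan a [fold_plan()] over the training ids.
#' @param max_epochs epochs to explore (default: the largest candidate
#'   `epochs`).
#' @param seed base seed; each (candidate, fold) gets a derived seed.
#' @return list with `config` (winning config, `epochs` set to the selected
#'   epoch), `best_epoch`, `best_loss`, and `candidates` (per-candidate mean
#'   validation-loss curves and per-fold losses at the selected epoch).
#' @export
cross_validate <- function(configs, inputs, targets, plan,
                           max_epochs = NULL, seed = 1L) {
  if (inherits(configs, "mlp_config")) configs <- list(configs)
  stopifnot(inherits(plan, "fold_plan"))
  X <- as.matrix(inputs); Y <- as.matrix(targets)
  ids <- rownames(X)
  if (is.null(ids)) stop("`inputs` must carry experiment ids as rownames")
  if (!setequal(unlist(plan), ids)) {
    stop("fold plan ids do not match the training ids")
  }
  if (is.null(max_epochs)) {
    max_epochs <- max(vapply(configs, `[[`, integer(1), "epochs"))
  }

  results <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    val_curves <- matrix(NA_real_, max_epochs, length(plan))
    for (fi in seq_along(plan)) {
      val_ids <- plan[[fi]]
      tr_ids <- setdiff(ids, val_ids)
      fit <- train_mlp(cfg, X[tr_ids, , drop = FALSE],
                       Y[tr_ids, , drop = FALSE],
                       seed = seed + 1000L * ci + fi,
                       epochs = max_epochs,
                       validation = list(inputs = X[val_ids, , drop = FALSE],
                                         targets = Y[val_ids, , drop = FALSE]))
      val_curves[, fi] <- fit$training_log$val_loss
    }
    mean_curve <- rowMeans(val_curves)
    best_ep <- which.min(mean_curve)
    results[[ci]] <- list(config = cfg, mean_curve = mean_curve,
                          best_epoch = best_ep,
                          best_loss = mean_curve[best_ep],
                          fold_losses = val_curves[best_ep, ])
  }
  losses <- vapply(results, `[[`, numeric(1), "best_loss")
  win <- which.min(losses)
  best_cfg <- results[[win]]$config
  best_cfg$epochs <- as.integer(results[[win]]$best_epoch)
  list(config = best_cfg, best_epoch = results[[win]]$best_epoch,
       best_loss = results[[win]]$best_loss, candidates = results)
}
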