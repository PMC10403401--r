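# MLP registry, training, and cross-validation

test_that("registry holds the 12 fixed architectures", {
  # direct rows: input -> hidden widths / dropout, one output, lr 0.001
  direct <- list(
    `2`  = list(c(128, 128, 64),  c(0.30, 0.30, 0.50)),
    `6`  = list(c(128, 128, 64),  c(0.10, 0.50, 0.50)),
    `8`  = list(c(128, 64, 64),   c(0.10, 0.30, 0.50)),
    `12` = list(c(96, 96, 64),    c(0.10, 0.10, 0.40)),
    `16` = list(c(128, 128, 128), c(0.10, 0.30, 0.30)),
    `24` = list(c(128, 128, 64),  c(0.10, 0.10, 0.30)))
  indirect <- list(
    `2`  = list(c(128, 128, 64), c(0.30, 0.30, 0.50)),
    `6`  = list(c(128, 64, 64),  c(0.20, 0.50, 0.50)),
    `8`  = list(c(128, 128, 64), c(0.25, 0.50, 0.50)),
    `12` = list(c(128, 64, 64),  c(0.10, 0.30, 0.50)),
    `16` = list(c(128, 64, 64),  c(0.10, 0.10, 0.50)),
    `24` = list(c(128, 128, 64), c(0.10, 0.20, 0.50)))
  for (h in WINDOW_HOURS) {
    w <- window_spec(h)
    cd <- registry_config(h, "direct")
    expect_identical(cd$n_input, w$n_input)
    expect_identical(cd$hidden, as.integer(direct[[as.character(h)]][[1]]))
    expect_identical(cd$dropout, direct[[as.character(h)]][[2]])
    expect_identical(cd$n_output, 1L)
    expect_identical(cd$learning_rate, 0.001)
    ci <- registry_config(h, "indirect")
    expect_identical(ci$hidden, as.integer(indirect[[as.character(h)]][[1]]))
    expect_identical(ci$dropout, indirect[[as.character(h)]][[2]])
    expect_identical(ci$n_output, w$n_output)
    expect_identical(ci$learning_rate, 1e-04)
  }
})

test_that("training is seed-reproducible and zero epochs leave init intact", {
  set.seed(1)
  X <- matrix(runif(8 * 25), 8)
  y <- matrix(runif(8, 5, 40), ncol = 1)
  cfg <- mlp_config(25, c(16, 16, 8), c(0.2, 0.2, 0.2), 1, epochs = 50)
  a <- train_mlp(cfg, X, y, seed = 4)
  b <- train_mlp(cfg, X, y, seed = 4)
  expect_identical(a$weights, b$weights)
  c2 <- train_mlp(cfg, X, y, seed = 5)
  expect_false(identical(a$weights, c2$weights))
  # zero epochs: the model is the seeded initialisation
  z <- train_mlp(cfg, X, y, seed = 4, epochs = 0)
  set.seed(4)
  expect_identical(z$weights, mfcbod5:::init_weights(cfg))
  expect_identical(nrow(z$training_log), 0L)
})

test_that("training loss decreases in trend and matches the configured loss", {
  set.seed(2)
  X <- matrix(runif(10 * 25), 10)
  y <- matrix(rowSums(X[, 1:5]) * 10, ncol = 1)
  cfg <- mlp_config(25, c(16, 16, 8), c(0, 0, 0), 1, epochs = 400)
  fit <- train_mlp(cfg, X, y, seed = 1)
  log <- fit$training_log$train_loss
  expect_lt(mean(tail(log, 20)), mean(head(log, 20)))
  # logged loss equals an independent elementwise recomputation
  pred <- predict_direct(fit, X)
  expect_equal(tail(log, 1), mse_direct(as.vector(y), pred),
               tolerance = 1e-10)
})

test_that("capacity check: a dropout-free net overfits 4 experiments", {
  set0 <- noiseless_set()
  ids <- set_ids(set0)[1:4]
  sub <- experiment_set(set0$traces[ids], rep("train", 4))
  des <- build_design(sub, 2, "direct")
  cfg <- registry_config(2, "direct", epochs = 2500, seed = 3)
  fit <- train_mlp(cfg, des$inputs, des$targets, dropout_off = TRUE)
  final <- tail(fit$training_log$train_loss, 1)
  expect_lt(final, 1e-4 * var(as.vector(des$targets)))
})

test_that("dropout is inactive at inference: repeated predictions identical", {
  set.seed(3)
  X <- matrix(runif(6 * 25), 6)
  y <- matrix(runif(6), ncol = 1)
  cfg <- mlp_config(25, c(32, 32, 16), c(0.5, 0.5, 0.5), 1, epochs = 30)
  fit <- train_mlp(cfg, X, y, seed = 1)
  p1 <- predict_direct(fit, X)
  p2 <- predict_direct(fit, X)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)) && all(p1 >= 0))
})

test_that("prediction dimensions and clamping follow the contracts", {
  set.seed(4)
  Xd <- matrix(runif(5 * 289), 5)
  fit_d <- train_mlp(registry_config(24, "direct", epochs = 5, seed = 1),
                     Xd, matrix(runif(5, 5, 40), ncol = 1))
  expect_length(predict_direct(fit_d, Xd[1, ]), 1)
  expect_true(all(predict_direct(fit_d, Xd) >= 0))
  expect_error(predict_direct(fit_d, Xd[, 1:100]), "columns")
  fit_i <- train_mlp(registry_config(16, "indirect", epochs = 2, seed = 1),
                     matrix(runif(5 * 193), 5), matrix(runif(5 * 1318), 5))
  out <- predict_continuation(fit_i, runif(193))
  expect_length(out, 1318)
  expect_true(all(is.finite(out)))
  expect_error(predict_direct(fit_i, runif(193)), "not a direct")
  expect_error(predict_continuation(fit_d, runif(289)), "not an indirect")
})

test_that("fold_plan partitions 40 ids into 5 disjoint blocks of 8", {
  ids <- sprintf("e%02d", 1:40)
  plan <- fold_plan(ids, 5)
  expect_length(plan, 5)
  expect_true(all(lengths(plan) == 8))
  expect_setequal(unlist(plan), ids)
  expect_identical(anyDuplicated(unlist(plan)), 0L)
  expect_error(fold_plan(ids[1:39], 5), "partition")
})

test_that("cross_validate rotates every block once and averages fold losses", {
  set.seed(6)
  n <- 10
  X <- matrix(runif(n * 25), n, dimnames = list(sprintf("e%d", 1:n), NULL))
  y <- matrix(rowSums(X[, 1:3]), ncol = 1, dimnames = list(rownames(X), NULL))
  cfg <- mlp_config(25, c(8, 8, 8), c(0, 0, 0), 1, epochs = 40)
  plan <- fold_plan(rownames(X), 5)
  cv <- cross_validate(cfg, X, y, plan, max_epochs = 40, seed = 2)
  cand <- cv$candidates[[1]]
  expect_length(cand$fold_losses, 5)
  expect_length(cand$mean_curve, 40)
  expect_identical(cv$best_epoch, which.min(cand$mean_curve))
  # mean validation loss = arithmetic mean of the 5 block losses,
  # recomputed by brute force at the selected epoch
  brute <- vapply(seq_along(plan), function(fi) {
    val <- plan[[fi]]; tr <- setdiff(rownames(X), val)
    fit <- train_mlp(cfg, X[tr, , drop = FALSE], y[tr, , drop = FALSE],
                     seed = 2 + 1000L + fi, epochs = cv$best_epoch)
    raw <- mfcbod5:::mlp_predict_matrix(fit, X[val, , drop = FALSE])
    mean((raw - y[val, ])^2)
  }, numeric(1))
  expect_equal(cand$mean_curve[cv$best_epoch], mean(brute), tolerance = 1e-8)
})
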