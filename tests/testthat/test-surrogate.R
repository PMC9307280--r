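test_that("network architecture follows the layer specification", {
  hp <- hyperparameters(3, 16, 32, 1e-2)
  m <- build_surrogate(hp, 8, 5, seed = 4)
  expect_length(m$params$W, 3)
  expect_equal(dim(m$params$W[[1]]), c(16, 8))
  expect_equal(dim(m$params$W[[2]]), c(16, 16))
  expect_equal(dim(m$params$W_out), c(5, 16))
  ## determinism under seed
  m2 <- build_surrogate(hp, 8, 5, seed = 4)
  expect_identical(m$params, m2$params)
  m3 <- build_surrogate(hp, 8, 5, seed = 5)
  expect_false(identical(m$params$W[[1]], m3$params$W[[1]]))
  ## smallest case: one hidden node
  m4 <- build_surrogate(hyperparameters(1, 1, 32, 1e-2), 60, 45)
  expect_equal(dim(m4$params$W[[1]]), c(1, 60))
  expect_equal(dim(m4$params$W_out), c(45, 1))
  expect_error(build_surrogate(hp, 0, 5), "domain error")
})

test_that("parameter count matches the closed form and a brute-force count", {
  ## printed best architecture
  expect_identical(count_parameters(hyperparameters(7, 200), 60, 45),
                   262445L)
  ## smallest case by hand: 1x60+1 + 45x1+45 = 61 + 90
  expect_identical(count_parameters(hyperparameters(1, 1), 60, 45), 151L)
  ## oracle equivalence: enumerate every weight/bias entry in the built
  ## model, across several architectures
  for (hp in list(hyperparameters(1, 1), hyperparameters(2, 7),
                  hyperparameters(5, 50), hyperparameters(7, 200))) {
    m <- build_surrogate(hp, 60, 45, seed = 1)
    brute <- sum(vapply(m$params$W, length, numeric(1))) +
      sum(vapply(m$params$b, length, numeric(1))) +
      length(m$params$W_out) + length(m$params$b_out)
    expect_identical(count_parameters(m), as.integer(brute))
  }
  ## doubling the width grows the count ~ quadratically
  c1 <- count_parameters(hyperparameters(5, 100), 60, 45)
  c2 <- count_parameters(hyperparameters(5, 200), 60, 45)
  expect_gt(c2 / c1, 3.3)
  expect_lt(c2 / c1, 4)
})

test_that("scaling maps bounds to [-1, 1] and standardizes outputs", {
  ld <- linear_dataset(n = 300, seed = 8)
  spec <- fit_scaling(ld$train, ld$manifest)
  ## bounds map to the interval ends
  lo <- ld$manifest$lower; names(lo) <- ld$manifest$name
  hi <- ld$manifest$upper; names(hi) <- ld$manifest$name
  expect_equal(unname(scale_inputs(rbind(lo), spec))[1, ],
               rep(-1, length(lo)))
  expect_equal(unname(scale_inputs(rbind(hi), spec))[1, ],
               rep(1, length(hi)))
  ## standardized training outputs: mean 0, SD 1
  Ys <- scale_outputs(ld$train$outputs, spec)
  expect_lt(max(abs(colMeans(Ys))), 1e-10)
  expect_lt(max(abs(apply(Ys, 2, stats::sd) - 1)), 1e-10)
  ## validation scaled with the training statistics, not its own
  Yv <- scale_outputs(ld$validation$outputs, spec)
  expect_equal(unname(Yv[1, 1]),
               unname((ld$validation$outputs[1, 1] - spec$out_mean[1]) /
                        spec$out_sd[1]))
  expect_gt(max(abs(colMeans(Yv))), 1e-10)
  ## round trip
  expect_equal(unscale_outputs(Ys, spec),
               as.matrix(ld$train$outputs), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## degenerate output column
  degen <- ld$train
  degen$outputs$y1 <- 1
  expect_error(fit_scaling(degen, ld$manifest), "scaling error")
})

test_that("the forward pass matches hand-computed matrix arithmetic", {
  ## 2-2-1 toy network without the batch-norm shift (gamma = sd, beta =
  ## mean restores the raw pre-activation)
  hp <- hyperparameters(1, 2, 4, 1e-2)
  m <- build_surrogate(hp, 2, 1, seed = 1)
  m$params$W[[1]] <- matrix(c(1, -1, 0.5, 2), 2, 2)
  m$params$b[[1]] <- c(0.1, -0.2)
  m$params$W_out <- matrix(c(3, -1), 1, 2)
  m$params$b_out <- 0.5
  ## evaluation mode with identity batch-norm statistics
  m$bn$mean[[1]] <- c(0, 0); m$bn$var[[1]] <- c(1, 1) - 1e-5
  x <- c(0.3, -0.7)
  z <- as.numeric(m$params$W[[1]] %*% x + m$params$b[[1]])
  h <- pmax(z, 0)
  hand <- as.numeric(m$params$W_out %*% h + m$params$b_out)
  fwd <- cowsim:::surrogate_forward
  got <- fwd(m, matrix(x, 1), train_mode = FALSE)$Yhat
  expect_equal(as.numeric(got), hand, tolerance = 1e-9)
  ## all-zero weights return the bias
  m$params$W[[1]][] <- 0; m$params$W_out[] <- 0; m$params$b[[1]][] <- 0
  got0 <- fwd(m, matrix(x, 1), train_mode = FALSE)$Yhat
  expect_equal(as.numeric(got0), 0.5)
})

test_that("prediction metrics reproduce their defining identities", {
  set.seed(2)
  R <- matrix(stats::rnorm(50), 10, 5)
  ## perfect fit
  m <- evaluate_metrics(R, R)
  expect_equal(m$mse_loss, 0)
  expect_equal(m$r2, 1)
  expect_equal(unname(m$mae), rep(0, 5))
  ## predicting the column means gives R^2 = 0
  M <- matrix(colMeans(R), 10, 5, byrow = TRUE)
  expect_equal(evaluate_metrics(M, R)$r2, 0)
  ## hand-computed half-explained case: refs {0, 2}, preds {0, 1}
  expect_equal(evaluate_metrics(matrix(c(0, 1)), matrix(c(0, 2)))$r2, 0.5)
  expect_equal(evaluate_metrics(matrix(c(0, 1)), matrix(c(0, 2)))$mse_loss,
               0.5)
  expect_error(evaluate_metrics(R, R[1:3, ]), "domain error")
})

test_that("training fits a representable target and restores the best epoch", {
  ld <- linear_dataset(n = 500, d = 6, k = 3, noise = 0.01, seed = 3)
  fit <- train_surrogate(ld$train, ld$validation, ld$manifest,
                         hyperparameters(2, 32, 64, 10^-2.5), seed = 2,
                         max_epochs = 400, window = 50, patience = 3)
  expect_gt(fit$report$best_r2_val, 0.99)
  expect_lte(fit$report$best_epoch, fit$report$stop_epoch)
  ## the restored weights reproduce the reported best validation R^2
  spec <- fit$model$scaling
  Yp <- predict_surrogate(fit$model, ld$validation$inputs,
                          warn_extrapolation = FALSE)
  Yv <- as.matrix(ld$validation$outputs)
  r2 <- 1 - sum((scale_outputs(Yv, spec) - scale_outputs(Yp, spec))^2) /
    sum(sweep(scale_outputs(Yv, spec), 2,
              colMeans(scale_outputs(Yv, spec)))^2)
  expect_equal(r2, fit$report$best_r2_val, tolerance = 1e-8)
  ## least-squares oracle: the linear fit's R^2 bounds what the net can
  ## achieve; the net should come close on a linear target
  Xtr <- as.matrix(ld$train$inputs); Ytr <- as.matrix(ld$train$outputs)
  ls_fit <- stats::lm.fit(cbind(1, Xtr), Ytr)
  Yls <- cbind(1, as.matrix(ld$validation$inputs)) %*% ls_fit$coefficients
  r2_ls <- 1 - sum((Yv - Yls)^2) / sum(sweep(Yv, 2, colMeans(Yv))^2)
  expect_gt(fit$report$best_r2_val, r2_ls - 0.02)

  ## batched prediction equals row-by-row prediction
  P1 <- predict_surrogate(fit$model, ld$test$inputs,
                          warn_extrapolation = FALSE)
  P2 <- t(apply(ld$test$inputs, 1, function(r) {
    predict_surrogate(fit$model, r, warn_extrapolation = FALSE)
  }))
  expect_equal(unname(P1), unname(P2), tolerance = 1e-10)
  ## extrapolation warning
  far <- ld$test$inputs[1, ]; far[1] <- 5
  expect_warning(predict_surrogate(fit$model, far), "extrapolating")
})

test_that("early stopping halts after three non-improving windows", {
  ## pure-noise target: validation R^2 cannot improve systematically, so
  ## the windowed rule must fire well before the epoch cap
  ld <- linear_dataset(n = 200, d = 4, k = 2, noise = 1e6, seed = 9)
  fit <- train_surrogate(ld$train, ld$validation, ld$manifest,
                         hyperparameters(1, 8, 64, 1e-2), seed = 1,
                         max_epochs = 2000, window = 10, patience = 3)
  expect_lt(fit$report$stop_epoch, 2000)
  expect_equal(fit$report$stop_epoch %% 10, 0)
})

test_that("checkpoints restore identical predictions", {
  ld <- linear_dataset(n = 200, seed = 5)
  fit <- train_surrogate(ld$train, ld$validation, ld$manifest,
                         hyperparameters(2, 16, 64, 1e-2), seed = 3,
                         max_epochs = 60, window = 20, patience = 2)
  path <- tempfile(fileext = ".json")
  save_surrogate(fit$model, path)
  m2 <- load_surrogate(path)
  P1 <- predict_surrogate(fit$model, ld$test$inputs,
                          warn_extrapolation = FALSE)
  P2 <- predict_surrogate(m2, ld$test$inputs, warn_extrapolation = FALSE)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("grid search enumerates the cells and picks the best test R^2", {
  ld <- linear_dataset(n = 300, seed = 6)
  gs <- grid_search(list(n_layer = c(1, 2), n_node = c(8, 16),
                         n_batch = 64, lr = 1e-2),
                    ld$train, ld$validation, ld$test, ld$manifest,
                    seed = 1, max_epochs = 40, window = 20, patience = 2)
  expect_equal(nrow(gs$results), 4)
  best_row <- which.max(gs$results$r2_test)
  expect_equal(gs$best_model$hp$n_layer, gs$results$n_layer[best_row])
  expect_equal(gs$best_model$hp$n_node, gs$results$n_node[best_row])
  ## singleton grids collapse to one run
  gs1 <- grid_search(list(n_layer = 1, n_node = 8, n_batch = 64, lr = 1e-2),
                     ld$train, ld$validation, ld$test, ld$manifest,
                     seed = 1, max_epochs = 20, window = 10, patience = 2)
  expect_equal(nrow(gs1$results), 1)
  expect_s3_class(gs1$best_model, "surrogate_model")
  ## the full-scale grids would enumerate 4^4 cells
  full <- expand.grid(n_layer = c(5, 7, 10, 13),
                      n_node = c(50, 100, 200, 400),
                      n_batch = c(300, 1000, 3000, 10000),
                      lr = 10^c(-3, -2.5, -2, -1.5))
  expect_equal(nrow(full), 256)
})
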