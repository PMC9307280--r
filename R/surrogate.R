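#' Surrogate hyperparameters
#'
#' The defaults are the best grid-search combination: 7 hidden layers of
#' 200 nodes, batch size 3000, initial learning rate 10^-2.5.
#'
#' @param n_layer number of hidden layers
#' @param n_node nodes per hidden layer
#' @param n_batch mini-batch size
#' @param lr initial Adam learning rate
#' @export
hyperparameters <- function(n_layer = 7, n_node = 200, n_batch = 3000,
                            lr = 10^-2.5) {
  stopifnot(n_layer >= 1, n_node >= 1, n_batch >= 1, lr > 0)
  structure(list(n_layer = as.integer(n_layer), n_node = as.integer(n_node),
                 n_batch = as.integer(n_batch), lr = lr),
            class = "hyperparameters")
}

#' Build an untrained fully connected surrogate
#'
#' Architecture: input layer, `n_layer` hidden layers (linear map, batch
#' normalization, then ReLU), and a linear output layer without
#' activation.  He-normal weight initialization, deterministic under
#' `seed`.
#'
#' @param hp a [hyperparameters()] object
#' @param d_in,d_out input/output dimensions
#' @param seed integer seed for the initialization
#' @return object of class `surrogate_model`
#' @export
build_surrogate <- function(hp, d_in, d_out, seed = 1) {
  if (d_in < 1 || d_out < 1) stop("domain error: non-positive dimensions")
  set.seed(seed)
  dims <- c(d_in, rep(hp$n_node, hp$n_layer))
  W <- list(); b <- list(); gamma <- list(); beta <- list()
  rmean <- list(); rvar <- list()
  for (l in seq_len(hp$n_layer)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(stats::rnorm(hp$n_node * fan_in, sd = sqrt(2 / fan_in)),
                     nrow = hp$n_node)
    b[[l]] <- numeric(hp$n_node)
    gamma[[l]] <- rep(1, hp$n_node)
    beta[[l]] <- numeric(hp$n_node)
    rmean[[l]] <- numeric(hp$n_node)
    rvar[[l]] <- rep(1, hp$n_node)
  }
  W_out <- matrix(stats::rnorm(d_out * hp$n_node,
                               sd = sqrt(2 / hp$n_node)), nrow = d_out)
  structure(list(
    hp = hp, d_in = d_in, d_out = d_out,
    params = list(W = W, b = b, gamma = gamma, beta = beta,
                  W_out = W_out, b_out = numeric(d_out)),
    bn = list(mean = rmean, var = rvar),
    scaling = NULL, input_names = NULL, output_names = NULL,
    training = NULL
  ), class = "surrogate_model")
}

#' Count trainable parameters (weights and biases)
#'
#' Sums `n_l * n_{l-1} + n_l` over all layers after the input layer.
#' Batch-normalization scale/shift parameters are excluded from this
#' count (they are stored in the checkpoint but not part of the reported
#' weight/bias total).
#'
#' @param x a `surrogate_model` or a [hyperparameters()] object
#' @param d_in,d_out dimensions (required when `x` is hyperparameters)
#' @return integer parameter count
#' @export
count_parameters <- function(x, d_in = NULL, d_out = NULL) {
  if (inherits(x, "surrogate_model")) {
    hp <- x$hp; d_in <- x$d_in; d_out <- x$d_out
  } else hp <- x
  dims <- c(d_in, rep(hp$n_node, hp$n_layer), d_out)
  as.integer(sum(vapply(seq_len(length(dims) - 1),
                        function(l) dims[l + 1] * dims[l] + dims[l + 1],
                        numeric(1))))
}

#' Fit input/output scaling from training data
#'
#' Inputs are mapped affinely so the declared manifest bounds land on
#' [-1, 1]; outputs are standardized to zero mean and unit SD using
#' training statistics only.  Validation and test data must be scaled
#' with these same statistics.
#'
#' @param train_ds a `cowsim_dataset` (the training partition)
#' @param manifest the input manifest (declared bounds)
#' @return object of class `scaling_spec`
#' @export
fit_scaling <- function(train_ds, manifest) {
  stopifnot(identical(names(train_ds$inputs), manifest$name))
  mu <- vapply(train_ds$outputs, mean, numeric(1))
  sd_ <- vapply(train_ds$outputs, stats::sd, numeric(1))
  if (any(sd_ <= 0)) {
    stop("scaling error: zero-variance output column(s): ",
         paste(names(sd_)[sd_ <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(in_lower = stats::setNames(manifest$lower, manifest$name),
                 in_upper = stats::setNames(manifest$upper, manifest$name),
                 out_mean = mu, out_sd = sd_),
            class = "scaling_spec")
}

#' @rdname fit_scaling
#' @param X matrix/data frame of raw inputs (columns in manifest order)
#' @param spec a `scaling_spec`
#' @export
scale_inputs <- function(X, spec) {
  X <- as.matrix(X)
  lo <- spec$in_lower; hi <- spec$in_upper
  sweep(sweep(X, 2, lo), 2, (hi - lo) / 2, "/") - 1
}

#' @rdname fit_scaling
#' @param Y matrix/data frame of outputs
#' @export
scale_outputs <- function(Y, spec) {
  sweep(sweep(as.matrix(Y), 2, spec$out_mean), 2, spec$out_sd, "/")
}

#' @rdname fit_scaling
#' @export
unscale_outputs <- function(Y, spec) {
  sweep(sweep(as.matrix(Y), 2, spec$out_sd, "*"), 2, spec$out_mean, "+")
}

## forward pass; train mode returns the cache for backprop
surrogate_forward <- function(model, X, train_mode = FALSE,
                              bn_momentum = 0.1, bn_eps = 1e-5) {
  p <- model$params
  L <- model$hp$n_layer
  H <- X
  cache <- if (train_mode) list(H = vector("list", L + 1),
                                Z = vector("list", L),
                                Zh = vector("list", L),
                                inv_sd = vector("list", L)) else NULL
  if (train_mode) cache$H[[1]] <- H
  for (l in seq_len(L)) {
    Z <- H %*% t(p$W[[l]])
    Z <- sweep(Z, 2, p$b[[l]], "+")
    if (train_mode) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
      model$bn$mean[[l]] <- (1 - bn_momentum) * model$bn$mean[[l]] +
        bn_momentum * mu
      model$bn$var[[l]] <- (1 - bn_momentum) * model$bn$var[[l]] +
        bn_momentum * v
    } else {
      mu <- model$bn$mean[[l]]
      v <- model$bn$var[[l]]
    }
    inv_sd <- 1 / sqrt(v + bn_eps)
    Zh <- sweep(sweep(Z, 2, mu), 2, inv_sd, "*")
    S <- sweep(sweep(Zh, 2, p$gamma[[l]], "*"), 2, p$beta[[l]], "+")
    Hn <- pmax(S, 0)
    if (train_mode) {
      cache$Z[[l]] <- Z; cache$Zh[[l]] <- Zh; cache$inv_sd[[l]] <- inv_sd
      cache$H[[l + 1]] <- Hn
    }
    H <- Hn
  }
  Yhat <- sweep(H %*% t(p$W_out), 2, p$b_out, "+")
  list(Yhat = Yhat, cache = cache, model = model)
}

## gradients of the mean-squared-error loss wrt all parameters
surrogate_backward <- function(model, cache, Yhat, Y) {
  p <- model$params
  L <- model$hp$n_layer
  n <- nrow(Y)
  g <- list(W = vector("list", L), b = vector("list", L),
            gamma = vector("list", L), beta = vector("list", L))
  dY <- 2 * (Yhat - Y) / (n * ncol(Y))
  g$W_out <- crossprod(dY, cache$H[[L + 1]])
  g$b_out <- colSums(dY)
  dH <- dY %*% p$W_out
  for (l in rev(seq_len(L))) {
    S_pos <- cache$H[[l + 1]] > 0
    dS <- dH * S_pos
    g$gamma[[l]] <- colSums(dS * cache$Zh[[l]])
    g$beta[[l]] <- colSums(dS)
    dZh <- sweep(dS, 2, p$gamma[[l]], "*")
    Zh <- cache$Zh[[l]]
    cs1 <- colSums(dZh)
    cs2 <- colSums(dZh * Zh)
    dZ <- sweep(
      dZh - sweep(sweep(Zh, 2, cs2, "*"), 2, cs1, "+") / n,
      2, cache$inv_sd[[l]], "*")
    g$W[[l]] <- crossprod(dZ, cache$H[[l]])
    g$b[[l]] <- colSums(dZ)
    if (l > 1) dH <- dZ %*% p$W[[l]]
  }
  g
}

#' Predict with a surrogate model
#'
#' Scales the inputs with the model's stored scaling, runs the forward
#' pass with evaluation-mode batch normalization, and inverts the output
#' scaling.  Accepts a single named vector or a batch (matrix / data
#' frame); batched prediction equals row-by-row prediction.
#'
#' @param model a trained `surrogate_model` (with scaling attached)
#' @param x named numeric vector, matrix or data frame of inputs
#' @param warn_extrapolation warn when inputs fall outside the declared
#'   training bounds
#' @return named output vector (or matrix for batched input)
#' @export
predict_surrogate <- function(model, x, warn_extrapolation = TRUE) {
  if (is.null(model$scaling)) stop("model has no scaling attached")
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
       else as.matrix(x)
  if (!is.null(colnames(X))) {
    if (!all(model$input_names %in% colnames(X))) {
      stop("layout error: missing input column(s)", call. = FALSE)
    }
    X <- X[, model$input_names, drop = FALSE]
  } else if (ncol(X) != model$d_in) {
    stop("layout error: expected ", model$d_in, " inputs", call. = FALSE)
  }
  Xs <- scale_inputs(X, model$scaling)
  if (warn_extrapolation && any(abs(Xs) > 1 + 1e-8)) {
    warning("input outside the trained bounds; surrogate is extrapolating",
            call. = FALSE)
  }
  Ys <- surrogate_forward(model, Xs, train_mode = FALSE)$Yhat
  Y <- unscale_outputs(Ys, model$scaling)
  colnames(Y) <- model$output_names
  if (single) Y[1, ] else Y
}

#' Prediction metrics
#'
#' Mean-squared-error loss `L = 1/(N_sample N_out) sum ||y - yhat||^2`,
#' pooled coefficient of determination
#' `R^2 = 1 - sum ||y - yhat||^2 / sum ||y - ybar||^2`, optional group
#' R^2 for flow/pressure column subsets, and per-output mean absolute
#' error.
#'
#' @param predictions,references matrices of equal shape
#' @param groups optional named list of column-index vectors for group
#'   R^2 values (e.g. flow vs pressure columns)
#' @return list with `mse_loss`, `r2`, `r2_groups`, `mae`
#' @export
evaluate_metrics <- function(predictions, references, groups = NULL) {
  P <- as.matrix(predictions); R <- as.matrix(references)
  if (!all(dim(P) == dim(R)) || nrow(P) == 0) {
    stop("domain error: shapes differ or empty input")
  }
  pooled_r2 <- function(p, r) {
    rc <- sweep(r, 2, colMeans(r))
    1 - sum((r - p)^2) / sum(rc^2)
  }
  r2g <- NULL
  if (!is.null(groups)) {
    r2g <- vapply(groups, function(j) {
      pooled_r2(P[, j, drop = FALSE], R[, j, drop = FALSE])
    }, numeric(1))
  }
  list(
    mse_loss = sum((P - R)^2) / (nrow(P) * ncol(P)),
    r2 = pooled_r2(P, R),
    r2_groups = r2g,
    mae = colMeans(abs(P - R))
  )
}

#' Train a surrogate
#'
#' Mini-batch Adam optimization of the mean-squared-error loss on
#' standardized outputs.  The pooled validation R^2 is computed at the
#' end of every epoch; every `window` epochs the trailing-`window` mean
#' R^2 is compared with the best window so far, and training stops after
#' `patience` successive non-improving evaluations.  The returned model
#' carries the weights of the single epoch with the highest validation
#' R^2.
#'
#' @param train_ds,val_ds training and validation `cowsim_dataset`s
#' @param manifest input manifest (declared bounds for input scaling)
#' @param hp a [hyperparameters()] object
#' @param seed integer seed (initialization and shuffling)
#' @param max_epochs hard epoch cap
#' @param window,patience early-stopping controls
#' @param verbose print progress every `window` epochs
#' @return list `model` (a `surrogate_model`), `report` (per-epoch
#'   validation R^2, best/stopping epoch, loss history)
#' @export
train_surrogate <- function(train_ds, val_ds, manifest,
                            hp = hyperparameters(), seed = 1,
                            max_epochs = 1000, window = 100, patience = 3,
                            verbose = FALSE) {
  spec <- fit_scaling(train_ds, manifest)
  Xtr <- scale_inputs(train_ds$inputs, spec)
  Ytr <- scale_outputs(train_ds$outputs, spec)
  Xva <- scale_inputs(val_ds$inputs, spec)
  Yva <- scale_outputs(val_ds$outputs, spec)
  model <- build_surrogate(hp, ncol(Xtr), ncol(Ytr), seed = seed)
  model$scaling <- spec
  model$input_names <- names(train_ds$inputs)
  model$output_names <- names(train_ds$outputs)

  ## Adam state
  adam <- list(); tstep <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  upd <- function(key, par, grad) {
    if (is.null(adam[[key]])) {
      adam[[key]] <<- list(m = par * 0, v = par * 0)
    }
    st <- adam[[key]]
    st$m <- b1 * st$m + (1 - b1) * grad
    st$v <- b2 * st$v + (1 - b2) * grad^2
    adam[[key]] <<- st
    mhat <- st$m / (1 - b1^tstep)
    vhat <- st$v / (1 - b2^tstep)
    par - hp$lr * mhat / (sqrt(vhat) + eps)
  }

  n <- nrow(Xtr)
  r2_hist <- numeric(0); loss_hist <- numeric(0)
  best_r2 <- -Inf; best_params <- NULL; best_bn <- NULL; best_epoch <- 0L
  best_window <- -Inf; n_bad <- 0L; stop_epoch <- NA_integer_
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = hp$n_batch)) {
      idx <- ord[start:min(start + hp$n_batch - 1, n)]
      if (length(idx) < 2) next   # batch statistics need >= 2 rows
      fw <- surrogate_forward(model, Xtr[idx, , drop = FALSE],
                              train_mode = TRUE)
      model <- fw$model
      g <- surrogate_backward(model, fw$cache, fw$Yhat,
                              Ytr[idx, , drop = FALSE])
      loss <- sum((fw$Yhat - Ytr[idx, , drop = FALSE])^2) /
        (length(idx) * ncol(Ytr))
      if (!is.finite(loss)) stop("training error: divergent loss")
      ep_loss <- ep_loss + loss; nb <- nb + 1
      tstep <- tstep + 1
      p <- model$params
      for (l in seq_len(hp$n_layer)) {
        p$W[[l]] <- upd(paste0("W", l), p$W[[l]], g$W[[l]])
        p$b[[l]] <- upd(paste0("b", l), p$b[[l]], g$b[[l]])
        p$gamma[[l]] <- upd(paste0("g", l), p$gamma[[l]], g$gamma[[l]])
        p$beta[[l]] <- upd(paste0("be", l), p$beta[[l]], g$beta[[l]])
      }
      p$W_out <- upd("Wo", p$W_out, g$W_out)
      p$b_out <- upd("bo", p$b_out, g$b_out)
      model$params <- p
    }
    loss_hist <- c(loss_hist, ep_loss / max(nb, 1))
    Yp <- surrogate_forward(model, Xva, train_mode = FALSE)$Yhat
    r2 <- 1 - sum((Yva - Yp)^2) / sum(sweep(Yva, 2, colMeans(Yva))^2)
    r2_hist <- c(r2_hist, r2)
    if (r2 > best_r2) {
      best_r2 <- r2; best_params <- model$params; best_bn <- model$bn
      best_epoch <- epoch
    }
    if (epoch %% window == 0) {
      wmean <- mean(utils::tail(r2_hist, window))
      if (verbose) {
        message(sprintf("epoch %d: window mean val R2 = %.5f", epoch, wmean))
      }
      if (wmean > best_window) {
        best_window <- wmean; n_bad <- 0L
      } else {
        n_bad <- n_bad + 1L
        if (n_bad >= patience) { stop_epoch <- epoch; break }
      }
    }
  }
  if (is.na(stop_epoch)) stop_epoch <- length(r2_hist)
  model$params <- best_params
  model$bn <- best_bn
  model$training <- list(best_epoch = best_epoch, stop_epoch = stop_epoch,
                         seed = seed, hp = unclass(hp))
  list(model = model,
       report = list(r2_val = r2_hist, loss = loss_hist,
                     best_epoch = best_epoch, stop_epoch = stop_epoch,
                     best_r2_val = best_r2))
}

#' Hyperparameter grid search
#'
#' Trains one model per combination of the supplied grids, compares the
#' pooled test R^2 and returns the best model with the full results
#' table.  Failed cells are recorded and skipped.
#'
#' @param grids list with vectors `n_layer`, `n_node`, `n_batch`, `lr`
#' @param train_ds,val_ds,test_ds dataset partitions
#' @param manifest input manifest
#' @param seed integer seed shared across cells
#' @param ... forwarded to [train_surrogate()]
#' @return list `best_model`, `results` (data frame over all cells)
#' @export
grid_search <- function(grids, train_ds, val_ds, test_ds, manifest,
                        seed = 1, ...) {
  combos <- expand.grid(n_layer = grids$n_layer, n_node = grids$n_node,
                        n_batch = grids$n_batch, lr = grids$lr)
  res <- combos
  res$r2_test <- NA_real_; res$error <- NA_character_
  best <- NULL; best_r2 <- -Inf
  for (i in seq_len(nrow(combos))) {
    hp <- hyperparameters(combos$n_layer[i], combos$n_node[i],
                          combos$n_batch[i], combos$lr[i])
    fit <- tryCatch(
      train_surrogate(train_ds, val_ds, manifest, hp, seed = seed, ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      res$error[i] <- conditionMessage(fit)
      next
    }
    pred <- predict_surrogate(fit$model, test_ds$inputs,
                              warn_extrapolation = FALSE)
    m <- evaluate_metrics(pred, test_ds$outputs)
    res$r2_test[i] <- m$r2
    if (m$r2 > best_r2) { best_r2 <- m$r2; best <- fit$model }
  }
  list(best_model = best, results = res)
}

#' Save / load a surrogate checkpoint
#'
#' Self-describing JSON archive bundling weights, batch-normalization
#' statistics, the scaling specification and the input/output names, so
#' predictions are reproducible without the training data.
#'
#' @param model a `surrogate_model`
#' @param path destination file
#' @export
save_surrogate <- function(model, path) {
  x <- list(
    hp = unclass(model$hp), d_in = model$d_in, d_out = model$d_out,
    params = lapply(model$params, function(p) {
      if (is.list(p)) lapply(p, function(m) {
        if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
        else list(dim = NULL, data = as.numeric(m))
      }) else if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    bn = model$bn,
    scaling = unclass(model$scaling),
    input_names = model$input_names, output_names = model$output_names,
    training = model$training
  )
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  unflat <- function(p) {
    if (!is.null(p$data)) {
      d <- num(p$dim)
      if (length(d) == 2) matrix(num(p$data), nrow = d[1], ncol = d[2])
      else num(p$data)
    } else lapply(p, unflat)
  }
  params <- lapply(x$params, unflat)
  hp <- do.call(hyperparameters, lapply(x$hp, function(v) unlist(v)))
  model <- build_surrogate(hp, num(x$d_in), num(x$d_out), seed = 1)
  model$params <- params
  model$bn <- list(mean = lapply(x$bn$mean, num),
                   var = lapply(x$bn$var, num))
  sc <- x$scaling
  nnum <- function(v) {
    out <- vapply(v, function(e) as.numeric(e[[1]]), numeric(1))
    stats::setNames(out, names(v))
  }
  model$scaling <- structure(
    list(in_lower = nnum(sc$in_lower), in_upper = nnum(sc$in_upper),
         out_mean = nnum(sc$out_mean), out_sd = nnum(sc$out_sd)),
    class = "scaling_spec")
  model$input_names <- as.character(unlist(x$input_names))
  model$output_names <- as.character(unlist(x$output_names))
  model$training <- x$training
  model
}
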