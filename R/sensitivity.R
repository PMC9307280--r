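#' Saltelli sampling design
#'
#' Monte Carlo design for first-order and total Sobol indices: two
#' independent uniform base matrices A and B of size N x D, plus the D
#' radial matrices AB_i (A with column i taken from B), for a total of
#' N (D + 2) evaluation points.  Deterministic under the seed.
#'
#' @param bounds D x 2 matrix (or data frame with columns `lower`,
#'   `upper`) of parameter intervals; row names name the parameters
#' @param N base sample size (a power of two is recommended; a warning
#'   is logged otherwise)
#' @param seed integer seed
#' @return object of class `saltelli_design`: `X` (the N(D+2) x D
#'   stacked evaluation matrix, blocks A, B, AB_1..AB_D), `N`, `D`
#' @export
saltelli_design <- function(bounds, N, seed = 1) {
  if (is.data.frame(bounds)) {
    bm <- cbind(bounds$lower, bounds$upper)
    rownames(bm) <- if (!is.null(bounds$name)) bounds$name
                    else rownames(bounds)
    bounds <- bm
  }
  D <- nrow(bounds)
  if (is.null(D) || D == 0) stop("domain error: no parameters")
  if (N < 2) stop("domain error: N must be >= 2")
  if (abs(log2(N) - round(log2(N))) > 1e-12) {
    message("saltelli_design: N = ", N, " is not a power of two")
  }
  set.seed(seed)
  A <- matrix(stats::runif(N * D), nrow = N)
  B <- matrix(stats::runif(N * D), nrow = N)
  blocks <- vector("list", D + 2)
  blocks[[1]] <- A; blocks[[2]] <- B
  for (i in seq_len(D)) {
    AB <- A; AB[, i] <- B[, i]
    blocks[[i + 2]] <- AB
  }
  X <- do.call(rbind, blocks)
  ## map the unit hypercube onto the parameter intervals
  X <- sweep(sweep(X, 2, bounds[, 2] - bounds[, 1], "*"), 2,
             bounds[, 1], "+")
  colnames(X) <- rownames(bounds)
  structure(list(X = X, N = as.integer(N), D = as.integer(D),
                 parameters = rownames(bounds)),
            class = "saltelli_design")
}

#' @keywords internal
sobol_point_estimates <- function(yA, yB, yAB, V) {
  N <- length(yA)
  S <- vapply(yAB, function(yi) {
    (V - mean((yB - yi)^2) / 2) / V
  }, numeric(1))
  ST <- vapply(yAB, function(yi) {
    mean((yA - yi)^2) / 2 / V
  }, numeric(1))
  list(S = S, ST = ST)
}

#' Sobol sensitivity indices from design evaluations
#'
#' Jansen-type estimators of the first-order index
#' `S_n = V[E[y|x_n]] / V[y]` and total index
#' `S_Tn = 1 - V[E[y|x_-n]] / V[y]`, with percentile bootstrap
#' confidence intervals over resampled evaluation blocks.
#'
#' @param y evaluations of the model on the rows of a
#'   [saltelli_design()] matrix, in design order
#' @param design the `saltelli_design` the evaluations belong to
#' @param bootstrap number of bootstrap resamples (0 disables the CIs)
#' @param level confidence level
#' @return object of class `sobol_result`: data frame with `parameter`,
#'   `S`, `S_lo`, `S_hi`, `ST`, `ST_lo`, `ST_hi`, plus `N`, `D`
#' @export
sobol_indices <- function(y, design, bootstrap = 1000, level = 0.95) {
  N <- design$N; D <- design$D
  stopifnot(length(y) == N * (D + 2))
  yA <- y[seq_len(N)]
  yB <- y[N + seq_len(N)]
  yAB <- lapply(seq_len(D), function(i) y[(i + 1) * N + seq_len(N)])
  V <- stats::var(c(yA, yB))
  if (V <= 0) stop("degenerate-output error: zero total variance")
  pt <- sobol_point_estimates(yA, yB, yAB, V)
  out <- data.frame(parameter = design$parameters %||% paste0("x", 1:D),
                    S = pt$S, ST = pt$ST)
  if (bootstrap > 0) {
    if (bootstrap < 100) stop("bootstrap size must be >= 100 (or 0)")
    bs <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      yAb <- yA[idx]; yBb <- yB[idx]
      yABb <- lapply(yAB, function(yi) yi[idx])
      Vb <- stats::var(c(yAb, yBb))
      if (Vb <= 0) return(rep(NA_real_, 2 * D))
      p <- sobol_point_estimates(yAb, yBb, yABb, Vb)
      c(p$S, p$ST)
    }, numeric(2 * D))
    al <- (1 - level) / 2
    qs <- apply(bs, 1, stats::quantile, probs = c(al, 1 - al),
                na.rm = TRUE)
    out$S_lo <- qs[1, seq_len(D)]; out$S_hi <- qs[2, seq_len(D)]
    out$ST_lo <- qs[1, D + seq_len(D)]; out$ST_hi <- qs[2, D + seq_len(D)]
  }
  structure(list(indices = out, N = N, D = D, V = V),
            class = "sobol_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance-based sensitivity analysis of a model function
#'
#' Convenience wrapper: builds the Saltelli design, evaluates `f` on
#' every row, and estimates the Sobol indices with bootstrap CIs.
#'
#' @param f function taking a named numeric vector (one design row) and
#'   returning a scalar, or, if `vectorized`, taking the whole matrix
#'   and returning a vector
#' @param bounds parameter intervals (see [saltelli_design()])
#' @param N base sample size
#' @param seed integer seed
#' @param bootstrap,level CI controls
#' @param vectorized whether `f` accepts the full design matrix
#' @export
sobol_sensitivity <- function(f, bounds, N = 1024, seed = 1,
                              bootstrap = 1000, level = 0.95,
                              vectorized = FALSE) {
  des <- saltelli_design(bounds, N, seed)
  y <- if (vectorized) f(des$X)
       else apply(des$X, 1, function(r) f(r))
  sobol_indices(y, des, bootstrap = bootstrap, level = level)
}

#' Sensitivity analysis through the UQ pipeline
#'
#' Runs the Saltelli design through the patient-specific prediction
#' chain: each design row fixes the uncertain parameters (diameters,
#' stenosis profile offset, Kt, flow targets), calibration adjusts the
#' PRs, the stenosis is virtually stented, and the model output is the
#' postoperative flow increase at the chosen outlet.  Rows whose
#' calibration does not converge are imputed with the nearest accepted
#' evaluation (in design order) and counted.
#'
#' @param predictor prediction contract
#' @param record a [patient_record()]
#' @param net base network
#' @param outlet output name of the focal outlet flow (default: the
#'   first CoW outlet on the stenosis side containing "mid" if present,
#'   else the first calibration outlet)
#' @param N base sample size
#' @param seed integer seed
#' @param bootstrap bootstrap resamples for the CIs
#' @param calib_args extra arguments for [calibrate()]
#' @return a `sobol_result` with an added `n_imputed` field
#' @export
run_sa <- function(predictor, record, net, outlet = NULL, N = 256,
                   seed = 1, bootstrap = 1000, calib_args = list()) {
  um <- build_uncertainty_model(record, net)
  cmap <- cow_calibration_map(net)
  if (is.null(outlet)) {
    cand <- grep("mid", cmap$q_output, value = TRUE)
    outlet <- if (length(cand)) cand[1] else cmap$q_output[1]
  }
  ## assemble the uncertain-parameter bounds
  rows <- um$intervals
  nspect <- length(um$flows$spect)
  extra <- data.frame(
    name = c("sten.delta",
             paste0("kt_", um$sten$sides),
             paste0("spect.", names(um$flows$spect)), "total_inflow"),
    lower = c(-um$sten$delta_half_mm,
              rep(um$sten$kt_lo, length(um$sten$sides)),
              um$flows$spect_lo, um$flows$total_lo),
    upper = c(um$sten$delta_half_mm,
              rep(um$sten$kt_hi, length(um$sten$sides)),
              um$flows$spect_hi, um$flows$total_hi)
  )
  bounds <- rbind(rows[, c("name", "lower", "upper")], extra)
  des <- saltelli_design(bounds, N, seed)
  spect_cols <- paste0("spect.", names(um$flows$spect))
  eval_row <- function(r) {
    x <- um$x0
    x[rows$name] <- r[rows$name]
    sp <- stenosis_from_profile(um$sten$profile, r[["sten.delta"]])
    for (side in um$sten$sides) {
      x[[paste0("sten_", side, ".Rv")]] <- min(sp$Rv, 500)
      x[[paste0("sten_", side, ".Dn")]] <- sp$Dn
      x[[paste0("sten_", side, ".SR")]] <- min(sp$SR, 0.99)
      x[[paste0("kt_", side)]] <- r[[paste0("kt_", side)]]
    }
    spect <- stats::setNames(r[spect_cols], names(um$flows$spect))
    targets <- target_flows_from_measurements(spect, r[["total_inflow"]],
                                              um$map)
    cal <- do.call(calibrate, c(list(predictor, x, targets, cmap),
                                calib_args))
    if (!cal$converged) return(NA_real_)
    x_post <- cal$x
    for (side in um$sten$sides) {
      x_post <- virtual_stenting(x_post, side, net)
    }
    y_post <- predictor(x_post)
    as.numeric(delta_q(cal$y, y_post, outlet))
  }
  y <- apply(des$X, 1, eval_row)
  n_imp <- sum(is.na(y))
  if (n_imp == length(y)) stop("UQ error: all calibrations failed")
  if (n_imp > 0) {
    ok <- which(!is.na(y))
    for (i in which(is.na(y))) {
      y[i] <- y[ok[which.min(abs(ok - i))]]
    }
  }
  res <- sobol_indices(y, des, bootstrap = bootstrap)
  res$n_imputed <- n_imp
  res$outlet <- outlet
  res
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> N =", x$N, ", D =", x$D, "\n")
  print(x$indices, digits = 3)
  invisible(x)
}
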