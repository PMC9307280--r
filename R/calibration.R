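#' Flow targets from measured per-outlet flows
#'
#' Per-outlet measured (SPECT-derived) flows are rescaled to sum to the
#' measured total CoW inflow while preserving their mutual ratios:
#' `Q_i^target = Q_total * Q_i^SPECT / sum_j Q_j^SPECT`.
#'
#' @param spect_flows named vector of per-outlet cycle-averaged flows,
#'   mL/min (names must match the outlet flow outputs used in
#'   calibration)
#' @param total_inflow measured total inflow to the CoW, mL/min
#' @param map measured mean arterial pressure, mmHg
#' @return object of class `flow_targets`: `q_spect`, `q_target`,
#'   `q_total`, `map_target`
#' @export
target_flows_from_measurements <- function(spect_flows, total_inflow, map) {
  if (any(spect_flows <= 0) || total_inflow <= 0 || map <= 0) {
    stop("domain error: flows and pressure must be positive", call. = FALSE)
  }
  q_target <- total_inflow * spect_flows / sum(spect_flows)
  structure(list(q_spect = spect_flows, q_target = q_target,
                 q_total = total_inflow, map_target = map),
            class = "flow_targets")
}

#' Calibration slot map for the CoW outlets
#'
#' Pairs each CoW outlet's PR input slot with the output name carrying
#' its cycle-averaged flow (the terminal artery's mid-point flow), plus
#' the slot bounds used for clamping.
#'
#' @param net a `vascular_network`
#' @return data frame `pr_slot`, `q_output`, `pr_lo`, `pr_hi`
#' @export
cow_calibration_map <- function(net) {
  man <- input_manifest(net)
  pr_rows <- man[man$kind == "pr", ]
  nm <- net$segments$name[match(pr_rows$target_id, net$segments$id)]
  slug <- function(x) gsub("_+", "_", gsub("[^A-Za-z0-9]", "_", x))
  data.frame(pr_slot = pr_rows$name,
             q_output = paste0("qbar.", slug(nm)),
             pr_lo = pr_rows$lower, pr_hi = pr_rows$upper)
}

#' Calibrate CoW outlet resistances and the total-PR scaling factor
#'
#' Iteratively adjusts the CoW outlet PR slots with damped multiplicative
#' fixed-point updates `PR <- PR (Q_pred / Q_target)^lambda` and the
#' total-PR scaling factor with a secant update against the MAP target,
#' until every outlet flow matches its target within `tol_flow`
#' (relative) and the predicted MAP is within `tol_map` (mmHg).
#' Adjusted PRs are clamped to their declared bounds; if a target needs
#' an out-of-bound PR the run ends non-converged with the residuals
#' reported.
#'
#' @param predictor function mapping a named input vector to the named
#'   output vector (simulator- or surrogate-backed)
#' @param x0 starting input vector
#' @param targets a [target_flows_from_measurements()] object whose
#'   `q_target` names match `cal_map$q_output`
#' @param cal_map slot map from [cow_calibration_map()]
#' @param tol_flow relative flow tolerance (default 0.5\%)
#' @param tol_map MAP tolerance, mmHg
#' @param max_iter iteration cap
#' @param lambda damping exponent of the multiplicative update
#' @param scale_bounds clamp interval for the scaling factor
#' @return object of class `calibration_result`: `x` (adjusted vector),
#'   `converged`, `iterations`, `max_flow_residual` (relative),
#'   `map_residual` (mmHg), `y` (predictor output at the final iterate)
#' @export
calibrate <- function(predictor, x0, targets, cal_map,
                      tol_flow = 0.005, tol_map = 1, max_iter = 200,
                      lambda = 0.8, scale_bounds = c(0.5, 2)) {
  x <- x0
  qt <- targets$q_target[cal_map$q_output]
  if (anyNA(qt)) {
    stop("layout error: target names do not match the calibration map",
         call. = FALSE)
  }
  s_prev <- NA_real_; map_prev <- NA_real_
  converged <- FALSE; it <- 0L
  fres <- Inf; mres <- Inf; y <- NULL
  while (it < max_iter) {
    it <- it + 1L
    y <- predictor(x)
    q <- y[cal_map$q_output]
    mp <- y[["map"]]
    if (any(!is.finite(q)) || any(q <= 0) || !is.finite(mp)) {
      ## pathological iterate; report as non-converged
      fres <- Inf; mres <- Inf
      break
    }
    fres <- max(abs(q / qt - 1))
    mres <- abs(mp - targets$map_target)
    if (fres <= tol_flow && mres <= tol_map) { converged <- TRUE; break }
    ## multiplicative PR update (higher predicted flow -> raise PR)
    pr <- x[cal_map$pr_slot] * (q / qt)^lambda
    x[cal_map$pr_slot] <- pmin(pmax(pr, cal_map$pr_lo), cal_map$pr_hi)
    ## scaling factor: secant on MAP, multiplicative damped fallback
    s <- x[["pr_scale"]]
    if (mres > tol_map) {
      s_new <- if (is.finite(s_prev) && abs(mp - map_prev) > 1e-9) {
        s - (mp - targets$map_target) * (s - s_prev) / (mp - map_prev)
      } else {
        s * (targets$map_target / mp)^lambda
      }
      s_prev <- s; map_prev <- mp
      x[["pr_scale"]] <- min(max(s_new, scale_bounds[1]), scale_bounds[2])
    }
  }
  structure(list(x = x, converged = converged, iterations = it,
                 max_flow_residual = fres, map_residual = mres, y = y),
            class = "calibration_result")
}

#' Predictor closures
#'
#' [simulator_predictor()] wraps the 1D-0D solver; [surrogate_predictor()]
#' wraps a trained surrogate.  Both return a function mapping a named
#' input vector to the named output vector, the contract shared by
#' [calibrate()] and the UQ pipeline.
#'
#' @param net base `vascular_network`
#' @param settings [solver_settings()]
#' @export
simulator_predictor <- function(net, settings = solver_settings()) {
  force(net); force(settings)
  function(x) simulate_output_vector(x, net, settings)
}

#' @rdname simulator_predictor
#' @param model a trained `surrogate_model`
#' @export
surrogate_predictor <- function(model) {
  force(model)
  function(x) predict_surrogate(model, x, warn_extrapolation = FALSE)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations;",
      "max flow residual", signif(x$max_flow_residual, 3),
      "; MAP residual", signif(x$map_residual, 3), "mmHg\n")
  invisible(x)
}
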