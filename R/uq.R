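#' Synthetic patient record
#'
#' Bundles the measured quantities the UQ pipeline consumes: arterial
#' diameters of the flagged segments (mm), image pixel size (mm/px), the
#' stenosis side and its sampled axial diameter profile, per-outlet
#' (SPECT-derived) flows, total CoW inflow with its measurement modality
#' (PC-MRI or ultrasound), and mean arterial pressure.  All records
#' handled by this package are synthetic; no real patient data is
#' bundled.
#'
#' @param diameters named vector (manifest diameter-slot names), mm
#' @param lengths named vector (manifest length-slot names), mm
#' @param pixel_size mm per pixel
#' @param stenosis_side "L", "R" or "both"
#' @param stenosis_profile data frame `x_mm`, `d_mm` sampling D(x) of
#'   the stenosis (used to derive Rv, Dn, SR and their uncertainty)
#' @param spect_flows named per-outlet flows (calibration output names),
#'   mL/min
#' @param total_inflow total CoW inflow, mL/min
#' @param inflow_modality "PC-MRI" or "ultrasound"
#' @param map mean arterial pressure, mmHg
#' @param age years
#' @param acoa_uncertain flag: anterior communicating artery possibly
#'   absent; its diameter interval becomes [0.1, 2.6] mm regardless of
#'   the measured value
#' @export
patient_record <- function(diameters, lengths, pixel_size, stenosis_side,
                           stenosis_profile, spect_flows, total_inflow,
                           inflow_modality = c("PC-MRI", "ultrasound"),
                           map, age = 65, acoa_uncertain = FALSE) {
  inflow_modality <- match.arg(inflow_modality)
  stopifnot(pixel_size > 0, stenosis_side %in% c("L", "R", "both"),
            total_inflow > 0, map > 0)
  structure(list(diameters = diameters, lengths = lengths,
                 pixel_size = pixel_size, stenosis_side = stenosis_side,
                 stenosis_profile = stenosis_profile,
                 spect_flows = spect_flows, total_inflow = total_inflow,
                 inflow_modality = inflow_modality, map = map, age = age,
                 acoa_uncertain = acoa_uncertain),
            class = "patient_record")
}

#' Stenosis parameters from a (possibly offset) diameter profile
#'
#' Applies one shared diameter offset `delta` to the whole profile (the
#' distal reference Dn moves together with the lumen), then recomputes
#' `Rv` by quadrature, `Dn` as the maximum profile diameter and
#' `SR = 1 - Ds/Dn` from the minimum diameter.
#'
#' @param profile data frame `x_mm`, `d_mm`
#' @param delta_mm diameter offset, mm
#' @return list with `Rv` (mmHg s/mL), `Dn` (mm), `SR`
#' @export
stenosis_from_profile <- function(profile, delta_mm = 0) {
  p <- profile
  p$d_mm <- pmax(p$d_mm + delta_mm, 0.05)
  dn <- max(p$d_mm)
  ds <- min(p$d_mm)
  list(Rv = viscous_resistance(p), Dn = dn, SR = 1 - ds / dn)
}

#' Modality-derived flow uncertainty fractions
#' @keywords internal
MODALITY_UNCERTAINTY <- c("PC-MRI" = 0.16, "ultrasound" = 0.35,
                          "SPECT" = 0.16)

#' Build the uncertainty model for a patient record
#'
#' Uniform intervals for every uncertain quantity: each measured
#' diameter +- 2 pixels (intersected with the declared slot bounds); the
#' stenosis geometry through a shared +-2 px profile offset (Rv, Dn, SR
#' recomputed per draw); Kt in [1.0, 2.699]; total inflow +-16\%
#' (PC-MRI) or +-35\% (ultrasound); each per-outlet flow +-16\% (SPECT);
#' and, when flagged, the ACoA diameter in [0.1, 2.6] mm.
#'
#' @param record a [patient_record()]
#' @param net the base `vascular_network`
#' @return object of class `uncertainty_model`
#' @export
build_uncertainty_model <- function(record, net) {
  man <- input_manifest(net)
  x0 <- network_input_vector(net)
  x0[names(record$diameters)] <- record$diameters
  x0[names(record$lengths)] <- record$lengths
  x0[["age"]] <- record$age
  half <- 2 * record$pixel_size
  dman <- man[man$kind == "diameter", ]
  ivals <- list()
  for (i in seq_len(nrow(dman))) {
    nm <- dman$name[i]
    if (!nm %in% names(record$diameters)) next
    d <- record$diameters[[nm]]
    lo <- max(d - half, dman$lower[i])
    hi <- min(d + half, dman$upper[i])
    if (record$acoa_uncertain && grepl("Ant_comm", nm)) {
      lo <- 0.1; hi <- 2.6
    }
    if (lo >= hi) {
      stop("modeling error: empty uncertainty interval for ", nm,
           call. = FALSE)
    }
    ivals[[length(ivals) + 1]] <- data.frame(name = nm, lower = lo,
                                             upper = hi)
  }
  intervals <- do.call(rbind, ivals)
  sides <- if (record$stenosis_side == "both") c("L", "R")
           else record$stenosis_side
  fu <- MODALITY_UNCERTAINTY[[record$inflow_modality]]
  fs <- MODALITY_UNCERTAINTY[["SPECT"]]
  structure(list(
    x0 = x0, intervals = intervals,
    sten = list(sides = sides, profile = record$stenosis_profile,
                delta_half_mm = half, kt_lo = 1.0, kt_hi = 2.699),
    flows = list(
      spect = record$spect_flows,
      spect_lo = record$spect_flows * (1 - fs),
      spect_hi = record$spect_flows * (1 + fs),
      total_lo = record$total_inflow * (1 - fu),
      total_hi = record$total_inflow * (1 + fu)),
    map = record$map,
    manifest = man
  ), class = "uncertainty_model")
}

#' Draw one uncertainty realization
#'
#' Independent uniform draws of all uncertain inputs and targets; the
#' flow targets are rebuilt from the drawn per-outlet flows and drawn
#' total inflow, so they always sum to the drawn total.
#'
#' @param um an `uncertainty_model`
#' @return list `x` (input vector), `targets` (a `flow_targets`)
#' @export
sample_case <- function(um) {
  x <- um$x0
  iv <- um$intervals
  if (!is.null(iv) && nrow(iv)) {
    x[iv$name] <- stats::runif(nrow(iv), iv$lower, iv$upper)
  }
  for (side in um$sten$sides) {
    delta <- stats::runif(1, -um$sten$delta_half_mm, um$sten$delta_half_mm)
    sp <- stenosis_from_profile(um$sten$profile, delta)
    x[[paste0("sten_", side, ".Rv")]] <- min(sp$Rv, 500)
    x[[paste0("sten_", side, ".Dn")]] <- sp$Dn
    x[[paste0("sten_", side, ".SR")]] <- min(sp$SR, 0.99)
    x[[paste0("kt_", side)]] <- stats::runif(1, um$sten$kt_lo, um$sten$kt_hi)
  }
  spect <- stats::runif(length(um$flows$spect), um$flows$spect_lo,
                        um$flows$spect_hi)
  names(spect) <- names(um$flows$spect)
  total <- stats::runif(1, um$flows$total_lo, um$flows$total_hi)
  list(x = x,
       targets = target_flows_from_measurements(spect, total, um$map))
}

#' Virtual stenting of one side
#'
#' Complete dilation of the stenosis: `Rv = 0`, `SR = 0`, `Kt = 0` and
#' `Dn` set to the (sampled) host-artery diameter.  All other slots are
#' unchanged; stenting is idempotent.
#'
#' @param x input vector
#' @param side "L" or "R"
#' @param net the network (locates the host diameter slot)
#' @export
virtual_stenting <- function(x, side, net) {
  man <- input_manifest(net)
  host <- net$stenosis_hosts$host_segment_id[net$stenosis_hosts$side == side]
  if (!length(host)) stop("no stenosis host on side ", side)
  d_slot <- man$name[man$kind == "diameter" & man$target_id == host]
  x[[paste0("sten_", side, ".Rv")]] <- 0
  x[[paste0("sten_", side, ".SR")]] <- 0
  x[[paste0("kt_", side)]] <- 0
  x[[paste0("sten_", side, ".Dn")]] <- x[[d_slot]]
  x
}

#' Postoperative flow increase
#'
#' `dQ_i = (Q_i^post - Q_i^pre) / Q_i^pre * 100` per CoW outlet; values
#' above 100\% define cerebral hyperperfusion.
#'
#' @param pre,post output vectors before/after stenting
#' @param q_outputs names of the outlet flow outputs
#' @return named percentages
#' @export
delta_q <- function(pre, post, q_outputs) {
  qpre <- pre[q_outputs]; qpost <- post[q_outputs]
  if (any(qpre <= 0)) stop("domain error: non-positive preoperative flow")
  (qpost - qpre) / qpre * 100
}

#' Monte Carlo uncertainty quantification of the postoperative flow
#' increase
#'
#' Implements the sampling loop: draw uncertain inputs and targets,
#' calibrate the CoW PRs and scaling factor to the drawn targets
#' (rejecting non-converged calibrations), predict the preoperative
#' state, virtually stent the stenosis while keeping the adjusted PRs,
#' predict the postoperative state, and record the per-outlet flow
#' increase.  The sample count grows by `increment` until the mean and
#' variance of every outlet's flow increase change by less than
#' `stat_tol` (relative) between increments.
#'
#' @param predictor prediction contract (see [simulator_predictor()])
#' @param record a [patient_record()]
#' @param net base `vascular_network`
#' @param seed integer seed
#' @param increment samples added per convergence check
#' @param stat_tol relative change threshold (default 0.1\%)
#' @param max_batches hard cap on the number of increments
#' @param calib_args list of extra arguments for [calibrate()]
#' @param um optional pre-built (possibly modified) `uncertainty_model`;
#'   by default built from the record
#' @return object of class `uq_result`
#' @export
run_uq <- function(predictor, record, net, seed = 1, increment = 10000,
                   stat_tol = 0.001, max_batches = 20,
                   calib_args = list(), um = NULL) {
  set.seed(seed)
  if (is.null(um)) um <- build_uncertainty_model(record, net)
  cmap <- cow_calibration_map(net)
  q_outputs <- cmap$q_output
  samples <- NULL
  rejected <- 0L
  trace <- list()
  mean_prev <- NULL; var_prev <- NULL
  converged <- FALSE
  for (b in seq_len(max_batches)) {
    new <- matrix(NA_real_, nrow = increment, ncol = length(q_outputs))
    got <- 0L
    while (got < increment) {
      cs <- sample_case(um)
      cal <- do.call(calibrate, c(list(predictor, cs$x, cs$targets, cmap),
                                  calib_args))
      if (!cal$converged) { rejected <- rejected + 1L; next }
      x_pre <- cal$x
      y_pre <- cal$y
      x_post <- x_pre
      for (side in um$sten$sides) {
        x_post <- virtual_stenting(x_post, side, net)
      }
      y_post <- predictor(x_post)
      dq <- as.numeric(delta_q(y_pre, y_post, q_outputs))
      got <- got + 1L
      new[got, ] <- dq
      if (rejected > 200 && rejected > 0.95 * (rejected + nrow_or0(samples) + got)) {
        stop("UQ error: calibration rejection rate above 95%", call. = FALSE)
      }
    }
    samples <- rbind(samples, new)
    mu <- colMeans(samples); va <- apply(samples, 2, stats::var)
    trace[[b]] <- data.frame(n = nrow(samples), outlet = q_outputs,
                             mean = mu, var = va)
    if (!is.null(mean_prev)) {
      dmu <- abs(mu - mean_prev) / pmax(abs(mean_prev), 1e-12)
      dva <- ifelse(va == 0 & var_prev == 0, 0,
                    abs(va - var_prev) / pmax(abs(var_prev), 1e-12))
      if (max(dmu, dva) < stat_tol) { converged <- TRUE; break }
    } else if (all(apply(samples, 2, stats::var) == 0)) {
      ## degenerate zero-uncertainty case: converged at the first check
      converged <- TRUE; break
    }
    mean_prev <- mu; var_prev <- va
  }
  colnames(samples) <- q_outputs
  tot <- nrow(samples) + rejected
  if (rejected > 0.5 * tot) {
    warning("more than half of the UQ samples were rejected")
  }
  mode_est <- apply(samples, 2, function(v) {
    if (stats::sd(v) == 0) return(v[1])
    h <- graphics::hist(v, breaks = "FD", plot = FALSE)
    h$mids[which.max(h$counts)]
  })
  structure(list(
    samples = samples,
    n_mc = nrow(samples), rejected = rejected,
    mean = colMeans(samples), var = apply(samples, 2, stats::var),
    mode = mode_est,
    min = apply(samples, 2, min), max = apply(samples, 2, max),
    p_ch = colMeans(samples > 100),
    converged = converged,
    trace = do.call(rbind, trace),
    seed = seed
  ), class = "uq_result")
}

#' @keywords internal
nrow_or0 <- function(x) if (is.null(x)) 0L else nrow(x)

#' @export
print.uq_result <- function(x, ...) {
  cat("<uq_result> N_MC:", x$n_mc, "; rejected:", x$rejected,
      if (x$converged) "(statistics converged)" else "(NOT converged)", "\n")
  tab <- data.frame(mean = round(x$mean, 1), mode = round(x$mode, 1),
                    min = round(x$min, 1), max = round(x$max, 1),
                    `P(CH)` = signif(x$p_ch, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}
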