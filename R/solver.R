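#' Solver settings
#'
#' Numerical settings for the closed-loop 1D-0D solver.  Defaults: blood
#' density 1060 kg/m^3, viscosity 0.0047 Pa s (friction parameter
#' K_R = 22 pi mu / rho), cardiac period 1 s, CFL number 0.9, nominal
#' grid spacing 2.5 mm, periodic-state tolerance 1e-3 (maximum relative
#' change of any cycle-averaged output between consecutive cycles) with
#' at most 30 cycles, junction Newton tolerance 1e-10 with analytic
#' Jacobian.
#'
#' @param target_dx_mm grid spacing used to (re)assign odd per-segment
#'   node counts; `NULL` keeps the node counts stored in the network
#' @param CFL Courant number in (0, 1]
#' @param max_cycles maximum number of cardiac cycles
#' @param periodicity_tol relative cycle-to-cycle change below which the
#'   run is declared periodic
#' @param newton_tol,newton_maxit junction/boundary Newton control
#' @param rho,mu blood density (kg/m^3) and viscosity (Pa s)
#' @param Tc cardiac period, s
#' @param dt_forced optional explicit time step (s); raises an
#'   instability error if it violates the CFL limit
#' @return list of class `solver_settings`
#' @export
solver_settings <- function(target_dx_mm = NULL, CFL = 0.9,
                            max_cycles = 30, periodicity_tol = 1e-3,
                            newton_tol = 1e-10, newton_maxit = 50,
                            rho = BLOOD_RHO, mu = BLOOD_MU,
                            Tc = CARDIAC_PERIOD, dt_forced = NULL) {
  stopifnot(CFL > 0, CFL <= 1, periodicity_tol > 0, max_cycles >= 1)
  structure(list(
    target_dx_mm = target_dx_mm, CFL = CFL, max_cycles = max_cycles,
    periodicity_tol = periodicity_tol, newton_tol = newton_tol,
    newton_maxit = newton_maxit, rho = rho, mu = mu,
    KR = 22 * pi * mu / rho, Tc = Tc, dt_forced = dt_forced
  ), class = "solver_settings")
}

#' Tube law: pressure from cross-sectional area
#'
#' Elastic tube law derived from Laplace's law:
#' `P = P0 + sqrt(pi) Eh / ((1 - sigma^2) A0) (sqrt(A) - sqrt(A0))`.
#'
#' @param A cross-sectional area, m^2
#' @param segment one row of a network's segment table (or any list with
#'   `diameter_mm`, `Eh`, `P0_mmHg`, `sigma`)
#' @return pressure in Pa
#' @export
tube_law_pressure <- function(A, segment) {
  if (any(A <= 0)) stop("state error: non-positive area")
  A0 <- pi * (segment$diameter_mm / 2 * 1e-3)^2
  beta <- sqrt(pi) * segment$Eh / (1 - segment$sigma^2)
  mmHg_to_Pa(segment$P0_mmHg) + beta / A0 * (sqrt(A) - sqrt(A0))
}

#' Tube law inverse: area from pressure
#' @param P pressure, Pa
#' @inheritParams tube_law_pressure
#' @return area in m^2
#' @export
tube_law_area <- function(P, segment) {
  A0 <- pi * (segment$diameter_mm / 2 * 1e-3)^2
  beta <- sqrt(pi) * segment$Eh / (1 - segment$sigma^2)
  s <- sqrt(A0) + (P - mmHg_to_Pa(segment$P0_mmHg)) * A0 / beta
  if (any(s <= 0)) stop("state error: pressure below collapse limit")
  s^2
}

#' Empirical stenosis pressure loss
#'
#' `dP = Rv Q + Kt 8 rho / (pi^2 Dn^4) ((1-SR)^-2 - 1)^2 Q|Q|
#'  + Ku 4 rho Ls / (pi Dn^2) dQ/dt`, accounting for viscous friction,
#' flow separation and pulsatility.
#'
#' @param Q flow, m^3/s
#' @param dQdt flow time derivative, m^3/s^2
#' @param sten a [stenosis_spec()] (clinical units; converted internally)
#' @param rho blood density, kg/m^3
#' @return pressure loss in Pa
#' @export
stenosis_pressure_loss <- function(Q, dQdt, sten, rho = BLOOD_RHO) {
  rv <- sten$Rv * RES_SI
  dn <- sten$Dn * 1e-3
  ls <- sten$Ls * 1e-3
  ksep <- sten$Kt * 8 * rho / (pi^2 * dn^4) * ((1 - sten$SR)^-2 - 1)^2
  kin <- sten$Ku * 4 * rho * ls / (pi * dn^2)
  rv * Q + ksep * Q * abs(Q) + kin * dQdt
}

#' Viscous resistance of a stenosis from its axial diameter profile
#'
#' Numerical quadrature of `128 mu / (pi D(x)^4)` along the profile
#' (trapezoidal rule); for a uniform profile this equals the Poiseuille
#' closed form `128 mu Ls / (pi D^4)`.
#'
#' @param profile data frame with columns `x_mm` (increasing) and `d_mm`
#' @param mu blood viscosity, Pa s
#' @return Rv in mmHg s mL^-1
#' @export
viscous_resistance <- function(profile, mu = BLOOD_MU) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 2)
  if (any(profile$d_mm <= 0)) stop("domain error: non-positive diameter")
  if (any(diff(profile$x_mm) <= 0)) stop("domain error: x must increase")
  x <- profile$x_mm * 1e-3
  f <- 128 * mu / (pi * (profile$d_mm * 1e-3)^4)
  rv_si <- sum(diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  rv_si / RES_SI
}

#' Trapezoidal cycle average
#'
#' @param values sampled scalar time series
#' @param times sampling times, s (uniform, spanning at least one period)
#' @param Tc cardiac period, s
#' @return the trapezoidal mean over the final window of length `Tc`
#' @export
cycle_average <- function(values, times, Tc = CARDIAC_PERIOD) {
  stopifnot(length(values) == length(times))
  span <- times[length(times)] - times[1]
  if (span < Tc * (1 - 1e-9)) {
    stop("domain error: sampling window (", signif(span, 6),
         " s) shorter than one period", call. = FALSE)
  }
  keep <- times >= times[length(times)] - Tc * (1 + 1e-12)
  t <- times[keep]; v <- values[keep]
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (t[length(t)] - t[1])
}

#' Names of the cycle-averaged output vector
#'
#' @param net a `vascular_network`
#' @return character vector: `qbar.*` (one per flagged segment),
#'   `pbar.*`, then `map`
#' @export
output_names <- function(net) {
  nm <- net$segments$name[match(net$cow_segment_ids, net$segments$id)]
  slug <- function(x) gsub("_+", "_", gsub("[^A-Za-z0-9]", "_", x))
  c(paste0("qbar.", slug(nm)), paste0("pbar.", slug(nm)), "map")
}

#' @keywords internal
net_to_solver <- function(net, settings) {
  seg <- net$segments
  if (!is.null(settings$target_dx_mm)) {
    seg$n_nodes <- vapply(seg$length_mm, segment_n_nodes, integer(1),
                          target_dx_mm = settings$target_dx_mm)
  }
  host_ids <- vapply(net$stenoses, function(s) s$host_segment_id, integer(1))
  if (length(host_ids)) {
    i <- match(host_ids, seg$id)
    seg$n_nodes[i] <- pmax(seg$n_nodes[i], 5L)
  }
  idx <- function(id) match(id, seg$id) - 1L  # 0-based for C++
  ns <- nrow(seg)
  sten_m <- rep(-1L, ns)
  sten_Rv <- sten_Ksep <- sten_Kin <- rep(0, ns)
  for (s in net$stenoses) {
    i <- match(s$host_segment_id, seg$id)
    sten_m[i] <- as.integer((seg$n_nodes[i] - 1) %/% 2)
    dn <- s$Dn * 1e-3
    sten_Rv[i] <- s$Rv * RES_SI
    sten_Ksep[i] <- s$Kt * 8 * settings$rho / (pi^2 * dn^4) *
      ((1 - s$SR)^-2 - 1)^2
    sten_Kin[i] <- s$Ku * 4 * settings$rho * (s$Ls * 1e-3) / (pi * dn^2)
  }
  segments <- list(
    n = as.integer(seg$n_nodes),
    dx = seg$length_mm * 1e-3 / (seg$n_nodes - 1),
    A0 = pi * (seg$diameter_mm / 2 * 1e-3)^2,
    beta = sqrt(pi) * seg$Eh / (1 - seg$sigma^2),
    P0 = mmHg_to_Pa(seg$P0_mmHg),
    sten_m = sten_m, sten_Rv = sten_Rv, sten_Ksep = sten_Ksep,
    sten_Kin = sten_Kin
  )
  junctions <- lapply(net$junctions, function(j) {
    list(seg = idx(j$segments), end = as.integer(j$ends == "end"))
  })
  out <- net$outlets
  outlets <- list(
    seg = idx(out$segment_id),
    R1 = out$R1 * RES_SI, R2 = out$R2 * RES_SI, C = out$C * CAP_SI,
    block = as.integer(out$body_block) - 1L,
    Pc0 = rep(mmHg_to_Pa(P0_MMHG), nrow(out))
  )
  bb <- net$body_blocks
  blocks <- list(R = bb$R * RES_SI, L = bb$L * RES_SI, C = bb$C * CAP_SI,
                 P0 = mmHg_to_Pa(bb$P_init))
  h <- net$heart
  heart <- list(
    Emax = h$Emax * MMHG_PA / 1e-6, Emin = h$Emin * MMHG_PA / 1e-6,
    V0 = h$V0 * 1e-6, Tvc = h$Tvc, Tvr = h$Tvr, Tc = h$Tc,
    Rav = h$R_av * RES_SI, Rmv = h$R_mv * RES_SI, Cat = h$C_at * CAP_SI,
    Pat0 = mmHg_to_Pa(h$P_at0), Vlv0 = h$V_lv0 * 1e-6
  )
  flags <- c(net$cow_segment_ids, net$map_segment_id)
  flag_seg <- idx(flags)
  flag_node <- as.integer((seg$n_nodes[flag_seg + 1L] - 1) %/% 2)
  list(
    segments = segments, junctions = junctions, outlets = outlets,
    blocks = blocks, heart = heart, root = idx(net$heart$root_segment_id),
    flag_seg = flag_seg, flag_node = flag_node,
    map_flag_idx = length(flags) - 1L,
    outlet_segment_ids = out$segment_id
  )
}

#' Run the solver to a periodic state
#'
#' Integrates cardiac cycles from a cold start (all areas at rest,
#' zero flow) until the cycle-averaged outputs change by less than
#' `periodicity_tol` between consecutive cycles, or `max_cycles` is
#' reached (then `converged = FALSE`).  Outputs are computed on the
#' final cycle.
#'
#' @param net a `vascular_network`
#' @param settings a [solver_settings()]
#' @param inflow optional prescribed-inflow mode: `list(t = seconds,
#'   q_mls = mL/s)`; replaces the elastance heart by the given root
#'   inflow waveform (open loop)
#' @param record optional data frame `(segment_id, node)` of extra nodes
#'   whose waveforms (`t`, `Q`, `P`, `A` in SI) are returned
#' @return object of class `cycle_averages`: `outputs` (named vector,
#'   flows mL/min, pressures mmHg), `outlet_flows` (mL/min, by segment
#'   id), `co` (cardiac output, mL/min), `cycles`, `converged`,
#'   `max_mass_residual` (m^3/s), and `waveforms` when recording
#' @export
run_to_periodic <- function(net, settings = solver_settings(),
                            inflow = NULL, record = NULL) {
  sl <- net_to_solver(net, settings)
  cs <- list(
    rho = settings$rho, KR = settings$KR, Tc = settings$Tc,
    CFL = settings$CFL, max_cycles = as.integer(settings$max_cycles),
    periodicity_tol = settings$periodicity_tol,
    newton_tol = settings$newton_tol,
    newton_maxit = as.integer(settings$newton_maxit),
    inflow_mode = 0L
  )
  if (!is.null(settings$dt_forced)) cs$dt_forced <- settings$dt_forced
  if (!is.null(inflow)) {
    cs$inflow_mode <- 1L
    cs$qin_t <- inflow$t
    cs$qin_q <- inflow$q_mls * 1e-6
  }
  if (!is.null(record)) {
    seg <- net$segments
    if (!is.null(settings$target_dx_mm)) {
      seg$n_nodes <- vapply(seg$length_mm, segment_n_nodes, integer(1),
                            target_dx_mm = settings$target_dx_mm)
    }
    cs$record_seg <- match(record$segment_id, seg$id) - 1L
    cs$record_node <- as.integer(record$node)
  }
  r <- .run_simulation_cpp(sl, cs)
  ncow <- length(net$cow_segment_ids)
  out <- c(m3s_to_mlmin(r$qbar[seq_len(ncow)]),
           Pa_to_mmHg(r$pbar[seq_len(ncow)]),
           Pa_to_mmHg(r$map))
  names(out) <- output_names(net)
  res <- list(
    outputs = out,
    outlet_flows = stats::setNames(m3s_to_mlmin(r$outlet_qbar),
                                   as.character(sl$outlet_segment_ids)),
    co = m3s_to_mlmin(r$co),
    cycles = r$cycles,
    converged = r$converged,
    max_mass_residual = r$max_mass_residual
  )
  if (!is.null(record)) {
    res$waveforms <- list(t = r$rec_t, Q = r$rec_Q, P = r$rec_P, A = r$rec_A)
  }
  structure(res, class = "cycle_averages")
}

#' Simulate the cycle-averaged output vector for an input vector
#'
#' Applies the input vector to the base network and runs the solver to a
#' periodic state; returns the flattened outputs (flows in mL/min,
#' pressures and MAP in mmHg) in the published layout.
#'
#' @param x named input vector per [input_manifest()]
#' @param net base `vascular_network`
#' @param settings [solver_settings()]
#' @param full return the full `cycle_averages` object instead of the
#'   output vector
#' @export
simulate_output_vector <- function(x, net, settings = solver_settings(),
                                   full = FALSE) {
  net2 <- apply_input_vector(net, x)
  r <- run_to_periodic(net2, settings)
  if (!r$converged) {
    attr(r$outputs, "converged") <- FALSE
  }
  if (full) r else r$outputs
}

#' Solve a single junction coupling problem
#'
#' Newton-Raphson solve of the nonlinear junction system: conservation
#' of mass and equality of total pressure `P + 1/2 rho (Q/A)^2` across
#' all connected segment ends, with the outgoing Riemann invariants
#' `u +- 4c` held at given values.  This is the same routine the time
#' stepper uses; exposed for verification.
#'
#' @param A0,beta per-end reference area (m^2) and stiffness coefficient
#'   `sqrt(pi) Eh / (1 - sigma^2)` (Pa m)
#' @param W per-end frozen outgoing invariant (m/s)
#' @param s_sign +1 if the end feeds the junction ('end' side), -1 if it
#'   leaves it ('start' side)
#' @param s_char +1 if the outgoing invariant is `u + 4c`, -1 for
#'   `u - 4c` (normally equal to `s_sign`)
#' @param A_init initial guess for the areas (m^2)
#' @param P0 reference pressure, Pa
#' @param rho blood density, kg/m^3
#' @param tol,maxit Newton control
#' @return list with `A` (m^2), `Q` (m^3/s), `mass_residual` (m^3/s)
#' @export
solve_junction <- function(A0, beta, W, s_sign = NULL, s_char = NULL,
                           A_init = A0, P0 = mmHg_to_Pa(P0_MMHG),
                           rho = BLOOD_RHO, tol = 1e-10, maxit = 50) {
  K <- length(A0)
  if (is.null(s_sign)) s_sign <- c(1, rep(-1, K - 1))
  if (is.null(s_char)) s_char <- s_sign
  .solve_junction_cpp(A0, beta, W, s_sign, s_char, A_init, P0, rho,
                      tol, as.integer(maxit))
}

#' @export
print.cycle_averages <- function(x, ...) {
  cat("<cycle_averages> cycles:", x$cycles,
      if (x$converged) "(periodic)" else "(NOT converged)", "\n")
  cat("  cardiac output:", round(x$co, 1), "mL/min; MAP:",
      round(x$outputs[["map"]], 1), "mmHg\n")
  invisible(x)
}
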