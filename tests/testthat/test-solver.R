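test_that("junction solve conserves mass and matches an independent root find", {
  rho <- 1060
  A0 <- c(5e-5, 3e-5, 2.5e-5)
  beta <- c(900, 600, 500)
  P0 <- 85 * 133.322
  s_sign <- c(1, -1, -1)   # one parent feeding two daughters
  ## hand-set invariants: parent carries forward flow
  cc <- sqrt(beta / (2 * rho * A0))
  c0 <- cc * A0^0.25
  W <- c(0.5 + 4 * c0[1], 0.1 - 4 * c0[2], 0.12 - 4 * c0[3])
  sol <- solve_junction(A0, beta, W, s_sign, s_sign, A_init = A0,
                        P0 = P0, rho = rho)
  ## mass conservation to solver tolerance
  expect_lt(abs(sum(s_sign * sol$Q)), 1e-10)
  expect_lt(sol$mass_residual, 1e-10)
  ## total pressure equal across ends
  pres <- P0 + beta / A0 * (sqrt(sol$A) - sqrt(A0))
  ptot <- pres + 0.5 * rho * (sol$Q / sol$A)^2
  expect_equal(ptot[1], ptot[2], tolerance = 1e-9)
  expect_equal(ptot[1], ptot[3], tolerance = 1e-9)

  ## independent oracle: generic least-squares minimization of the same
  ## residual system with a different algorithm and start point
  resid <- function(A) {
    u <- W - s_sign * 4 * cc * A^0.25
    p <- P0 + beta / A0 * (sqrt(A) - sqrt(A0))
    pt <- p + 0.5 * rho * u^2
    c(sum(s_sign * A * u) * 1e5, (pt[1] - pt[2]) * 1e-3,
      (pt[1] - pt[3]) * 1e-3)
  }
  ## optimize over log-areas to keep the iterates positive
  fit <- stats::optim(log(A0 * 1.05), function(la) sum(resid(exp(la))^2),
                      method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  expect_equal(sol$A, exp(fit$par), tolerance = 1e-5)

  ## symmetric bifurcation splits the flow equally
  sym <- solve_junction(A0 = c(5e-5, 3e-5, 3e-5),
                        beta = c(900, 600, 600),
                        W = c(0.5 + 4 * c0[1], 0.1 - 4 * c0[2],
                              0.1 - 4 * c0[2]),
                        s_sign = s_sign, s_char = s_sign,
                        A_init = c(5e-5, 3e-5, 3e-5), P0 = P0, rho = rho)
  expect_equal(sym$Q[2], sym$Q[3], tolerance = 1e-12)
})

test_that("cycle averaging is exact on known signals", {
  t <- seq(0, 1, length.out = 1001)
  expect_equal(cycle_average(rep(3.5, 1001), t), 3.5, tolerance = 1e-12)
  expect_equal(cycle_average(sin(2 * pi * t), t), 0, tolerance = 1e-6)
  expect_equal(cycle_average(2 + sin(2 * pi * t), t), 2, tolerance = 1e-6)
  expect_error(cycle_average(1:10, seq(0, 0.5, length.out = 10)),
               "domain error")
})

test_that("steady flow in a uniform tube reproduces the Poiseuille-limit drop", {
  net <- single_tube_network(d_mm = 4, len_mm = 100, Eh = 4000)
  Q0 <- 5  # mL/s
  r <- run_to_periodic(
    net, solver_settings(target_dx_mm = 2.5, max_cycles = 10),
    inflow = list(t = c(0, 100), q_mls = c(Q0, Q0)),
    record = data.frame(segment_id = 1, node = c(10, 30)))
  n <- length(r$waveforms$t)
  dp <- r$waveforms$P[[1]][n] - r$waveforms$P[[2]][n]
  A <- r$waveforms$A[[1]][n]
  expect_equal(dp, 22 * pi * 0.0047 * (20 * 2.5e-3) * (Q0 * 1e-6) / A^2,
               tolerance = 0.01)
})

test_that("small pulses travel at the analytic wave speed", {
  net <- single_tube_network(d_mm = 8, len_mm = 800, pr = 10)
  tt <- seq(0, 0.2, by = 1e-3)
  pulse <- 0.5 * exp(-((tt - 0.03) / 0.008)^2)
  r <- run_to_periodic(
    net, solver_settings(target_dx_mm = 2.5, max_cycles = 1),
    inflow = list(t = tt, q_mls = pulse),
    record = data.frame(segment_id = 1, node = c(80, 200)))
  first_passage <- function(i) {
    w <- r$waveforms$Q[[i]]; t <- r$waveforms$t
    win <- t < 0.15           # before reflections dominate
    w <- w[win]; t <- t[win]
    j <- which.max(w)
    a <- w[j - 1]; b <- w[j]; cc <- w[j + 1]
    t[j] + 0.5 * (t[j] - t[j - 1]) * (a - cc) / (a - 2 * b + cc)
  }
  c_meas <- (120 * 2.5e-3) / (first_passage(2) - first_passage(1))
  c0 <- analytic_c0(net$segments$Eh[1], 8)
  expect_equal(c_meas, c0, tolerance = 0.03)
})

test_that("a forced time step above the CFL limit raises an instability error", {
  net <- build_toy_network()
  expect_error(
    run_to_periodic(net, solver_settings(target_dx_mm = 5, max_cycles = 1,
                                         dt_forced = 0.01)),
    "instability")
})

test_that("the closed-loop toy run conserves cycle-averaged flow", {
  net <- build_toy_network()
  r <- run_to_periodic(net, solver_settings(target_dx_mm = 5,
                                            periodicity_tol = 2e-4))
  expect_true(r$converged)
  ## junction balance: parent mean flow equals the summed daughters
  q <- r$outputs
  expect_equal(q[["qbar.Carotid_like"]],
               q[["qbar.Cerebral_A"]] + q[["qbar.Cerebral_B"]],
               tolerance = 1e-3)
  expect_equal(q[["qbar.Root"]],
               q[["qbar.Carotid_like"]] + q[["qbar.Systemic_branch"]],
               tolerance = 1e-3)
  ## closed loop: cardiac output equals total outflow within 1%
  expect_equal(r$co, sum(r$outlet_flows), tolerance = 0.01)
  ## junction Newton mass residuals stay below tolerance at every step
  expect_lt(r$max_mass_residual, 1e-10)
})

test_that("outputs are grid-converged on the toy network", {
  net <- build_toy_network()
  st <- function(dx) solver_settings(target_dx_mm = dx,
                                     periodicity_tol = 2e-4)
  r1 <- run_to_periodic(net, st(5))
  r2 <- run_to_periodic(net, st(2.5))
  rel <- abs(r2$outputs - r1$outputs) / pmax(abs(r1$outputs), 1)
  expect_lt(max(rel), 0.005)
})

test_that("output responses have the expected physiology", {
  net <- build_toy_network()
  st <- solver_settings(target_dx_mm = 5)
  x <- network_input_vector(net)
  y0 <- simulate_output_vector(x, net, st)
  ## doubling the cerebral outlet PRs lowers total cerebral outflow
  x2 <- x
  x2[c("pr.Cerebral_A", "pr.Cerebral_B")] <-
    2 * x[c("pr.Cerebral_A", "pr.Cerebral_B")]
  y2 <- simulate_output_vector(x2, net, st)
  expect_lt(y2[["qbar.Cerebral_A"]] + y2[["qbar.Cerebral_B"]],
            y0[["qbar.Cerebral_A"]] + y0[["qbar.Cerebral_B"]])
  ## a severe stenosis starves the host branch
  x3 <- x
  x3[["sten_L.SR"]] <- 0.95
  x3[["sten_L.Rv"]] <- 100
  x3[["sten_L.Dn"]] <- 5
  x3[["kt_L"]] <- 1.52
  y3 <- simulate_output_vector(x3, net, st)
  expect_lt(y3[["qbar.Carotid_like"]], 0.5 * y0[["qbar.Carotid_like"]])
  ## symmetric inputs give symmetric outputs
  expect_equal(y0[["qbar.Cerebral_A"]], y0[["qbar.Cerebral_B"]],
               tolerance = 1e-6)
})

test_that("stenosis interface enforces the empirical pressure jump", {
  ## steady flow through a stenosed tube: the pressure difference across
  ## the interface matches the loss model at the interface flow
  net <- single_tube_network(d_mm = 6, len_mm = 100, Eh = 4000, pr = 10,
                             dx = 2.5)
  net$stenoses <- list(stenosis_spec(1L, Rv = 5, Dn = 4, SR = 0.6,
                                     Kt = 1.52))
  Q0 <- 4
  mid <- (net$segments$n_nodes[1] - 1) %/% 2
  r <- run_to_periodic(
    net, solver_settings(target_dx_mm = 2.5, max_cycles = 12),
    inflow = list(t = c(0, 100), q_mls = c(Q0, Q0)),
    record = data.frame(segment_id = 1, node = c(mid, mid + 1)))
  n <- length(r$waveforms$t)
  dp <- r$waveforms$P[[1]][n] - r$waveforms$P[[2]][n]
  q <- r$waveforms$Q[[1]][n]
  s <- net$stenoses[[1]]
  ## total-pressure jump at steady state (equal areas up/downstream make
  ## the dynamic terms nearly cancel)
  expect_equal(dp, stenosis_pressure_loss(q, 0, s), tolerance = 0.005)
})
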