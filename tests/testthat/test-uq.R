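test_that("uncertainty intervals follow pixel size, modality and flags", {
  net <- build_toy_network()
  rec <- toy_patient_record(pixel_size = 0.4)
  um <- build_uncertainty_model(rec, net)
  ## diameter 4 mm with 0.4 mm pixels: [d - 0.8, d + 0.8]
  iv <- um$intervals
  d0 <- rec$diameters[["d.Cerebral_A"]]
  row <- iv[iv$name == "d.Cerebral_A", ]
  expect_equal(row$lower, max(d0 - 0.8, 2))
  expect_equal(row$upper, min(d0 + 0.8, 6))
  ## PC-MRI total inflow 400: [336, 464]
  expect_equal(um$flows$total_lo, 400 * 0.84)
  expect_equal(um$flows$total_hi, 400 * 1.16)
  ## ultrasound widens the inflow interval to +-35%
  rec2 <- toy_patient_record(modality = "ultrasound")
  um2 <- build_uncertainty_model(rec2, net)
  expect_equal(um2$flows$total_lo, 400 * 0.65)
  ## SPECT outflows at +-16%
  expect_equal(unname(um$flows$spect_lo), c(168, 168))
  ## a worked decimal case: pixel 0.4, diameter 3.0 -> [2.2, 3.8] before
  ## clamping to slot bounds
  expect_equal(c(3 - 2 * 0.4, 3 + 2 * 0.4), c(2.2, 3.8))
})

test_that("possibly-absent collaterals get the full anatomical interval", {
  net <- build_default_network()
  x0 <- network_input_vector(net)
  man <- input_manifest(net)
  dn <- man$name[man$kind == "diameter"]
  ln <- man$name[man$kind == "length"]
  prof <- data.frame(x_mm = 0:20, d_mm = c(rep(4.5, 5), rep(1.5, 11),
                                           rep(4.5, 5)))
  rec <- patient_record(
    diameters = x0[dn], lengths = x0[ln], pixel_size = 0.35,
    stenosis_side = "L", stenosis_profile = prof,
    spect_flows = stats::setNames(
      c(95, 95, 120, 120, 70, 70),
      cow_calibration_map(net)$q_output),
    total_inflow = 600, inflow_modality = "PC-MRI", map = 95,
    acoa_uncertain = TRUE)
  um <- build_uncertainty_model(rec, net)
  row <- um$intervals[um$intervals$name == "d.Ant_comm_", ]
  expect_equal(c(row$lower, row$upper), c(0.1, 2.6))
})

test_that("drawn cases stay in their intervals and rebuild the targets", {
  net <- build_toy_network()
  rec <- toy_patient_record()
  um <- build_uncertainty_model(rec, net)
  set.seed(31)
  draws <- replicate(400, {
    cs <- sample_case(um)
    expect_equal(sum(cs$targets$q_target), cs$targets$q_total,
                 tolerance = 1e-9)
    c(cs$x[["d.Cerebral_A"]], cs$targets$q_total, cs$x[["sten_L.Rv"]])
  })
  iv <- um$intervals
  row <- iv[iv$name == "d.Cerebral_A", ]
  expect_gte(min(draws[1, ]), row$lower)
  expect_lte(max(draws[1, ]), row$upper)
  expect_gte(min(draws[2, ]), um$flows$total_lo)
  expect_lte(max(draws[2, ]), um$flows$total_hi)
  ## uniform marginals (KS)
  expect_gt(stats::ks.test(draws[1, ], "punif", row$lower,
                           row$upper)$p.value, 0.01)
  expect_gt(stats::ks.test(draws[2, ], "punif", um$flows$total_lo,
                           um$flows$total_hi)$p.value, 0.01)
  ## stenosis parameters respond to the shared profile offset
  expect_gt(stats::sd(draws[3, ]), 0)
})

test_that("virtual stenting restores the intact convention and is idempotent", {
  net <- build_toy_network()
  set.seed(4)
  x <- sample_input_vector(net, "left_stenosis")
  y <- virtual_stenting(x, "L", net)
  expect_identical(unname(y[c("sten_L.Rv", "sten_L.SR", "kt_L")]),
                   c(0, 0, 0))
  expect_identical(y[["sten_L.Dn"]], x[["d.Carotid_like"]])
  ## idempotent, and only the stenosis slots change
  expect_identical(virtual_stenting(y, "L", net), y)
  untouched <- setdiff(names(x), c("sten_L.Rv", "sten_L.SR", "sten_L.Dn",
                                   "kt_L"))
  expect_identical(y[untouched], x[untouched])
})

test_that("the flow-increase definition matches its arithmetic", {
  pre <- c(q1 = 100, q2 = 80)
  expect_equal(unname(delta_q(pre, pre, c("q1", "q2"))), c(0, 0))
  expect_equal(unname(delta_q(pre, 2 * pre, c("q1", "q2"))), c(100, 100))
  expect_equal(unname(delta_q(c(q1 = 100), c(q1 = 250), "q1")), 150)
  expect_error(delta_q(c(q1 = 0), c(q1 = 10), "q1"), "domain error")
})

test_that("zero-width uncertainty collapses the Monte Carlo loop", {
  net <- build_toy_network()
  rec <- toy_patient_record()
  um <- build_uncertainty_model(rec, net)
  ## degenerate model: all intervals shrunk to their midpoint
  um$intervals$lower <- um$intervals$upper <-
    (um$intervals$lower + um$intervals$upper) / 2
  um$sten$delta_half_mm <- 0
  um$sten$kt_lo <- um$sten$kt_hi <- 1.52
  um$flows$spect_lo <- um$flows$spect_hi <- um$flows$spect
  um$flows$total_lo <- um$flows$total_hi <- 400
  r <- run_uq(analytic_toy_predictor(), rec, net, seed = 8,
              increment = 50, um = um)
  expect_true(r$converged)
  expect_equal(unname(r$var), c(0, 0))
  expect_true(all(r$p_ch %in% c(0, 1)))
  expect_equal(r$min, r$max)
})

test_that("the estimated hyperperfusion probability matches a closed form", {
  net <- build_toy_network()
  rec <- toy_patient_record(pixel_size = 0.2, stenosis_d = 1.2,
                            stenosis_len = 20)
  pred <- analytic_toy_predictor(K = 2700, w = 0.5)
  r <- run_uq(pred, rec, net, seed = 12, increment = 1500, stat_tol = 0.01,
              max_batches = 4)
  expect_gt(r$n_mc, 1000)
  expect_gte(r$rejected, 0)

  ## closed-form oracle: with the Ohmic predictor, calibration matching
  ## the drawn targets (qa, qb, map) gives, after stenting,
  ##   dq_i = 100 * w Rv qt_i / (K map/90 - w Rv qt_i)
  ## with Rv from the +-2 px profile offset and qt_i from the drawn flow
  ## targets; evaluate the probability by direct dense sampling of that
  ## formula, independent of the pipeline
  set.seed(999)
  M <- 2e5
  um <- build_uncertainty_model(rec, net)
  delta <- stats::runif(M, -um$sten$delta_half_mm, um$sten$delta_half_mm)
  rv <- vapply(delta, function(d) {
    min(stenosis_from_profile(um$sten$profile, d)$Rv, 500)
  }, numeric(1))
  qa <- stats::runif(M, um$flows$spect_lo[1], um$flows$spect_hi[1])
  qb <- stats::runif(M, um$flows$spect_lo[2], um$flows$spect_hi[2])
  tot <- stats::runif(M, um$flows$total_lo, um$flows$total_hi)
  qta <- tot * qa / (qa + qb)
  qtb <- tot * qb / (qa + qb)
  mapf <- um$map / 90
  ## cases whose required PR leaves the declared clamp interval are the
  ## ones the pipeline rejects at calibration; condition on validity
  pra <- 2700 * mapf / qta - 0.5 * rv
  prb <- 2700 * mapf / qtb - 0.5 * rv
  valid <- pra >= 2 & pra <= 30 & prb >= 2 & prb <= 30
  dq_true <- 100 * 0.5 * rv * qta / (2700 * mapf - 0.5 * rv * qta)
  p_true <- mean(dq_true[valid] > 100)
  expect_gt(p_true, 0.01); expect_lt(p_true, 0.99)

  p_hat <- r$p_ch[["qbar.Cerebral_A"]]
  se <- sqrt(p_true * (1 - p_true) / r$n_mc)
  expect_lt(abs(p_hat - p_true), 3 * se + 3 * sqrt(p_true * (1 - p_true) / M))

  ## removing a resistance cannot reduce flow: all increases non-negative
  expect_gte(min(r$samples), 0)
  ## reproducibility under the seed
  r2 <- run_uq(pred, rec, net, seed = 12, increment = 1500,
               stat_tol = 0.01, max_batches = 4)
  expect_identical(r$samples, r2$samples)
  expect_identical(r$trace, r2$trace)
})
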