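## Shared fixtures, all built in code at test time.

## a single uniform elastic tube closed by one Windkessel outlet;
## optionally with fixed (overridden) wall stiffness
single_tube_network <- function(d_mm = 4, len_mm = 100, Eh = NULL,
                                pr = 10, dx = 2.5) {
  seg <- data.frame(
    id = 1L, name = "tube", d_base_mm = d_mm, length_mm = len_mm,
    is_aortic = FALSE, is_cow = TRUE,
    eh_override = if (is.null(Eh)) NA_real_ else Eh,
    d_lo = 1, d_hi = 20, l_lo = 10, l_hi = 2000)
  seg <- cowsim:::finalize_segments(seg, cowsim:::default_eh_law(),
                                    cowsim:::default_age_table(), 45, dx)
  outlets <- data.frame(segment_id = 1L, R1 = 0.2 * pr, R2 = 0.8 * pr,
                        C = 0.3, PR_base = pr, is_cow_outlet = FALSE,
                        body_block = 1L, pr_lo = NA, pr_hi = NA)
  bb <- data.frame(name = "body", R = 0.08, L = 5e-4, C = 40, P_init = 9)
  vascular_network(
    seg, list(), outlets, bb, cowsim:::default_heart(1L),
    cow_inlet_ids = integer(), cow_outlet_ids = integer(),
    cow_segment_ids = 1L, map_segment_id = 1L,
    stenosis_hosts = data.frame(host_segment_id = integer(),
                                side = character(), dn_lo = numeric(),
                                dn_hi = numeric()),
    target_dx_mm = dx)
}

## wave speed of the square-root tube law at the reference area
analytic_c0 <- function(Eh, d_mm, sigma = 0.5, rho = 1060) {
  A0 <- pi * (d_mm / 2 * 1e-3)^2
  beta <- sqrt(pi) * Eh / (1 - sigma^2)
  sqrt(beta * sqrt(A0) / (2 * rho * A0))
}

## tiny dataset triple with a linear input-output map, through the
## dataset container used by the surrogate
linear_dataset <- function(n = 500, d = 6, k = 3, noise = 0.01, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n * d, -1, 1), n)
  W <- matrix(stats::rnorm(d * k), d)
  Y <- X %*% W + noise * matrix(stats::rnorm(n * k), n)
  man <- data.frame(name = paste0("x", seq_len(d)), kind = "diameter",
                    target_id = seq_len(d), side = NA_character_,
                    lower = -1, upper = 1, unit = "-")
  mk <- function(i) {
    structure(list(
      inputs = stats::setNames(as.data.frame(X[i, , drop = FALSE]),
                               man$name),
      outputs = stats::setNames(as.data.frame(Y[i, , drop = FALSE]),
                                paste0("y", seq_len(k))),
      scenario = rep("intact", length(i)), meta = list(seed = seed)),
      class = "cowsim_dataset")
  }
  n1 <- floor(0.6 * n); n2 <- floor(0.8 * n)
  list(train = mk(seq_len(n1)), validation = mk((n1 + 1):n2),
       test = mk((n2 + 1):n), manifest = man, W = W)
}

## analytic toy predictor over the toy-network manifest: outlet flows
## follow an Ohmic law in the PR slots and stenosis Rv, MAP follows the
## scaling factor; used as a fast stand-in prediction contract
analytic_toy_predictor <- function(K = 2700, w = 0.5) {
  function(x) {
    map <- 60 + 20 * x[["pr_scale"]]
    rv <- x[["sten_L.Rv"]]
    qa <- K * (map / 90) / (x[["pr.Cerebral_A"]] + w * rv)
    qb <- K * (map / 90) / (x[["pr.Cerebral_B"]] + w * rv)
    c(qbar.Root = unname(qa + qb) * 2, qbar.Carotid_like = unname(qa + qb),
      qbar.Systemic_branch = unname(qa + qb),
      qbar.Cerebral_A = unname(qa), qbar.Cerebral_B = unname(qb),
      pbar.Root = 90, pbar.Carotid_like = 85, pbar.Systemic_branch = 85,
      pbar.Cerebral_A = 80, pbar.Cerebral_B = 80, map = unname(map))
  }
}

## synthetic toy patient record matching the toy-network manifest
toy_patient_record <- function(pixel_size = 0.2, stenosis_d = 1.2,
                               stenosis_len = 20, total = 400, map = 90,
                               modality = "PC-MRI") {
  net <- build_toy_network()
  x0 <- network_input_vector(net)
  man <- input_manifest(net)
  dnames <- man$name[man$kind == "diameter"]
  lnames <- man$name[man$kind == "length"]
  profile <- data.frame(x_mm = seq(0, stenosis_len, by = 1))
  profile$d_mm <- ifelse(
    profile$x_mm > 0.2 * stenosis_len & profile$x_mm < 0.8 * stenosis_len,
    stenosis_d, 4.5)
  patient_record(
    diameters = x0[dnames], lengths = x0[lnames],
    pixel_size = pixel_size, stenosis_side = "L",
    stenosis_profile = profile,
    spect_flows = c(qbar.Cerebral_A = 200, qbar.Cerebral_B = 200),
    total_inflow = total, inflow_modality = modality, map = map,
    age = 60)
}
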