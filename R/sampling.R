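#' Upper sampling bound for the stenosis viscous resistance
#'
#' The admissible viscous resistance grows with stenosis severity as
#' `128 mu Ls_max / (pi Dn_min^4 (1 - SR)^4)`, capped at
#' 500 mmHg s mL^-1, with `Ls_max` = 40 mm and `Dn_min` = 2.9 mm.
#'
#' @param SR stenosis ratio, fraction in [0, 1)
#' @param mu blood viscosity, Pa s
#' @param ls_max_mm,dn_min_mm geometric extremes of the stenosis
#' @param cap cap in mmHg s mL^-1
#' @return upper bound for Rv in mmHg s mL^-1
#' @export
rv_upper_bound <- function(SR, mu = BLOOD_MU, ls_max_mm = 40,
                           dn_min_mm = 2.9, cap = 500) {
  if (any(SR < 0) || any(SR >= 1)) {
    stop("domain error: SR must be in [0, 1)", call. = FALSE)
  }
  rv_si <- 128 * mu * (ls_max_mm * 1e-3) /
    (pi * (dn_min_mm * 1e-3)^4 * (1 - SR)^4)
  pmin(rv_si / RES_SI, cap)
}

#' Stenosis scenarios
#' @keywords internal
SCENARIOS <- c("intact", "left_stenosis", "right_stenosis", "bilateral")

#' @keywords internal
stenosed_sides <- function(scenario) {
  switch(scenario,
    intact = character(),
    left_stenosis = "L",
    right_stenosis = "R",
    bilateral = c("L", "R"),
    stop("unknown scenario: ", scenario)
  )
}

#' Draw one input vector
#'
#' Uniform independent draws within the manifest intervals (uses R's
#' global RNG; seed with [set.seed()]).  Stenosis slots follow the
#' scenario: on a stenosed side, `SR ~ U[0, 0.99]`,
#' `Rv ~ U[0, rv_upper_bound(SR)]`, `Dn` and `Kt` uniform in their
#' ranges; on an intact side `Rv = SR = Kt = 0` and `Dn` equals that
#' side's sampled host-artery diameter.
#'
#' @param net a `vascular_network` (defines the manifest)
#' @param scenario one of `"intact"`, `"left_stenosis"`,
#'   `"right_stenosis"`, `"bilateral"`
#' @return named numeric vector in manifest order
#' @export
sample_input_vector <- function(net, scenario = "intact") {
  scenario <- match.arg(scenario, SCENARIOS)
  man <- input_manifest(net)
  sides <- stenosed_sides(scenario)
  if (!all(sides %in% net$stenosis_hosts$side)) {
    stop("scenario ", scenario, " requires stenosis host side(s) ",
         paste(setdiff(sides, net$stenosis_hosts$side), collapse = ", "),
         " absent from this network", call. = FALSE)
  }
  x <- stats::setNames(numeric(nrow(man)), man$name)
  plain <- !(man$kind %in% c("sten_rv", "sten_dn", "sten_sr", "sten_kt"))
  x[plain] <- stats::runif(sum(plain), man$lower[plain], man$upper[plain])
  for (j in seq_len(nrow(net$stenosis_hosts))) {
    h <- net$stenosis_hosts[j, ]
    nm <- function(f) paste0("sten_", h$side, ".", f)
    if (h$side %in% sides) {
      sr <- stats::runif(1, 0, 0.99)
      x[nm("SR")] <- sr
      x[nm("Rv")] <- stats::runif(1, 0, rv_upper_bound(sr))
      x[nm("Dn")] <- stats::runif(1, h$dn_lo, h$dn_hi)
      x[paste0("kt_", h$side)] <- stats::runif(1, 1.0, 2.699)
    } else {
      x[nm("SR")] <- 0
      x[nm("Rv")] <- 0
      x[paste0("kt_", h$side)] <- 0
      host_d_slot <- man$name[man$kind == "diameter" &
                                man$target_id == h$host_segment_id]
      x[nm("Dn")] <- x[host_d_slot]
    }
  }
  x
}

#' Generate a simulated learning dataset
#'
#' For each requested scenario, draws input vectors, evaluates the
#' predictor (by default the 1D-0D simulator on `net`), and rejects
#' unphysical samples -- any negative cycle-averaged pressure, reversed
#' (negative) cycle-averaged flow in an outlet-bearing artery, a
#' non-periodic run, or non-finite outputs -- redrawing until
#' `n_per_scenario` samples are accepted per scenario.
#'
#' @param net base `vascular_network`
#' @param n_per_scenario accepted samples per scenario
#' @param scenarios character vector of scenario names
#' @param predictor function mapping an input vector to the named output
#'   vector; defaults to [simulate_output_vector()] on `net`
#' @param settings [solver_settings()] for the default predictor
#' @param seed integer seed (dataset generation is deterministic given
#'   the seed)
#' @param max_reject_ratio abort when the running rejection rate exceeds
#'   this value after 50 draws (suggests misconfiguration)
#' @return object of class `cowsim_dataset`: `inputs` (rows x slots),
#'   `outputs` (rows x outputs), `scenario`, `meta`
#' @export
generate_dataset <- function(net, n_per_scenario,
                             scenarios = c("intact", "left_stenosis"),
                             predictor = NULL,
                             settings = solver_settings(), seed = 1) {
  stopifnot(n_per_scenario >= 1)
  if (is.null(predictor)) {
    predictor <- function(x) simulate_output_vector(x, net, settings)
  }
  set.seed(seed)
  onames <- output_names(net)
  terminal_flag <- intersect(net$cow_segment_ids, net$outlets$segment_id)
  term_cols <- paste0("qbar.", gsub("_+", "_", gsub(
    "[^A-Za-z0-9]", "_",
    net$segments$name[match(terminal_flag, net$segments$id)])))
  inputs <- list(); outputs <- list(); scen <- character()
  n_rejected <- 0L; n_tried <- 0L
  for (sc in scenarios) {
    acc <- 0L
    while (acc < n_per_scenario) {
      x <- sample_input_vector(net, sc)
      y <- tryCatch(predictor(x), error = function(e) NULL)
      n_tried <- n_tried + 1L
      bad <- is.null(y) || anyNA(y) || any(!is.finite(y)) ||
        isFALSE(attr(y, "converged")) ||
        any(y[grepl("^pbar\\.|^map$", names(y))] < 0) ||
        any(y[intersect(term_cols, names(y))] < 0)
      if (bad) {
        n_rejected <- n_rejected + 1L
        if (n_tried > 50 && n_rejected / n_tried > 0.9) {
          stop("generation error: rejection rate above 90% -- check the ",
               "network or solver configuration", call. = FALSE)
        }
        next
      }
      inputs[[length(inputs) + 1L]] <- x
      outputs[[length(outputs) + 1L]] <- as.numeric(y[onames])
      scen <- c(scen, sc)
      acc <- acc + 1L
    }
  }
  inp <- as.data.frame(do.call(rbind, inputs))
  out <- as.data.frame(do.call(rbind, outputs))
  names(out) <- onames
  structure(
    list(inputs = inp, outputs = out, scenario = scen,
         meta = list(seed = as.integer(seed), n_rejected = n_rejected,
                     network = net$name,
                     generated = as.character(Sys.time()))),
    class = "cowsim_dataset"
  )
}

#' Split a dataset 6:2:2
#'
#' Deterministic, scenario-stratified shuffling into disjoint training,
#' validation and test partitions (remainder rows go to training).
#'
#' @param ds a `cowsim_dataset`
#' @param seed integer seed
#' @param ratio three non-negative weights, default `c(6, 2, 2)`
#' @return list with elements `train`, `validation`, `test`, each a
#'   `cowsim_dataset`
#' @export
split_dataset <- function(ds, seed = 1, ratio = c(6, 2, 2)) {
  n <- nrow(ds$inputs)
  if (n < 10) stop("domain error: need at least 10 rows to split")
  set.seed(seed)
  frac <- ratio / sum(ratio)
  idx <- list(train = integer(), validation = integer(), test = integer())
  for (sc in unique(ds$scenario)) {
    rows <- sample(which(ds$scenario == sc))
    m <- length(rows)
    nv <- floor(frac[2] * m); nt <- floor(frac[3] * m)
    idx$validation <- c(idx$validation, rows[seq_len(nv)])
    idx$test <- c(idx$test, rows[nv + seq_len(nt)])
    idx$train <- c(idx$train, rows[(nv + nt + 1):m])
  }
  subset_ds <- function(i) {
    structure(list(inputs = ds$inputs[i, , drop = FALSE],
                   outputs = ds$outputs[i, , drop = FALSE],
                   scenario = ds$scenario[i], meta = ds$meta),
              class = "cowsim_dataset")
  }
  lapply(idx, subset_ds)
}

#' Write / read a dataset as columnar CSV plus JSON metadata
#'
#' @param ds a `cowsim_dataset`
#' @param dir destination directory (created if needed)
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$inputs, file.path(dir, "inputs.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$outputs, file.path(dir, "outputs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = ds$scenario, meta = ds$meta),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(inputs = utils::read.csv(file.path(dir, "inputs.csv"),
                                  check.names = FALSE),
         outputs = utils::read.csv(file.path(dir, "outputs.csv"),
                                   check.names = FALSE),
         scenario = meta$scenario, meta = meta$meta),
    class = "cowsim_dataset"
  )
}

#' @export
print.cowsim_dataset <- function(x, ...) {
  cat("<cowsim_dataset> ", nrow(x$inputs), " samples x ",
      ncol(x$inputs), " inputs / ", ncol(x$outputs), " outputs; ",
      "scenarios: ", paste(unique(x$scenario), collapse = ", "),
      "; rejected: ", x$meta$n_rejected, "\n", sep = "")
  invisible(x)
}
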