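#' Arterial network data model
#'
#' A `vascular_network` bundles everything the closed-loop 1D-0D solver
#' needs: the 1D arterial segments (straight deformable tubes), the
#' junction topology, optional stenosis specifications, three-element
#' Windkessel outlets, lumped (0D) body compartments and the heart model.
#'
#' Segments live in a data frame with one row per artery.  `diameter_mm`
#' and `Eh` are the *realized* values (after age adjustment for aortic
#' segments); `d_base_mm` holds the reference-age diameter from which the
#' aortic age scaling is applied.  Wall stiffness `Eh` (in Pa m) is
#' assigned from the radius through an empirical exponential-plus-constant
#' law unless `eh_override` is set for a segment.
#'
#' @name vascular_network
NULL

#' Empirical wall-stiffness law Eh(r)
#'
#' Exponential-plus-constant relation between lumen radius and the
#' stiffness product Eh used in the tube law.  Constants are stored in the
#' network (`eh_law`) and can be overridden per segment; the shipped
#' values are literature-informed defaults.
#'
#' @param r_mm lumen radius in mm
#' @param law list with elements `k1`, `k2`, `k3` (CGS-flavoured
#'   constants: `Eh/r = k1 exp(k2 r) + k3` with r in cm and Eh/r in
#'   dyn cm^-2... the returned value is converted to Pa m)
#' @return Eh in Pa m
#' @export
eh_from_radius <- function(r_mm, law = default_eh_law()) {
  r_cm <- r_mm / 10
  ## Eh [dyn/cm] = r_cm * (k1 exp(k2 r_cm) + k3); 1 dyn/cm = 1e-3 N/m
  eh_dyn_cm <- r_cm * (law$k1 * exp(law$k2 * r_cm) + law$k3)
  eh_dyn_cm * 1e-3
}

#' @keywords internal
default_eh_law <- function() list(k1 = 2e7, k2 = -22.53, k3 = 8.65e5)

#' Piecewise-linear aortic age adjustment
#'
#' Aortic diameter and stiffness change with age; non-aortic segments are
#' unaffected.  The mapping is a documented piecewise-linear interpolation
#' table stored in the network config, anchored at a reference age where
#' both scales are 1.
#'
#' @keywords internal
default_age_table <- function() {
  list(
    reference_age = 45,
    age = c(25, 45, 65, 90),
    d_scale = c(0.96, 1.00, 1.05, 1.10),
    eh_scale = c(0.80, 1.00, 1.55, 2.40)
  )
}

#' @keywords internal
age_scales <- function(age, tab) {
  if (age < min(tab$age) || age > max(tab$age)) {
    stop("age ", age, " outside the supported range [",
         min(tab$age), ", ", max(tab$age), "]", call. = FALSE)
  }
  list(
    d = stats::approx(tab$age, tab$d_scale, xout = age)$y,
    eh = stats::approx(tab$age, tab$eh_scale, xout = age)$y
  )
}

#' Odd node count for a segment
#' @keywords internal
segment_n_nodes <- function(length_mm, target_dx_mm) {
  n <- max(3L, as.integer(round(length_mm / target_dx_mm)) + 1L)
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Construct a stenosis specification
#'
#' Empirical pressure-loss model for a stenosed artery.  `Rv` is the
#' viscous (Poiseuille-type) resistance of the narrowed lumen, `Dn` the
#' maximum diameter distal to the stenosis, `SR = 1 - Ds/Dn` the diameter
#' reduction ratio, `Kt` the flow-separation coefficient and `Ku` the
#' pulsatility coefficient (1.2, held fixed).  An intact vessel has
#' `Rv = 0, SR = 0, Kt = 0, Dn = ` host diameter.
#'
#' @param host_segment_id id of the 1D segment carrying the stenosis
#' @param Rv viscous resistance, mmHg s mL^-1
#' @param Dn distal reference diameter, mm
#' @param SR stenosis ratio, fraction in [0, 1)
#' @param Kt separation coefficient (dimensionless)
#' @param Ku pulsatility coefficient (dimensionless)
#' @param Ls stenosis length, mm (used only by the pulsatility term)
#' @param profile optional data frame with columns `x_mm`, `d_mm`
#'   sampling the axial diameter profile D(x)
#' @export
stenosis_spec <- function(host_segment_id, Rv, Dn, SR, Kt,
                          Ku = 1.2, Ls = 20, profile = NULL) {
  stopifnot(Rv >= 0, SR >= 0, SR < 1, Dn > 0, Kt >= 0, Ku >= 0, Ls >= 0)
  structure(
    list(host_segment_id = as.integer(host_segment_id), Rv = Rv, Dn = Dn,
         SR = SR, Kt = Kt, Ku = Ku, Ls = Ls, profile = profile),
    class = "stenosis_spec"
  )
}

#' Assemble a vascular network object
#'
#' Low-level constructor; most users will call [build_default_network()]
#' or [build_toy_network()].  Validates all structural invariants.
#'
#' @param segments data frame of 1D segments (see package docs)
#' @param junctions list of junctions, each `list(segments=, ends=)` where
#'   `ends` is "end" (distal end feeds the junction) or "start"
#' @param outlets data frame of Windkessel outlets
#' @param body_blocks data frame of RLC venous compartments
#' @param heart list of elastance-heart parameters
#' @param stenoses list of [stenosis_spec()] objects
#' @param cow_inlet_ids,cow_outlet_ids,cow_segment_ids id bookkeeping for
#'   the circle of Willis (3 inlets, 6 outlets, 22 cerebral segments) or
#'   analogous sets for reduced networks
#' @param map_segment_id segment whose mid-node cycle-averaged pressure is
#'   reported as the mean arterial pressure
#' @param age age in years (drives the aortic adjustment)
#' @param eh_law,age_table,pr_split config blocks (see details)
#' @param name network label
#' @export
vascular_network <- function(segments, junctions, outlets, body_blocks,
                             heart, stenoses = list(),
                             cow_inlet_ids = integer(), cow_outlet_ids,
                             cow_segment_ids, map_segment_id, age = 45,
                             eh_law = default_eh_law(),
                             age_table = default_age_table(),
                             pr_split = 0.2, name = "network",
                             stenosis_hosts = NULL, target_dx_mm = 2.5) {
  net <- structure(
    list(segments = segments, junctions = junctions, outlets = outlets,
         body_blocks = body_blocks, heart = heart, stenoses = stenoses,
         cow_inlet_ids = as.integer(cow_inlet_ids),
         cow_outlet_ids = as.integer(cow_outlet_ids),
         cow_segment_ids = as.integer(cow_segment_ids),
         map_segment_id = as.integer(map_segment_id),
         age = age, eh_law = eh_law, age_table = age_table,
         pr_split = pr_split, name = name,
         stenosis_hosts = stenosis_hosts, target_dx_mm = target_dx_mm),
    class = "vascular_network"
  )
  validate_network(net)
  net
}

#' Validate a vascular network
#'
#' Checks segment invariants (positive geometry, odd node counts, area
#' consistency), outlet invariants, junction id references and global
#' connectivity with the heart inlet as the single source.
#'
#' @param net a `vascular_network`
#' @return the network, invisibly
#' @export
validate_network <- function(net) {
  seg <- net$segments
  need <- c("id", "name", "length_mm", "diameter_mm", "Eh", "n_nodes",
            "is_cow", "is_aortic", "P0_mmHg", "sigma")
  miss <- setdiff(need, names(seg))
  if (length(miss)) {
    stop("configuration error: segment table lacks field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(seg$id)) stop("configuration error: duplicated segment ids")
  if (any(seg$length_mm <= 0)) stop("configuration error: length_mm must be > 0")
  if (any(seg$diameter_mm <= 0)) stop("configuration error: diameter_mm must be > 0")
  if (any(seg$Eh <= 0)) stop("configuration error: Eh must be > 0")
  if (any(seg$n_nodes < 3 | seg$n_nodes %% 2 == 0)) {
    stop("configuration error: n_nodes must be odd and >= 3")
  }
  a0 <- pi * (seg$diameter_mm / 2)^2
  if ("A0_mm2" %in% names(seg) &&
      any(abs(seg$A0_mm2 - a0) > 1e-9 * pmax(a0, 1))) {
    stop("configuration error: A0_mm2 inconsistent with diameter_mm")
  }
  for (j in net$junctions) {
    if (!all(j$segments %in% seg$id)) {
      stop("topology error: junction references missing segment id ",
           paste(setdiff(j$segments, seg$id), collapse = ", "), call. = FALSE)
    }
    if (length(j$segments) != length(j$ends) || length(j$segments) < 2) {
      stop("topology error: malformed junction", call. = FALSE)
    }
  }
  out <- net$outlets
  if (any(out$R1 <= 0) || any(out$R2 <= 0) || any(out$C <= 0)) {
    stop("configuration error: outlet R1, R2, C must be > 0")
  }
  if (!all(out$segment_id %in% seg$id)) {
    stop("topology error: outlet references missing segment id")
  }
  ## each segment end is used at most once (junction or outlet)
  ends_used <- c(
    paste0(unlist(lapply(net$junctions, function(j) j$segments)), ":",
           unlist(lapply(net$junctions, function(j) j$ends))),
    paste0(out$segment_id, ":end"),
    paste0(net$heart$root_segment_id, ":start")
  )
  if (anyDuplicated(ends_used)) {
    stop("topology error: a segment end is attached twice")
  }
  ## every segment must have both ends attached (closed loop through 0D)
  for (id in seg$id) {
    for (e in c("start", "end")) {
      if (!paste0(id, ":", e) %in% ends_used) {
        stop("topology error: segment ", id, " has a free ", e, call. = FALSE)
      }
    }
  }
  ## connectivity via junctions from the root
  adj <- new.env(parent = emptyenv())
  for (j in net$junctions) {
    for (a in j$segments) {
      key <- as.character(a)
      assign(key, union(if (exists(key, adj)) get(key, adj) else integer(),
                        setdiff(j$segments, a)), envir = adj)
    }
  }
  seen <- net$heart$root_segment_id
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(as.character(frontier), function(k) {
      if (exists(k, adj)) get(k, adj) else integer()
    })))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  if (!setequal(seen, seg$id)) {
    stop("topology error: network not connected (unreached segments: ",
         paste(setdiff(seg$id, seen), collapse = ", "), ")", call. = FALSE)
  }
  for (s in net$stenoses) {
    if (!s$host_segment_id %in% seg$id) {
      stop("topology error: stenosis host segment not in network")
    }
  }
  invisible(net)
}

#' Peripheral resistance of each outlet
#'
#' The PR of a three-element Windkessel outlet is the sum of its proximal
#' and distal resistances.
#'
#' @param net a `vascular_network`
#' @return named numeric vector, mmHg s mL^-1, named by segment id
#' @export
outlet_pr <- function(net) {
  stats::setNames(net$outlets$R1 + net$outlets$R2,
                  as.character(net$outlets$segment_id))
}

#' @keywords internal
set_outlet_pr <- function(net, segment_id, pr) {
  i <- match(segment_id, net$outlets$segment_id)
  stopifnot(!anyNA(i), all(pr > 0))
  net$outlets$R1[i] <- net$pr_split * pr
  net$outlets$R2[i] <- (1 - net$pr_split) * pr
  net
}

#' Read a network configuration file
#'
#' Reads the JSON schema written by [write_network_config()]; numeric
#' fields round-trip at full precision.
#'
#' @param path path to a JSON network config
#' @return a validated `vascular_network`
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stenoses <- list()
  if (!is.null(x$stenoses) && length(x$stenoses$host_segment_id)) {
    st <- x$stenoses
    stenoses <- lapply(seq_along(st$host_segment_id), function(i) {
      prof <- st$profile[[i]]
      if (!is.null(prof) && length(prof)) {
        prof <- as.data.frame(prof)
      } else prof <- NULL
      stenosis_spec(st$host_segment_id[i], st$Rv[i], st$Dn[i], st$SR[i],
                    st$Kt[i], st$Ku[i], st$Ls[i], prof)
    })
  }
  jx <- x$junctions
  junctions <- if (is.data.frame(jx)) {
    lapply(seq_len(nrow(jx)), function(i) {
      list(segments = as.integer(jx$segments[[i]]),
           ends = as.character(jx$ends[[i]]))
    })
  } else {
    lapply(jx, function(j) {
      list(segments = as.integer(j$segments), ends = as.character(j$ends))
    })
  }
  ## JSON carries no int/double distinction: restore double storage for
  ## all numeric fields except genuine counters/ids
  fix_types <- function(df, int_cols) {
    for (nm in names(df)) {
      if (nm %in% int_cols) df[[nm]] <- as.integer(df[[nm]])
      else if (is.numeric(df[[nm]])) df[[nm]] <- as.numeric(df[[nm]])
    }
    df
  }
  vascular_network(
    segments = fix_types(as.data.frame(x$segments), c("id", "n_nodes")),
    junctions = junctions,
    outlets = fix_types(as.data.frame(x$outlets),
                        c("segment_id", "body_block")),
    body_blocks = fix_types(as.data.frame(x$body_blocks), character()),
    heart = x$heart,
    stenoses = stenoses,
    cow_inlet_ids = x$cow_inlet_ids,
    cow_outlet_ids = x$cow_outlet_ids,
    cow_segment_ids = x$cow_segment_ids,
    map_segment_id = x$map_segment_id,
    age = x$age, eh_law = x$eh_law, age_table = x$age_table,
    pr_split = x$pr_split, name = x$name,
    stenosis_hosts = if (!is.null(x$stenosis_hosts)) {
      fix_types(as.data.frame(x$stenosis_hosts), "host_segment_id")
    },
    target_dx_mm = if (!is.null(x$target_dx_mm)) x$target_dx_mm else 2.5
  )
}

#' Write a network configuration file
#'
#' @param net a `vascular_network`
#' @param path destination path (JSON)
#' @export
write_network_config <- function(net, path) {
  sten <- NULL
  if (length(net$stenoses)) {
    gf <- function(f) vapply(net$stenoses, function(s) s[[f]], numeric(1))
    sten <- list(
      host_segment_id = as.integer(gf("host_segment_id")),
      Rv = gf("Rv"), Dn = gf("Dn"), SR = gf("SR"), Kt = gf("Kt"),
      Ku = gf("Ku"), Ls = gf("Ls"),
      profile = lapply(net$stenoses, function(s) {
        if (is.null(s$profile)) list() else s$profile
      })
    )
  }
  x <- list(
    name = net$name, age = net$age,
    segments = net$segments, junctions = net$junctions,
    outlets = net$outlets, body_blocks = net$body_blocks,
    heart = net$heart, stenoses = sten,
    cow_inlet_ids = net$cow_inlet_ids, cow_outlet_ids = net$cow_outlet_ids,
    cow_segment_ids = net$cow_segment_ids,
    map_segment_id = net$map_segment_id,
    eh_law = net$eh_law, age_table = net$age_table, pr_split = net$pr_split,
    stenosis_hosts = net$stenosis_hosts, target_dx_mm = net$target_dx_mm
  )
  ok <- tryCatch({
    jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                         dataframe = "columns", pretty = FALSE, na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", x$name, "\n",
      "  segments: ", nrow(x$segments),
      " (", sum(x$segments$is_cow), " cerebral/carotid)\n",
      "  outlets:  ", nrow(x$outlets),
      " (", sum(x$outlets$is_cow_outlet), " circle-of-Willis)\n",
      "  stenoses: ", length(x$stenoses), "; age ", x$age, " y\n", sep = "")
  invisible(x)
}
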