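#' Input-vector manifest
#'
#' The surrogate interface between anatomy/physiology and predicted
#' hemodynamics is a fixed, named slot order.  For the default 83-segment
#' network this is the published 60-slot layout: 22 carotid/cerebral
#' diameters (mm), the 22 matching lengths (mm), the 6 CoW outlet
#' peripheral resistances (mmHg s/mL), the total-PR scaling factor (-),
#' age (years), left then right stenosis triplets \{Rv, Dn, SR\}, and the
#' left/right separation coefficients Kt.  Reduced networks get the
#' analogous layout derived from their own flagged segments and outlets.
#'
#' @param net a `vascular_network`
#' @return data frame with columns `name`, `kind`, `target_id`, `side`,
#'   `lower`, `upper`, `unit`
#' @export
input_manifest <- function(net) {
  seg <- net$segments
  flag <- seg[match(net$cow_segment_ids, seg$id), ]
  slug <- function(x) gsub("_+", "_", gsub("[^A-Za-z0-9]", "_", x))
  rows <- list()
  rows$d <- data.frame(
    name = paste0("d.", slug(flag$name)), kind = "diameter",
    target_id = flag$id, side = NA_character_,
    lower = flag$d_lo, upper = flag$d_hi, unit = "mm"
  )
  rows$l <- data.frame(
    name = paste0("l.", slug(flag$name)), kind = "length",
    target_id = flag$id, side = NA_character_,
    lower = flag$l_lo, upper = flag$l_hi, unit = "mm"
  )
  cow_out <- net$outlets[match(net$cow_outlet_ids, net$outlets$segment_id), ]
  oname <- seg$name[match(cow_out$segment_id, seg$id)]
  rows$pr <- data.frame(
    name = paste0("pr.", slug(oname)), kind = "pr",
    target_id = cow_out$segment_id, side = NA_character_,
    lower = cow_out$pr_lo, upper = cow_out$pr_hi, unit = "mmHg.s/mL"
  )
  rows$sc <- data.frame(
    name = "pr_scale", kind = "pr_scale", target_id = NA_integer_,
    side = NA_character_, lower = 0.5, upper = 2.0, unit = "-"
  )
  rows$age <- data.frame(
    name = "age", kind = "age", target_id = NA_integer_,
    side = NA_character_,
    lower = min(net$age_table$age), upper = max(net$age_table$age),
    unit = "years"
  )
  hosts <- net$stenosis_hosts
  sten <- do.call(rbind, lapply(seq_len(nrow(hosts)), function(i) {
    h <- hosts[i, ]
    ## the Dn slot also carries the host diameter on intact sides, so its
    ## declared interval spans both the stenosis range and the host range
    d_lo_host <- seg$d_lo[seg$id == h$host_segment_id]
    d_hi_host <- seg$d_hi[seg$id == h$host_segment_id]
    data.frame(
      name = paste0("sten_", h$side, ".", c("Rv", "Dn", "SR")),
      kind = c("sten_rv", "sten_dn", "sten_sr"),
      target_id = h$host_segment_id, side = h$side,
      lower = c(0, min(h$dn_lo, d_lo_host), 0),
      upper = c(500, max(h$dn_hi, d_hi_host), 0.99),
      unit = c("mmHg.s/mL", "mm", "-")
    )
  }))
  kt <- do.call(rbind, lapply(seq_len(nrow(hosts)), function(i) {
    h <- hosts[i, ]
    data.frame(
      name = paste0("kt_", h$side), kind = "sten_kt",
      target_id = h$host_segment_id, side = h$side,
      lower = 1.0, upper = 2.699, unit = "-"
    )
  }))
  out <- rbind(rows$d, rows$l, rows$pr, rows$sc, rows$age, sten, kt)
  rownames(out) <- NULL
  out
}

#' Current input vector of a network
#'
#' Reads the manifest slots off a network; the inverse of
#' [apply_input_vector()] for in-range networks.  Absent stenoses read as
#' the intact convention (Rv = 0, SR = 0, Kt = 0, Dn = host diameter).
#'
#' @param net a `vascular_network`
#' @return named numeric vector in manifest order
#' @export
network_input_vector <- function(net) {
  man <- input_manifest(net)
  seg <- net$segments
  pr <- outlet_pr(net)
  sten_for <- function(id) {
    for (s in net$stenoses) if (s$host_segment_id == id) return(s)
    NULL
  }
  x <- vapply(seq_len(nrow(man)), function(i) {
    m <- man[i, ]
    switch(m$kind,
      diameter = seg$diameter_mm[seg$id == m$target_id],
      length = seg$length_mm[seg$id == m$target_id],
      pr = unname(pr[as.character(m$target_id)]),
      pr_scale = {
        non_cow <- !net$outlets$is_cow_outlet
        mean((net$outlets$R1 + net$outlets$R2)[non_cow] /
               net$outlets$PR_base[non_cow])
      },
      age = net$age,
      sten_rv = { s <- sten_for(m$target_id); if (is.null(s)) 0 else s$Rv },
      sten_dn = {
        s <- sten_for(m$target_id)
        if (is.null(s)) seg$diameter_mm[seg$id == m$target_id] else s$Dn
      },
      sten_sr = { s <- sten_for(m$target_id); if (is.null(s)) 0 else s$SR },
      sten_kt = { s <- sten_for(m$target_id); if (is.null(s)) 0 else s$Kt },
      stop("unknown manifest kind ", m$kind)
    )
  }, numeric(1))
  stats::setNames(x, man$name)
}

#' Apply an input vector to a network
#'
#' Overwrites the flagged carotid/cerebral diameters and lengths, sets
#' the CoW outlet PRs (split into proximal/distal parts by the network's
#' fixed `pr_split` fraction), multiplies all non-CoW outlet PRs by the
#' total-PR scaling factor *relative to their initial values*, installs
#' stenosis interfaces on the host arteries, and re-applies the aortic
#' age adjustment.  Wall stiffness is re-derived from the new radii
#' through the network's Eh(r) law.  Returns a new network; the input is
#' unchanged.  Applying the same vector twice equals applying it once.
#'
#' @param net a `vascular_network`
#' @param x named numeric vector matching `input_manifest(net)$name`
#' @return modified `vascular_network`
#' @export
apply_input_vector <- function(net, x) {
  man <- input_manifest(net)
  if (is.null(names(x)) || !identical(sort(names(x)), sort(man$name))) {
    stop("layout error: input vector names do not match the network's ",
         "input manifest", call. = FALSE)
  }
  x <- x[man$name]
  seg <- net$segments
  for (i in which(man$kind == "diameter")) {
    seg$d_base_mm[seg$id == man$target_id[i]] <- x[[i]]
  }
  for (i in which(man$kind == "length")) {
    seg$length_mm[seg$id == man$target_id[i]] <- x[[i]]
  }
  net$age <- x[["age"]]
  net$segments <- finalize_segments(seg, net$eh_law, net$age_table, net$age,
                                    net$target_dx_mm)
  ## outlet resistances
  ids <- man$target_id[man$kind == "pr"]
  net <- set_outlet_pr(net, ids, unname(x[man$kind == "pr"]))
  sf <- x[["pr_scale"]]
  non_cow <- !net$outlets$is_cow_outlet
  net$outlets$R1[non_cow] <- net$pr_split * net$outlets$PR_base[non_cow] * sf
  net$outlets$R2[non_cow] <- (1 - net$pr_split) *
    net$outlets$PR_base[non_cow] * sf
  ## stenoses: intact hosts (Rv = SR = Kt = 0) carry no interface
  sten <- list()
  for (j in seq_len(nrow(net$stenosis_hosts))) {
    h <- net$stenosis_hosts[j, ]
    side <- h$side
    rv <- x[[paste0("sten_", side, ".Rv")]]
    dn <- x[[paste0("sten_", side, ".Dn")]]
    sr <- x[[paste0("sten_", side, ".SR")]]
    kt <- x[[paste0("kt_", side)]]
    if (rv > 0 || sr > 0 || kt > 0) {
      sten[[length(sten) + 1]] <-
        stenosis_spec(h$host_segment_id, Rv = rv, Dn = dn, SR = sr, Kt = kt)
    }
  }
  net$stenoses <- sten
  validate_network(net)
  net
}
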