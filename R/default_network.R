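#' Default systemic arterial networks
#'
#' [build_default_network()] assembles an 83-segment systemic arterial
#' tree including the 22 carotid/cerebral segments that form the circle
#' of Willis (CoW): 3 inlets (the two internal carotids and the basilar
#' artery) redistribute flow to 6 outlets (left/right anterior, middle
#' and posterior cerebral arteries) through the anterior and posterior
#' communicating arteries.  Geometry, Windkessel, 0D-block and heart
#' parameters are literature-informed defaults built in code; they are
#' not a bit-for-bit copy of any published table.
#'
#' [build_toy_network()] is a 5-segment reduced network with the same
#' structure (one bifurcating tree, one stenosis host, Windkessel
#' outlets, closed 0D loop) used for fast experimentation and testing.
#'
#' @name default_networks
NULL

## canonical Table-like ordering of the 22 carotid/cerebral arteries
COW_SEGMENT_NAMES <- c(
  "R. com. carotid", "L. com. carotid",
  "R. int. carotid I", "L. int. carotid I",
  "R. int. carotid II", "L. int. carotid II",
  "R. vertebral", "L. vertebral", "Basilar",
  "R. ant. cerebral I", "L. ant. cerebral I",
  "R. ant. cerebral II", "L. ant. cerebral II",
  "R. mid. cerebral", "L. mid. cerebral",
  "R. post. cerebral I", "L. post. cerebral I",
  "R. post. cerebral II", "L. post. cerebral II",
  "Ant. comm.", "R. post. comm.", "L. post. comm."
)

#' @keywords internal
finalize_segments <- function(seg, eh_law, age_table, age,
                              target_dx_mm = 2.5) {
  sc <- age_scales(age, age_table)
  seg$diameter_mm <- ifelse(seg$is_aortic, seg$d_base_mm * sc$d, seg$d_base_mm)
  eh <- eh_from_radius(seg$diameter_mm / 2, eh_law)
  eh <- ifelse(seg$is_aortic, eh * sc$eh, eh)
  seg$Eh <- ifelse(is.na(seg$eh_override), eh, seg$eh_override)
  seg$A0_mm2 <- pi * (seg$diameter_mm / 2)^2
  seg$n_nodes <- vapply(seg$length_mm, segment_n_nodes, integer(1),
                        target_dx_mm = target_dx_mm)
  seg$P0_mmHg <- P0_MMHG
  seg$sigma <- WALL_SIGMA
  seg
}

#' @keywords internal
default_heart <- function(root_segment_id) {
  list(
    root_segment_id = as.integer(root_segment_id),
    Emax = 2.5,      # mmHg/mL
    Emin = 0.08,     # mmHg/mL
    V0 = 10,         # mL
    Tvc = 0.30,      # s, contraction time
    Tvr = 0.15,      # s, relaxation time
    Tc = CARDIAC_PERIOD,
    R_av = 0.02,     # mmHg s/mL, aortic valve
    R_mv = 0.01,     # mmHg s/mL, mitral valve
    C_at = 15,       # mL/mmHg, passive atrium
    P_at0 = 8,       # mmHg, initial atrial pressure
    V_lv0 = 130      # mL, initial ventricular volume
  )
}

#' Build the default 83-segment systemic network
#'
#' @param age patient age in years (25-90); aortic stiffness and diameter
#'   are adjusted by the piecewise-linear age mapping stored in the
#'   network, all other segments are age-independent
#' @param target_dx_mm nominal spatial resolution used to assign odd
#'   per-segment node counts
#' @return a `vascular_network` with 83 segments, 22 flagged
#'   cerebral/carotid segments, 6 CoW outlets and 3 CoW inlets
#' @export
build_default_network <- function(age = 45, target_dx_mm = 2.5) {
  S <- function(id, name, d, len, aortic = FALSE)
    data.frame(id = id, name = name, d_base_mm = d, length_mm = len,
               is_aortic = aortic, stringsAsFactors = FALSE)
  sys <- rbind(
    S(1, "Ascending aorta", 28, 40, TRUE),
    S(2, "Aortic arch A", 24, 20, TRUE),
    S(3, "Aortic arch B", 22, 39, TRUE),
    S(4, "Thoracic aorta A", 20, 52, TRUE),
    S(5, "Thoracic aorta B", 17, 104, TRUE),
    S(6, "Abdominal aorta A", 15, 53, TRUE),
    S(7, "Abdominal aorta B", 13, 20, TRUE),
    S(8, "Abdominal aorta C", 12, 20, TRUE),
    S(9, "Abdominal aorta D", 11, 53, TRUE),
    S(10, "Abdominal aorta E", 10.5, 40, TRUE),
    S(11, "Brachiocephalic", 12.5, 34),
    S(12, "R. coronary", 4, 100),
    S(13, "L. coronary", 4, 100),
    S(14, "R. ext. carotid", 4.5, 110),
    S(15, "L. ext. carotid", 4.5, 110),
    S(16, "R. subclavian A", 8.5, 34),
    S(17, "L. subclavian A", 8.5, 34),
    S(18, "R. subclavian B", 8, 68),
    S(19, "L. subclavian B", 8, 68),
    S(20, "R. int. thoracic", 3, 150),
    S(21, "L. int. thoracic", 3, 150),
    S(22, "R. brachial", 6, 220),
    S(23, "L. brachial", 6, 220),
    S(24, "R. radial", 3, 230),
    S(25, "L. radial", 3, 230),
    S(26, "R. ulnar", 3.5, 230),
    S(27, "L. ulnar", 3.5, 230),
    S(28, "R. interosseous", 2, 80),
    S(29, "L. interosseous", 2, 80),
    S(30, "Intercostal", 3.5, 80),
    S(31, "Celiac A", 7.8, 20),
    S(32, "Celiac B", 7, 20),
    S(33, "Gastric", 3, 70),
    S(34, "Hepatic", 4.5, 65),
    S(35, "Splenic", 4.5, 60),
    S(36, "Gastroduodenal", 3, 50),
    S(37, "Sup. mesenteric", 7, 60),
    S(38, "R. suprarenal", 2.5, 30),
    S(39, "L. suprarenal", 2.5, 30),
    S(40, "R. renal", 5.5, 30),
    S(41, "L. renal", 5.5, 30),
    S(42, "Inf. mesenteric", 4, 50),
    S(43, "Median sacral", 2, 50),
    S(44, "R. com. iliac", 8, 58),
    S(45, "L. com. iliac", 8, 58),
    S(46, "R. ext. iliac", 6.5, 83),
    S(47, "L. ext. iliac", 6.5, 83),
    S(48, "R. int. iliac", 4.5, 50),
    S(49, "L. int. iliac", 4.5, 50),
    S(50, "R. deep femoral", 4.5, 125),
    S(51, "L. deep femoral", 4.5, 125),
    S(52, "R. femoral", 6, 120),
    S(53, "L. femoral", 6, 120),
    S(54, "R. popliteal", 5, 190),
    S(55, "L. popliteal", 5, 190),
    S(56, "R. ant. tibial", 3, 250),
    S(57, "L. ant. tibial", 3, 250),
    S(58, "R. post. tibial", 3.5, 300),
    S(59, "L. post. tibial", 3.5, 300),
    S(60, "R. peroneal", 3, 80),
    S(61, "L. peroneal", 3, 80)
  )
  cow_d <- c(7.0, 7.0, 5.0, 5.0, 4.0, 4.0, 3.5, 3.5, 3.2, 2.5, 2.5, 2.4,
             2.4, 3.0, 3.0, 2.2, 2.2, 2.1, 2.1, 1.5, 1.5, 1.5)
  cow_l <- c(150, 180, 160, 160, 6, 6, 200, 200, 25, 15, 15, 25, 25, 30,
             30, 10, 10, 25, 25, 4, 15, 15)
  cow <- data.frame(id = 62:83, name = COW_SEGMENT_NAMES, d_base_mm = cow_d,
                    length_mm = cow_l, is_aortic = FALSE,
                    stringsAsFactors = FALSE)
  seg <- rbind(sys, cow)
  seg$is_cow <- seg$id >= 62
  seg$eh_override <- NA_real_
  ## sampling intervals for the 22 carotid/cerebral diameters and lengths
  seg$d_lo <- NA_real_; seg$d_hi <- NA_real_
  seg$l_lo <- NA_real_; seg$l_hi <- NA_real_
  seg$d_lo[62:83] <- c(3.9, 3.9, 2.3, 2.3, 1.9, 1.9, 1.4, 1.4, 1.6, 0.1,
                       0.1, 1.2, 1.2, 1.4, 1.4, 0.1, 0.1, 1.1, 1.1, 0.1,
                       0.1, 0.1)
  seg$d_hi[62:83] <- c(11.6, 11.6, 6.8, 6.8, 6.0, 6.0, 4.9, 4.9, 4.9, 3.6,
                       3.6, 3.6, 3.6, 4.3, 4.3, 3.2, 3.2, 3.2, 3.2, 2.6,
                       2.7, 2.7)
  seg$l_lo[62:83] <- c(78, 109, 120, 120, 2, 2, 113, 113, 15, 7, 7, 6, 6,
                       10, 10, 2, 2, 2, 2, 2, 4, 4)
  seg$l_hi[62:83] <- c(222, 252, 195, 195, 12, 12, 276, 276, 36, 31, 31,
                       45, 45, 51, 51, 23, 23, 54, 54, 7, 27, 27)

  J <- function(ids, ends) list(segments = as.integer(ids), ends = ends)
  junctions <- list(
    J(c(1, 11, 2, 12, 13), c("end", "start", "start", "start", "start")),
    J(c(2, 63, 3), c("end", "start", "start")),
    J(c(3, 17, 4), c("end", "start", "start")),
    J(c(11, 62, 16), c("end", "start", "start")),
    J(c(62, 64, 14), c("end", "start", "start")),
    J(c(63, 65, 15), c("end", "start", "start")),
    J(c(64, 66), c("end", "start")),
    J(c(65, 67), c("end", "start")),
    J(c(66, 75, 71, 82), c("end", "start", "start", "start")),
    J(c(67, 76, 72, 83), c("end", "start", "start", "start")),
    J(c(71, 73, 81), c("end", "start", "start")),
    J(c(72, 81, 74), c("end", "end", "start")),
    J(c(16, 68, 20, 18), c("end", "start", "start", "start")),
    J(c(17, 69, 21, 19), c("end", "start", "start", "start")),
    J(c(68, 69, 70), c("end", "end", "start")),
    J(c(70, 77, 78), c("end", "start", "start")),
    J(c(77, 82, 79), c("end", "end", "start")),
    J(c(78, 83, 80), c("end", "end", "start")),
    J(c(18, 22), c("end", "start")),
    J(c(19, 23), c("end", "start")),
    J(c(22, 24, 26, 28), c("end", "start", "start", "start")),
    J(c(23, 25, 27, 29), c("end", "start", "start", "start")),
    J(c(4, 30, 5), c("end", "start", "start")),
    J(c(5, 6), c("end", "start")),
    J(c(6, 31, 7), c("end", "start", "start")),
    J(c(31, 33, 32), c("end", "start", "start")),
    J(c(32, 34, 35, 36), c("end", "start", "start", "start")),
    J(c(7, 37, 38, 39, 8), c("end", "start", "start", "start", "start")),
    J(c(8, 40, 41, 9), c("end", "start", "start", "start")),
    J(c(9, 42, 10), c("end", "start", "start")),
    J(c(10, 44, 45, 43), c("end", "start", "start", "start")),
    J(c(44, 46, 48), c("end", "start", "start")),
    J(c(45, 47, 49), c("end", "start", "start")),
    J(c(46, 52, 50), c("end", "start", "start")),
    J(c(47, 53, 51), c("end", "start", "start")),
    J(c(52, 54), c("end", "start")),
    J(c(53, 55), c("end", "start")),
    J(c(54, 56, 58, 60), c("end", "start", "start", "start")),
    J(c(55, 57, 59, 61), c("end", "start", "start", "start"))
  )

  ## outlet targets: nominal mean flow (mL/min) and body-block assignment
  O <- function(id, q, blk) data.frame(segment_id = id, q_nominal = q,
                                       block = blk)
  out <- rbind(
    O(12, 100, 1), O(13, 100, 1), O(14, 150, 1), O(15, 150, 1),
    O(20, 50, 1), O(21, 50, 1), O(24, 70, 1), O(25, 70, 1),
    O(26, 80, 1), O(27, 80, 1), O(28, 20, 1), O(29, 20, 1),
    O(30, 100, 2),
    O(33, 100, 2), O(34, 350, 2), O(35, 300, 2), O(36, 80, 2),
    O(37, 500, 2), O(38, 30, 2), O(39, 30, 2), O(40, 550, 2),
    O(41, 550, 2), O(42, 100, 2), O(43, 20, 2),
    O(48, 150, 2), O(49, 150, 2), O(50, 150, 2), O(51, 150, 2),
    O(56, 60, 2), O(57, 60, 2), O(58, 80, 2), O(59, 80, 2),
    O(60, 50, 2), O(61, 50, 2),
    ## circle of Willis outlets
    O(73, 95, 1), O(74, 95, 1), O(75, 120, 1), O(76, 120, 1),
    O(79, 70, 1), O(80, 70, 1)
  )
  map_mmHg <- 93
  p_ven <- 5
  pr <- (map_mmHg - p_ven) / (out$q_nominal / 60)  # mmHg s/mL
  ctot <- 1.0                                      # mL/mmHg peripheral
  pr_split <- 0.2
  outlets <- data.frame(
    segment_id = out$segment_id,
    R1 = pr_split * pr,
    R2 = (1 - pr_split) * pr,
    C = ctot * out$q_nominal / sum(out$q_nominal),
    PR_base = pr,
    is_cow_outlet = out$segment_id %in% c(73, 74, 75, 76, 79, 80),
    body_block = out$block,
    pr_lo = NA_real_, pr_hi = NA_real_
  )
  ## sampling intervals for the six CoW outlet PRs; the open lower end of
  ## the interval is implemented as 1 mmHg s/mL
  cow_pr_bounds <- c(`73` = 200, `74` = 200, `75` = 100, `76` = 100,
                     `79` = 250, `80` = 250)
  i <- match(as.integer(names(cow_pr_bounds)), outlets$segment_id)
  outlets$pr_lo[i] <- 1
  outlets$pr_hi[i] <- unname(cow_pr_bounds)

  body_blocks <- data.frame(
    name = c("upper", "lower"),
    R = c(0.12, 0.06),    # mmHg s/mL
    L = c(5e-4, 5e-4),    # mmHg s^2/mL
    C = c(30, 60),        # mL/mmHg
    P_init = c(13, 13)    # mmHg (sets closed-loop volume, hence preload)
  )

  seg <- finalize_segments(seg, default_eh_law(), default_age_table(), age,
                           target_dx_mm)
  vascular_network(
    segments = seg, junctions = junctions, outlets = outlets,
    body_blocks = body_blocks, heart = default_heart(1),
    stenoses = list(),
    cow_inlet_ids = c(64, 65, 70),
    cow_outlet_ids = c(73, 74, 75, 76, 79, 80),
    cow_segment_ids = 62:83,
    map_segment_id = 17, age = age,
    name = "adult-83 (literature defaults)",
    stenosis_hosts = data.frame(
      host_segment_id = c(65L, 64L), side = c("L", "R"),
      dn_lo = 2.9, dn_hi = 7.0
    ),
    target_dx_mm = target_dx_mm
  )
}

#' Build the 5-segment toy network
#'
#' A reduced network for fast tests and desk-scale surrogate training:
#' a root artery bifurcates into a systemic branch (Windkessel outlet,
#' driven by the total-PR scaling factor) and a "carotid-like" branch
#' hosting the stenosis interface, which bifurcates into two
#' "cerebral-like" outlet arteries whose peripheral resistances play the
#' role of the CoW outlet PRs.
#'
#' @param age years (kept for interface symmetry; the toy network has no
#'   aortic segments so age has no hemodynamic effect)
#' @param target_dx_mm nominal grid spacing, mm
#' @return a `vascular_network` with 5 segments and 3 outlets
#' @export
build_toy_network <- function(age = 45, target_dx_mm = 5) {
  seg <- data.frame(
    id = 1:5,
    name = c("Root", "Carotid-like", "Systemic branch",
             "Cerebral A", "Cerebral B"),
    d_base_mm = c(12, 6, 7, 4, 4),
    length_mm = c(60, 50, 50, 40, 40),
    is_aortic = FALSE,
    is_cow = TRUE,
    eh_override = NA_real_,
    stringsAsFactors = FALSE
  )
  seg$d_lo <- c(8, 3, 4, 2, 2)
  seg$d_hi <- c(16, 9, 10, 6, 6)
  seg$l_lo <- round(0.6 * seg$length_mm)
  seg$l_hi <- round(1.4 * seg$length_mm)
  junctions <- list(
    list(segments = c(1L, 2L, 3L), ends = c("end", "start", "start")),
    list(segments = c(2L, 4L, 5L), ends = c("end", "start", "start"))
  )
  pr <- c(4, 8, 8)    # outlet PRs for segments 3, 4, 5 (mmHg s/mL)
  pr_split <- 0.2
  outlets <- data.frame(
    segment_id = c(3L, 4L, 5L),
    R1 = pr_split * pr, R2 = (1 - pr_split) * pr,
    C = c(0.5, 0.15, 0.15),
    PR_base = pr,
    is_cow_outlet = c(FALSE, TRUE, TRUE),
    body_block = c(1L, 1L, 1L),
    pr_lo = c(NA, 2, 2), pr_hi = c(NA, 30, 30)
  )
  body_blocks <- data.frame(name = "body", R = 0.08, L = 5e-4, C = 40,
                            P_init = 9)
  seg <- finalize_segments(seg, default_eh_law(), default_age_table(), age,
                           target_dx_mm)
  vascular_network(
    segments = seg, junctions = junctions, outlets = outlets,
    body_blocks = body_blocks, heart = default_heart(1),
    stenoses = list(),
    cow_inlet_ids = 2L,
    cow_outlet_ids = c(4L, 5L),
    cow_segment_ids = 1:5,
    map_segment_id = 1L, age = age,
    name = "toy-5",
    stenosis_hosts = data.frame(
      host_segment_id = 2L, side = "L", dn_lo = 2.9, dn_hi = 7.0
    ),
    target_dx_mm = target_dx_mm
  )
}
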