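test_that("default network has the documented structure", {
  net <- build_default_network(45)
  expect_s3_class(net, "vascular_network")
  expect_equal(nrow(net$segments), 83)
  expect_equal(sum(net$segments$is_cow), 22)
  expect_length(net$cow_outlet_ids, 6)
  expect_length(net$cow_inlet_ids, 3)
  expect_equal(sum(net$outlets$is_cow_outlet), 6)
  ## the 22 flagged segments are exactly the named carotid/cerebral set
  flagged <- net$segments$name[net$segments$is_cow]
  expect_setequal(flagged, c(
    "R. com. carotid", "L. com. carotid", "R. int. carotid I",
    "L. int. carotid I", "R. int. carotid II", "L. int. carotid II",
    "R. vertebral", "L. vertebral", "Basilar", "R. ant. cerebral I",
    "L. ant. cerebral I", "R. ant. cerebral II", "L. ant. cerebral II",
    "R. mid. cerebral", "L. mid. cerebral", "R. post. cerebral I",
    "L. post. cerebral I", "R. post. cerebral II", "L. post. cerebral II",
    "Ant. comm.", "R. post. comm.", "L. post. comm."))
  ## PR is the sum of the two Windkessel resistances
  expect_equal(unname(outlet_pr(net)), net$outlets$R1 + net$outlets$R2)
  ## odd node counts and consistent reference areas
  expect_true(all(net$segments$n_nodes %% 2 == 1))
  expect_true(all(net$segments$n_nodes >= 3))
  expect_equal(net$segments$A0_mm2,
               pi * (net$segments$diameter_mm / 2)^2, tolerance = 1e-12)
})

test_that("the shipped default config loads the full network", {
  path <- system.file("extdata", "adult_83.json", package = "cowsim")
  expect_true(nzchar(path))
  net <- read_network_config(path)
  expect_equal(nrow(net$segments), 83)
  expect_equal(sum(net$outlets$is_cow_outlet), 6)
  expect_equal(net$segments$diameter_mm,
               build_default_network(45)$segments$diameter_mm)
  ## a re-read config supports the full input-vector machinery
  expect_equal(nrow(input_manifest(net)), 60)
  toy <- read_network_config(system.file("extdata", "toy_5.json",
                                         package = "cowsim"))
  expect_equal(nrow(toy$segments), 5)
  expect_identical(network_input_vector(toy),
                   network_input_vector(build_toy_network()))
})

test_that("config files round-trip bit-identically", {
  net <- build_default_network(60)
  net$stenoses <- list(stenosis_spec(64L, Rv = 11.3, Dn = 4.8, SR = 0.83,
                                     Kt = 1.52))
  path <- tempfile(fileext = ".json")
  write_network_config(net, path)
  net2 <- read_network_config(path)
  expect_identical(net2$segments$diameter_mm, net$segments$diameter_mm)
  expect_identical(net2$segments$Eh, net$segments$Eh)
  expect_identical(net2$outlets$R1, net$outlets$R1)
  expect_identical(net2$outlets$R2, net$outlets$R2)
  expect_identical(net2$body_blocks$C, net$body_blocks$C)
  expect_equal(length(net2$stenoses), 1)
  expect_identical(net2$stenoses[[1]]$Rv, 11.3)
  expect_equal(length(net2$junctions), length(net$junctions))
  ## write(read(config)) is content-identical
  path2 <- tempfile(fileext = ".json")
  write_network_config(net2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid configurations are rejected with topology errors", {
  net <- build_default_network(45)
  bad <- net
  bad$junctions[[1]]$segments[2] <- 999L
  expect_error(validate_network(bad), "topology error")
  bad2 <- net
  bad2$segments$diameter_mm[5] <- -1
  expect_error(validate_network(bad2), "configuration error")
  expect_error(read_network_config(tempfile()), "no such file")
})

test_that("aortic age adjustment is monotone and local", {
  n25 <- build_default_network(25)
  n90 <- build_default_network(90)
  aort <- n25$segments$is_aortic
  ## stiffness non-decreasing with age on every aortic segment
  expect_true(all(n90$segments$Eh[aort] >= n25$segments$Eh[aort]))
  expect_true(all(n90$segments$diameter_mm[aort] >
                    n25$segments$diameter_mm[aort]))
  ## non-aortic segments identical
  expect_identical(n25$segments$Eh[!aort], n90$segments$Eh[!aort])
  expect_identical(n25$segments$diameter_mm[!aort],
                   n90$segments$diameter_mm[!aort])
  ## reference age returns the unmodified base values
  nref <- build_default_network(45)
  expect_equal(nref$segments$diameter_mm[aort],
               nref$segments$d_base_mm[aort])
  expect_error(build_default_network(101), "outside")
})

test_that("applying an input vector is exact, local and idempotent", {
  net <- build_default_network(45)
  x <- network_input_vector(net)
  ## identity: applying the current values changes nothing material
  net_id <- apply_input_vector(net, x)
  expect_equal(net_id$segments$diameter_mm, net$segments$diameter_mm)
  expect_equal(outlet_pr(net_id), outlet_pr(net))

  ## scaling factor doubles every non-CoW PR, leaves CoW PRs untouched
  x2 <- x; x2[["pr_scale"]] <- 2
  net2 <- apply_input_vector(net, x2)
  non_cow <- !net$outlets$is_cow_outlet
  expect_equal(outlet_pr(net2)[non_cow], 2 * outlet_pr(net)[non_cow])
  expect_equal(outlet_pr(net2)[!non_cow], outlet_pr(net)[!non_cow])

  ## idempotence
  x3 <- sample_input_vector(net, "left_stenosis")
  a <- apply_input_vector(net, x3)
  b <- apply_input_vector(a, x3)
  expect_equal(a$segments, b$segments)
  expect_equal(a$outlets, b$outlets)
  expect_equal(length(a$stenoses), length(b$stenoses))

  ## PR split preserves the sum with the fixed proximal fraction
  i <- match(net$cow_outlet_ids, net2$outlets$segment_id)
  expect_equal(net2$outlets$R1[i] / (net2$outlets$R1 + net2$outlets$R2)[i],
               rep(net$pr_split, 6))

  ## layout error on wrong names
  xbad <- x; names(xbad)[1] <- "nonsense"
  expect_error(apply_input_vector(net, xbad), "layout error")
})

test_that("intact-side stenosis input produces zero pressure loss", {
  net <- build_toy_network()
  x <- network_input_vector(net)
  expect_equal(x[["sten_L.Rv"]], 0)
  net2 <- apply_input_vector(net, x)
  ## no interface installed, so the loss is identically zero at any flow
  expect_length(net2$stenoses, 0)
  ## an explicitly intact spec evaluates to zero loss except the
  ## (excluded) inertance term
  s <- stenosis_spec(2L, Rv = 0, Dn = 6, SR = 0, Kt = 0, Ls = 0)
  for (q in c(-10, 0, 5, 50) * 1e-6) {
    expect_identical(stenosis_pressure_loss(q, 0, s), 0)
  }
})

test_that("wall stiffness follows the radius law unless overridden", {
  net <- build_toy_network()
  seg <- net$segments
  expect_equal(seg$Eh, eh_from_radius(seg$diameter_mm / 2, net$eh_law))
  x <- network_input_vector(net)
  x[["d.Cerebral_A"]] <- 3
  net2 <- apply_input_vector(net, x)
  i <- which(net2$segments$name == "Cerebral A")
  expect_equal(net2$segments$Eh[i], eh_from_radius(1.5, net$eh_law))
})
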