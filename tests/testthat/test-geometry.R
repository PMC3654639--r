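# Voxel geometry: region presence, conduction-chain topology,
# atrioventricular isolation, determinism, resolution behaviour and volume
# sanity.

heart_label_values <- unname(label_table()[c("SAN", "atria", "AVN", "His",
                                             "BNL", "Purkinje",
                                             "ventricles")])

test_that("default geometry contains the seven heart regions plus passives", {
  f <- build_geometry()
  present <- sort(unique(as.vector(f$lab)))
  expect_true(all(heart_label_values %in% present))
  expect_true(all(label_table()[c("torso", "lungs", "blood")] %in% present))
  # exactly seven heart labels, no more
  expect_equal(sum(present %in% heart_label_values), 7)
  rep <- validate_geometry(f)
  expect_true(rep$all_pass)
})

test_that("tiny fixture geometry passes validation and stays under 24^3", {
  f <- build_geometry(make_fixture("tiny-3d")$geometry)
  expect_true(validate_geometry(f)$all_pass)
  expect_lte(prod(dim(f$lab)), 24^3)
})

test_that("halving dx preserves every region and the topology checks", {
  cfg <- make_fixture("tiny-3d")$geometry
  cfg$dx <- cfg$dx / 2
  f <- build_geometry(cfg)
  rep <- validate_geometry(f)
  expect_true(rep$all_pass)
})

test_that("unresolvable regions at coarse dx are rejected by name", {
  cfg <- make_fixture("tiny-3d")$geometry
  cfg$dx <- cfg$dx * 2
  expect_error(build_geometry(cfg), "not resolvable")
})

test_that("atria and ventricles share no face outside the AV junction", {
  f <- build_geometry(make_fixture("tiny-3d")$geometry)
  prs <- bidecg:::.adjacency_pairs(f$lab, label_table()[["atria"]],
                                   label_table()[["ventricles"]])
  expect_null(prs)
})

test_that("validator reports a broken conduction chain and stray contacts", {
  f <- build_geometry(make_fixture("tiny-3d")$geometry)
  # delete the AVN
  f2 <- f
  f2$lab[f2$lab == label_table()[["AVN"]]] <- label_table()[["atria"]]
  rep <- validate_geometry(f2)
  expect_false(rep$all_pass)
  bad <- rep$checks[!rep$checks$pass, ]
  expect_true(any(grepl("AVN", bad$check)))
  # stray atrial voxel touching the ventricles breaks isolation
  f3 <- f
  vent <- which(f3$lab == label_table()[["ventricles"]], arr.ind = TRUE)
  v <- vent[which.max(vent[, 3]), ]        # basal ventricular voxel
  nb <- v + c(0, 0, 1)                     # voxel above lies in the AV gap
  f3$lab[nb[1], nb[2], nb[3]] <- label_table()[["atria"]]
  rep3 <- validate_geometry(f3)
  iso <- rep3$checks[grepl("isolation", rep3$checks$check), ]
  expect_false(iso$pass)
  expect_match(iso$detail, "voxel")
})

test_that("geometry construction is deterministic", {
  cfg <- make_fixture("tiny-3d")$geometry
  f1 <- build_geometry(cfg)
  f2 <- build_geometry(cfg)
  expect_identical(f1$lab, f2$lab)
  expect_identical(f1$origin, f2$origin)
})

test_that("heart voxel volume matches the analytic sphere within a surface layer", {
  cfg <- make_fixture("tiny-3d")$geometry
  f <- build_geometry(cfg)
  R <- cfg$heart$radius
  hc <- cfg$heart$center
  dx <- cfg$dx
  # heart volume = sphere minus the AV gap slab (labelled passive), His aside
  z_av <- hc[3] + cfg$heart$av_plane_frac * R
  g2 <- cfg$heart$av_gap / 2
  slab <- stats::integrate(function(z) pi * (R^2 - (z - hc[3])^2),
                           z_av - g2, z_av + g2)$value
  vol_analytic <- 4 / 3 * pi * R^3 - slab
  heart_set <- c(label_table()[["blood"]], heart_label_values)
  vol_vox <- sum(f$lab %in% heart_set) * dx^3
  slack <- 1.5 * 4 * pi * R^2 * dx         # one voxel-surface layer
  expect_lt(abs(vol_vox - vol_analytic), slack)
})

test_that("strip geometry contains exactly one heart region", {
  f <- build_geometry(make_fixture("strip-1d")$geometry)
  hl <- unique(f$lab[array(f$lab %in% heart_label_values, dim(f$lab))])
  expect_length(hl, 1)
  expect_true(validate_geometry(f)$all_pass)
})
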