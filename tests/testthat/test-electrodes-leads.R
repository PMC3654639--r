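# Electrode placement and the per-sample lead calculus.

test_that("default layout places 10 standard + 7 Frank electrodes on the surface", {
  f <- build_geometry(make_fixture("tiny-3d")$geometry)
  es <- place_electrodes(f)
  expect_equal(nrow(es), 17)
  expect_setequal(es$name, c("VR", "VL", "VF", "VGND", paste0("V", 1:6),
                             "A", "C", "E", "F", "H", "I", "M"))
  # every electrode voxel is conducting and touches the outside
  outside_adj <- bidecg:::.adjacent_to(f$lab, 0L)
  expect_true(all(f$lab[es$voxel] > 0))
  expect_true(all(outside_adj[es$voxel]))
})

test_that("electrode placement rejects bad fractions and warns on collisions", {
  f <- build_geometry(make_fixture("tiny-3d")$geometry)
  expect_error(place_electrodes(f, list(VR = c(1.5, 0.5, 0.5))), "outside")
  expect_warning(place_electrodes(f, list(e1 = c(0.5, 0.97, 0.5),
                                          e2 = c(0.5, 0.97, 0.5))),
                 "shared node")
})

test_that("Einthoven, augmented, precordial and Frank leads match hand values", {
  n <- 5
  expect_equal(einthoven(rep(2, n), rep(2, n), rep(2, n)),
               data.frame(lead_I = rep(0, n), lead_II = rep(0, n),
                          lead_III = rep(0, n)))
  e <- einthoven(VL = 1, VR = 0, VF = 0)
  expect_equal(unlist(e), c(lead_I = 1, lead_II = 0, lead_III = -1))
  a <- augmented(VL = 0, VR = 1, VF = 0)
  expect_equal(unlist(a), c(aVR = 1, aVL = -0.5, aVF = -0.5))
  p <- precordial(V1 = 2, V2 = 1, V3 = 0, V4 = 0, V5 = 0, V6 = 0,
                  VL = 0, VR = 0, VF = 0)
  expect_equal(p$lead_V1, 2)
  p2 <- precordial(V1 = 0, V2 = 1, V3 = 0, V4 = 0, V5 = 0, V6 = 0,
                   VL = 3, VR = 0, VF = 0)
  expect_equal(p2$lead_V2, 0)                 # 1 - 3/3
  fr <- frank_xyz(A = 1, C = 0, E = 0, F = 0, H = 0, I = 0, M = 0)
  expect_equal(unlist(fr), c(X = 0.610, Y = 0, Z = 0.133))
  fr2 <- frank_xyz(A = 0, C = 0, E = 0, F = 0, H = 0, I = 0, M = 1)
  expect_equal(unlist(fr2), c(X = 0, Y = 0.345, Z = 0.736))
  expect_equal(rms_curve(3, 4, 0), sqrt(25 / 3))
  expect_equal(rms_curve(0, 0, 0), 0)
  expect_error(einthoven(1:3, 1:2, 1:3), "length mismatch")
})

test_that("per-sample lead identities hold to 1e-12 on arbitrary traces", {
  set.seed(42)
  n <- 500
  tr <- as.data.frame(matrix(rnorm(17 * n), n, 17))
  names(tr) <- c("VR", "VL", "VF", "VGND", paste0("V", 1:6),
                 "A", "C", "E", "F", "H", "I", "M")
  tr <- cbind(time_s = seq_len(n) / 1000, tr)
  ld <- derive_leads(tr)
  expect_lt(max(abs(ld$lead_II - ld$lead_I - ld$lead_III)), 1e-12)
  expect_lt(max(abs(ld$aVR + ld$aVL + ld$aVF)), 1e-12)
  # Frank leads reject a common-mode offset on all seven electrodes
  tr2 <- tr
  for (ch in c("A", "C", "E", "F", "H", "I", "M")) tr2[[ch]] <- tr2[[ch]] + 7.5
  ld2 <- derive_leads(tr2)
  for (ch in c("X", "Y", "Z"))
    expect_lt(max(abs(ld2[[ch]] - ld[[ch]])), 1e-10)
  # RMS curves are non-negative, zero only where all inputs vanish
  expect_true(all(ld$VRMS >= 0))
  expect_true(all(ld$VSAECG >= 0))
})

test_that("derive_leads names missing electrode channels", {
  tr <- data.frame(time_s = 1:3 / 1000, VR = 0, VL = 0, VF = 0)
  expect_error(derive_leads(tr), "VGND")
  expect_error(derive_leads(tr), "missing electrode")
})

test_that("lead traces round-trip through CSV with the fixed channel set", {
  set.seed(7)
  n <- 50
  tr <- as.data.frame(matrix(rnorm(17 * n), n, 17))
  names(tr) <- c("VR", "VL", "VF", "VGND", paste0("V", 1:6),
                 "A", "C", "E", "F", "H", "I", "M")
  tr <- cbind(time_s = seq_len(n) / 1000, tr)
  ld <- derive_leads(tr)
  expect_equal(names(ld), bidecg:::.channel_order)
  fp <- tempfile(fileext = ".csv")
  write_lead_traces(ld, fp)
  back <- read_lead_traces(fp, require = c("lead_II", "X"))
  expect_equal(back$lead_II, ld$lead_II, tolerance = 1e-12)
  expect_error(read_lead_traces(fp, require = "nonexistent"), "missing channel")
  unlink(fp)
})
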