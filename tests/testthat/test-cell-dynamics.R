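# Membrane kinetics: parameter registry, ionic current, recovery rate and
# the cubic root structure.

test_that("region registry returns the tabulated parameter sets", {
  san <- region_defaults("SAN")
  expect_equal(san$a, -0.60)
  expect_equal(san$b, -0.30)
  expect_equal(san$e, 0.0660)
  expect_equal(san$A, 33)
  expect_equal(san$B, -22)
  expect_equal(san$c1, 1000)
  expect_equal(san$sigma_e, 0.5)
  expect_equal(san$sigma_i, 0.5)

  v <- region_defaults("Ventricles")
  expect_equal(v$a, 0.13)
  expect_equal(v$b, 0)
  expect_equal(v$e, 0.0060)
  expect_equal(v$A, 140)
  expect_equal(v$B, -85)
  expect_equal(v$k, 1000)
  expect_equal(v$c1, 2.6)
  expect_equal(v$sigma_e, 8)

  expect_equal(region_defaults("Purkinje")$sigma_i, 35)
  expect_equal(region_defaults("BNL")$e, 0.0022)
  expect_error(region_defaults("Liver"), "valid regions")
  expect_error(region_defaults("Liver"), "SAN")  # message lists valid names
})

test_that("initial states follow the tabulated values", {
  s <- initial_state("SAN")
  expect_equal(s$Vi_mV, -60)
  expect_equal(s$Ve_mV, 0)
  expect_equal(s$u, 0)
  expect_equal(s$Vm_mV, s$Vi_mV - s$Ve_mV)
  for (r in region_names()[-1]) {
    s <- initial_state(r)
    expect_equal(s$Vi_mV, -85)
    expect_equal(s$Vm_mV, -85)
  }
  expect_error(initial_state("Liver"), "unknown region")
})

test_that("ionic current matches direct evaluation of the kinetics", {
  v <- region_defaults("Ventricles")
  expect_equal(iion(-85, 0, v), 0)            # cubic vanishes at Vm = B
  expect_equal(iion(55, 0, v), 0)             # (1 - v) factor vanishes
  expect_equal(iion(-15, 0, v),
               1000 * 2.6 * 0.070 * (0.13 - 0.5) * (1 - 0.5))
  san <- region_defaults("SAN")
  expect_equal(iion(-22, 1, san), 1000 * 1.0)  # cubic zero, k c2 u remains
  # non-SAN recovery current scales with (Vm - B)
  expect_equal(iion(-85, 1, v), 0)
  expect_equal(iion(-15, 2, v) - iion(-15, 0, v), 1000 * 1.0 * 2 * 0.070)
})

test_that("recovery rate matches the tabulated form", {
  v <- region_defaults("Ventricles")
  expect_equal(du_dt(-85, 0, v), 0)
  expect_equal(du_dt(-85 + 140, 0, v), 1000 * 0.0060)
  san <- region_defaults("SAN")
  # b = -0.30 means the SAN rest state is not an equilibrium
  expect_equal(du_dt(-22, 0, san), 1000 * 0.0660 * 0.30)
  expect_gt(abs(du_dt(san$B, 0, san)), 0)
})

test_that("cubic roots sit at B, B + aA, B + A and satisfy iion = 0", {
  v <- region_defaults("Ventricles")
  rv <- cubic_roots(v)
  expect_equal(rv, c(-85, -66.8, 55), tolerance = 1e-9)
  expect_equal(max(rv) - min(rv), v$A, tolerance = 1e-9)
  san <- region_defaults("SAN")
  rs <- cubic_roots(san)
  expect_equal(rs, c(-41.8, -22, 11), tolerance = 1e-9)
  for (r in c(rv, rs)) {
    p <- if (r %in% rv) v else san
    expect_lt(abs(iion(r, 0, p)), 1e-9)
  }
  expect_error(cubic_roots(region_defaults("SAN", override = list(c1 = 0))),
               "no cubic")
})

test_that("non-SAN rest state is an exact fixed point of the kinetics", {
  for (r in region_names()[-1]) {
    p <- region_defaults(r)
    expect_identical(iion(p$B, 0, p), 0)
    expect_identical(du_dt(p$B, 0, p), 0)
  }
})
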