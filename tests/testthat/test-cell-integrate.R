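# Single-cell integration: rest stability, spontaneous sinoatrial
# oscillation, stimulated action potentials, convergence and the role of
# the rate-scale parameter e.

cycle_peaks <- function(tr) {
  vm <- tr$Vm_mV
  pk <- which(diff(sign(diff(vm))) == -2) + 1L
  pk[vm[pk] > (min(vm) + 0.7 * (max(vm) - min(vm)))]
}

test_that("unstimulated ventricular cell stays at rest for 2 s", {
  tr <- integrate_cell(region_defaults("Ventricles"), duration = 2)
  expect_lt(max(abs(tr$Vm_mV + 85)), 1e-9)
  expect_lt(max(abs(tr$u)), 1e-9)
})

test_that("SAN cell oscillates spontaneously, stably and periodically", {
  tr <- integrate_cell(region_defaults("SAN"), duration = 2)
  pk <- cycle_peaks(tr)
  expect_gte(length(pk), 2)
  cyc <- diff(tr$time_s[pk])
  if (length(cyc) >= 2)
    expect_lt(max(abs(diff(cyc))) / mean(cyc), 0.02)  # cycle lengths agree
  amps <- tr$Vm_mV[pk]
  if (length(amps) >= 2)  # amplitude not decaying beyond 2 % per cycle
    expect_gt(min(diff(amps) / amps[-length(amps)]), -0.02)
})

test_that("suprathreshold pulse elicits a full-amplitude action potential", {
  p <- region_defaults("Ventricles")
  tr <- integrate_cell(p, duration = 1, stimulus = default_stimulus(p))
  exc <- max(tr$Vm_mV) - tr$Vm_mV[1]
  expect_gt(exc, 0.8 * p$A)
  expect_lt(exc, 1.2 * p$A)
  # independent stiff-solver oracle agrees to 3 significant figures;
  # integrate the stimulus segments separately so the adaptive solver sees
  # no hidden discontinuity
  st <- default_stimulus(p)
  rhs <- function(t, y, parms) {
    list(c(-iion(y[1] * 1000, y[2], p) + parms,
           du_dt(y[1] * 1000, y[2], p)))
  }
  seg <- function(y0, times, stim)
    deSolve::lsoda(y0, times, rhs, stim, rtol = 1e-10, atol = 1e-12)
  t1s <- seq(0, st$t_on, by = 1e-3)
  s1 <- seg(c(vm = -0.085, u = 0), t1s, 0)
  s2 <- seg(s1[nrow(s1), -1], c(st$t_on, st$t_on + st$duration),
            st$amplitude)
  t3s <- seq(st$t_on + st$duration, 1, by = 1e-3)
  s3 <- seg(s2[nrow(s2), -1], t3s, 0)
  ref_vm <- c(s1[-nrow(s1), "vm"], s3[, "vm"]) * 1000
  ref_t <- c(t1s[-length(t1s)], t3s)
  rk_vm <- tr$Vm_mV[match(round(ref_t, 6), round(tr$time_s, 6))]
  expect_lt(max(abs(ref_vm - rk_vm)), 0.2)   # sup norm over 140 mV excursion
})

test_that("halving dt changes the ventricular AP by under 0.5 mV", {
  p <- region_defaults("Ventricles")
  st <- default_stimulus(p)
  t1 <- integrate_cell(p, duration = 0.6, dt = 2e-4, stimulus = st)
  t2 <- integrate_cell(p, duration = 0.6, dt = 1e-4, stimulus = st)
  expect_lt(max(abs(t1$Vm_mV - t2$Vm_mV[seq(1, nrow(t2), by = 2)])), 0.5)
})

test_that("action potential duration decreases monotonically in e", {
  es <- c(0.0022, 0.0047, 0.0060, 0.0132)
  apds <- vapply(es, function(e) {
    p <- region_defaults("Ventricles", override = list(e = e))
    apd(integrate_cell(p, duration = 1.5, stimulus = default_stimulus(p)))
  }, numeric(1))
  expect_false(anyNA(apds))
  expect_true(all(diff(apds) < 0))
})

test_that("cell traces round-trip through CSV", {
  tr <- integrate_cell(region_defaults("Atria"), duration = 0.05)
  f <- tempfile(fileext = ".csv")
  write_cell_trace(tr, f)
  back <- read.csv(f)
  expect_equal(names(back), c("time_s", "Vm_mV", "u"))
  expect_equal(back$Vm_mV, tr$Vm_mV, tolerance = 1e-12)
  unlink(f)
})
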