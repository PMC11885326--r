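# Waveform scaling, Murray split, 0-D network dynamics, RCR tuning and
# Reynolds numbers.

test_that("waveform scaling hits the target mean and is idempotent", {
  w <- steady_waveform(q = 83.3)
  ws <- scale_waveform(w, 5)
  expect_equal(waveform_mean(ws), 5000 / 60, tolerance = 1e-10)
  # factor for a mean-83.3 waveform to 5 L/min is ~1.0004
  expect_equal(ws$flow[1] / w$flow[1], (5000 / 60) / 83.3,
               tolerance = 1e-12)
  expect_equal(scale_waveform(ws, 5)$flow, ws$flow, tolerance = 1e-12)

  wc <- scale_waveform(steady_waveform(q = 1), 6)
  expect_true(all(abs(wc$flow - 100) < 1e-9))

  w0 <- inflow_waveform(seq(0, 1, length.out = 101),
                        sin(2 * pi * seq(0, 1, length.out = 101)))
  expect_error(scale_waveform(w0, 5), "zero-mean")
})

test_that("Murray split follows d^k / sum d^k", {
  expect_equal(murray_split(c(1, 1)), c(0.5, 0.5))
  expect_equal(murray_split(c(1, 1, sqrt(2))), c(0.25, 0.25, 0.5),
               tolerance = 1e-12)
  expect_equal(murray_split(2.3), 1.0)
  expect_equal(sum(murray_split(c(0.9, 1.4, 2.2, 0.4))), 1, tolerance = 1e-14)
  expect_error(murray_split(numeric()), "at least one")
})

test_that("steady network pressure equals Q*(Rp+Rd) within 0.1%", {
  w <- steady_waveform(q = 80)
  sim <- simulate_network(w, list(list(diameter = 2,
                                       rcr = rcr(100, 1e-3, 1200))))
  expect_rel_equal(sim$systolic, 80 * 1300 / 1333.22, 0.001)
  expect_rel_equal(sim$diastolic, 80 * 1300 / 1333.22, 0.001)
  expect_gte(sim$n_cycles, 8)
})

test_that("large capacitance pins the pulse pressure to Rp*(Qmax-Qmin)", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  sim <- simulate_network(w, list(list(diameter = 2,
                                       rcr = rcr(120, 50, 1400))),
                          max_cycles = 12)
  pp <- (sim$systolic - sim$diastolic) * 1333.22
  expect_rel_equal(pp, 120 * (max(w$flow) - min(w$flow)), 0.01)
})

test_that("two identical outlets equal one merged outlet", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  two <- simulate_network(w, list(
    list(diameter = 1.5, rcr = rcr(200, 5e-4, 2400)),
    list(diameter = 1.5, rcr = rcr(200, 5e-4, 2400))))
  one <- simulate_network(w, list(
    list(diameter = 1.5 * sqrt(2), rcr = rcr(100, 1e-3, 1200))))
  expect_rel_equal(two$root_pressure, one$root_pressure, 0.001)
})

test_that("outlet flows sum exactly to the inlet flow", {
  w <- scale_waveform(default_inflow_waveform(), 4.2)
  sim <- simulate_network(w, list(
    list(diameter = 1.2, rcr = rcr(300, 4e-4, 3000)),
    list(diameter = 0.8, rcr = rcr(700, 2e-4, 7000)),
    list(diameter = 2.2, rcr = rcr(120, 9e-4, 1300))))
  expect_lt(max(abs(rowSums(sim$outlet_flow) - sim$inlet_flow)), 1e-9)
})

test_that("cycle-to-cycle variability is non-increasing after cycle 2", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  out <- list(list(diameter = 2, rcr = rcr(100, 8e-4, 1400)))
  sim <- simulate_network(w, out, max_cycles = 14, cycle_tol = 1e-9)
  v <- sim$cycle_variability
  expect_true(all(diff(v[-1]) <= 1e-12 + v[-c(1, length(v))] * 1e-6))
  expect_gte(sim$n_cycles, 8)
})

test_that("a short run is flagged unconverged, never silently accepted", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  # start far from the periodic state so few cycles cannot converge
  out <- list(list(diameter = 2, rcr = rcr(100, 5e-2, 1400)))
  sim <- simulate_network(w, out, max_cycles = 3)
  expect_false(sim$converged)
  expect_equal(sim$n_cycles, 3)
})

test_that("tuner recovers pressures generated by a known RCR set", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  frac <- murray_split(c(1.2, 0.8, 2.4))
  rcrs <- neoaorta:::distribute_rcr(1400, 1.2e-3, frac, 0.04)
  outlets <- lapply(1:3, function(i)
    list(diameter = c(1.2, 0.8, 2.4)[i], rcr = rcrs[[i]]))
  truth <- simulate_network(w, outlets)
  fit <- tune_rcr(w, c(1.2, 0.8, 2.4), truth$systolic, truth$diastolic,
                  tol = 0.01,
                  init = list(R_total = 2 * 1400, C_total = 1.2e-3 / 2))
  expect_true(fit$converged)
  expect_lt(max(fit$rel_error), 0.01)
})

test_that("constant-inflow tuning recovers the total resistance", {
  w <- steady_waveform(q = 80)
  target <- 95  # mmHg, both systolic and diastolic under steady flow
  fit <- tune_rcr(w, c(1.0, 2.0), target + 0.5, target - 0.5, tol = 0.01)
  R_tot <- 1 / sum(1 / vapply(fit$rcrs, function(r) r$Rp + r$Rd,
                              numeric(1)))
  expect_rel_equal(R_tot, target * 1333.22 / 80, 0.02)
})

test_that("exhausted tuning iterations return a flagged best-so-far", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  fit <- tune_rcr(w, c(1.2, 2.4), 120, 70, max_iter = 1)
  expect_false(fit$converged)
  expect_true(is.finite(fit$achieved[["systolic"]]))
  expect_equal(fit$n_iter, 1)
})

test_that("Reynolds number matches the hand-evaluated chain and scalings", {
  # U = (5 L/min)/(pi 2.4^2/4) = 18.4207 cm/s; Re = U d / nu = 1171.56
  expect_rel_equal(reynolds(5, 2.4), 1171.557, 0.001)
  expect_rel_equal(reynolds(5, 4.8), reynolds(5, 2.4) / 2, 1e-9)
  # cohort sweep stays laminar/transitional
  for (co in c(3.8, 5, 6)) for (d in c(2.0, 2.5, 3.0)) {
    expect_lt(reynolds(co, d), 4000)
  }
})

test_that("time-step halving changes pressures by well under 3%", {
  w <- scale_waveform(default_inflow_waveform(), 5)
  out <- list(list(diameter = 2, rcr = rcr(100, 8e-4, 1400)))
  s1 <- simulate_network(w, out, dt = 0.001)
  s2 <- simulate_network(w, out, dt = 0.0005)
  expect_rel_equal(s2$systolic, s1$systolic, 0.03)
  expect_rel_equal(s2$diastolic, s1$diastolic, 0.03)
})
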