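test_that("steady-state gates hit their sigmoid midpoints and bounds", {
  g <- steady_state_gates(-30)
  expect_equal(g[["m"]], 0.5)
  expect_equal(g[["n"]], 0.5)
  expect_equal(steady_state_gates(-53)[["h"]], 0.5)
  expect_equal(steady_state_gates(-39)[["z"]], 0.5)
  expect_equal(steady_state_gates(-60)[["m"]], 1 / (1 + exp(30 / 9.5)),
               tolerance = 1e-12)
  V <- seq(-120, 60, by = 1)
  gm <- steady_state_gates(V)
  expect_true(all(gm > 0 & gm < 1))
  expect_true(all(diff(gm[, "m"]) > 0))
  expect_true(all(diff(gm[, "n"]) > 0))
  expect_true(all(diff(gm[, "z"]) > 0))
  expect_true(all(diff(gm[, "h"]) < 0))
  expect_error(steady_state_gates(NaN), "finite")
})

test_that("gate time constants are positive, with fixed slow M-gate", {
  V <- seq(-100, 40, by = 2)
  tc <- gate_time_constants(V)
  expect_true(all(tc > 0))
  expect_true(all(tc[, "z"] == 75))
  expect_equal(gate_time_constants(-40.5)[["h"]], 0.37 + 2.78 / 2)
  expect_equal(gate_time_constants(-27)[["n"]], 0.37 + 1.85 / 2)
})

test_that("membrane derivative matches its defining terms", {
  p <- type1()
  # at V = EL with n = z = 0 only the sodium term drives the membrane
  st <- c(V = -60, h = unname(steady_state_gates(-60)[["h"]]), n = 0, z = 0)
  d <- membrane_derivative(st, p)
  m <- steady_state_gates(-60)[["m"]]
  expect_equal(d[["V"]], -24 * m^3 * st[["h"]] * (-60 - 55), tolerance = 1e-12)
  # gating fixed point
  ss <- steady_state_gates(-48)
  st2 <- c(V = -48, h = ss[["h"]], n = ss[["n"]], z = ss[["z"]])
  d2 <- membrane_derivative(st2, p)
  expect_equal(unname(d2[c("h", "n", "z")]), c(0, 0, 0), tolerance = 1e-14)
  # M-current is proportional to z: gKs irrelevant when z = 0
  st3 <- c(V = -40, h = 0.4, n = 0.3, z = 0)
  expect_equal(membrane_derivative(st3, type2()),
               membrane_derivative(st3, type1()))
  # Isyn enters with a minus sign
  d4 <- membrane_derivative(st3, p, Iapp = 1, Isyn = 1)
  d5 <- membrane_derivative(st3, p, Iapp = 0, Isyn = 0)
  expect_equal(d4[["V"]], d5[["V"]])
})

test_that("isolated Type I cell fires spontaneously but not under -0.2", {
  sim0 <- simulate_single_neuron(type1(), Iapp = 0, duration = 2000)
  expect_gt(steady_rate(sim0$spikes, c(500, 2000)), 0)
  expect_true(all(diff(sim0$spikes) > 0))
  simh <- simulate_single_neuron(type1(), Iapp = -0.2, duration = 2000)
  expect_length(simh$spikes[simh$spikes > 500], 0)
})

test_that("spike times self-converge under step halving", {
  for (cfg in list(list(p = type1(), I = 0.6), list(p = type2(), I = 3))) {
    s1 <- simulate_single_neuron(cfg$p, cfg$I, duration = 1000, dt = 0.05)$spikes
    s2 <- simulate_single_neuron(cfg$p, cfg$I, duration = 1000, dt = 0.025)$spikes
    expect_equal(length(s1), length(s2))
    expect_lt(max(abs(s1 - s2)), 1)
  }
})

test_that("trace matches an adaptive high-accuracy integrator", {
  skip_if_not_installed("deSolve")
  p <- type1()
  rhs <- function(t, y, parms) {
    list(unname(membrane_derivative(y, p, Iapp = -0.2)))
  }
  y0 <- c(V = -62, h = 0.3, n = 0.3, z = 0.15)
  times <- seq(0, 100, by = 0.5)
  ref <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  sim <- simulate_single_neuron(p, -0.2, 100, dt = 0.05,
                                init = neuron_state(-62, 0.3, 0.3, 0.15),
                                record_trace = TRUE)
  ours <- sim$V[match(times, round(sim$time, 10))]
  expect_lt(max(abs(ours - ref[, "V"])), 1e-4)
})

test_that("gating variables stay inside [0, 1] while spiking", {
  for (cfg in list(list(p = type1(), I = 1), list(p = type2(), I = 5))) {
    sim <- simulate_single_neuron(cfg$p, cfg$I, duration = 500,
                                  init = neuron_state(-30, 0.8, 0.2, 0.25),
                                  record_trace = TRUE)
    expect_gt(length(sim$spikes), 5)
    expect_true(all(sim$h >= 0 & sim$h <= 1))
    expect_true(all(sim$n >= 0 & sim$n <= 1))
    expect_true(all(sim$z >= 0 & sim$z <= 1))
  }
})

test_that("global error on a subthreshold trace shows fourth-order decay", {
  run <- function(dt) simulate_single_neuron(
    type1(), -0.2, 100, dt = dt,
    init = neuron_state(-62, 0.3, 0.3, 0.15), record_trace = TRUE)
  ref <- run(0.05)  # dt/8 reference
  err <- function(dt) {
    s <- run(dt)
    stride <- as.integer(round(dt / 0.05))
    max(abs(s$V - ref$V[seq(1, length(ref$V), by = stride)]))
  }
  ratio <- err(0.4) / err(0.2)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("with gKs = 0 the M-gate has no effect on the trajectory", {
  a <- simulate_single_neuron(type1(), 0.6, 300,
                              init = neuron_state(-50, 0.5, 0.5, 0.05),
                              record_trace = TRUE)
  b <- simulate_single_neuron(type1(), 0.6, 300,
                              init = neuron_state(-50, 0.5, 0.5, 0.95),
                              record_trace = TRUE)
  expect_identical(a$V, b$V)
  expect_identical(a$spikes, b$spikes)
})

test_that("I-F curves separate Type I and Type II onset", {
  grid1 <- seq(-0.24, 0, by = 0.01)
  f1 <- fi_curve(type1(), grid1, duration = 1500)
  expect_true(all(diff(f1$rate) > -1))  # nondecreasing within grid noise
  expect_equal(f1$rate[1], 0)           # subthreshold
  on1 <- min(f1$rate[f1$rate > 0])
  expect_lt(on1, 5)
  f2 <- fi_curve(type2(), seq(1.0, 1.6, by = 0.01), duration = 1500)
  on2 <- min(f2$rate[f2$rate > 0])
  expect_gt(on2, 2 * on1)
})

test_that("drive calibration hits the target rate and is monotone", {
  p <- type1()
  i45 <- calibrate_drive(p, 45, tol = 0.1)
  r45 <- fi_curve(p, i45)$rate
  expect_gt(r45, 44.75); expect_lt(r45, 45.25)
  i55 <- calibrate_drive(p, 55, tol = 0.1)
  expect_gt(i55, i45)
  expect_identical(i45, calibrate_drive(p, 45, tol = 0.1))  # deterministic
  expect_error(calibrate_drive(p, 500, bracket = c(0, 1)), "not bracketed")
})

test_that("PRC sign structure distinguishes the two excitability types", {
  p1 <- type1(); p2 <- type2()
  i1 <- calibrate_drive(p1, 45); i2 <- calibrate_drive(p2, 45)
  prc1 <- compute_prc(p1, i1)
  expect_true(all(diff(prc1$phase) > 0))
  expect_true(all(abs(prc1$shift) < 1))
  expect_gte(min(prc1$shift), -0.01)          # Type I: advances only
  prc2 <- compute_prc(p2, i2)
  expect_lt(min(prc2$shift[prc2$phase < 0.5]), 0)  # Type II: early delays
  # null pulse produces null shifts
  prc0 <- compute_prc(p1, i1, pulse_amplitude = 0, n_phases = 8)
  expect_true(all(abs(prc0$shift) < 0.005))
  expect_error(compute_prc(p1, -0.2), "undefined")
})
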