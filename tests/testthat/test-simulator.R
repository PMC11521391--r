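test_that("synaptic kernel peaks at its closed-form maximum", {
  tau_r <- 0.2; tau_d <- 5.5
  tpk <- synaptic_peak_time(tau_r, tau_d)
  kern <- function(t) exp(-t / tau_d) - exp(-t / tau_r)
  expect_gt(kern(tpk), kern(tpk - 0.01))
  expect_gt(kern(tpk), kern(tpk + 0.01))
  # current at the peak equals gsyn * (V - Esyn) * kernel peak
  expect_equal(synaptic_current(10, 10 + tpk, V_post = -60, gsyn = 0.002,
                                Esyn = -75, tau_r = tau_r, tau_d = tau_d),
               0.002 * 15 * kern(tpk), tolerance = 1e-12)
  expect_equal(synaptic_current(numeric(0), 5, -60, 0.002, -75), 0)
})

test_that("incremental accumulator equals the explicit spike sum", {
  set.seed(1)
  dt <- 0.05; tau_d <- 5.5; tau_r <- 0.2
  steps <- 500
  spike_steps <- sort(sample(steps, 40))
  spike_times <- spike_steps * dt
  Ad <- 0; Ar <- 0
  for (k in seq_len(steps)) {
    Ad <- Ad * exp(-dt / tau_d); Ar <- Ar * exp(-dt / tau_r)
    if (k %in% spike_steps) { Ad <- Ad + 1; Ar <- Ar + 1 }
  }
  direct <- oracle_synapse_sum(spike_times, steps * dt, tau_d, tau_r)
  expect_equal(Ad - Ar, direct, tolerance = 1e-9)
})

test_that("a driven synapse reproduces explicit-sum R reintegration", {
  # two excitatory cells, one directed synapse 1 -> 2; re-integrate cell 2
  # in R using the explicit double-exponential sum over cell 1's recorded
  # spikes and compare voltage traces
  cfg <- network_config(n_exc = 2, n_inh = 0, g_inter = 0, g_II = 0,
                        g_EE = 0.01, p_EE = 0, seed = 11,
                        synapse_scale = 1)
  net <- build_network(cfg)
  net$adjacency$EE <- list(2L, integer(0))
  net$drive <- c(0.6, -0.1)
  st <- simulation_settings(duration = 300, dt = 0.05, seed = 12,
                            record = 2L)
  ras <- run_simulation(net, st)
  pre <- ras$spikes[[1]]
  expect_gt(length(pre), 5)
  got <- attr(ras, "traces")[, 1]

  set.seed(st$seed)
  init <- draw_initial_state(2)
  p <- net$params_exc
  deliv <- pre[pre >= st$synapse_onset]
  f <- function(s, gexc) {
    d <- membrane_derivative(s, p, Iapp = -0.1,
                             Isyn = gexc * (s[1] - st$Esyn_exc))
    unname(d)
  }
  s <- init[2, ]
  nsteps <- 300 / 0.05
  V <- numeric(nsteps + 1); V[1] <- s[1]
  for (k in 0:(nsteps - 1)) {
    t <- k * 0.05
    ds <- deliv[deliv <= t]
    ksum <- sum(exp(-(t - ds) / st$tau_d_exc) - exp(-(t - ds) / st$tau_r))
    gexc <- net$g[["EE"]] * ksum
    k1 <- f(s, gexc); k2 <- f(s + 0.025 * k1, gexc)
    k3 <- f(s + 0.025 * k2, gexc); k4 <- f(s + 0.05 * k3, gexc)
    s <- s + 0.05 / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    V[k + 2] <- s[1]
  }
  expect_lt(max(abs(V - got)), 1e-6)
})

test_that("decoupled network reduces to independent single-cell runs", {
  cfg <- tiny_config(g_inter = 0, g_II = 0, g_EE = 0, seed = 13)
  net <- build_network(cfg)
  st <- simulation_settings(duration = 500, seed = 14)
  ras <- run_simulation(net, st)
  set.seed(st$seed)
  init <- draw_initial_state(25)
  for (i in c(1, 7, 21, 25)) {
    p <- if (i <= 20) net$params_exc else net$params_inh
    solo <- simulate_single_neuron(p, net$drive[i], 500,
                                   init = neuron_state(init[i, 1], init[i, 2],
                                                       init[i, 3], init[i, 4]))
    expect_equal(length(ras$spikes[[i]]), length(solo$spikes))
    if (length(solo$spikes))
      expect_lt(max(abs(ras$spikes[[i]] - solo$spikes)), 1)
  }
})

test_that("initial conditions fall in the documented ranges", {
  set.seed(3)
  init <- draw_initial_state(5000)
  expect_true(all(init[, "V"] > -62 & init[, "V"] < -22))
  expect_true(all(init[, "h"] > 0.2 & init[, "h"] < 0.8))
  expect_true(all(init[, "n"] > 0.2 & init[, "n"] < 0.8))
  expect_true(all(init[, "z"] > 0.15 & init[, "z"] < 0.25))
})

test_that("simulation is deterministic given network and seed", {
  net <- build_network(tiny_config(seed = 15))
  st <- simulation_settings(duration = 400, seed = 16)
  r1 <- run_simulation(net, st)
  r2 <- run_simulation(net, st)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("synapses are silent before the 100 ms onset", {
  cfg <- tiny_config(g_inter = 0.02, g_II = 0.004, seed = 17)
  net <- build_network(cfg)
  uncoupled <- net; uncoupled$g[] <- 0
  st <- simulation_settings(duration = 400, seed = 18)
  rc <- run_simulation(net, st)
  ru <- run_simulation(uncoupled, st)
  before <- function(r) lapply(r$spikes, function(s) s[s <= 100])
  expect_identical(before(rc), before(ru))
  expect_false(identical(rc$spikes, ru$spikes))  # coupling acts later
})

test_that("without I->E synapses inhibitory cells cannot move E cells", {
  net <- ablate_IE(build_network(tiny_config(g_inter = 0.02, g_II = 0.004,
                                             seed = 19)))
  st <- simulation_settings(duration = 500, seed = 20)
  r1 <- run_simulation(net, st)
  altered <- net
  altered$drive[21:25] <- altered$drive[21:25] + 0.5  # perturb I drives only
  r2 <- run_simulation(altered, st)
  expect_identical(r1$spikes[1:20], r2$spikes[1:20])
  expect_false(identical(r1$spikes[21:25], r2$spikes[21:25]))
})

test_that("early burst centers are stable under integration-step halving", {
  # the coupled network is chaotic, so dt and dt/2 trajectories decorrelate
  # at long horizons; convergence is asserted on the first bursts after
  # synapse onset
  net <- build_network(network_config(n_exc = 200, n_inh = 50,
                                      g_inter = 0.00175, g_II = 0.00025,
                                      seed = 7))
  b <- lapply(c(0.05, 0.025), function(dt) {
    ras <- run_simulation(net, simulation_settings(duration = 400, dt = dt,
                                                   seed = 8))
    burst_detect(ras, "E", window = c(100, 400))
  })
  k <- 4
  expect_gte(min(nrow(b[[1]]), nrow(b[[2]])), k)
  expect_lt(max(abs(b[[1]]$center[1:k] - b[[2]]$center[1:k])), 2)
})

test_that("raster round-trips through JSON and CSV export orders cells", {
  net <- build_network(tiny_config(seed = 21))
  ras <- run_simulation(net, simulation_settings(duration = 300, seed = 22))
  f <- tempfile(fileext = ".json")
  write_raster_json(ras, f)
  back <- read_raster_json(f)
  expect_equal(back$spikes, ras$spikes, tolerance = 1e-12)
  expect_identical(back$population, ras$population)
  fc <- tempfile(fileext = ".csv")
  write_raster_csv(ras, fc, drive = net$drive)
  df <- utils::read.csv(fc)
  expect_true(all(df$neuron_index %in% 1:25))
  unlink(c(f, fc))
})
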