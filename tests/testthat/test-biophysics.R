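test_that("synaptic kernels peak at the closed-form time with the stated maximum", {
  t <- seq(0, 20, by = 1e-4)
  for (tc in list(c(0.1, 0.18, 0.13225), c(0.45, 2.0, 0.86617))) {
    pop <- synapse_population(1, 1, tc[1], tc[2], 0.0031, -75,
                              sign = "inhibitory")
    k <- kernel_peak(tc[1], tc[2])
    expect_equal(k$t_peak, tc[3], tolerance = 1e-4)
    g <- synaptic_kernel(pop, t)
    # numerical argmax agrees with the closed form (to the grid step)
    expect_lt(abs(t[which.max(g)] - k$t_peak), 2e-4)
    expect_equal(max(g), pop$g_peak, tolerance = 1e-6)
    expect_identical(g[1], 0)
    expect_lt(g[length(g)], 1e-3 * pop$g_peak)
  }
  expect_error(synapse_population(1, 1, 2, 0.5, 0.001, 0), "invalid kinetics")
})

test_that("a trial without synaptic input stays at rest", {
  m <- default_model()
  tr <- simulate_trial(m, 0, 0, 0)
  expect_false(attr(tr, "spike"))
  expect_lt(max(abs(tr$V1 - m$E_rest)), 1e-6)
  expect_lt(max(abs(tr$V2 - m$E_rest)), 1e-6)
})

test_that("inhibition alone only hyperpolarizes", {
  m <- default_model()
  for (ns in c(2, 8)) {
    tr <- simulate_trial(m, 0, ns, 0)
    expect_lte(max(tr$V1), m$E_rest + 1e-9)
    expect_lte(max(tr$V2), m$E_rest + 1e-9)
    expect_lt(min(tr$V1), m$E_rest - 0.5)
  }
  tr <- simulate_trial(m, 0, 0, 2)   # AIS-targeting inhibition
  expect_lte(max(tr$V2), m$E_rest + 1e-9)
})

test_that("full excitation spikes with a ~30 mV backpropagated soma AP", {
  m <- default_model()
  tr <- simulate_trial(m, n_exc = 20)
  expect_true(attr(tr, "spike"))
  amp <- max(tr$V1) - m$E_rest
  expect_gt(amp, 25)
  expect_lt(amp, 35)
  # AIS spike leads the backpropagated soma deflection
  expect_gt(max(tr$V2), m$spike_threshold)
})

test_that("the integrator is converged at the default step", {
  m <- default_model()
  a <- simulate_trial(m, n_exc = 12, n_inh_soma = 6, itd = 0.3, dt = 0.002)
  b <- simulate_trial(m, n_exc = 12, n_inh_soma = 6, itd = 0.3, dt = 0.001)
  expect_lt(abs(max(a$V1) - max(b$V1)), 0.05)
  expect_identical(attr(a, "spike"), attr(b, "spike"))
  # repeated runs are bit-identical
  a2 <- simulate_trial(m, n_exc = 12, n_inh_soma = 6, itd = 0.3, dt = 0.002)
  expect_identical(a$V1, a2$V1)
})

test_that("sodium-conductance calibration hits its target and its ratio contract", {
  m <- default_model()
  expect_true(m$calibrated)
  expect_gte(m$calibration$threshold_epsp, 9.5)
  expect_lte(m$calibration$threshold_epsp, 10.5)
  expect_identical(m$currents$g_KHT, 0.1 * m$currents$g_Na)
})

test_that("threshold EPSP amplitude decreases with increasing g_Na", {
  m <- default_model()
  probe <- function(gna) {
    m$currents$g_Na <- gna
    m$currents$g_KHT <- 0.1 * gna
    lsoveto:::threshold_epsp(m)$epsp
  }
  e <- vapply(m$currents$g_Na * c(0.5, 1, 2), probe, numeric(1))
  expect_gt(e[1], e[2])
  expect_gt(e[2], e[3])
})

test_that("IPSP statistics are reproducible and monotone in active count", {
  m <- default_model()
  s1 <- ipsp_statistics(m, n_trials = 2000, seed = 5)
  s2 <- ipsp_statistics(m, n_trials = 2000, seed = 5)
  expect_identical(s1$mean, s2$mean)
  expect_identical(s1$counts, s2$counts)
  # peak hyperpolarization deepens with each extra active input
  expect_true(all(diff(s1$peaks) < 0))
  expect_identical(s1$peaks[1], 0)
  # binomial draw statistics: mean ~ 8 * 0.92, all-active share ~ 0.92^8
  n <- length(s1$counts)
  se_mean <- sqrt(8 * 0.92 * 0.08 / n)
  expect_lt(abs(mean(s1$counts) - 8 * 0.92), 3 * se_mean)
  p8 <- 0.92^8
  expect_lt(abs(mean(s1$counts == 8) - p8), 3 * sqrt(p8 * (1 - p8) / n))
})

test_that("the mature synaptic preset carries the faster kinetics", {
  pre <- synapse_preset("mature_invivo")
  expect_equal(pre$exc$tau_rise, 0.25)
  expect_equal(pre$inh$tau_decay, 0.7)
  expect_equal(pre$inh$g_peak, 0.0039)
  expect_equal(pre$exc$p_release, 0.82)
})
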