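test_that("coupling-constant inversion reproduces the steady-state network", {
  p <- passive_from_coupling(0.95, 0.6, R1 = 40, fit_c1 = FALSE)
  # frozen values from the algebraic inversion, checked against the
  # steady-state solve below
  expect_equal(p$gax, 0.6 / (40 * (1 - 0.95 * 0.6)), tolerance = 1e-12)
  expect_equal(p$gax, 0.034884, tolerance = 1e-4)
  expect_equal(p$g1, 0.023256, tolerance = 1e-4)
  expect_equal(p$g2, 0.0018360, tolerance = 1e-4)

  ss <- steady_state_resistances(p$g1, p$g2, p$gax)
  expect_equal(p$R1, 40, tolerance = 1e-9)
  expect_equal(ss$R1, p$R1, tolerance = 1e-9)
  expect_equal(ss$R2, p$R2, tolerance = 1e-9)
  expect_equal(ss$R12, p$R12, tolerance = 1e-9)
  expect_equal(ss$R12, ss$R21, tolerance = 1e-12)  # transfer symmetry
  expect_equal(p$R2, 63.33, tolerance = 1e-3)
  expect_equal(p$R12, 38, tolerance = 1e-9)        # R1 * kappa_fwd
})

test_that("symmetric coupling gives equal conductances and resistances", {
  p <- passive_from_coupling(0.5, 0.5, R1 = 40, fit_c1 = FALSE)
  expect_equal(p$g1, 1 / 60, tolerance = 1e-12)
  expect_equal(p$g2, 1 / 60, tolerance = 1e-12)
  expect_equal(p$gax, 1 / 60, tolerance = 1e-12)
  expect_equal(p$R2, 40, tolerance = 1e-9)
  expect_equal(p$R12, 20, tolerance = 1e-9)
})

test_that("invalid coupling configurations are rejected", {
  expect_error(passive_from_coupling(1.2, 0.5), "invalid configuration")
  expect_error(passive_from_coupling(0.5, 0), "invalid configuration")
  expect_error(passive_from_coupling(0.5, 0.5, R1 = -1), "positive")
  expect_error(passive_from_coupling(0.5, 0.5, alpha = 1.5), "alpha")
})

test_that("transfer-resistance identity and round trip hold over random couplings", {
  set.seed(11)
  for (i in 1:25) {
    kf <- runif(1, 0.05, 0.95)
    kb <- runif(1, 0.05, 0.95)
    p <- passive_from_coupling(kf, kb, R1 = runif(1, 10, 100), fit_c1 = FALSE)
    # R1 * kappa_fwd = R2 * kappa_bwd = R12
    expect_equal(p$R1 * kf, p$R12, tolerance = 1e-9)
    expect_equal(p$R2 * kb, p$R12, tolerance = 1e-9)
    expect_lt(p$R12, min(p$R1, p$R2))
    # AIS-inhibition dominance: R2 > R1 * kappa_fwd whenever kappa_bwd < 1
    expect_gt(p$R2, p$R1 * kf)
    # inversion identity
    k <- coupling_from_passive(p)
    expect_equal(k$kappa_fwd, kf, tolerance = 1e-9)
    expect_equal(k$kappa_bwd, kb, tolerance = 1e-9)
  }
})

test_that("passive decay matches an independent stiff ODE integration", {
  skip_if_not_installed("deSolve")
  p <- passive_from_coupling(0.95, 0.6, R1 = 40)
  t <- seq(0, 10, by = 0.01)
  U <- passive_decay(p, t = t)
  sol <- deSolve::lsoda(
    y = c(1, p$kappa_fwd), times = t,
    func = function(t, y, parms) list(-parms %*% y),
    parms = lsoveto:::decay_matrix(p, p$c1),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(U[, "U1"] - sol[, 2])), 1e-6)
  expect_lt(max(abs(U[, "U2"] - sol[, 3])), 1e-6)
})

test_that("passive decay is stable: zero stays zero, any start decays to rest", {
  p <- passive_from_coupling(0.8, 0.4, R1 = 55)
  z <- passive_decay(p, U0 = c(0, 0), t = seq(0, 5, by = 0.1))
  expect_true(all(z == 0))
  far <- passive_decay(p, U0 = c(-3, 7), t = c(0, 100))
  expect_lt(max(abs(far[2, ])), 1e-10)
})

test_that("decay-matrix eigenvalues are real and positive for random configurations", {
  set.seed(21)
  for (i in 1:20) {
    p <- passive_from_coupling(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                               R1 = runif(1, 10, 100), fit_c1 = FALSE)
    ev <- eigen(lsoveto:::decay_matrix(p, c1 = runif(1, 0.005, 0.1)))$values
    expect_false(is.complex(ev))
    expect_true(all(ev > 0))
  }
})

test_that("fitted capacitance matches a dense grid-search oracle", {
  p <- passive_from_coupling(0.95, 0.6, R1 = 40)
  err <- function(c1) lsoveto:::capacitance_error(p, c1)
  # two-pass grid search, 1000 points per pass
  grid <- seq(p$c1 / 4, p$c1 * 4, length.out = 1000)
  e <- vapply(grid, err, numeric(1))
  c_star <- grid[which.min(e)]
  grid2 <- seq(0.98 * c_star, 1.02 * c_star, length.out = 1000)
  e2 <- vapply(grid2, err, numeric(1))
  c_star <- grid2[which.min(e2)]
  expect_equal(p$c1, c_star, tolerance = 1e-3)
  # optimality certificate
  expect_lte(err(p$c1), err(0.8 * p$c1))
  expect_lte(err(p$c1), err(1.25 * p$c1))
})

test_that("fitted soma decay approximates single-exponential decay", {
  p <- passive_from_coupling(0.95, 0.6, R1 = 40)
  t <- seq(0, 5 * p$tau_m, by = 0.001)
  U1 <- passive_decay(p, t = t)[, "U1"]
  rms <- sqrt(mean((U1 - exp(-t / p$tau_m))^2))
  expect_lt(rms, 0.05)
})

test_that("capacitance fit collapses to tau_m/R1 in the single-compartment limit", {
  p <- passive_from_coupling(0.995, 0.995, R1 = 40, alpha = 1e-3)
  expect_equal(p$c1 * p$R1, p$tau_m, tolerance = 0.02)
})
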