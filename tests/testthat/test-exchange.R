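ctx <- spectrometer_context(60.8, "15N")

test_that("two-site construction splits k_ex by population", {
  sys <- two_site_system(p_b = 0.01, delta_b = 2, k_ex = 1 / 750e-6)
  # k_ex = 1333.3 s^-1 split as k(a->b) = p_b k_ex, k(b->a) = p_a k_ex
  expect_equal(sys$K["b", "a"], 0.01 / 750e-6, tolerance = 1e-10)
  expect_equal(sys$K["a", "b"], 0.99 / 750e-6, tolerance = 1e-10)
  expect_equal(sum(sys$K %*% sys$p), 0, tolerance = 1e-10)
})

test_that("constructed rate matrices are stationary and balanced for random systems", {
  set.seed(11)
  for (i in 1:20) {
    eq <- equilibrium_model(10^stats::runif(1, -2, 0), 10^stats::runif(1, -2, 0),
                            10^stats::runif(1, -6, -4))
    st <- solve_prenucleation_equilibrium(eq, totals(10^stats::runif(1, -4, -2)))
    for (topo in c("chain", "star")) {
      sys <- build_exchange_system(st, topology = topo)
      ev <- eigen(sys$K)
      # stationary vector (eigenvalue 0) proportional to populations
      i0 <- which.min(abs(ev$values))
      v <- Re(ev$vectors[, i0]); v <- v / sum(v)
      expect_equal(v, unname(sys$p), tolerance = 1e-8)
      expect_lt(max(abs(colSums(sys$K))), 1e-8 * max(abs(sys$K)))
    }
  }
})

test_that("single-site and no-exchange systems are inert", {
  sys <- exchange_system(c(m = 1), c(m = 0.5), K = NULL, R2_0 = 12)
  expect_identical(unname(sys$K), matrix(0, 1, 1))
  obs <- observed_lineshape_parameters(sys, ctx)
  expect_equal(unname(obs["shift_ppm"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(obs["Rex"]), 0, tolerance = 1e-10)
})

test_that("fast-limit delta_ex is the population-weighted shift", {
  sys <- two_site_system(p_b = 0.05, delta_b = 2, k_ex = 5e4)
  expect_equal(delta_ex_fast(sys), 0.1, tolerance = 1e-12)
  sys0 <- two_site_system(p_b = 0.05, delta_b = 0, k_ex = 5e4)
  expect_identical(delta_ex_fast(sys0), 0)
  # matches the eigenvalue observed shift when k_ex >> dw
  dw <- 2 * pi * 2 * 60.8  # 764 rad/s; k_ex = 50000 >> 50*dw? use 50*dw
  sysf <- two_site_system(p_b = 0.05, delta_b = 2, k_ex = 50 * dw)
  obs <- observed_lineshape_parameters(sysf, ctx)
  expect_equal(unname(obs["shift_ppm"]), delta_ex_fast(sysf), tolerance = 0.01)
})

test_that("exchange broadening follows the fast-exchange formula", {
  dw <- 2 * pi * 2 * 60.8
  k_ex <- 60 * dw
  sys <- two_site_system(p_b = 0.05, delta_b = 2, k_ex = k_ex, R2_0 = 10)
  obs <- observed_lineshape_parameters(sys, ctx)
  expect_equal(unname(obs["Rex"]), fast_exchange_rex(0.95, 0.05, dw, k_ex),
               tolerance = 0.02)
})

test_that("eigenvalue lineshape agrees with direct FID simulation", {
  set.seed(3)
  for (i in 1:10) {
    p_b <- stats::runif(1, 0.01, 0.2)
    delta_b <- stats::runif(1, 0.5, 3)
    k_ex <- 10^stats::runif(1, 3, 4.5)
    sys <- two_site_system(p_b, delta_b, k_ex, R2_0 = 8)
    obs <- observed_lineshape_parameters(sys, ctx)
    oracle <- fid_lineshape(sys$p, sys$delta, sys$K, sys$R2, 60.8)
    expect_equal(unname(obs["shift_ppm"]), oracle$shift_ppm, tolerance = 0.02)
    expect_equal(8 + unname(obs["Rex"]), oracle$R2_obs, tolerance = 0.05)
  }
})

test_that("CPMG matrix propagation matches Carver-Richards within 2%", {
  nu <- c(50, 100, 200, 400, 800, 2000)
  dw <- 2 * pi * 2 * 60.8
  sys <- two_site_system(p_b = 0.05, delta_b = 2, k_ex = 1333, R2_0 = 10)
  sim <- simulate_cpmg(sys, ctx, nu, T_relax = 0.04)
  cr <- carver_richards(nu, 0.95, 0.05, dw, 1333, 10)
  expect_equal(sim$R2_eff, cr, tolerance = 0.02)
})

test_that("CPMG profiles are flat without exchange or without shift differences", {
  sys_noex <- exchange_system(c(a = 0.9, b = 0.1), c(a = 0, b = 2),
                              K = NULL, R2_0 = 9)
  flat <- simulate_cpmg(sys_noex, ctx, c(50, 400, 1600))
  expect_equal(flat$R2_eff, rep(9, 3), tolerance = 1e-6)
  sys_nodw <- two_site_system(p_b = 0.1, delta_b = 0, k_ex = 1000, R2_0 = 9)
  flat2 <- simulate_cpmg(sys_nodw, ctx, c(50, 400, 1600))
  expect_equal(flat2$R2_eff, rep(9, 3), tolerance = 1e-6)
})

test_that("R1rho reproduces the analytic fast-exchange dispersion within 3%", {
  dw <- 2 * pi * 2 * 60.8
  k_ex <- 2e4
  sys <- two_site_system(p_b = 0.05, delta_b = 2, k_ex = k_ex, R2_0 = 10)
  rr <- simulate_r1rho(sys, ctx, omega1 = c(750, 1500, 3000))
  rex <- fast_exchange_rex(0.95, 0.05, dw, k_ex, omega_e = 2 * pi * rr$omega1)
  expect_equal(rr$R1rho, 10 + rex, tolerance = 0.03)
  # spin-lock ordering: weaker fields see more exchange broadening
  expect_true(all(diff(rr$R1rho) < 0))
  # very strong lock quenches the dispersion entirely
  rr_hi <- simulate_r1rho(sys, ctx, omega1 = 5e4)
  expect_equal(rr_hi$R1rho, 10, tolerance = 0.01)
})

test_that("inhibitor binding suppresses delta_ex, Rex and CPMG amplitude in order", {
  eq <- q7_model(KD_mI = 50e-6)
  i_series <- c(0, 2e-4, 4e-4, 8e-4)
  fx <- exchange_fixture(shifts = c(D = 2, D_star = 1, T = 4), R2_0 = 8)
  dx <- numeric(); rex <- numeric(); amp <- numeric(); r1r <- numeric()
  for (i_tot in i_series) {
    st <- solve_prenucleation_equilibrium(eq, totals(1.2e-3, i_tot))
    sys <- build_exchange_system(st, shifts = fx$shifts, R2_0 = fx$R2_0)
    obs <- observed_lineshape_parameters(sys, ctx)
    dx <- c(dx, delta_ex_fast(sys))
    rex <- c(rex, obs["Rex"])
    disp <- simulate_cpmg(sys, ctx, c(25, 3000), T_relax = 0.04)
    amp <- c(amp, disp$R2_eff[1] - disp$R2_eff[2])
    r1r <- c(r1r, simulate_r1rho(sys, ctx, 750)$R1rho)
  }
  expect_true(all(diff(dx) < 0))
  expect_true(all(diff(rex) < 0))
  expect_true(all(diff(amp) < 0))
  expect_true(all(diff(r1r) < 0))
  expect_true(all(amp >= -1e-8))
})

test_that("delta_ex increases with total protein concentration", {
  fx <- exchange_fixture(shifts = c(D = 2, D_star = 1, T = 4))
  so <- static_observables(q7_model(), P_tot = seq(2e-4, 1.2e-3, length.out = 6),
                           fixture = fx)
  expect_true(all(diff(so$delta_ex) > 0))
})

test_that("exchange-system validation catches broken rate matrices", {
  K_bad <- matrix(c(-10, 10, 5, -5), 2, 2)  # not balanced with p
  expect_error(exchange_system(c(a = 0.9, b = 0.1), c(0, 2), K_bad),
               "stationary|balance")
  expect_error(two_site_system(0.5, 1, 100, R2_0 = -1))
  expect_error(simulate_cpmg(two_site_system(0.1, 1, 100), ctx, nu_cpmg = -5),
               "positive")
})
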