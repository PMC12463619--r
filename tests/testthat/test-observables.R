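fx <- exchange_fixture(shifts = c(D = 2, D_star = 1, T = 4), R2_0 = 8)
st4 <- observable_settings(R2_ref = 4)

make_tc <- function(P = 7.5e-4, I = 0, scheme = "none", P0 = 1e-9,
                    t_grid = seq(0, 20 * 3600, length.out = 41)) {
  eq <- if (scheme == "none") q35_model() else
    q35_model(KD_mI = 50e-6, KD_PI = 50e-6)
  km <- kinetic_model(eq, k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = P0,
                      scheme = scheme)
  simulate_aggregation(km, totals(P, I), t_grid,
                       mode = "quasi_equilibrium")
}

test_that("PRD signal starts at 1, decays monotonically, vanishes when fibrillized", {
  tc <- make_tc()
  pd <- prd_decay(tc)
  # P0 carries 4 P0 / P_tot ~ 5e-6 of the mass into M at t = 0
  expect_equal(pd$intensity[1], 1, tolerance = 1e-4)
  expect_true(all(diff(pd$intensity) <= 1e-10))
  expect_lt(pd$intensity[41], 0.02)  # near-complete fibrillization by 20 h
  # no aggregation: constant 1
  km0 <- kinetic_model(q35_model(), k_conv = 0, k_e = 0, k_2 = 0, P0 = 0)
  tc0 <- simulate_aggregation(km0, totals(3.8e-4), seq(0, 3600, length.out = 5))
  expect_equal(prd_decay(tc0)$intensity, rep(1, 5), tolerance = 1e-8)
})

test_that("PRD decays slow down in order with increasing inhibitor", {
  i_series <- c(0, 2e-4, 4e-4, 8e-4)
  at10h <- vapply(i_series, function(i) {
    pd <- prd_decay(make_tc(P = 3.8e-4, I = i, scheme = "monomer_binding"))
    stats::approx(pd$t, pd$intensity, 10 * 3600)$y
  }, numeric(1))
  expect_true(all(diff(at10h) > 0))
})

test_that("intensity shows an interior maximum while volume decreases", {
  tc <- make_tc(P = 7.5e-4)
  vi <- nt_volume_intensity(tc, fx, st4)
  expect_true(all(diff(vi$V) <= 1e-10))
  imax <- which.max(vi$I)
  expect_gt(imax, 1)                 # interior, not at t = 0
  expect_lt(imax, nrow(vi))
  expect_gt(max(vi$I), 1.05)         # a real rise, not numerical noise
  # peak in the early phase, before bulk fibrillization
  expect_lt(tc$t[imax], 6 * 3600)
})

test_that("without exchange broadening V and I coincide", {
  tc <- make_tc()
  fx0 <- exchange_fixture(shifts = c(D = 0, D_star = 0, T = 0), R2_0 = 8)
  vi <- nt_volume_intensity(tc, fx0, st4)
  expect_equal(vi$I, vi$V, tolerance = 1e-8)
  expect_equal(vi$VI_ratio, rep(1, nrow(vi)), tolerance = 1e-8)
})

test_that("V/I at t = 0 increases with protein concentration", {
  vi0 <- vapply(seq(2e-4, 7.5e-4, length.out = 5), function(p) {
    so <- static_observables(q35_model(), p, fixture = fx, settings = st4)
    so$VI_ratio
  }, numeric(1))
  expect_true(all(diff(vi0) > 0))
})

test_that("delta_ex decays over time and matches the static model pointwise", {
  tc <- make_tc(P = 3.8e-4)
  dx <- delta_ex_timecourse(tc, fx)
  expect_lt(stats::approx(dx$t, dx$delta_ex, 10 * 3600)$y, dx$delta_ex[1])
  # adiabatic consistency: rebuild from the instantaneous pool via the
  # static equilibrium + exchange route
  i <- 15
  tr <- tc$trajectories[i, ]
  pool <- tr$m + tr$mI + 2 * tr$D + 2 * tr$D_star + 4 * tr$T
  st_static <- solve_prenucleation_equilibrium(q35_model(), totals(pool))
  sys <- build_exchange_system(st_static, shifts = fx$shifts, R2_0 = fx$R2_0)
  expect_equal(dx$delta_ex[i], delta_ex_fast(sys), tolerance = 1e-6)
  # static trajectory: constant delta_ex
  km0 <- kinetic_model(q35_model(), k_conv = 0, k_e = 0, k_2 = 0, P0 = 0)
  tc0 <- simulate_aggregation(km0, totals(3.8e-4), seq(0, 3600, length.out = 5))
  dx0 <- delta_ex_timecourse(tc0, fx)
  expect_equal(dx0$delta_ex, rep(dx0$delta_ex[1], 5), tolerance = 1e-8)
})

test_that("nucleus binding leaves delta_ex and V/I at no-inhibitor values (P0 = 0)", {
  # nuclei form downstream of the m <-> D <-> T equilibrium, so before
  # appreciable fibril mass accumulates the equilibrium observables are
  # indistinguishable from the no-inhibitor run; afterwards only the
  # (slowed) monomer depletion feeds back on them
  tg <- seq(0, 1800, length.out = 21)
  tc0 <- make_tc(P = 3.8e-4, I = 0, scheme = "none", P0 = 0, t_grid = tg)
  tcP <- make_tc(P = 3.8e-4, I = 8e-4, scheme = "nucleus_binding", P0 = 0,
                 t_grid = tg)
  win <- which(tc0$trajectories$M < 1e-4 * 3.8e-4)
  expect_gt(length(win), 3)
  dx0 <- delta_ex_timecourse(tc0, fx)
  dxP <- delta_ex_timecourse(tcP, fx)
  expect_equal(dxP$delta_ex[win], dx0$delta_ex[win], tolerance = 1e-3)
  vi0 <- nt_volume_intensity(tc0, fx, st4)
  viP <- nt_volume_intensity(tcP, fx, st4)
  expect_equal(viP$VI_ratio[win], vi0$VI_ratio[win], tolerance = 1e-3)
  # at t = 0 the pre-nucleation species are exactly the no-inhibitor ones
  expect_equal(tcP$trajectories$m[1], tc0$trajectories$m[1], tolerance = 1e-9)
})
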