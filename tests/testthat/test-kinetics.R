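tg_short <- seq(0, 2 * 3600, length.out = 21)
tg_long <- seq(0, 20 * 3600, length.out = 31)

test_that("without conversion or seeds no fibrils ever form", {
  km <- kinetic_model(q35_model(), k_conv = 0, k_e = 500, k_2 = 1, P0 = 0)
  tc <- simulate_aggregation(km, totals(3.8e-4), tg_short)
  expect_equal(max(tc$trajectories$M), 0, tolerance = 1e-20)
  # trajectories sit at the static pre-nucleation equilibrium
  st <- solve_prenucleation_equilibrium(q35_model(), totals(3.8e-4))
  expect_equal(tc$trajectories$m, rep(st$m, 21), tolerance = 1e-6)
  expect_equal(tc$trajectories$T, rep(st$T, 21), tolerance = 1e-4)
})

test_that("monomer units are conserved along all four schemes", {
  eq <- q35_model(KD_mI = 50e-6, KD_PI = 50e-6)
  for (scheme in c("none", "monomer_binding", "nucleus_binding", "dual")) {
    km <- kinetic_model(eq, k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 1e-9,
                        scheme = scheme)
    tc <- simulate_aggregation(km, totals(3.8e-4, 4e-4), tg_long)
    expect_lt(max(abs(conservation_residual(tc))), 1e-8)
  }
})

test_that("pure elongation decays the monomer as exp(-2 k_e P0 t)", {
  # pre-nucleation switched off via astronomically weak dissociation
  eq <- equilibrium_model(1e9, 1e9, 1e9)
  k_e <- 1e4; P0 <- 1e-8
  km <- kinetic_model(eq, k_conv = 0, k_e = k_e, k_2 = 0, P0 = P0)
  t_grid <- seq(0, 5e4, length.out = 11)
  tc <- simulate_aggregation(km, totals(1e-4 + 4 * P0), t_grid)
  m0 <- tc$trajectories$m[1]
  expect_equal(m0, 1e-4, tolerance = 1e-6)
  expect_equal(tc$trajectories$m, m0 * exp(-2 * k_e * P0 * t_grid),
               tolerance = 1e-3)
})

test_that("full-network and quasi-equilibrium modes agree", {
  km <- kinetic_model(q35_model(), k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 1e-9)
  tc_f <- simulate_aggregation(km, totals(3.8e-4), tg_long, mode = "full")
  tc_q <- simulate_aggregation(km, totals(3.8e-4), tg_long,
                               mode = "quasi_equilibrium")
  expect_equal(tc_q$trajectories$M, tc_f$trajectories$M,
               tolerance = 0.01)
  expect_equal(tc_q$trajectories$m, tc_f$trajectories$m, tolerance = 0.01)
})

test_that("nucleus binding leaves pre-nucleation species at no-inhibitor values", {
  eq <- q35_model(KD_PI = 50e-6)
  km0 <- kinetic_model(q35_model(), k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 0)
  kmP <- kinetic_model(eq, k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 0,
                       scheme = "nucleus_binding")
  tc0 <- simulate_aggregation(km0, totals(3.8e-4, 0), tg_short)
  tcP <- simulate_aggregation(kmP, totals(3.8e-4, 8e-4), tg_short)
  expect_equal(tcP$trajectories$m[1], tc0$trajectories$m[1], tolerance = 1e-9)
  expect_equal(tcP$trajectories$T[1], tc0$trajectories$T[1], tolerance = 1e-7)
  expect_equal(tcP$trajectories$D[1], tc0$trajectories$D[1], tolerance = 1e-7)
})

test_that("fibril growth slows monotonically with monomer-binding inhibitor", {
  eq <- q35_model(KD_mI = 50e-6)
  M_at_end <- vapply(c(0, 2e-4, 4e-4, 8e-4), function(i_tot) {
    km <- kinetic_model(eq, k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 1e-9,
                        scheme = "monomer_binding")
    tc <- simulate_aggregation(km, totals(3.8e-4, i_tot), tg_long,
                               mode = "quasi_equilibrium")
    tc$trajectories$M[31]
  }, numeric(1))
  expect_true(all(diff(M_at_end) < 0))
})

test_that("secondary nucleation needs fibril mass and primary needs tetramers", {
  # with M(0) = 0 and k_conv = 0 the P0-seeded system grows only by
  # elongation: P stays at P0 when secondary is off, and adding a
  # secondary term with M(0) = 0 changes nothing at t = 0
  eq <- q35_model()
  km <- kinetic_model(eq, k_conv = 0, k_e = 500, k_2 = 5, P0 = 1e-9)
  tc <- simulate_aggregation(km, totals(3.8e-4), tg_short)
  # M(0) = n_c P0 only (nucleus mass); dP(0)/dt has no primary term
  expect_equal(tc$trajectories$M[1], 4e-9, tolerance = 1e-6)
  # P grows only once fibril mass exists: growth is tiny initially
  expect_lt(tc$trajectories$P_free[2] / 1e-9 - 1, 0.05)
})

test_that("identical schemes never diverge; mechanisms diverge over time", {
  eq <- q35_model(KD_mI = 50e-6, KD_PI = 50e-6)
  km_m <- kinetic_model(eq, k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 1e-9,
                        scheme = "monomer_binding")
  km_p <- kinetic_model(eq, k_conv = 2e-6, k_e = 500, k_2 = 1, P0 = 1e-9,
                        scheme = "nucleus_binding")
  same <- compare_inhibition_schemes(km_m, km_m, totals(3.8e-4, 8e-4), tg_long,
                                     mode = "quasi_equilibrium")
  expect_true(all(same$signal_difference < 1e-10))
  cmp <- compare_inhibition_schemes(km_m, km_p, totals(3.8e-4, 8e-4), tg_long,
                                    mode = "quasi_equilibrium")
  # early-time window: pre-existing nuclei dominate, schemes look alike
  expect_lt(cmp$signal_difference[2], 0.01)
  # monomer binding suppresses de-novo nucleus production
  n <- length(tg_long)
  expect_lt(cmp$P_free[n, "model_m"], cmp$P_free[n, "model_P"])
})

test_that("divergence time shrinks as conversion accelerates", {
  eq <- q35_model(KD_mI = 50e-6, KD_PI = 50e-6)
  tdiv <- vapply(c(2e-6, 8e-6, 3e-5), function(kc) {
    km_m <- kinetic_model(eq, k_conv = kc, k_e = 500, k_2 = 1, P0 = 1e-9,
                          scheme = "monomer_binding")
    km_p <- kinetic_model(eq, k_conv = kc, k_e = 500, k_2 = 1, P0 = 1e-9,
                          scheme = "nucleus_binding")
    cmp <- compare_inhibition_schemes(km_m, km_p, totals(3.8e-4, 8e-4),
                                      seq(0, 20 * 3600, length.out = 200),
                                      threshold = 0.02,
                                      mode = "quasi_equilibrium")
    cmp$t_diverge
  }, numeric(1))
  expect_true(all(is.finite(tdiv)))
  expect_true(all(diff(tdiv) < 0))
})

test_that("kinetic model validation rejects inconsistent inputs", {
  expect_error(kinetic_model(q35_model(), scheme = "monomer_binding"),
               "KD_mI")
  km <- kinetic_model(q35_model(), P0 = 1e-3)
  expect_error(simulate_aggregation(km, totals(1e-4), tg_short),
               "exceeds total protein")
  expect_error(simulate_aggregation(kinetic_model(q35_model()),
                                    totals(1e-4), c(1, 2)),
               "start at 0")
})
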