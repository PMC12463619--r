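test_that("printed oligomer populations are reproduced at 1.2 mM", {
  st <- solve_prenucleation_equilibrium(q7_model(), totals("1.2 mM"))
  fr <- population_fractions(st)
  # off-pathway dimer ~1%, productive dimer ~3% of protein mass
  expect_equal(unname(fr[["D_star"]]), 0.01, tolerance = 0.15)
  expect_equal(unname(fr[["D"]]), 0.03, tolerance = 0.15)
  expect_equal(sum(fr), 1, tolerance = 1e-10)
})

test_that("monomer-binding inhibitor suppresses the off-pathway dimer to ~0.2%", {
  eq <- q7_model(KD_mI = 50e-6)
  st <- solve_prenucleation_equilibrium(eq, totals("1.2 mM", "0.8 mM"))
  fr <- population_fractions(st)
  expect_equal(unname(fr[["D_star"]]), 0.002, tolerance = 0.2)
  # inhibitor balance: I_free + mI = I_tot
  expect_equal(st$I_free + st$mI, 8e-4, tolerance = 1e-10)
})

test_that("empty system returns all-zero species", {
  st <- solve_prenucleation_equilibrium(q7_model(), totals(0))
  expect_identical(st$m, 0)
  expect_identical(st$T, 0)
  expect_length(population_fractions(st), 0)
})

test_that("mass balances hold to 1e-10 relative over random parameter draws", {
  set.seed(42)
  for (i in 1:50) {
    eq <- equilibrium_model(KD1 = 10^stats::runif(1, -3, 0),
                            KD1_star = 10^stats::runif(1, -3, 0),
                            KD2 = 10^stats::runif(1, -6, -3),
                            KD_mI = 10^stats::runif(1, -6, -3))
    tot <- totals(10^stats::runif(1, -5, -2), 10^stats::runif(1, -5, -2))
    st <- solve_prenucleation_equilibrium(eq, tot)
    prot <- st$m + st$mI + 2 * st$D + 2 * st$D_star + 4 * st$T
    expect_lt(abs(prot - tot$P_tot) / tot$P_tot, 1e-10)
    expect_lt(abs(st$I_free + st$mI - tot$I_tot) / tot$I_tot, 1e-10)
  }
})

test_that("solver agrees with a brute-force grid search", {
  set.seed(7)
  for (i in 1:10) {
    KD1 <- 10^stats::runif(1, -3, 0); KD1s <- 10^stats::runif(1, -3, 0)
    KD2 <- 10^stats::runif(1, -6, -3); P <- 10^stats::runif(1, -4, -2)
    eq <- equilibrium_model(KD1, KD1s, KD2)
    st <- solve_prenucleation_equilibrium(eq, totals(P))
    oracle <- grid_equilibrium(KD1, KD1s, KD2, P)
    # grid resolution is the limiting accuracy
    expect_equal(st$m, oracle$m, tolerance = 1e-4)
    expect_equal(st$T, oracle$T, tolerance = 1e-3)
  }
})

test_that("tetramer mass fraction scales as monomer cubed in the dilute limit", {
  eq <- q7_model()
  p <- c(1e-6, 2e-6)
  st <- lapply(p, function(x) solve_prenucleation_equilibrium(eq, totals(x)))
  # [T]/[m]^4 approaches 1/(KD1^2 KD2)
  ratio <- vapply(st, function(s) s$T / s$m^4, numeric(1))
  expect_equal(ratio[1], 1 / (70e-3^2 * 30e-6), tolerance = 1e-4)
  # hence mass fraction 4T/P ~ m^3: doubling P multiplies it by ~8
  fr <- vapply(st, function(s) 4 * s$T / s$totals$P_tot, numeric(1))
  expect_equal(fr[2] / fr[1], 8, tolerance = 0.01)
})

test_that("increasing inhibitor strictly decreases m, D and T", {
  eq <- q7_model(KD_mI = 50e-6)
  sweep <- equilibrium_series(eq, 1.2e-3, I_tot = c(0, 2e-4, 4e-4, 8e-4))
  expect_true(all(diff(sweep$m) < 0))
  expect_true(all(diff(sweep$D) < 0))
  expect_true(all(diff(sweep$T) < 0))
})

test_that("pure-monomer fractions and fraction normalization are exact", {
  eq <- equilibrium_model(1e6, 1e6, 1e6)  # so weak nothing associates
  st <- solve_prenucleation_equilibrium(eq, totals(1e-3))
  fr <- population_fractions(st)
  expect_equal(unname(fr[["m"]]), 1, tolerance = 1e-8)
  st2 <- solve_prenucleation_equilibrium(q7_model(), totals(5e-4))
  expect_equal(sum(population_fractions(st2)), 1, tolerance = 1e-12)
})

test_that("free-energy differences match direct evaluation", {
  # tetramer stabilization from KD2 = 30 uM to 11 uM at 5 C falls in the
  # 0.4-0.6 kcal/mol range
  dG <- free_energy_difference(30e-6, 11e-6, 278.15)
  expect_gt(dG, 0.4)
  expect_lt(dG, 0.6)
  expect_identical(free_energy_difference(5e-5, 5e-5, 300), 0)
  expect_equal(free_energy_difference(2e-5, 1e-5, 278.15),
               1.987204259e-3 * 278.15 * log(2), tolerance = 1e-12)
  expect_error(free_energy_difference(-1e-5, 1e-5), "positive")
})

test_that("validation rejects non-physical inputs", {
  expect_error(equilibrium_model(-1, 0.2, 3e-5), "positive")
  expect_error(totals(-1e-3), "P_tot")
  expect_error(totals(1e-3, -1), "I_tot")
})
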