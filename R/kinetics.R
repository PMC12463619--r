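#' Aggregation kinetic model
#'
#' Parameterizes the aggregation cascade: fast reversible pre-nucleation
#' equilibria (m <-> D <-> T, off-pathway m <-> D*), irreversible
#' conversion of tetramers into elongation-competent nuclei (T -> P),
#' fibril elongation by monomer addition at two growing ends, and
#' fibril-catalyzed secondary nucleation. Four inhibitor schemes are
#' supported: `"none"`, `"monomer_binding"` (m + I <-> mI),
#' `"nucleus_binding"` (P + I <-> PI, PI elongation-incompetent), and
#' `"dual"` (both).
#'
#' Rate laws (number concentrations for P/PI, monomer-equivalent mass for
#' fibrils M, which includes nucleus mass):
#' \deqn{dP/dt = k_{conv}[T] + k_2 [m]^{n_2} M - binding}
#' \deqn{dM/dt = n_c (k_{conv}[T] + k_2 [m]^{n_2} M) + 2 k_e [m] [P]}
#' Secondary nucleation removes `n_c` monomer units per nucleus;
#' elongation removes one per added monomer.
#'
#' @param equilibrium an [equilibrium_model] (supplies KD1, KD1*, KD2
#'   and, for the binding schemes, KD_mI / KD_PI unless on/off rates are
#'   given explicitly).
#' @param k_conv tetramer-to-nucleus conversion rate, s^-1.
#' @param k_e elongation rate constant, M^-1 s^-1.
#' @param k_2 secondary-nucleation rate constant, M^-n2 s^-1 per unit
#'   fibril mass.
#' @param n_2 secondary-nucleation reaction order in monomer.
#' @param n_c monomer units per nucleus (4: one tetramer).
#' @param scheme inhibitor scheme.
#' @param kon_mI,koff_mI monomer-inhibitor on/off rates (M^-1 s^-1, s^-1);
#'   defaults derive koff from `kon_mI * KD_mI`.
#' @param kon_PI,koff_PI nucleus-inhibitor on/off rates, likewise.
#' @param P0 initial nucleus number concentration, M.
#' @param relax_rate dissociation rate assigned to the fast pre-nucleation
#'   steps when they are integrated as explicit reversible reactions,
#'   s^-1; must be much faster than aggregation.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(equilibrium, k_conv = 1e-4, k_e = 1e4, k_2 = 0,
                          n_2 = 2, n_c = 4,
                          scheme = c("none", "monomer_binding",
                                     "nucleus_binding", "dual"),
                          kon_mI = 1e4, koff_mI = NULL,
                          kon_PI = 1e4, koff_PI = NULL,
                          P0 = 0, relax_rate = 1e3) {
  stopifnot(inherits(equilibrium, "equilibrium_model"))
  scheme <- match.arg(scheme)
  if (scheme %in% c("monomer_binding", "dual")) {
    if (is.na(equilibrium$KD_mI) && is.null(koff_mI)) {
      stop("monomer-binding scheme needs KD_mI (or koff_mI)")
    }
    if (is.null(koff_mI)) koff_mI <- kon_mI * equilibrium$KD_mI
  } else { kon_mI <- 0; koff_mI <- 0 }
  if (scheme %in% c("nucleus_binding", "dual")) {
    if (is.na(equilibrium$KD_PI) && is.null(koff_PI)) {
      stop("nucleus-binding scheme needs KD_PI (or koff_PI)")
    }
    if (is.null(koff_PI)) koff_PI <- kon_PI * equilibrium$KD_PI
  } else { kon_PI <- 0; koff_PI <- 0 }
  pars <- list(equilibrium = equilibrium, k_conv = k_conv, k_e = k_e,
               k_2 = k_2, n_2 = n_2, n_c = n_c, scheme = scheme,
               kon_mI = kon_mI, koff_mI = koff_mI,
               kon_PI = kon_PI, koff_PI = koff_PI,
               P0 = parse_quantity(P0), relax_rate = relax_rate)
  for (nm in c("k_conv", "k_e", "k_2", "n_2", "n_c", "kon_mI", "koff_mI",
               "kon_PI", "koff_PI", "P0", "relax_rate")) {
    if (!is.finite(pars[[nm]]) || pars[[nm]] < 0) {
      stop(sprintf("%s must be a finite non-negative number", nm))
    }
  }
  structure(pars, class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Aggregation kinetic model (scheme:", x$scheme, ")\n")
  cat(sprintf("  k_conv = %g s^-1, k_e = %g M^-1 s^-1, k_2 = %g, n_2 = %g, n_c = %d\n",
              x$k_conv, x$k_e, x$k_2, x$n_2, as.integer(x$n_c)))
  if (x$kon_mI > 0) cat(sprintf("  m + I:  kon = %g, koff = %g (KD = %s)\n",
                                x$kon_mI, x$koff_mI, format_molar(x$koff_mI / x$kon_mI)))
  if (x$kon_PI > 0) cat(sprintf("  P + I:  kon = %g, koff = %g (KD = %s)\n",
                                x$kon_PI, x$koff_PI, format_molar(x$koff_PI / x$kon_PI)))
  cat("  P0 =", format_molar(x$P0), "\n")
  invisible(x)
}

# full reaction-network RHS; y = (m, I, mI, D, Dstar, T, P, PI, M)
.agg_rhs_full <- function(t, y, pm) {
  m <- y[1]; I <- y[2]; mI <- y[3]; D <- y[4]; Ds <- y[5]
  T_ <- y[6]; P <- y[7]; PI <- y[8]
  eq <- pm$eq
  kb <- pm$relax_rate
  # reversible pre-nucleation steps (dissociation at relax_rate)
  v1 <- (kb / eq$KD1) * m^2 - kb * D              # 2m -> D
  v1s <- (kb / eq$KD1_star) * m^2 - kb * Ds       # 2m -> D*
  v2 <- (kb / eq$KD2) * D^2 - kb * T_             # 2D -> T
  vB <- pm$kon_mI * m * I - pm$koff_mI * mI       # m + I -> mI
  vP <- pm$kon_PI * P * I - pm$koff_PI * PI       # P + I -> PI
  # irreversible cascade
  r_prim <- pm$k_conv * T_
  r_sec <- if (pm$k_2 > 0 && y[9] > 0 && m > 0) pm$k_2 * m^pm$n_2 * y[9] else 0
  r_el <- 2 * pm$k_e * m * P
  dm <- -2 * v1 - 2 * v1s - vB - pm$n_c * r_sec - r_el
  dI <- -vB - vP
  dmI <- vB
  dD <- v1 - 2 * v2
  dDs <- v1s
  dT <- v2 - r_prim
  dP <- r_prim + r_sec - vP
  dPI <- vP
  dM <- pm$n_c * (r_prim + r_sec) + r_el
  list(c(dm, dI, dmI, dD, dDs, dT, dP, dPI, dM))
}

# quasi-equilibrium RHS; y = (P, PI, M). The pre-nucleation pool
# P_tot - M is re-equilibrated algebraically at every evaluation; the
# previous monomer root seeds the next Newton solve.
.agg_rhs_qe <- function(t, y, pm) {
  P <- y[1]; PI <- y[2]; M <- y[3]
  pool <- max(pm$P_tot - M, 0)
  I_pool <- max(pm$I_tot - PI, 0)
  eq <- pm$eq_solver
  m <- .solve_monomer(eq, pool, I_pool, guess = pm$cache$m)
  pm$cache$m <- m
  T_ <- (m^2 / eq$KD1)^2 / eq$KD2
  I_free <- if (!is.na(eq$KD_mI) && I_pool > 0) I_pool / (1 + m / eq$KD_mI) else I_pool
  r_prim <- pm$k_conv * T_
  r_sec <- if (pm$k_2 > 0 && M > 0 && m > 0) pm$k_2 * m^pm$n_2 * M else 0
  vP <- pm$kon_PI * P * I_free - pm$koff_PI * PI
  r_el <- 2 * pm$k_e * m * P
  list(c(r_prim + r_sec - vP, vP, pm$n_c * (r_prim + r_sec) + r_el))
}

#' Integrate the aggregation cascade
#'
#' Solves the full reaction network with a stiff integrator
#' (`deSolve::lsoda`): pre-nucleation steps as explicit fast reversible
#' mass-action reactions (dissociation rates `relax_rate`, forward rates
#' derived from the equilibrium constants), the irreversible cascade, and
#' the inhibitor-binding reactions of the chosen scheme. A
#' quasi-equilibrium mode (`mode = "quasi_equilibrium"`) instead
#' re-equilibrates the pre-nucleation pool algebraically at every
#' derivative evaluation and integrates only P, PI and M; the two modes
#' agree closely when `relax_rate` is fast relative to aggregation.
#'
#' Initial conditions: the pre-nucleation species start at their
#' equilibrium values for (`P_tot - n_c * P0`, `I_tot`), nuclei at `P0`,
#' fibril mass at `n_c * P0` (a nucleus carries its monomer units in M).
#'
#' @param model a [kinetic_model].
#' @param totals a [totals] object.
#' @param t_grid increasing time grid starting at 0, s.
#' @param mode `"full"` or `"quasi_equilibrium"`.
#' @param rtol,atol integrator tolerances.
#' @return object of class `time_course`: list with `t` and a data.frame
#'   `trajectories` (columns m, mI, D, D_star, T, P_free, PI, M, I_free).
#' @export
simulate_aggregation <- function(model, totals, t_grid,
                                 mode = c("full", "quasi_equilibrium"),
                                 rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(model, "kinetic_model"), inherits(totals, "totals"))
  mode <- match.arg(mode)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be increasing and start at 0")
  }
  eq <- model$equilibrium
  # initial pre-nucleation equilibrium over the non-fibril pool.
  # The monomer-binding reaction participates explicitly in the full
  # network, so the initial equilibrium includes mI when the scheme has it.
  eq_init <- eq
  if (!model$scheme %in% c("monomer_binding", "dual")) eq_init$KD_mI <- NA_real_
  P0 <- model$P0
  pool0 <- totals$P_tot - model$n_c * P0
  if (pool0 < 0) stop("P0 exceeds total protein")
  st0 <- solve_prenucleation_equilibrium(eq_init, totals(pool0, totals$I_tot))

  if (mode == "full") {
    y0 <- c(m = st0$m, I = st0$I_free, mI = st0$mI, D = st0$D,
            Dstar = st0$D_star, T = st0$T, P = P0, PI = 0,
            M = model$n_c * P0)
    pm <- list(eq = eq_init, relax_rate = model$relax_rate,
               kon_mI = model$kon_mI, koff_mI = model$koff_mI,
               kon_PI = model$kon_PI, koff_PI = model$koff_PI,
               k_conv = model$k_conv, k_e = model$k_e, k_2 = model$k_2,
               n_2 = model$n_2, n_c = model$n_c)
    sol <- deSolve::lsoda(y0, t_grid, .agg_rhs_full, pm,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) stop("stiff integrator failed on the aggregation network")
    sol <- as.data.frame(sol)
    traj <- data.frame(m = sol$m, mI = sol$mI, D = sol$D, D_star = sol$Dstar,
                       T = sol$T, P_free = sol$P, PI = sol$PI, M = sol$M,
                       I_free = sol$I)
  } else {
    pm <- list(eq_solver = eq_init, P_tot = totals$P_tot, I_tot = totals$I_tot,
               kon_PI = model$kon_PI, koff_PI = model$koff_PI,
               k_conv = model$k_conv, k_e = model$k_e, k_2 = model$k_2,
               n_2 = model$n_2, n_c = model$n_c,
               cache = new.env(parent = emptyenv()))
    pm$cache$m <- st0$m
    y0 <- c(P = P0, PI = 0, M = model$n_c * P0)
    sol <- deSolve::lsoda(y0, t_grid, .agg_rhs_qe, pm,
                          rtol = max(rtol, 1e-10), atol = max(atol, 1e-18),
                          maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) stop("stiff integrator failed (quasi-equilibrium mode)")
    sol <- as.data.frame(sol)
    # reconstruct the fast species at each output time
    rows <- lapply(seq_len(nrow(sol)), function(i) {
      st <- solve_prenucleation_equilibrium(
        pm$eq_solver,
        totals(max(pm$P_tot - sol$M[i], 0), max(pm$I_tot - sol$PI[i], 0)))
      c(m = st$m, mI = st$mI, D = st$D, D_star = st$D_star, T = st$T,
        I_free = st$I_free)
    })
    fast <- do.call(rbind, rows)
    traj <- data.frame(m = fast[, "m"], mI = fast[, "mI"], D = fast[, "D"],
                       D_star = fast[, "D_star"], T = fast[, "T"],
                       P_free = sol$P, PI = sol$PI, M = sol$M,
                       I_free = fast[, "I_free"])
  }
  neg <- min(as.matrix(traj))
  if (neg < -1e-6 * max(totals$P_tot, totals$I_tot, 1e-12)) {
    stop(sprintf("negative concentrations beyond tolerance (min %.3e M)", neg))
  }
  traj[traj < 0] <- 0
  structure(list(t = t_grid, trajectories = traj, totals = totals,
                 model = model, mode = mode),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Aggregation time course: %d time points over %g s (%s mode, scheme %s)\n",
              length(x$t), max(x$t), x$mode, x$model$scheme))
  last <- x$trajectories[nrow(x$trajectories), ]
  cat(sprintf("  final fibril mass M = %s (%.1f%% of P_tot)\n",
              format_molar(last$M), 100 * last$M / max(x$totals$P_tot, 1e-300)))
  invisible(x)
}

#' Monomer-unit conservation residual of a time course
#'
#' Relative deviation of `m + mI + 2D + 2D* + 4T + M` from `P_tot` at
#' each output time. P and PI are number concentrations whose monomer
#' content is already counted inside M.
#'
#' @param tc a `time_course`.
#' @return numeric vector of relative residuals.
#' @export
conservation_residual <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  tr <- tc$trajectories
  total <- tr$m + tr$mI + 2 * tr$D + 2 * tr$D_star + 4 * tr$T + tr$M
  (total - tc$totals$P_tot) / tc$totals$P_tot
}

#' Compare monomer- and nucleus-sequestration schemes
#'
#' Runs two kinetic models sharing all non-inhibitor parameters and
#' reports the m(t) and P_free(t) trajectories under each together with
#' the time at which their PRD-proxy signals (visible monomer-unit
#' fraction, 1 - M/P_tot) first differ by `threshold`. With pre-existing
#' nuclei (P0 > 0) both schemes start from identical elongation-dominated
#' kinetics and diverge only as de-novo nucleus formation and monomer
#' depletion proceed differently.
#'
#' @param model_m,model_P two [kinetic_model]s (e.g. monomer- and
#'   nucleus-binding) sharing non-inhibitor parameters.
#' @param totals a [totals] object.
#' @param t_grid time grid, s.
#' @param threshold PRD-signal difference defining divergence.
#' @param mode integration mode passed to [simulate_aggregation].
#' @return list with class `scheme_comparison`: trajectories, signal
#'   difference, and `t_diverge` (NA if never crossed).
#' @export
compare_inhibition_schemes <- function(model_m, model_P, totals, t_grid,
                                       threshold = 0.01, mode = "full") {
  tc_m <- simulate_aggregation(model_m, totals, t_grid, mode = mode)
  tc_P <- simulate_aggregation(model_P, totals, t_grid, mode = mode)
  sig_m <- 1 - tc_m$trajectories$M / totals$P_tot
  sig_P <- 1 - tc_P$trajectories$M / totals$P_tot
  d <- abs(sig_m - sig_P)
  idx <- which(d >= threshold)
  structure(list(t = t_grid,
                 m = cbind(model_m = tc_m$trajectories$m,
                           model_P = tc_P$trajectories$m),
                 P_free = cbind(model_m = tc_m$trajectories$P_free,
                                model_P = tc_P$trajectories$P_free),
                 signal_difference = d,
                 t_diverge = if (length(idx)) t_grid[min(idx)] else NA_real_,
                 threshold = threshold),
            class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("Inhibition-scheme comparison\n")
  if (is.na(x$t_diverge)) {
    cat(sprintf("  PRD proxies never differ by %g over %g s\n",
                x$threshold, max(x$t)))
  } else {
    cat(sprintf("  PRD proxies first differ by %g at t = %g s (%.2f h)\n",
                x$threshold, x$t_diverge, x$t_diverge / 3600))
  }
  invisible(x)
}
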