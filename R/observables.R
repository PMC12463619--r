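#' Observable settings
#'
#' Controls how kinetic trajectories are turned into NMR observables.
#' Species in fast exchange with the monomer (m, mI, D, D*, T)
#' contribute to the single observed cross-peak and are NMR-visible;
#' fibril-phase species (P, PI, M) are broadened beyond detection.
#'
#' @param R2_ref reference linewidth-equivalent relaxation rate of the
#'   NT resonance absent exchange, s^-1.
#' @param visible character vector of visible species among
#'   `c("m", "mI", "D", "D_star", "T")`.
#' @return object of class `observable_settings`.
#' @export
observable_settings <- function(R2_ref = 10,
                                visible = c("m", "mI", "D", "D_star", "T")) {
  if (R2_ref <= 0) stop("R2_ref must be positive")
  allowed <- c("m", "mI", "D", "D_star", "T")
  if (!all(visible %in% allowed)) stop("unknown species in 'visible'")
  structure(list(R2_ref = R2_ref, visible = visible),
            class = "observable_settings")
}

# visible monomer-unit signal fraction at each time point
.visible_signal <- function(tc, settings) {
  tr <- tc$trajectories
  stoich <- c(m = 1, mI = 1, D = 2, D_star = 2, T = 4)
  sig <- rep(0, nrow(tr))
  for (sp in settings$visible) sig <- sig + stoich[[sp]] * tr[[sp]]
  sig / tc$totals$P_tot
}

#' PRD intensity decay
#'
#' The proline-rich domain resonances are free of fast-exchange
#' broadening, so their intensity simply tracks the fraction of protein
#' still in the NMR-visible (non-fibrillar) pool:
#' `signal(t) = sum_visible stoich * [X](t) / P_tot`. The decay is
#' monotone non-increasing for irreversible aggregation and equals 1 at
#' t = 0 when no fibril mass is present initially.
#'
#' @param tc a `time_course` from [simulate_aggregation].
#' @param settings an [observable_settings].
#' @return data.frame with columns `t` (s) and `intensity` (normalized).
#' @export
prd_decay <- function(tc, settings = observable_settings()) {
  stopifnot(inherits(tc, "time_course"))
  data.frame(t = tc$t, intensity = .visible_signal(tc, settings))
}

# rebuild the instantaneous exchange system from a trajectory row
.exchange_at <- function(tc, i, fixture) {
  tr <- tc$trajectories[i, ]
  st <- .species_state(tr$m, tr$D, tr$D_star, tr$T, tr$mI, tr$I_free,
                       totals(tr$m + tr$mI + 2 * tr$D + 2 * tr$D_star + 4 * tr$T,
                              tr$I_free + tr$mI))
  build_exchange_system(st,
                        tau_mDstar = fixture$tau_mDstar,
                        tau_mT = fixture$tau_mT,
                        shifts = fixture$shifts,
                        R2_0 = fixture$R2_0,
                        topology = fixture$topology %||% "chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exchange fixture
#'
#' Bundles the exchange parameters (timescales, oligomer shift offsets,
#' intrinsic relaxation) needed to evaluate exchange observables along a
#' kinetic trajectory. Oligomer chemical shifts are not observable
#' directly and enter as fixture parameters.
#'
#' @param tau_mDstar,tau_mT exchange timescales, s.
#' @param shifts named ppm offsets for `D`, `D_star`, `T` (and `mI`).
#' @param R2_0 intrinsic transverse relaxation rate, s^-1.
#' @param context a [spectrometer_context].
#' @param topology exchange topology, `"chain"` or `"star"`.
#' @return list of class `exchange_fixture`.
#' @export
exchange_fixture <- function(tau_mDstar = 750e-6, tau_mT = 50e-6,
                             shifts = c(D = 1.5, D_star = 1.0, T = 2.5),
                             R2_0 = 10,
                             context = spectrometer_context(),
                             topology = "chain") {
  structure(list(tau_mDstar = tau_mDstar, tau_mT = tau_mT, shifts = shifts,
                 R2_0 = R2_0, context = context, topology = topology),
            class = "exchange_fixture")
}

#' Cross-peak volume and intensity time course
#'
#' NT-region cross-peak volume is proportional to the NMR-visible
#' monomer-unit signal; peak intensity (height) additionally scales
#' inversely with the linewidth, modelled as a Lorentzian with width
#' proportional to `R2_ref + Rex(t)`. `Rex(t)` is evaluated adiabatically
#' by rebuilding the exchange system from the instantaneous free-species
#' concentrations at each output time. Because the tetramer population
#' scales steeply with monomer, the early drop in monomer relieves
#' exchange broadening faster than it removes signal, producing the
#' characteristic interior maximum in intensity while volume decreases
#' monotonically.
#'
#' Volume is normalized to 1 at t = 0; intensity to its exchange-broadened
#' value at t = 0.
#'
#' @param tc a `time_course`.
#' @param fixture an [exchange_fixture].
#' @param settings an [observable_settings].
#' @return data.frame with columns `t`, `V`, `I`, `VI_ratio`, `Rex`.
#' @export
nt_volume_intensity <- function(tc, fixture = exchange_fixture(),
                                settings = observable_settings()) {
  stopifnot(inherits(tc, "time_course"))
  V <- .visible_signal(tc, settings)
  Rex <- vapply(seq_along(tc$t), function(i) {
    if (V[i] <= 0) return(0)
    sys <- .exchange_at(tc, i, fixture)
    unname(observed_lineshape_parameters(sys, fixture$context)["Rex"])
  }, numeric(1))
  I_raw <- V * settings$R2_ref / (settings$R2_ref + Rex)
  V_n <- V / V[1]
  I_n <- I_raw / I_raw[1]
  data.frame(t = tc$t, V = V_n, I = I_n, VI_ratio = V_n / I_n, Rex = Rex)
}

#' Time-dependent exchange-induced chemical shift
#'
#' Evaluates the fast-limit exchange-induced shift from the instantaneous
#' populations at each output time of a kinetic trajectory. As free
#' monomer and oligomers deplete into fibrils, the observed resonance
#' relaxes back toward the pure-monomer position, so the shift decreases
#' over time in an aggregating run.
#'
#' @param tc a `time_course`.
#' @param fixture an [exchange_fixture].
#' @return data.frame with columns `t` (s) and `delta_ex` (ppm).
#' @export
delta_ex_timecourse <- function(tc, fixture = exchange_fixture()) {
  stopifnot(inherits(tc, "time_course"))
  dx <- vapply(seq_along(tc$t), function(i) {
    tr <- tc$trajectories[i, ]
    if (tr$m + tr$mI + 2 * tr$D + 2 * tr$D_star + 4 * tr$T <= 0) return(0)
    delta_ex_fast(.exchange_at(tc, i, fixture))
  }, numeric(1))
  data.frame(t = tc$t, delta_ex = dx)
}

#' Concentration-dependent static observables
#'
#' Computes the equilibrium (t = 0) observables measured in
#' concentration-series experiments: exchange-induced shift, V/I ratio
#' and optionally R1rho and CPMG dispersion, for each combination of
#' total protein and inhibitor concentration.
#'
#' @param eq an [equilibrium_model].
#' @param P_tot,I_tot concentration vectors, molar (recycled).
#' @param fixture an [exchange_fixture].
#' @param settings an [observable_settings].
#' @return data.frame with columns `p_tot`, `i_tot`, `delta_ex` (ppm),
#'   `Rex` (s^-1), `VI_ratio`.
#' @export
static_observables <- function(eq, P_tot, I_tot = 0,
                               fixture = exchange_fixture(),
                               settings = observable_settings()) {
  n <- max(length(P_tot), length(I_tot))
  P_tot <- rep_len(vapply(P_tot, parse_quantity, numeric(1)), n)
  I_tot <- rep_len(vapply(I_tot, parse_quantity, numeric(1)), n)
  rows <- lapply(seq_len(n), function(i) {
    st <- solve_prenucleation_equilibrium(eq, totals(P_tot[i], I_tot[i]))
    sys <- build_exchange_system(st, tau_mDstar = fixture$tau_mDstar,
                                 tau_mT = fixture$tau_mT,
                                 shifts = fixture$shifts, R2_0 = fixture$R2_0,
                                 topology = fixture$topology %||% "chain")
    obs <- observed_lineshape_parameters(sys, fixture$context)
    Rex <- unname(obs["Rex"])
    # V/I ratio: height suppressed by exchange broadening relative to area
    data.frame(p_tot = P_tot[i], i_tot = I_tot[i],
               delta_ex = delta_ex_fast(sys), Rex = Rex,
               VI_ratio = (settings$R2_ref + Rex) / settings$R2_ref)
  })
  do.call(rbind, rows)
}
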