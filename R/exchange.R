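#' Spectrometer context
#'
#' Holds the nucleus Larmor frequency used to interconvert chemical-shift
#' offsets in ppm and angular frequencies in rad/s. The default, 60.8
#' MHz, is the 15N Larmor frequency at a 14.1 T (600 MHz 1H) magnet.
#'
#' @param B0_frequency nucleus Larmor frequency, MHz.
#' @param nucleus label, e.g. `"15N"` or `"13C"`.
#' @return object of class `spectrometer_context`.
#' @export
spectrometer_context <- function(B0_frequency = 60.8, nucleus = "15N") {
  stopifnot(is.numeric(B0_frequency), B0_frequency > 0)
  structure(list(B0_frequency = B0_frequency, nucleus = nucleus),
            class = "spectrometer_context")
}

ppm_to_rad <- function(delta_ppm, context) {
  2 * pi * delta_ppm * context$B0_frequency  # ppm * MHz = Hz
}

#' N-site chemical exchange system
#'
#' Low-level constructor: populations, chemical-shift offsets relative to
#' the monomer, intrinsic relaxation, and a first-order exchange rate
#' matrix `K` (columns sum to zero; `K[i,j]` is the rate j -> i). The
#' matrix must have the supplied populations as its stationary vector and
#' satisfy detailed balance on connected pairs.
#'
#' @param p named population vector (sums to 1, non-negative).
#' @param delta chemical-shift offsets vs the monomer, ppm (same names).
#' @param K exchange rate matrix, s^-1, or `NULL` for no exchange.
#' @param R2_0 intrinsic transverse relaxation rate, s^-1 (scalar baseline
#'   or per-site vector).
#' @param R1 longitudinal relaxation rate, s^-1.
#' @return object of class `exchange_system`.
#' @export
exchange_system <- function(p, delta, K = NULL, R2_0 = 10, R1 = 0) {
  n <- length(p)
  stopifnot(length(delta) == n, all(p >= -1e-12))
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-8) stop("populations must sum to 1")
  p <- p / sum(p)
  if (is.null(names(p))) names(p) <- paste0("site", seq_len(n))
  if (is.null(K)) K <- matrix(0, n, n)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  if (max(abs(colSums(K))) > 1e-6 * max(1, max(abs(K)))) {
    stop("exchange matrix columns must sum to zero")
  }
  # stationarity: K p = 0
  if (max(abs(K %*% p)) > 1e-6 * max(1, max(abs(K)))) {
    stop("populations are not stationary under the exchange matrix")
  }
  # detailed balance on connected pairs
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (K[i, j] > 0 || K[j, i] > 0)) {
      flux_ij <- K[i, j] * p[j]; flux_ji <- K[j, i] * p[i]
      if (abs(flux_ij - flux_ji) > 1e-6 * max(flux_ij, flux_ji, 1e-300)) {
        stop("exchange matrix violates detailed balance")
      }
    }
  }
  R2 <- if (length(R2_0) == 1L) rep(R2_0, n) else R2_0
  stopifnot(length(R2) == n, all(R2 >= 0))
  structure(list(p = p, delta = stats::setNames(as.numeric(delta), names(p)),
                 K = K, R2 = R2, R2_0 = min(R2), R1 = R1),
            class = "exchange_system")
}

#' @export
print.exchange_system <- function(x, ...) {
  cat("Chemical exchange system (", length(x$p), "sites )\n")
  df <- data.frame(site = names(x$p), p = round(x$p, 5),
                   delta_ppm = x$delta, R2_s = x$R2)
  print(df, row.names = FALSE)
  kex <- -diag(x$K)
  cat("  site exit rates (s^-1):", paste(signif(kex, 4), collapse = ", "), "\n")
  invisible(x)
}

# pairwise connection obeying detailed balance: within the pair (i, j)
# k_ex = k_ij + k_ji and rates split proportionally to the partner's
# population, k(i->j) = k_ex * p_j / (p_i + p_j).
.connect_pair <- function(K, p, i, j, k_ex) {
  psum <- p[i] + p[j]
  if (psum <= 0) return(K)
  kf <- k_ex * p[j] / psum   # i -> j
  kb <- k_ex * p[i] / psum   # j -> i
  K[j, i] <- K[j, i] + kf; K[i, i] <- K[i, i] - kf
  K[i, j] <- K[i, j] + kb; K[j, j] <- K[j, j] - kb
  K
}

#' Build an exchange system from an equilibrium state
#'
#' Converts a solved pre-nucleation [species_state] into an N-site
#' exchange system using monomer-unit population weights over the
#' NMR-visible fast-exchanging species. Two topologies are supported:
#' the full linear productive chain `m <-> D <-> T` plus the off-pathway
#' branch `m <-> D*` (default), or a lumped star in which D and T are
#' merged into a single productive oligomer site exchanging directly
#' with m. Exchange timescales are specified as `tau = 1/k_ex`, with
#' `k_ex` the sum of forward and reverse rates of the step; rates are
#' split between the partners in proportion to their populations so that
#' detailed balance holds.
#'
#' The monomer-inhibitor complex mI binds on a much slower (ms-s)
#' timescale than the microsecond oligomerization steps and is excluded
#' from the exchange network by default: its population is dropped and
#' the remaining sites renormalized, so a large mI pool dilutes the
#' exchanging populations. Set `include_mI = TRUE` to include it as an
#' additional site exchanging with m at `tau_mI`.
#'
#' @param state a [species_state].
#' @param tau_mDstar exchange timescale of the m <-> D* step, s
#'   (~750 us in huntingtin exon 1).
#' @param tau_mT exchange timescale of the productive branch, s (~50 us);
#'   applied to each step of the linear chain, or to the single lumped
#'   m <-> T step.
#' @param shifts named offsets (ppm vs m) for `D`, `D_star`, `T`, and
#'   optionally `mI`; missing entries default to 0.
#' @param R2_0 intrinsic transverse relaxation rate, s^-1.
#' @param R1 longitudinal rate, s^-1 (0 by default: on-resonance R1rho
#'   dispersion is reported as R2_0 + Rex).
#' @param topology `"chain"` (default) or `"star"`.
#' @param include_mI include mI as an exchange-visible site.
#' @param tau_mI binding timescale used when `include_mI = TRUE`, s.
#' @return an [exchange_system].
#' @export
build_exchange_system <- function(state, tau_mDstar = 750e-6, tau_mT = 50e-6,
                                  shifts = c(D = 0, D_star = 0, T = 0),
                                  R2_0 = 10, R1 = 0,
                                  topology = c("chain", "star"),
                                  include_mI = FALSE, tau_mI = 10e-3) {
  stopifnot(inherits(state, "species_state"))
  topology <- match.arg(topology)
  if (tau_mDstar <= 0 || tau_mT <= 0) stop("exchange timescales must be positive")
  fr <- population_fractions(state)
  if (length(fr) == 0) stop("cannot build an exchange system from an empty state")
  sh <- function(nm) if (nm %in% names(shifts)) as.numeric(shifts[[nm]]) else 0

  sites <- c("m", "D", "D_star", "T")
  if (include_mI) sites <- c(sites, "mI")
  p <- fr[sites]
  names(p) <- sites
  p[is.na(p)] <- 0
  p <- p / sum(p)  # renormalize over exchange-visible species

  if (topology == "star") {
    # lump D and T into one productive oligomer site, weight-averaged shift
    pT <- p[["D"]] + p[["T"]]
    dT <- if (pT > 0) (p[["D"]] * sh("D") + p[["T"]] * sh("T")) / pT else sh("T")
    sites2 <- c("m", "D_star", "T")
    p2 <- c(m = p[["m"]], D_star = p[["D_star"]], T = pT)
    delta <- c(m = 0, D_star = sh("D_star"), T = dT)
    if (include_mI) {
      sites2 <- c(sites2, "mI"); p2 <- c(p2, mI = p[["mI"]])
      delta <- c(delta, mI = sh("mI"))
    }
    K <- matrix(0, length(p2), length(p2), dimnames = list(sites2, sites2))
    idx <- function(s) match(s, sites2)
    if (p2[["D_star"]] > 0) K <- .connect_pair(K, p2, idx("m"), idx("D_star"), 1 / tau_mDstar)
    if (p2[["T"]] > 0) K <- .connect_pair(K, p2, idx("m"), idx("T"), 1 / tau_mT)
    if (include_mI && p2[["mI"]] > 0) K <- .connect_pair(K, p2, idx("m"), idx("mI"), 1 / tau_mI)
    return(exchange_system(p2, delta, K, R2_0 = R2_0, R1 = R1))
  }

  delta <- c(m = 0, D = sh("D"), D_star = sh("D_star"), T = sh("T"))
  if (include_mI) delta <- c(delta, mI = sh("mI"))
  K <- matrix(0, length(p), length(p), dimnames = list(sites, sites))
  idx <- function(s) match(s, sites)
  if (p[["D_star"]] > 0) K <- .connect_pair(K, p, idx("m"), idx("D_star"), 1 / tau_mDstar)
  if (p[["D"]] > 0) K <- .connect_pair(K, p, idx("m"), idx("D"), 1 / tau_mT)
  if (p[["D"]] > 0 && p[["T"]] > 0) K <- .connect_pair(K, p, idx("D"), idx("T"), 1 / tau_mT)
  if (include_mI && p[["mI"]] > 0) K <- .connect_pair(K, p, idx("m"), idx("mI"), 1 / tau_mI)
  exchange_system(p, delta, K, R2_0 = R2_0, R1 = R1)
}

#' Two-site exchange system
#'
#' Convenience constructor for a minor state b exchanging with a major
#' state a, parameterized by the minor population, shift difference and
#' total exchange rate `k_ex = k_ab + k_ba`.
#'
#' @param p_b minor-state population.
#' @param delta_b shift of the minor state vs the major, ppm.
#' @param k_ex total exchange rate, s^-1.
#' @param R2_0 intrinsic transverse relaxation rate, s^-1.
#' @param R1 longitudinal rate, s^-1.
#' @return an [exchange_system].
#' @export
two_site_system <- function(p_b, delta_b, k_ex, R2_0 = 10, R1 = 0) {
  p <- c(a = 1 - p_b, b = p_b)
  K <- matrix(0, 2, 2, dimnames = list(names(p), names(p)))
  K <- .connect_pair(K, p, 1, 2, k_ex)
  exchange_system(p, c(a = 0, b = delta_b), K, R2_0 = R2_0, R1 = R1)
}

#' Exchange-induced chemical shift, fast-exchange limit
#'
#' In the fast limit the observed resonance sits at the population
#' average of the site shifts, so its displacement from the pure-monomer
#' position is \eqn{\delta_{ex} = \sum_i p_i \delta_i} (ppm).
#'
#' @param system an [exchange_system].
#' @return exchange-induced shift, ppm.
#' @export
delta_ex_fast <- function(system) {
  stopifnot(inherits(system, "exchange_system"))
  sum(system$p * system$delta)
}

# free-precession Bloch-McConnell evolution matrix for transverse
# magnetization M+ : dM/dt = L M with L = K - diag(R2) + i*diag(Omega)
.bm_matrix <- function(system, context, carrier_ppm = 0) {
  omega <- ppm_to_rad(system$delta - carrier_ppm, context)
  system$K - diag(system$R2, length(system$p)) + 1i * diag(omega, length(system$p))
}

#' Observed line position and exchange broadening
#'
#' Computes the complex eigenvalue of the free-evolution Bloch-McConnell
#' matrix whose eigenvector overlaps most with the population vector (the
#' observable coherence). The imaginary part gives the observed shift
#' (converted to ppm); the real part gives the decay rate, from which the
#' exchange contribution `Rex = -Re(lambda) - R2_0` is extracted.
#'
#' @param system an [exchange_system].
#' @param context a [spectrometer_context].
#' @return named numeric vector `c(shift_ppm, Rex)`.
#' @export
observed_lineshape_parameters <- function(system, context = spectrometer_context()) {
  stopifnot(inherits(system, "exchange_system"))
  L <- .bm_matrix(system, context)
  ev <- eigen(L)
  # overlap of each (detected) eigenmode with the equilibrium coherence
  w <- abs(t(Conj(ev$vectors)) %*% system$p) /
    sqrt(colSums(abs(ev$vectors)^2))
  ord <- order(w, decreasing = TRUE)
  if (length(ord) > 1 && abs(w[ord[1]] - w[ord[2]]) < 1e-12 * max(w)) {
    warning("degenerate dominant eigenmodes; tie broken by overlap order")
  }
  lam <- ev$values[ord[1]]
  shift_ppm <- Im(lam) / (2 * pi * context$B0_frequency)
  c(shift_ppm = shift_ppm, Rex = -Re(lam) - system$R2_0)
}

# matrix exponential of a (small, possibly complex) matrix by
# eigen-decomposition with a scaling-and-squaring Taylor fallback
.cexpm <- function(A) {
  ev <- try(eigen(A), silent = TRUE)
  if (!inherits(ev, "try-error")) {
    V <- ev$vectors
    rc <- try(solve(V), silent = TRUE)
    if (!inherits(rc, "try-error")) {
      err <- max(abs(V %*% rc - diag(nrow(A))))
      if (is.finite(err) && err < 1e-8) {
        return(V %*% (exp(ev$values) * rc))
      }
    }
  }
  # fallback: scaling and squaring with a truncated Taylor series
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))))
  B <- A / 2^s
  E <- diag(1 + 0i, n); term <- diag(1 + 0i, n)
  for (k in 1:20) {
    term <- term %*% B / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Simulate CPMG relaxation dispersion
#'
#' Propagates in-phase transverse magnetization through the repeating
#' tau - 180 - tau echo blocks of a CPMG experiment (tau = 1/(4 nu_cpmg),
#' ideal instantaneous 180-degree pulses implemented as complex
#' conjugation) using the full N-site Bloch-McConnell free-evolution
#' matrix, and reports
#' \eqn{R_{2,eff}(\nu) = -\ln(S(T_{relax})/S(0)) / T_{relax}}.
#'
#' @param system an [exchange_system].
#' @param context a [spectrometer_context].
#' @param nu_cpmg CPMG pulsing frequencies, Hz. The number of echo blocks
#'   `2 * nu * T_relax` is rounded to the nearest even integer >= 2 and
#'   the actual total relaxation time used accordingly.
#' @param T_relax total relaxation delay, s.
#' @return data.frame with columns `nu_cpmg` (Hz) and `R2_eff` (s^-1).
#' @export
simulate_cpmg <- function(system, context = spectrometer_context(),
                          nu_cpmg = c(50, 100, 200, 400, 800, 1600),
                          T_relax = 0.04) {
  stopifnot(inherits(system, "exchange_system"))
  if (any(nu_cpmg <= 0)) stop("nu_cpmg must be positive")
  if (T_relax <= 0) stop("T_relax must be positive")
  L <- .bm_matrix(system, context)
  M0 <- as.complex(system$p)
  S0 <- Re(sum(M0))
  R2_eff <- vapply(nu_cpmg, function(nu) {
    n_blocks <- max(2L, 2L * round(nu * T_relax))  # even echo count
    tau <- 1 / (4 * nu)
    P <- .cexpm(L * tau)
    M <- M0
    for (b in seq_len(n_blocks)) {
      M <- P %*% M
      M <- Conj(M)       # ideal 180-degree pulse
      M <- P %*% M
    }
    T_actual <- n_blocks * 2 * tau
    S <- abs(sum(M))
    -log(S / S0) / T_actual
  }, numeric(1))
  data.frame(nu_cpmg = nu_cpmg, R2_eff = R2_eff)
}

# rotating-frame evolution matrix, spin lock along x, on resonance with
# the population-average line. Block layout: (Mx, My, Mz) per site.
.r1rho_matrix <- function(system, context, omega1_hz) {
  n <- length(system$p)
  omega <- ppm_to_rad(system$delta, context)
  omega <- omega - sum(system$p * omega)  # carrier at observed line
  w1 <- 2 * pi * omega1_hz
  A <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    r <- (3 * (i - 1) + 1):(3 * i)
    # relaxation + offset rotation about z + spin lock about x
    A[r, r] <- matrix(c(-system$R2[i], -omega[i],     0,
                        omega[i],      -system$R2[i], -w1,
                        0,             w1,            -system$R1), 3, 3,
                      byrow = TRUE)
  }
  A + kronecker(system$K, diag(3))
}

#' Simulate on-resonance R1rho dispersion
#'
#' Rotating-frame relaxation under a spin-lock field applied on resonance
#' with the observed (population-average) line. The rate is the decay of
#' the eigenmode of the full Bloch-McConnell rotating-frame matrix with
#' maximal overlap with the spin-locked initial state (x-magnetization
#' weighted by populations). With `R1 = 0` (default) the result is
#' `R2_0 + Rex(omega1)`; increasing spin-lock strength quenches Rex.
#'
#' @param system an [exchange_system].
#' @param context a [spectrometer_context].
#' @param omega1 spin-lock field strengths, Hz.
#' @return data.frame with columns `omega1` (Hz) and `R1rho` (s^-1).
#' @export
simulate_r1rho <- function(system, context = spectrometer_context(),
                           omega1 = c(750, 1500, 3000)) {
  stopifnot(inherits(system, "exchange_system"))
  if (any(omega1 <= 0)) stop("spin-lock strengths must be positive")
  n <- length(system$p)
  M0 <- numeric(3 * n)
  M0[seq(1, 3 * n, by = 3)] <- system$p  # along x
  R1rho <- vapply(omega1, function(w1) {
    A <- .r1rho_matrix(system, context, w1)
    ev <- eigen(A)
    w <- abs(t(Conj(ev$vectors)) %*% M0) / sqrt(colSums(abs(ev$vectors)^2))
    -Re(ev$values[which.max(w)])
  }, numeric(1))
  data.frame(omega1 = omega1, R1rho = R1rho)
}
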