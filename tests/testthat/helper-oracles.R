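# Independent oracles used to validate the package's forward models.
# These implementations deliberately avoid the package's code paths.

# brute-force equilibrium: dense log-grid search over free monomer
# minimizing the protein-balance residual
grid_equilibrium <- function(KD1, KD1_star, KD2, P_tot, I_tot = 0,
                             KD_mI = NA, n_grid = 1e6) {
  m <- exp(seq(log(P_tot * 1e-8), log(P_tot), length.out = n_grid))
  mI <- if (!is.na(KD_mI) && I_tot > 0) {
    m * (I_tot / (1 + m / KD_mI)) / KD_mI
  } else 0
  D <- m^2 / KD1
  Ds <- m^2 / KD1_star
  T_ <- D^2 / KD2
  resid <- abs(m + mI + 2 * D + 2 * Ds + 4 * T_ - P_tot)
  i <- which.min(resid)
  list(m = m[i], D = D[i], D_star = Ds[i], T = T_[i],
       mI = if (length(mI) > 1) mI[i] else 0)
}

# Carver-Richards closed form for two-site CPMG dispersion
# (equal intrinsic R2 in both states)
carver_richards <- function(nu_cpmg, p_a, p_b, dw_rad, k_ex, R2_0) {
  k_ab <- p_b * k_ex
  k_ba <- p_a * k_ex
  tcp <- 1 / (2 * nu_cpmg)
  psi <- (k_ba - k_ab)^2 - dw_rad^2 + 4 * k_ab * k_ba
  zeta <- 2 * dw_rad * (k_ba - k_ab)
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw_rad^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw_rad^2) / root)
  eta_p <- tcp / sqrt(2) * sqrt(psi + root)
  eta_m <- tcp / sqrt(2) * sqrt(-psi + root)
  R2_0 + 0.5 * (k_ex - (1 / tcp) * acosh(Dp * cosh(eta_p) - Dm * cos(eta_m)))
}

# fast-exchange analytic Rex for two sites under a spin lock
# (omega_e in rad/s; omega_e = 0 gives the free-precession value)
fast_exchange_rex <- function(p_a, p_b, dw_rad, k_ex, omega_e = 0) {
  p_a * p_b * dw_rad^2 * k_ex / (k_ex^2 + omega_e^2)
}

# direct time-domain FID simulation + mono-exponential envelope fit,
# independent of the eigenvalue route: evolve site magnetizations with
# explicit small-step propagation and fit ln|S(t)|
fid_lineshape <- function(p, delta_ppm, K, R2, B0_MHz, t_max = 0.05,
                          n_steps = 4000) {
  n <- length(p)
  omega <- 2 * pi * delta_ppm * B0_MHz
  L <- K - diag(R2, n) + 1i * diag(omega, n)
  dt <- t_max / n_steps
  # dense propagator by repeated squaring of a small-step Euler-Richardson
  P1 <- diag(n) + L * dt + (L %*% L) * dt^2 / 2 + (L %*% L %*% L) * dt^3 / 6
  M <- as.complex(p)
  S <- complex(n_steps + 1)
  S[1] <- sum(M)
  for (i in seq_len(n_steps)) {
    M <- P1 %*% M
    S[i + 1] <- sum(M)
  }
  tt <- seq(0, t_max, length.out = n_steps + 1)
  # observed decay rate and frequency from the tail (after fast modes die)
  sel <- tt > t_max / 4
  fit_decay <- stats::lm(log(abs(S[sel])) ~ tt[sel])
  phase <- unwrap_phase(Arg(S[sel]))
  fit_freq <- stats::lm(phase ~ tt[sel])
  list(R2_obs = -unname(stats::coef(fit_decay)[2]),
       shift_ppm = unname(stats::coef(fit_freq)[2]) / (2 * pi * B0_MHz))
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}

# shared ground-truth fixtures for the huntingtin exon 1 system
q7_model <- function(...) {
  equilibrium_model(KD1 = 70e-3, KD1_star = 200e-3, KD2 = 30e-6, ...)
}
q35_model <- function(...) {
  equilibrium_model(KD1 = 70e-3, KD1_star = 200e-3, KD2 = 11e-6, ...)
}
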