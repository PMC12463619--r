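#' Branched pre-nucleation equilibrium model
#'
#' Defines the dissociation constants of the branched oligomerization
#' scheme of huntingtin exon 1: monomers (m) form productive coiled-coil
#' dimers (D) that assemble into tetrameric helical bundles (T), while a
#' competing off-pathway yields non-productive dimers (D*). A
#' monomer-binding inhibitor (m + I <-> mI) and a nucleus-binding
#' inhibitor (P + I <-> PI, used by the kinetics module) are optional.
#'
#' Conventions (all molar):
#' \itemize{
#'   \item `KD1   = [m]^2 / [D]`      (m <-> D, productive dimer)
#'   \item `KD1_star = [m]^2 / [D*]`  (m <-> D*, off-pathway dimer)
#'   \item `KD2   = [D]^2 / [T]`      (D <-> T, tetramer)
#'   \item `KD_mI = [m][I] / [mI]`    (monomer sequestration, optional)
#'   \item `KD_PI = [P][I] / [PI]`    (nucleus sequestration, optional)
#' }
#'
#' @param KD1 dissociation constant of the productive dimer, molar.
#'   Unit strings such as `"70 mM"` are accepted for all arguments.
#' @param KD1_star dissociation constant of the off-pathway dimer, molar.
#' @param KD2 dissociation constant of the dimer-to-tetramer step, molar.
#' @param KD_mI monomer-inhibitor dissociation constant, molar, or `NA`
#'   for no monomer binding.
#' @param KD_PI nucleus-inhibitor dissociation constant, molar, or `NA`
#'   for no nucleus binding.
#' @return an object of class `equilibrium_model`.
#' @examples
#' eq <- equilibrium_model(KD1 = "70 mM", KD1_star = "200 mM", KD2 = "30 uM")
#' solve_prenucleation_equilibrium(eq, totals("1.2 mM"))
#' @export
equilibrium_model <- function(KD1, KD1_star, KD2, KD_mI = NA, KD_PI = NA) {
  num <- function(x) if (length(x) == 1L && is.na(x)) NA_real_ else parse_quantity(x)
  m <- structure(
    list(KD1 = num(KD1), KD1_star = num(KD1_star), KD2 = num(KD2),
         KD_mI = num(KD_mI), KD_PI = num(KD_PI)),
    class = "equilibrium_model"
  )
  for (nm in c("KD1", "KD1_star", "KD2")) {
    if (!is.finite(m[[nm]]) || m[[nm]] <= 0) {
      stop(sprintf("%s must be a positive dissociation constant", nm))
    }
  }
  for (nm in c("KD_mI", "KD_PI")) {
    if (!is.na(m[[nm]]) && m[[nm]] <= 0) {
      stop(sprintf("%s must be positive when supplied", nm))
    }
  }
  m
}

#' @export
print.equilibrium_model <- function(x, ...) {
  cat("Branched pre-nucleation equilibrium model\n")
  cat("  KD1  (m <-> D)  :", format_molar(x$KD1), "\n")
  cat("  KD1* (m <-> D*) :", format_molar(x$KD1_star), "\n")
  cat("  KD2  (D <-> T)  :", format_molar(x$KD2), "\n")
  if (!is.na(x$KD_mI)) cat("  KD_mI (m + I)   :", format_molar(x$KD_mI), "\n")
  if (!is.na(x$KD_PI)) cat("  KD_PI (P + I)   :", format_molar(x$KD_PI), "\n")
  invisible(x)
}

#' Total concentrations
#'
#' @param P_tot total protein in monomer-equivalent molar units.
#' @param I_tot total inhibitor, molar (0 if absent).
#' @return an object of class `totals`.
#' @export
totals <- function(P_tot, I_tot = 0) {
  t <- structure(list(P_tot = parse_quantity(P_tot),
                      I_tot = parse_quantity(I_tot)),
                 class = "totals")
  if (!is.finite(t$P_tot) || t$P_tot < 0) stop("P_tot must be finite and >= 0")
  if (!is.finite(t$I_tot) || t$I_tot < 0) stop("I_tot must be finite and >= 0")
  t
}

# protein monomer-unit balance as a function of free monomer m.
# Strictly increasing in m, so the root on [0, P_tot] is unique.
.protein_balance <- function(m, model, tot) {
  mI <- 0
  if (!is.na(model$KD_mI) && tot$I_tot > 0) {
    I_free <- tot$I_tot / (1 + m / model$KD_mI)
    mI <- m * I_free / model$KD_mI
  }
  D <- m^2 / model$KD1
  Dstar <- m^2 / model$KD1_star
  T_ <- D^2 / model$KD2
  m + mI + 2 * D + 2 * Dstar + 4 * T_ - tot$P_tot
}

# fast scalar solve of the protein balance: safeguarded Newton with
# analytic derivative, bracket [0, P_tot]. Returns free monomer.
.solve_monomer <- function(model, P_tot, I_tot, guess = NULL, tol = 1e-15) {
  if (P_tot <= 0) return(0)
  kd1 <- model$KD1; kd1s <- model$KD1_star; kd2 <- model$KD2
  kmi <- model$KD_mI
  has_I <- !is.na(kmi) && I_tot > 0
  f <- function(m) {
    v <- m + 2 * m^2 / kd1 + 2 * m^2 / kd1s + 4 * m^4 / (kd1^2 * kd2) - P_tot
    if (has_I) v <- v + m * I_tot / (kmi + m)
    v
  }
  fp <- function(m) {
    v <- 1 + 4 * m / kd1 + 4 * m / kd1s + 16 * m^3 / (kd1^2 * kd2)
    if (has_I) v <- v + I_tot * kmi / (kmi + m)^2
    v
  }
  lo <- 0; hi <- P_tot
  m <- if (!is.null(guess) && guess > 0 && guess < P_tot) guess else P_tot / 2
  for (it in 1:100) {
    fv <- f(m)
    if (fv > 0) hi <- m else lo <- m
    step <- fv / fp(m)
    m_new <- m - step
    if (!(m_new > lo && m_new < hi)) m_new <- (lo + hi) / 2  # bisect safeguard
    conv <- abs(m_new - m) < tol * max(1e-3, m)
    m <- m_new
    if (conv) break
  }
  m
}

#' Solve the branched pre-nucleation equilibrium
#'
#' Finds the unique non-negative species concentrations satisfying the
#' coupled mass-action equilibria and the protein and inhibitor balances
#' \deqn{m + mI + 2D + 2D^* + 4T = P_{tot}, \qquad I_{free} + mI = I_{tot}.}
#' Free inhibitor is eliminated analytically,
#' `I_free = I_tot / (1 + m/KD_mI)`, and the remaining scalar protein
#' balance, strictly increasing in free monomer, is solved by bracketed
#' root-finding on `[0, P_tot]` followed by Newton polishing.
#'
#' @param model an [equilibrium_model].
#' @param totals a [totals] object (or a bare molar concentration, taken
#'   as `P_tot` with no inhibitor).
#' @param tol absolute tolerance on the monomer concentration, molar.
#' @return an object of class `species_state`: a named list with molar
#'   concentrations `m`, `D`, `D_star`, `T`, `mI`, `I_free`, plus the
#'   totals used and the residual of the protein balance.
#' @export
solve_prenucleation_equilibrium <- function(model, totals, tol = 1e-15) {
  stopifnot(inherits(model, "equilibrium_model"))
  if (!inherits(totals, "totals")) totals <- totals(totals)
  tot <- totals
  if (tot$P_tot == 0) {
    return(.species_state(0, 0, 0, 0, 0, tot$I_tot, tot))
  }
  # f(0) = -P_tot < 0 and f(P_tot) >= 0: bracketed and strictly increasing
  m <- .solve_monomer(model, tot$P_tot, tot$I_tot, tol = tol)
  resid <- .protein_balance(m, model, tot)
  if (abs(resid) > 1e-8 * max(tot$P_tot, 1e-12)) {
    stop(sprintf("equilibrium solver did not converge: residual %.3e M", resid))
  }
  mI <- 0; I_free <- tot$I_tot
  if (!is.na(model$KD_mI) && tot$I_tot > 0) {
    I_free <- tot$I_tot / (1 + m / model$KD_mI)
    mI <- m * I_free / model$KD_mI
  }
  D <- m^2 / model$KD1
  Dstar <- m^2 / model$KD1_star
  T_ <- D^2 / model$KD2
  st <- .species_state(m, D, Dstar, T_, mI, I_free, tot)
  st$residual <- resid
  st
}

.species_state <- function(m, D, D_star, T_, mI, I_free, tot) {
  structure(
    list(m = m, D = D, D_star = D_star, T = T_, mI = mI, I_free = I_free,
         totals = tot, residual = 0),
    class = "species_state"
  )
}

#' @export
print.species_state <- function(x, ...) {
  cat("Pre-nucleation species state (P_tot =", format_molar(x$totals$P_tot),
      ", I_tot =", format_molar(x$totals$I_tot), ")\n")
  conc <- c(m = x$m, D = x$D, `D*` = x$D_star, T = x$T,
            mI = x$mI, I_free = x$I_free)
  fr <- population_fractions(x)
  for (nm in names(conc)) {
    key <- sub("\\*", "_star", nm)
    fstr <- if (key %in% names(fr)) sprintf("  (%5.2f%% of protein)", 100 * fr[[key]]) else ""
    cat(sprintf("  %-7s %12s%s\n", nm, format_molar(conc[[nm]]), fstr))
  }
  invisible(x)
}

#' Monomer-unit population fractions
#'
#' Expresses each protein species as the fraction of total protein mass
#' (in monomer units) it carries: `frac_X = stoich_X * [X] / P_tot` with
#' stoichiometries m:1, mI:1, D:2, D*:2, T:4. This is the convention in
#' which oligomer populations of a few percent are reported for this
#' system; fractions sum to 1 over protein species.
#'
#' @param state a `species_state`.
#' @param totals optional [totals]; defaults to those stored in `state`.
#' @return named numeric vector `m, mI, D, D_star, T` (empty if
#'   `P_tot == 0`).
#' @export
population_fractions <- function(state, totals = NULL) {
  stopifnot(inherits(state, "species_state"))
  tot <- if (is.null(totals)) state$totals else totals
  if (tot$P_tot == 0) return(stats::setNames(numeric(0), character(0)))
  c(m = state$m, mI = state$mI, D = 2 * state$D,
    D_star = 2 * state$D_star, T = 4 * state$T) / tot$P_tot
}

#' Free-energy difference between two dissociation constants
#'
#' `Delta G = R * T * ln(KD_a / KD_b)` in kcal/mol: the stabilization of
#' the complex when the dissociation constant tightens from `KD_a` to
#' `KD_b`. Used, e.g., to express the increased tetramer stability of the
#' pathological polyQ-expanded construct relative to the short one.
#'
#' @param KD_a,KD_b dissociation constants, molar (unit strings accepted).
#' @param temperature absolute temperature, kelvin.
#' @return free-energy difference, kcal/mol.
#' @examples
#' free_energy_difference("30 uM", "11 uM", 278.15)  # ~0.55 kcal/mol
#' @export
free_energy_difference <- function(KD_a, KD_b, temperature = 298.15) {
  a <- parse_quantity(KD_a); b <- parse_quantity(KD_b)
  if (a <= 0 || b <= 0 || temperature <= 0) {
    stop("dissociation constants and temperature must be positive")
  }
  R_kcal <- 1.987204259e-3  # gas constant, kcal/(mol K)
  R_kcal * temperature * log(a / b)
}

#' Equilibrium species over a concentration series
#'
#' Convenience sweep of [solve_prenucleation_equilibrium] over total
#' protein and/or inhibitor concentrations.
#'
#' @param model an [equilibrium_model].
#' @param P_tot numeric vector of total protein, molar.
#' @param I_tot numeric vector of total inhibitor, molar (recycled).
#' @return data.frame with concentrations and monomer-unit fractions.
#' @export
equilibrium_series <- function(model, P_tot, I_tot = 0) {
  n <- max(length(P_tot), length(I_tot))
  P_tot <- rep_len(vapply(P_tot, parse_quantity, numeric(1)), n)
  I_tot <- rep_len(vapply(I_tot, parse_quantity, numeric(1)), n)
  rows <- lapply(seq_len(n), function(i) {
    st <- solve_prenucleation_equilibrium(model, totals(P_tot[i], I_tot[i]))
    fr <- population_fractions(st)
    if (length(fr) == 0) fr <- c(m = 0, mI = 0, D = 0, D_star = 0, T = 0)
    data.frame(p_tot = P_tot[i], i_tot = I_tot[i],
               m = st$m, D = st$D, D_star = st$D_star, T = st$T,
               mI = st$mI, I_free = st$I_free,
               frac_m = fr[["m"]], frac_D = fr[["D"]],
               frac_Dstar = fr[["D_star"]], frac_T = fr[["T"]],
               frac_mI = fr[["mI"]])
  })
  do.call(rbind, rows)
}
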