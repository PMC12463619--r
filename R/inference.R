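#' Experiment dataset and experiment set
#'
#' An `experiment` couples one measured table to its type and conditions;
#' an `experiment_set` is a list of them fitted jointly. Supported types
#' and required table columns:
#' \itemize{
#'   \item `delta_ex`: `p_tot, i_tot, value, sigma` (ppm vs protein conc.)
#'   \item `vi`: `p_tot, i_tot, value, sigma` (V/I ratio vs protein conc.)
#'   \item `r1rho`: `omega1, value, sigma` (s^-1 vs spin-lock Hz)
#'   \item `cpmg`: `nu_cpmg, value, sigma` (s^-1 vs pulsing Hz)
#'   \item `prd_decay`: `t, value, sigma` (normalized intensity vs s)
#' }
#'
#' @param type dataset type.
#' @param table data.frame with the columns above.
#' @param conditions named list; `p_tot`/`i_tot` (molar) for time-course
#'   and dispersion types, optionally `field` (MHz), `temperature` (K).
#' @return object of class `experiment`.
#' @export
experiment <- function(type = c("delta_ex", "vi", "r1rho", "cpmg", "prd_decay"),
                       table, conditions = list()) {
  type <- match.arg(type)
  req <- switch(type,
                delta_ex = c("p_tot", "i_tot", "value", "sigma"),
                vi = c("p_tot", "i_tot", "value", "sigma"),
                r1rho = c("omega1", "value", "sigma"),
                cpmg = c("nu_cpmg", "value", "sigma"),
                prd_decay = c("t", "value", "sigma"))
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop(sprintf("experiment table of type '%s' lacks columns: %s",
                 type, paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(table$sigma)) || any(table$sigma <= 0)) {
    stop("per-point uncertainties must be positive and finite")
  }
  xcol <- req[1]
  table <- table[order(table[[xcol]]), , drop = FALSE]
  structure(list(type = type, table = table, conditions = conditions),
            class = "experiment")
}

#' @rdname experiment
#' @param ... `experiment` objects.
#' @export
experiment_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "experiment")) {
    xs <- xs[[1]]
  }
  stopifnot(all(vapply(xs, inherits, logical(1), "experiment")))
  structure(xs, class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("Experiment set:", length(x), "datasets\n")
  for (e in x) {
    cond <- if (length(e$conditions)) {
      paste(names(e$conditions),
            vapply(e$conditions, function(v) format(v, digits = 3), ""),
            sep = "=", collapse = ", ")
    } else ""
    cat(sprintf("  %-10s %4d points  %s\n", e$type, nrow(e$table), cond))
  }
  invisible(x)
}

# Model template: closure context used by the fit. Holds fixed parameter
# values and the fixtures needed to forward-model every dataset type.
.default_template <- function() {
  list(KD1 = 70e-3, KD1_star = 200e-3, KD2 = 30e-6,
       KD_mI = NA_real_, KD_PI = NA_real_,
       k_conv = 1e-4, k_e = 1e4, k_2 = 0, n_2 = 2, n_c = 4, P0 = 0,
       fixture = exchange_fixture(), settings = observable_settings(),
       scheme = "none")
}

#' Forward-model an experiment set
#'
#' Predicts every dataset in `data` from a named parameter list (the
#' union of a template and any overrides), dispatching to the static
#' equilibrium/exchange models for `delta_ex`, `vi`, `r1rho` and `cpmg`
#' types and to the aggregation integrator (quasi-equilibrium mode) for
#' `prd_decay`.
#'
#' @param data an [experiment_set].
#' @param params named list of model parameters (see
#'   [global_fit] for the naming).
#' @return list of numeric prediction vectors, one per dataset.
#' @export
predict_experiments <- function(data, params) {
  tmpl <- utils::modifyList(.default_template(), params)
  eq <- equilibrium_model(tmpl$KD1, tmpl$KD1_star, tmpl$KD2,
                          KD_mI = tmpl$KD_mI, KD_PI = tmpl$KD_PI)
  lapply(data, function(e) {
    tb <- e$table
    if (e$type %in% c("delta_ex", "vi")) {
      so <- static_observables(eq, tb$p_tot, tb$i_tot,
                               fixture = tmpl$fixture, settings = tmpl$settings)
      if (e$type == "delta_ex") so$delta_ex else so$VI_ratio
    } else if (e$type == "r1rho") {
      st <- solve_prenucleation_equilibrium(
        eq, totals(e$conditions$p_tot, e$conditions$i_tot %||% 0))
      sys <- build_exchange_system(st, tau_mDstar = tmpl$fixture$tau_mDstar,
                                   tau_mT = tmpl$fixture$tau_mT,
                                   shifts = tmpl$fixture$shifts,
                                   R2_0 = tmpl$fixture$R2_0,
                                   topology = tmpl$fixture$topology)
      simulate_r1rho(sys, tmpl$fixture$context, omega1 = tb$omega1)$R1rho
    } else if (e$type == "cpmg") {
      st <- solve_prenucleation_equilibrium(
        eq, totals(e$conditions$p_tot, e$conditions$i_tot %||% 0))
      sys <- build_exchange_system(st, tau_mDstar = tmpl$fixture$tau_mDstar,
                                   tau_mT = tmpl$fixture$tau_mT,
                                   shifts = tmpl$fixture$shifts,
                                   R2_0 = tmpl$fixture$R2_0,
                                   topology = tmpl$fixture$topology)
      simulate_cpmg(sys, tmpl$fixture$context, nu_cpmg = tb$nu_cpmg)$R2_eff
    } else if (e$type == "prd_decay") {
      km <- kinetic_model(eq, k_conv = tmpl$k_conv, k_e = tmpl$k_e,
                          k_2 = tmpl$k_2, n_2 = tmpl$n_2, n_c = tmpl$n_c,
                          scheme = tmpl$scheme, P0 = tmpl$P0)
      tt <- tb$t
      grid <- sort(unique(c(0, tt)))
      tc <- simulate_aggregation(
        km, totals(e$conditions$p_tot, e$conditions$i_tot %||% 0),
        grid, mode = "quasi_equilibrium", rtol = 1e-8, atol = 1e-14)
      pd <- prd_decay(tc, tmpl$settings)
      pd$intensity[match(tt, pd$t)]
    } else stop("unknown experiment type")
  })
}

.weighted_residuals <- function(data, params) {
  pred <- predict_experiments(data, params)
  unlist(lapply(seq_along(data), function(i) {
    (data[[i]]$table$value - pred[[i]]) / data[[i]]$table$sigma
  }), use.names = FALSE)
}

#' Global fit of heterogeneous NMR and kinetic datasets
#'
#' Minimizes the inverse-variance-weighted residual sum of squares over
#' all datasets simultaneously, using the package's forward models.
#' Parameters are optimized on the log scale (all model parameters are
#' positive rates or constants) by Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]) with deterministic seeded multi-start.
#'
#' Recognized parameter names: `KD1`, `KD1_star`, `KD2`, `KD_mI`,
#' `KD_PI`, `k_conv`, `k_e`, `k_2`, `P0`. Identifiability depends on the
#' dataset types present: dissociation constants of the pre-nucleation
#' steps require concentration-resolved `delta_ex`/`vi` (or dispersion)
#' data; `k_conv`, `k_e`, `k_2`, `P0` require `prd_decay` time courses;
#' `KD_mI`/`KD_PI` require an inhibitor series. Requesting, e.g., `KD2`
#' from decay data alone triggers a warning.
#'
#' @param data an [experiment_set].
#' @param free character vector of free parameter names.
#' @param start named list/vector of start values for the free
#'   parameters (natural scale).
#' @param fixed named list of fixed parameter values and fixtures
#'   overriding the defaults (`scheme`, `fixture`, `settings`, ...).
#' @param n_starts number of multi-start points (log-uniform within
#'   `spread` decades around `start`).
#' @param spread multi-start spread, decades.
#' @param seed integer seed making the multi-start deterministic.
#' @param control passed to [minpack.lm::nls.lm.control].
#' @return object of class `agg_fit`.
#' @export
global_fit <- function(data, free, start, fixed = list(),
                       n_starts = 8, spread = 1, seed = 1,
                       control = list(maxiter = 100, ptol = 1e-10)) {
  stopifnot(inherits(data, "experiment_set"), length(data) >= 1)
  free <- as.character(free)
  start <- unlist(start)[free]
  if (any(is.na(start)) || any(start <= 0)) {
    stop("a positive start value is required for every free parameter")
  }
  types <- vapply(data, function(e) e$type, character(1))
  eq_pars <- c("KD1", "KD1_star", "KD2")
  if (any(free %in% eq_pars) &&
      !any(types %in% c("delta_ex", "vi", "r1rho", "cpmg"))) {
    warning("pre-nucleation constants are poorly identifiable without an equilibrium-sensitive dataset")
  }
  kin_pars <- c("k_conv", "k_e", "k_2", "P0")
  if (any(free %in% kin_pars) && !"prd_decay" %in% types) {
    warning("kinetic rate constants are poorly identifiable without a fibrillation time course")
  }

  objective <- function(lp) {
    params <- as.list(exp(lp))
    names(params) <- free
    r <- try(.weighted_residuals(data, utils::modifyList(fixed, params)),
             silent = TRUE)
    if (inherits(r, "try-error") || any(!is.finite(r))) {
      return(rep(1e6, .n_points(data)))
    }
    r
  }

  set.seed(seed)
  lp0 <- log(start)
  starts <- list(lp0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- lp0 + stats::runif(length(lp0), -spread, spread) * log(10)
    }
  }
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(par = s, fn = objective,
                                  control = do.call(minpack.lm::nls.lm.control,
                                                    control)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      converged <- fit$info %in% 1:4
    }
  }
  if (is.null(best)) stop("all optimization starts failed")

  est <- exp(best$par)
  names(est) <- free
  resid <- .weighted_residuals(data, utils::modifyList(fixed, as.list(est)))
  n <- length(resid); k <- length(free)
  chisq <- sum(resid^2)
  # per-dataset weighted RSS
  idx <- rep(seq_along(data), vapply(data, function(e) nrow(e$table), 0L))
  per_dataset <- tapply(resid^2, idx, sum)
  names(per_dataset) <- vapply(data, function(e) e$type, character(1))
  # approximate covariance from the Jacobian (log scale)
  se <- rep(NA_real_, k)
  J <- best$hessian
  if (!is.null(J)) {
    cov <- try(solve(J) * 2 * chisq / max(n - k, 1), silent = TRUE)
    if (!inherits(cov, "try-error")) {
      se_log <- sqrt(pmax(diag(cov), 0))
      se <- est * se_log  # delta method back to natural scale
    }
  }
  aicc <- chisq + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(estimates = est, se = stats::setNames(se, free),
                 chisq = chisq, per_dataset = per_dataset,
                 df = n - k, n = n, k = k, aicc = aicc,
                 converged = converged, fixed = fixed, data = data,
                 residuals = resid, seed = seed),
            class = "agg_fit")
}

.n_points <- function(data) sum(vapply(data, function(e) nrow(e$table), 0L))

#' @export
print.agg_fit <- function(x, ...) {
  cat("Global fit of", length(x$data), "datasets (",
      x$n, "points,", x$k, "free parameters )\n")
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  cat(sprintf("  weighted chi-square = %.4g (df = %d), AICc = %.4g\n",
              x$chisq, x$df, x$aicc))
  est <- x$estimates
  for (nm in names(est)) {
    cat(sprintf("  %-9s = %.6g", nm, est[[nm]]))
    if (is.finite(x$se[[nm]])) cat(sprintf("  (+/- %.3g)", x$se[[nm]]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.agg_fit <- function(object, ...) {
  out <- list(
    coefficients = data.frame(estimate = object$estimates,
                              std_error = object$se,
                              row.names = names(object$estimates)),
    chisq = object$chisq, df = object$df,
    reduced_chisq = object$chisq / max(object$df, 1),
    aicc = object$aicc, per_dataset = object$per_dataset,
    converged = object$converged)
  class(out) <- "summary.agg_fit"
  out
}

#' @export
print.summary.agg_fit <- function(x, ...) {
  cat("Coefficients:\n"); print(x$coefficients)
  cat(sprintf("\nWeighted chi-square: %.4g on %d df (reduced %.3g), AICc %.4g\n",
              x$chisq, x$df, x$reduced_chisq, x$aicc))
  cat("Per-dataset weighted RSS:\n"); print(x$per_dataset)
  invisible(x)
}

#' @export
coef.agg_fit <- function(object, ...) object$estimates

#' @export
residuals.agg_fit <- function(object, ...) object$residuals

#' @export
predict.agg_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  predict_experiments(data, utils::modifyList(object$fixed,
                                              as.list(object$estimates)))
}

#' @export
logLik.agg_fit <- function(object, ...) {
  # Gaussian log-likelihood with known per-point sigma, up to the
  # sigma-dependent constant shared by all candidate schemes
  structure(-object$chisq / 2, df = object$k, class = "logLik")
}

#' Classify an inhibitor's mechanism by model selection
#'
#' Fits the four candidate inhibitor schemes (no effect, monomer
#' sequestration, nucleus sequestration, dual) to the same experiment set
#' with [global_fit] and ranks them by small-sample-corrected Akaike
#' information criterion. The data must contain at least one
#' equilibrium-sensitive observable (`delta_ex` or `vi`) and one
#' fibrillation observable (`prd_decay`), each at two or more inhibitor
#' concentrations: the equilibrium observables separate monomer from
#' nucleus binding (only monomer binding perturbs the m <-> D <-> T
#' populations), while the decay data separate either from no effect.
#'
#' @param data an [experiment_set].
#' @param shared named list of shared fixed parameters/fixtures (as
#'   `fixed` in [global_fit]); ground-truth kinetic constants and
#'   fixtures, not inhibitor constants.
#' The verdict is the most parsimonious scheme whose AICc lies within
#' `parsimony_margin` of the minimum (Burnham-Anderson substantial-support
#' rule): nested candidates differing by less than the margin are treated
#' as statistically indistinguishable and the one with fewer inhibitor
#' parameters wins, which keeps the dual scheme from absorbing noise when
#' a single mechanism generated the data.
#'
#' @return object of class `mechanism_verdict`.
#' @export
classify_mechanism <- function(data, shared = list(), KD_start = 50e-6,
                               n_starts = 4, seed = 1,
                               parsimony_margin = 2) {
  stopifnot(inherits(data, "experiment_set"))
  types <- vapply(data, function(e) e$type, character(1))
  if (!any(types %in% c("delta_ex", "vi"))) {
    stop("classification needs an equilibrium-sensitive dataset (delta_ex or vi)")
  }
  if (!"prd_decay" %in% types) {
    stop("classification needs a fibrillation dataset (prd_decay)")
  }
  i_levels <- unique(unlist(lapply(data, function(e) {
    if (e$type %in% c("delta_ex", "vi")) unique(e$table$i_tot)
    else e$conditions$i_tot %||% 0
  })))
  if (length(i_levels) < 2) {
    stop("classification needs data at two or more inhibitor concentrations")
  }

  candidates <- list(
    none = list(free = character(0), scheme = "none"),
    monomer_sequestration = list(free = "KD_mI", scheme = "monomer_binding"),
    nucleus_sequestration = list(free = "KD_PI", scheme = "nucleus_binding"),
    dual = list(free = c("KD_mI", "KD_PI"), scheme = "dual")
  )
  fits <- lapply(candidates, function(cand) {
    fixed <- utils::modifyList(shared, list(scheme = cand$scheme))
    if (length(cand$free) == 0) {
      # no free parameters: evaluate the chi-square directly
      resid <- .weighted_residuals(data, fixed)
      n <- length(resid)
      structure(list(estimates = numeric(0), se = numeric(0),
                     chisq = sum(resid^2), df = n, n = n, k = 0,
                     aicc = sum(resid^2), converged = TRUE,
                     per_dataset = NULL, fixed = fixed, data = data,
                     residuals = resid, seed = seed),
                class = "agg_fit")
    } else {
      start <- stats::setNames(rep(KD_start, length(cand$free)), cand$free)
      global_fit(data, free = cand$free, start = start, fixed = fixed,
                 n_starts = n_starts, seed = seed)
    }
  })
  ic <- vapply(fits, function(f) f$aicc, numeric(1))
  k_par <- vapply(fits, function(f) f$k, numeric(1))
  supported <- which(ic - min(ic) <= parsimony_margin)
  label <- names(supported)[order(k_par[supported], ic[supported])][1]

  # evidence summary: which observable families discriminated
  eq_idx <- which(types %in% c("delta_ex", "vi"))
  agg_idx <- which(types == "prd_decay")
  chisq_by <- function(fit, idx) {
    pts <- rep(seq_along(data), vapply(data, function(e) nrow(e$table), 0L))
    sum(fit$residuals[pts %in% idx]^2)
  }
  evidence <- data.frame(
    scheme = names(fits),
    aicc = ic,
    chisq_equilibrium = vapply(fits, chisq_by, numeric(1), eq_idx),
    chisq_fibrillation = vapply(fits, chisq_by, numeric(1), agg_idx),
    row.names = NULL)
  structure(list(label = label, ic = ic, fits = fits, evidence = evidence),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("Inhibitor mechanism verdict:", x$label, "\n")
  ord <- order(x$ic)
  tab <- x$evidence[ord, ]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.mechanism_verdict <- function(object, ...) {
  cat("Verdict:", object$label, "\n\nBest fit for each candidate scheme:\n")
  for (nm in names(object$fits)) {
    f <- object$fits[[nm]]
    est <- if (length(f$estimates)) {
      paste(names(f$estimates), signif(f$estimates, 4),
            sep = " = ", collapse = ", ")
    } else "(no free parameters)"
    cat(sprintf("  %-22s AICc %9.3f   %s\n", nm, f$aicc, est))
  }
  invisible(object)
}
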