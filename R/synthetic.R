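#' Named simulation scenarios
#'
#' Returns a fully specified ground-truth scenario for synthetic-data
#' generation. The printed constants of the huntingtin exon 1 system are
#' used where available: KD1 = 70 mM, KD1* = 200 mM, KD2 = 30 uM (Q7
#' pre-nucleation) or 11 uM (Q35 aggregation), inhibitor dissociation
#' constants 50 uM, exchange timescales 750 us (m <-> D*) and 50 us
#' (productive branch), protein concentration series 0.20-0.75 mM, and
#' inhibitor series 0, 0.2, 0.4, 0.8 mM. Quantities not observable
#' directly (oligomer chemical shifts, intrinsic relaxation rates, the
#' aggregation rate constants and initial nucleus concentration) are
#' fixture constants chosen to produce realistic observables; they are
#' labelled as such in the scenario object and its manifest.
#'
#' @param name one of `"q7_prenucleation"`, `"q7_inhibited"`,
#'   `"q35_aggregation"`, `"q35_monomer_inhibition"`,
#'   `"q35_nucleus_inhibition"`.
#' @param noise relative Gaussian noise level applied to every observable.
#' @param seed integer seed fixing all randomness.
#' @return object of class `scenario_spec`.
#' @export
make_scenario <- function(name = c("q7_prenucleation", "q7_inhibited",
                                   "q35_aggregation",
                                   "q35_monomer_inhibition",
                                   "q35_nucleus_inhibition"),
                          noise = 0.02, seed = 1) {
  name <- match.arg(name)
  if (noise < 0) stop("noise must be non-negative")
  q7_eq <- list(KD1 = 70e-3, KD1_star = 200e-3, KD2 = 30e-6)
  q35_eq <- list(KD1 = 70e-3, KD1_star = 200e-3, KD2 = 11e-6)
  # fixture constants, not derived from printed observables
  fixture <- exchange_fixture(tau_mDstar = 750e-6, tau_mT = 50e-6,
                              shifts = c(D = 2, D_star = 1, T = 4),
                              R2_0 = 8)
  settings <- observable_settings(R2_ref = 4)
  kin <- list(k_conv = 2e-6, k_e = 500, k_2 = 1, n_2 = 2, n_c = 4, P0 = 1e-9)
  conc_series <- seq(0.20e-3, 0.75e-3, length.out = 8)
  i_series <- c(0, 0.2e-3, 0.4e-3, 0.8e-3)
  t_grid <- seq(0, 20 * 3600, length.out = 25)

  base <- list(name = name, noise = noise, seed = as.integer(seed),
               fixture = fixture, settings = settings,
               conc_series = conc_series, t_grid = t_grid,
               dispersion_p_tot = c(0.3e-3, 0.6e-3, 0.8e-3),
               p_vi = 0.75e-3,
               nu_cpmg = c(50, 100, 200, 400, 800, 1600),
               omega1 = c(750, 1500, 3000))
  sc <- switch(name,
    q7_prenucleation = c(base, list(
      equilibrium = q7_eq, kinetics = NULL, scheme = "none",
      i_series = 0, p_ref = 1.2e-3)),
    q7_inhibited = c(base, list(
      equilibrium = c(q7_eq, KD_mI = 50e-6), kinetics = NULL,
      scheme = "monomer_binding", i_series = i_series, p_ref = 1.2e-3)),
    q35_aggregation = c(base, list(
      equilibrium = q35_eq, kinetics = kin, scheme = "none",
      i_series = 0, p_ref = 0.38e-3)),
    q35_monomer_inhibition = c(base, list(
      equilibrium = c(q35_eq, KD_mI = 50e-6), kinetics = kin,
      scheme = "monomer_binding", i_series = i_series, p_ref = 0.38e-3)),
    q35_nucleus_inhibition = c(base, list(
      equilibrium = c(q35_eq, KD_PI = 50e-6), kinetics = kin,
      scheme = "nucleus_binding", i_series = i_series, p_ref = 0.38e-3)))
  structure(sc, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Synthetic scenario:", x$name, "\n")
  cat("  noise:", x$noise, " seed:", x$seed, "\n")
  cat("  equilibrium constants:",
      paste(names(x$equilibrium), format_molar(unlist(x$equilibrium)),
            sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$kinetics)) {
    cat("  kinetics:", paste(names(x$kinetics), unlist(x$kinetics),
                             sep = " = ", collapse = ", "), "\n")
  }
  cat("  scheme:", x$scheme, "\n")
  invisible(x)
}

.scenario_eq <- function(sc) {
  e <- sc$equilibrium
  equilibrium_model(e$KD1, e$KD1_star, e$KD2,
                    KD_mI = e$KD_mI %||% NA, KD_PI = e$KD_PI %||% NA)
}

.scenario_km <- function(sc) {
  k <- sc$kinetics
  kinetic_model(.scenario_eq(sc), k_conv = k$k_conv, k_e = k$k_e,
                k_2 = k$k_2, n_2 = k$n_2, n_c = k$n_c,
                scheme = sc$scheme, P0 = k$P0)
}

.add_noise <- function(values, noise, scale = NULL) {
  if (is.null(scale)) scale <- pmax(abs(values), 1e-12)
  sigma <- noise * scale
  list(value = values + stats::rnorm(length(values), 0, sigma),
       sigma = if (noise > 0) sigma else pmax(0.01 * scale, 1e-12))
}

#' Generate a synthetic experiment set from a scenario
#'
#' Simulates all dataset types the scenario supports with the package's
#' forward models, adds relative Gaussian noise, and returns an
#' [experiment_set] plus the ground truth. Equilibrium scenarios yield
#' concentration-resolved `delta_ex` and `vi` tables and dispersion
#' (`r1rho`, `cpmg`) tables; aggregation scenarios additionally yield
#' `prd_decay` time courses over the inhibitor series.
#'
#' @param sc a [make_scenario] object.
#' @param types subset of dataset types to generate (default: all the
#'   scenario supports).
#' @return list with elements `data` (an [experiment_set]) and
#'   `ground_truth` (named list of generating parameters).
#' @export
generate_experiments <- function(sc, types = NULL) {
  stopifnot(inherits(sc, "scenario_spec"))
  set.seed(sc$seed)
  eq <- .scenario_eq(sc)
  supported <- c("delta_ex", "vi", "r1rho", "cpmg",
                 if (!is.null(sc$kinetics)) "prd_decay")
  if (is.null(types)) types <- supported
  stopifnot(all(types %in% supported))
  exps <- list()

  grid_ci <- expand.grid(p_tot = sc$conc_series, i_tot = sc$i_series)
  if ("delta_ex" %in% types || "vi" %in% types) {
    so <- static_observables(eq, grid_ci$p_tot, grid_ci$i_tot,
                             fixture = sc$fixture, settings = sc$settings)
    if ("delta_ex" %in% types) {
      nz <- .add_noise(so$delta_ex, sc$noise, scale = max(abs(so$delta_ex)))
      exps <- c(exps, list(experiment("delta_ex", data.frame(
        p_tot = so$p_tot, i_tot = so$i_tot,
        value = nz$value, sigma = nz$sigma))))
    }
    if ("vi" %in% types) {
      nz <- .add_noise(so$VI_ratio, sc$noise)
      exps <- c(exps, list(experiment("vi", data.frame(
        p_tot = so$p_tot, i_tot = so$i_tot,
        value = nz$value, sigma = nz$sigma))))
    }
  }
  if (any(c("r1rho", "cpmg") %in% types)) {
    for (p in sc$dispersion_p_tot) {
      st <- solve_prenucleation_equilibrium(eq, totals(p, 0))
      sys <- build_exchange_system(st, tau_mDstar = sc$fixture$tau_mDstar,
                                   tau_mT = sc$fixture$tau_mT,
                                   shifts = sc$fixture$shifts,
                                   R2_0 = sc$fixture$R2_0,
                                   topology = sc$fixture$topology)
      if ("r1rho" %in% types) {
        rr <- simulate_r1rho(sys, sc$fixture$context, omega1 = sc$omega1)
        nz <- .add_noise(rr$R1rho, sc$noise)
        exps <- c(exps, list(experiment("r1rho", data.frame(
          omega1 = rr$omega1, value = nz$value, sigma = nz$sigma),
          conditions = list(p_tot = p, i_tot = 0))))
      }
      if ("cpmg" %in% types) {
        cp <- simulate_cpmg(sys, sc$fixture$context, nu_cpmg = sc$nu_cpmg)
        nz <- .add_noise(cp$R2_eff, sc$noise)
        exps <- c(exps, list(experiment("cpmg", data.frame(
          nu_cpmg = cp$nu_cpmg, value = nz$value, sigma = nz$sigma),
          conditions = list(p_tot = p, i_tot = 0))))
      }
    }
  }
  if ("prd_decay" %in% types) {
    km <- .scenario_km(sc)
    for (i_tot in sc$i_series) {
      tc <- simulate_aggregation(km, totals(sc$p_ref, i_tot), sc$t_grid,
                                 mode = "quasi_equilibrium",
                                 rtol = 1e-8, atol = 1e-14)
      pd <- prd_decay(tc, sc$settings)
      nz <- .add_noise(pd$intensity, sc$noise, scale = 1)
      exps <- c(exps, list(experiment("prd_decay", data.frame(
        t = pd$t, value = nz$value, sigma = nz$sigma),
        conditions = list(p_tot = sc$p_ref, i_tot = i_tot))))
    }
  }
  ground_truth <- c(sc$equilibrium, sc$kinetics,
                    list(scheme = sc$scheme, noise = sc$noise,
                         seed = sc$seed, name = sc$name,
                         fixture = list(tau_mDstar = sc$fixture$tau_mDstar,
                                        tau_mT = sc$fixture$tau_mT,
                                        shifts = as.list(sc$fixture$shifts),
                                        R2_0 = sc$fixture$R2_0,
                                        B0_frequency = sc$fixture$context$B0_frequency,
                                        topology = sc$fixture$topology),
                         R2_ref = sc$settings$R2_ref))
  list(data = experiment_set(exps), ground_truth = ground_truth)
}

#' Write a synthetic experiment set to disk
#'
#' Writes each dataset as a tab-delimited table plus a JSON manifest
#' recording the ground-truth parameters, conditions, seed and file
#' names, so recovery tests can reload everything.
#'
#' @param gen result of [generate_experiments].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_experiments <- function(gen, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- integer(0)
  for (i in seq_along(gen$data)) {
    e <- gen$data[[i]]
    fn <- sprintf("%02d_%s.tsv", i, e$type)
    write_experiment_table(e, file.path(out_dir, fn))
    files <- c(files, fn)
  }
  manifest <- list(
    ground_truth = gen$ground_truth,
    datasets = lapply(seq_along(gen$data), function(i) {
      e <- gen$data[[i]]
      list(file = files[i], type = e$type, conditions = e$conditions,
           n = nrow(e$table))
    }))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Rebuild fixed fitting context from a manifest ground truth
#'
#' Converts the `ground_truth` entry of a synthetic-data manifest back
#' into the `fixed` list consumed by [global_fit] and
#' [classify_mechanism]: model constants, rate constants, and the
#' exchange fixture / observable settings objects. Parameters listed in
#' `free` are dropped so they can be fitted.
#'
#' @param gt ground-truth list (from [read_experiments] or
#'   [generate_experiments]).
#' @param free parameter names to exclude.
#' @return named list of fixed parameters.
#' @export
ground_truth_fixed <- function(gt, free = character(0)) {
  fixed <- gt[intersect(names(gt),
                        c("KD1", "KD1_star", "KD2", "KD_mI", "KD_PI",
                          "k_conv", "k_e", "k_2", "n_2", "n_c", "P0",
                          "scheme"))]
  if (!is.null(gt$fixture)) {
    fx <- gt$fixture
    fixed$fixture <- exchange_fixture(
      tau_mDstar = fx$tau_mDstar, tau_mT = fx$tau_mT,
      shifts = unlist(fx$shifts), R2_0 = fx$R2_0,
      context = spectrometer_context(fx$B0_frequency %||% 60.8),
      topology = fx$topology %||% "chain")
  }
  if (!is.null(gt$R2_ref)) fixed$settings <- observable_settings(R2_ref = gt$R2_ref)
  fixed[setdiff(names(fixed), free)]
}

#' Read a synthetic experiment set from disk
#'
#' @param dir directory written by [write_experiments].
#' @return list with `data` (an [experiment_set]) and `ground_truth`.
#' @export
read_experiments <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  exps <- lapply(manifest$datasets, function(d) {
    read_experiment_table(file.path(dir, d$file), d$type,
                          conditions = d$conditions)
  })
  list(data = experiment_set(exps), ground_truth = manifest$ground_truth)
}
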