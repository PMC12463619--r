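#' Parse a structured-text configuration file
#'
#' Reads a YAML configuration with sections `equilibrium`, `kinetics`,
#' `exchange`, `observables`, `fitting` and `totals`, converting every
#' unit-bearing scalar (e.g. `"70 mM"`, `"750 us"`, `"3000 Hz"`) to base
#' SI-molar units. Unknown keys are rejected so typos fail loudly.
#'
#' @param path path to a YAML file.
#' @return object of class `aggnmr_config`: nested list of numeric
#'   values in base units.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- list(
    equilibrium = c("kd1", "kd1_star", "kd2", "kd_mi", "kd_pi"),
    totals = c("p_tot", "i_tot"),
    kinetics = c("k_conv", "k_e", "k_2", "n_2", "n_c", "p0", "scheme",
                 "kon_mi", "koff_mi", "kon_pi", "koff_pi", "relax_rate"),
    exchange = c("tau_mdstar", "tau_mt", "delta_d", "delta_dstar",
                 "delta_t", "delta_mi", "r2_0", "b0_frequency", "nucleus",
                 "topology"),
    observables = c("r2_ref", "t_relax", "nu_cpmg", "omega1", "t_grid"),
    fitting = c("free", "n_starts", "seed", "spread", "noise")
  )
  bad_sections <- setdiff(names(raw), names(allowed))
  if (length(bad_sections)) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  }
  out <- list()
  for (sec in names(raw)) {
    keys <- names(raw[[sec]])
    bad <- setdiff(keys, allowed[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s",
                   sec, paste(bad, collapse = ", ")))
    }
    text_keys <- c("scheme", "nucleus", "topology", "free")
    vals <- raw[[sec]]
    out[[sec]] <- lapply(stats::setNames(keys, keys), function(k) {
      v <- vals[[k]]
      if (k %in% text_keys) return(unlist(v))
      if (is.list(v) || length(v) > 1L) {
        vapply(v, parse_quantity, numeric(1))
      } else parse_quantity(v)
    })
  }
  structure(out, class = "aggnmr_config")
}

#' Write a configuration back to YAML
#'
#' Values are written in base units (numbers), so
#' `parse_config(write_config(cfg, f))` round-trips exactly.
#'
#' @param config an `aggnmr_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Build model objects from a parsed configuration
#'
#' @param config an `aggnmr_config`.
#' @return list with any of `equilibrium` ([equilibrium_model]),
#'   `totals` ([totals]), `kinetics` ([kinetic_model]), `fixture`
#'   ([exchange_fixture]), `settings` ([observable_settings]) the config
#'   defines.
#' @export
config_models <- function(config) {
  stopifnot(inherits(config, "aggnmr_config"))
  out <- list()
  if (!is.null(config$equilibrium)) {
    e <- config$equilibrium
    if (is.null(e$kd1) || is.null(e$kd1_star) || is.null(e$kd2)) {
      stop("equilibrium section requires kd1, kd1_star and kd2")
    }
    out$equilibrium <- equilibrium_model(e$kd1, e$kd1_star, e$kd2,
                                         KD_mI = e$kd_mi %||% NA,
                                         KD_PI = e$kd_pi %||% NA)
  }
  if (!is.null(config$totals)) {
    if (is.null(config$totals$p_tot)) stop("totals section requires p_tot")
    out$totals <- totals(config$totals$p_tot, config$totals$i_tot %||% 0)
  }
  if (!is.null(config$exchange)) {
    x <- config$exchange
    out$fixture <- exchange_fixture(
      tau_mDstar = x$tau_mdstar %||% 750e-6,
      tau_mT = x$tau_mt %||% 50e-6,
      shifts = c(D = x$delta_d %||% 0, D_star = x$delta_dstar %||% 0,
                 T = x$delta_t %||% 0, mI = x$delta_mi %||% 0),
      R2_0 = x$r2_0 %||% 10,
      context = spectrometer_context(x$b0_frequency %||% 60.8,
                                     x$nucleus %||% "15N"),
      topology = x$topology %||% "chain")
  }
  if (!is.null(config$observables)) {
    out$settings <- observable_settings(R2_ref = config$observables$r2_ref %||% 10)
  }
  if (!is.null(config$kinetics)) {
    if (is.null(out$equilibrium)) stop("kinetics section requires an equilibrium section")
    k <- config$kinetics
    out$kinetics <- kinetic_model(
      out$equilibrium,
      k_conv = k$k_conv %||% 1e-4, k_e = k$k_e %||% 1e4,
      k_2 = k$k_2 %||% 0, n_2 = k$n_2 %||% 2, n_c = k$n_c %||% 4,
      scheme = k$scheme %||% "none", P0 = k$p0 %||% 0,
      relax_rate = k$relax_rate %||% 1e3)
  }
  out
}

#' Write an experiment table as delimited text
#'
#' Tab-delimited with a header row; conditions are carried in the
#' manifest (see [write_experiments]) rather than in the table.
#'
#' @param exp an [experiment].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_experiment_table <- function(exp, path) {
  stopifnot(inherits(exp, "experiment"))
  utils::write.table(format(exp$table, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an experiment table
#'
#' Validates the column schema for the declared type, requires positive
#' uncertainties, and sorts by the independent variable. Duplicated
#' abscissa values (replicates) are allowed and preserved.
#'
#' @param path path to a delimited table.
#' @param type dataset type (see [experiment]).
#' @param conditions named list of conditions.
#' @param sep field separator.
#' @return an [experiment].
#' @export
read_experiment_table <- function(path, type, conditions = list(), sep = "\t") {
  if (!file.exists(path)) stop("table not found: ", path)
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  bad <- which(!is.finite(tb$sigma) | tb$sigma <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or missing sigma in rows: %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  experiment(type, tb, conditions = conditions)
}
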