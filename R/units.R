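#' Parse a unit-bearing quantity string
#'
#' Converts strings like `"70 mM"`, `"50 uM"`, `"750 us"`, `"3000 Hz"` or
#' `"0.5 ppm"` to a numeric value in base units (molar, seconds, Hz, ppm,
#' kcal/mol, dimensionless). Bare numbers pass through unchanged. Numeric
#' input is returned as-is, so already-converted values are accepted
#' everywhere a quantity is expected.
#'
#' @param x character scalar (e.g. `"1.2 mM"`) or numeric scalar.
#' @return numeric scalar in base units.
#' @examples
#' parse_quantity("70 mM")   # 0.07
#' parse_quantity("50 uM")   # 5e-05
#' parse_quantity("750 us")  # 7.5e-04
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("quantity must be a numeric or character scalar")
  }
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([A-Za-z/%µ]*)$", s))[[1]]
  if (length(m) == 0L || m[2] == "") {
    stop(sprintf("malformed quantity: '%s'", x))
  }
  value <- suppressWarnings(as.numeric(m[2]))
  if (is.na(value)) stop(sprintf("malformed numeric part in quantity: '%s'", x))
  unit <- m[3]
  if (unit == "") return(value)
  value * .unit_factor(unit, x)
}

# scale factor to base units; errors on unknown units
.unit_factor <- function(unit, original) {
  u <- gsub("µ", "u", unit)
  factors <- c(
    "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "nM" = 1e-9, "pM" = 1e-12,
    "s" = 1, "ms" = 1e-3, "us" = 1e-6, "ns" = 1e-9,
    "h" = 3600, "min" = 60,
    "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
    "ppm" = 1, "ppb" = 1e-3,
    "K" = 1, "percent" = 1e-2, "%" = 1e-2,
    "kcal/mol" = 1
  )
  if (!u %in% names(factors)) {
    stop(sprintf("unknown unit '%s' in quantity '%s'", unit, original))
  }
  unname(factors[u])
}

#' Format a molar concentration for display
#'
#' Picks an SI prefix (M, mM, uM, nM) so the mantissa is in a readable
#' range. Used by print methods and the CLI.
#'
#' @param x numeric vector, molar.
#' @param digits significant digits.
#' @return character vector.
#' @export
format_molar <- function(x, digits = 3) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(sprintf("%g M", v))
    a <- abs(v)
    if (a >= 1e-1) sprintf("%.*g M", digits, v)
    else if (a >= 1e-4) sprintf("%.*g mM", digits, v * 1e3)
    else if (a >= 1e-7) sprintf("%.*g uM", digits, v * 1e6)
    else sprintf("%.*g nM", digits, v * 1e9)
  }, character(1))
}
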