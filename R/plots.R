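#' Plot an aggregation time course
#'
#' Base-graphics overview: visible species (log-scaled concentrations)
#' and the growth of fibril mass.
#'
#' @param x a `time_course`.
#' @param species which trajectories to draw.
#' @param ... passed to [graphics::matplot].
#' @export
plot.time_course <- function(x, species = c("m", "T", "P_free", "M"), ...) {
  tr <- x$trajectories[, species, drop = FALSE]
  graphics::matplot(x$t / 3600, as.matrix(tr), type = "l", lty = 1,
                    xlab = "time (h)", ylab = "concentration (M)",
                    log = "y", ...)
  graphics::legend("right", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Plot a global fit
#'
#' Draws observed values against model predictions, one panel per
#' dataset.
#'
#' @param x an `agg_fit`.
#' @param ... unused.
#' @export
plot.agg_fit <- function(x, ...) {
  pred <- predict(x)
  n <- length(x$data)
  old <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(n)) {
    e <- x$data[[i]]
    xc <- switch(e$type, delta_ex = , vi = e$table$p_tot,
                 r1rho = e$table$omega1, cpmg = e$table$nu_cpmg,
                 prd_decay = e$table$t)
    graphics::plot(xc, e$table$value, pch = 16, cex = 0.6,
                   xlab = e$type, ylab = "value", main = e$type)
    ord <- order(xc)
    graphics::lines(xc[ord], pred[[i]][ord], col = 2)
  }
  invisible(x)
}
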