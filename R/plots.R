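# ggplot2 helpers for the result types.

#' Plot a radial distribution function
#' @param g_tbl tibble from \code{\link{rdf}}.
#' @return a ggplot.
#' @export
plot_rdf <- function(g_tbl) {
  ggplot2::ggplot(g_tbl, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "r (nm)", y = "g(r)")
}

#' Plot a per-bead dipole distribution
#' @param stats a \code{cg_dipole_stats}.
#' @return a ggplot.
#' @export
plot_dipole_distribution <- function(stats) {
  ggplot2::ggplot(stats$histogram,
                  ggplot2::aes(x = .data$dipole, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dipole moment (Debye)", y = "probability density")
}

#' Plot the per-window TI integrand
#' @param result a \code{cg_ti_result}.
#' @return a ggplot.
#' @export
plot_ti <- function(result) {
  w <- result$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$lambda, y = .data$dHdl)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$dHdl - .data$error,
                                          ymax = .data$dHdl + .data$error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda),
                  y = expression(paste("<", partialdiff * H / partialdiff * lambda,
                                       "> (kJ/mol)")))
}

#' Plot a potential of mean force
#' @param result a \code{cg_pmf_result}.
#' @return a ggplot.
#' @export
plot_pmf <- function(result) {
  pr <- result$profile[result$profile$covered, ]
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$z, y = .data$pmf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "PMF (kJ/mol)")
}

#' Plot logged run quantities over time
#' @param log the log tibble of a \code{cg_run}.
#' @param quantity column name to plot (default \code{"temperature"}).
#' @return a ggplot.
#' @export
plot_log <- function(log, quantity = "temperature") {
  stopifnot(quantity %in% names(log))
  ggplot2::ggplot(log, ggplot2::aes(x = .data$time, y = .data[[quantity]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = quantity)
}
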