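# Solvation free energies by thermodynamic integration with soft-core
# decoupling, and umbrella-sampling PMFs recombined with WHAM.

#' Soft-core pair interaction
#'
#' Separation-shifted soft-core form used to decouple a solute: the plain
#' shifted LJ + Coulomb pair Hamiltonian is evaluated at
#' \eqn{r_A = (r^6 + \alpha\sigma^6(1-\lambda))^{1/6}} and scaled by
#' \eqn{\lambda}. At \eqn{\lambda = 1} the plain kernels are recovered
#' exactly; at \eqn{\lambda = 0} energy and force vanish identically; for
#' \eqn{\lambda < 1} the energy stays finite down to r = 0.
#'
#' @param r distances (nm), vectorized.
#' @param lambda coupling parameter in [0, 1].
#' @param lj list with \code{epsilon}, \code{sigma} (as returned by
#'   \code{\link{lookup_lj_params}}), or NULL for a Coulomb-only pair.
#' @param q_a,q_b charges (e).
#' @param eps_r dielectric screening constant.
#' @param alpha soft-core alpha (default 0.5).
#' @param sigma_q radius-shift sigma for the Coulomb term (nm).
#' @param r_shift,r_cut LJ shift onset and cutoff (nm).
#' @return tibble with \code{r}, \code{energy}, \code{force}, \code{dHdl}.
#' @export
softcore_pair <- function(r, lambda, lj = NULL, q_a = 0, q_b = 0,
                          eps_r = 2.5, alpha = 0.5, sigma_q = 0.47,
                          r_shift = 0.9, r_cut = 1.2) {
  if (lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]", call. = FALSE)
  has_lj <- !is.null(lj)
  out <- softcore_eval_cpp(as.numeric(r), lambda, has_lj,
                           if (has_lj) lj$epsilon else 0,
                           if (has_lj) lj$sigma else 0.47,
                           q_a, q_b, eps_r, alpha, sigma_q, r_shift, r_cut)
  tibble::tibble(r = as.numeric(r), energy = out$energy, force = out$force,
                 dHdl = out$dHdl)
}

#' Thermodynamic integration over a lambda grid
#'
#' Runs one MD window per lambda value with the tagged solute molecule
#' soft-core-coupled to its surroundings (solvent-solvent interactions are
#' untouched), collects \eqn{\langle\partial H/\partial\lambda\rangle} with
#' block-averaged errors after discarding an equilibration fraction, and
#' integrates with the trapezoidal rule. The hydration/solvation free energy
#' is \eqn{\Delta G = G(\lambda{=}1) - G(\lambda{=}0)} (negative = favorable
#' solvation).
#'
#' @param system a \code{cg_system} containing the solute.
#' @param ff a \code{cg_forcefield}.
#' @param protocol a \code{cg_protocol} used per window (its \code{lambda}
#'   field is overridden).
#' @param solute the molecule id of the tagged solute (exactly one molecule).
#' @param lambdas lambda grid, strictly increasing, endpoints 0 and 1
#'   (default 22 evenly spaced points).
#' @param equil_fraction fraction of each window discarded as equilibration.
#' @param n_blocks blocks for the per-window error estimate.
#' @return object of class \code{cg_ti_result}.
#' @export
ti_run <- function(system, ff, protocol, solute, lambdas = seq(0, 1,
                   length.out = 22), equil_fraction = 0.2, n_blocks = 5) {
  stopifnot(inherits(system, "cg_system"), length(solute) == 1)
  if (is.unsorted(lambdas, strictly = TRUE) ||
      abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)
    stop("lambdas must increase strictly from 0 to 1", call. = FALSE)
  if (!solute %in% system$sites$mol_id)
    stop("solute molecule id not present in system", call. = FALSE)
  rows <- lapply(seq_along(lambdas), function(k) {
    p <- protocol
    p$lambda <- lambdas[k]
    sys <- system
    # independently seeded initial velocities per window
    withr::with_seed(protocol$seed + 7919L * k, {
      sys <- .mb_velocities(sys, protocol$temperature)
    })
    run <- run_md(sys, ff, p, solute = solute)
    x <- run$log$dHdl
    keep <- x[seq.int(floor(length(x) * equil_fraction) + 1L, length(x))]
    be <- .block_mean_err(keep, n_blocks)
    # flag windows whose block means drift monotonically (unequilibrated)
    idx <- cut(seq_along(keep), n_blocks, labels = FALSE)
    bm <- vapply(split(keep, idx), mean, numeric(1))
    drift <- !is.na(be[["error"]]) && be[["error"]] > 0 &&
      abs(bm[n_blocks] - bm[1]) > 4 * stats::sd(bm)
    tibble::tibble(lambda = lambdas[k], dHdl = be[["mean"]],
                   error = be[["error"]], n_samples = length(keep),
                   drift_warning = drift)
  })
  res <- structure(list(windows = dplyr::bind_rows(rows),
                        protocol = protocol, solute = solute),
                   class = "cg_ti_result")
  dg <- ti_integrate(res)
  res$delta_G <- dg$delta_G
  res$error <- dg$error
  res
}

#' Integrate a TI result with the trapezoidal rule
#'
#' @param result a \code{cg_ti_result}, or a tibble with \code{lambda},
#'   \code{dHdl} and optionally \code{error} columns.
#' @return tibble with \code{delta_G} (kJ/mol) and propagated \code{error}
#'   (root-sum-square of trapezoid-weighted window errors).
#' @export
ti_integrate <- function(result) {
  w <- if (inherits(result, "cg_ti_result")) result$windows else result
  stopifnot(nrow(w) >= 2)
  l <- w$lambda; y <- w$dHdl
  n <- length(l)
  wt <- numeric(n)
  wt[1] <- (l[2] - l[1]) / 2
  wt[n] <- (l[n] - l[n - 1]) / 2
  if (n > 2) wt[2:(n - 1)] <- (l[3:n] - l[1:(n - 2)]) / 2
  err <- if (!is.null(w$error) && !anyNA(w$error))
    sqrt(sum((wt * w$error)^2)) else NA_real_
  tibble::tibble(delta_G = sum(wt * y), error = err)
}

#' @export
print.cg_ti_result <- function(x, ...) {
  cat("<cg_ti_result>", nrow(x$windows), "windows | delta_G =",
      round(x$delta_G, 2), "+/-",
      ifelse(is.na(x$error), NA, round(x$error, 2)), "kJ/mol\n")
  invisible(x)
}

#' Per-window TI table
#' @param x a \code{cg_ti_result}.
#' @param ... unused.
#' @return tibble with one row per lambda window.
#' @method tidy cg_ti_result
#' @export
tidy.cg_ti_result <- function(x, ...) x$windows

#' One-row TI summary
#' @param x a \code{cg_ti_result}.
#' @param ... unused.
#' @return tibble with \code{delta_G}, \code{error}, \code{n_windows}.
#' @method glance cg_ti_result
#' @export
glance.cg_ti_result <- function(x, ...) {
  tibble::tibble(delta_G = x$delta_G, error = x$error,
                 n_windows = nrow(x$windows),
                 any_drift_warning = any(x$windows$drift_warning))
}

#' Recombine umbrella-sampling windows into a PMF (WHAM)
#'
#' Self-consistent weighted-histogram recombination of harmonically biased
#' windows \eqn{w(z) = \frac{1}{2} k (z - z_0)^2} along a one-dimensional
#' reaction coordinate.
#'
#' @param windows list of windows, each a list with \code{samples} (numeric
#'   reaction-coordinate values), \code{z0} (bias center) and \code{k} (bias
#'   force constant, kJ/mol/nm^2).
#' @param temperature temperature (K).
#' @param bin_width histogram bin (nm).
#' @param reference range \code{c(lo, hi)} of the coordinate where the PMF is
#'   zeroed (mean over the range); NULL zeroes at the global minimum.
#' @param tol convergence tolerance on the window free-energy constants.
#' @param maxit iteration cap.
#' @return object of class \code{cg_pmf_result} with the \code{profile}
#'   tibble (\code{z}, \code{pmf} in kJ/mol), window constants and the final
#'   self-consistency residual.
#' @export
umbrella_pmf <- function(windows, temperature = 300, bin_width = 0.02,
                         reference = NULL, tol = 1e-8, maxit = 10000) {
  stopifnot(length(windows) >= 1)
  kT <- .KB * temperature
  allz <- unlist(lapply(windows, function(w) w$samples))
  lo <- min(allz); hi <- max(allz)
  nbins <- max(2L, ceiling((hi - lo) / bin_width))
  edges <- lo + (hi - lo) * seq(0, nbins) / nbins
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  H <- vapply(windows, function(w)
    graphics::hist(w$samples, breaks = edges, plot = FALSE)$counts,
    numeric(nbins))                                   # nbins x nwin
  Ntot <- rowSums(t(H))                               # total count per window
  covered <- rowSums(H) > 0
  if (length(windows) > 1) {
    # windows must chain together: sorted by first occupied bin, each window
    # must start at or before the reach of the windows preceding it
    occ <- apply(H > 0, 2, function(col) range(which(col)))
    ord <- order(occ[1, ])
    reach <- occ[2, ord[1]]
    for (w in ord[-1]) {
      if (occ[1, w] > reach + 1)
        stop(sprintf("coverage error: window histograms leave a gap near z = %.3f",
                     mids[min(reach + 1, nbins)]), call. = FALSE)
      reach <- max(reach, occ[2, w])
    }
  }
  bias <- vapply(windows, function(w) 0.5 * w$k * (mids - w$z0)^2,
                 numeric(nbins))                      # nbins x nwin
  expb <- exp(-bias / kT)
  Nw <- colSums(H)
  f <- rep(0, length(windows))                        # exp(-beta f_w) scale
  resid <- Inf
  for (it in seq_len(maxit)) {
    denom <- as.numeric(expb %*% (Nw * exp(f / kT)))
    P <- rowSums(H) / pmax(denom, .Machine$double.xmin)
    fnew <- -kT * log(pmax(as.numeric(t(expb) %*% P), .Machine$double.xmin))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
  }
  P <- P / sum(P)
  pmf <- -kT * log(pmax(P, .Machine$double.xmin))
  if (is.null(reference)) {
    pmf <- pmf - min(pmf[covered])
  } else {
    sel <- covered & mids >= reference[1] & mids <= reference[2]
    if (!any(sel)) stop("reference range not covered by the sampled PMF",
                        call. = FALSE)
    pmf <- pmf - mean(pmf[sel])
  }
  structure(list(profile = tibble::tibble(z = mids, pmf = pmf,
                                          covered = covered),
                 window_f = f, residual = resid,
                 temperature = temperature),
            class = "cg_pmf_result")
}

#' @export
print.cg_pmf_result <- function(x, ...) {
  cat("<cg_pmf_result>", nrow(x$profile), "bins | residual:",
      format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' PMF profile table
#' @param x a \code{cg_pmf_result}.
#' @param ... unused.
#' @return the profile tibble.
#' @method tidy cg_pmf_result
#' @export
tidy.cg_pmf_result <- function(x, ...) x$profile
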