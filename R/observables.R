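# Property estimators: density, dielectric constant from dipole fluctuations,
# per-bead dipole statistics, RDFs, surface tension from pressure anisotropy,
# self-diffusion with the effective-time convention, charge/potential profiles.

.traj_frame <- function(traj, k) traj$frames[[k]]

.block_mean_err <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks) return(c(mean = mean(x), error = NA_real_))
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- vapply(split(x, idx), mean, numeric(1))
  c(mean = mean(x), error = stats::sd(bm) / sqrt(n_blocks))
}

#' Dipole moment of one polarizable water bead
#'
#' The bead dipole is \eqn{q (r_{WP} - r_{WM})}; its magnitude ranges from 0
#' (satellites coincident) to \eqn{2 q l} (antipodal satellites), i.e. 6.2
#' Debye for q = 0.46 e and l = 0.14 nm.
#'
#' @param wp_pos,wm_pos positions (length-3 vectors or n x 3 matrices, nm).
#' @param q satellite charge magnitude (e).
#' @return tibble with dipole components (e nm) and \code{magnitude} (Debye).
#' @export
bead_dipole <- function(wp_pos, wm_pos, q = 0.46) {
  wp <- unname(rbind(wp_pos)); wm <- unname(rbind(wm_pos))
  d <- q * (wp - wm)
  dimnames(d) <- NULL
  tibble::tibble(mu_x = d[, 1], mu_y = d[, 2], mu_z = d[, 3],
                 magnitude = sqrt(rowSums(d^2)) * .DEBYE)
}

#' Per-bead dipole statistics over a trajectory
#'
#' Computes the dipole magnitude of every polarizable water bead in every
#' frame and summarizes the distribution.
#'
#' @param traj a \code{cg_trajectory} from a polarizable-water run.
#' @param breaks histogram bin edges (Debye).
#' @return list of class \code{cg_dipole_stats}: \code{mean} (Debye),
#'   \code{max} observed, \code{histogram} tibble (bin midpoints, density),
#'   \code{per_frame} tibble of frame means.
#' @export
dipole_stats <- function(traj, breaks = seq(0, 7, by = 0.1)) {
  stopifnot(inherits(traj, "cg_trajectory"))
  wp <- which(traj$sites$type == "POL-WP")
  wm <- which(traj$sites$type == "POL-WM")
  if (length(wp) == 0) stop("no polarizable water in trajectory", call. = FALSE)
  q <- abs(traj$sites$charge[wp[1]])
  counts <- numeric(length(breaks) - 1)
  frame_means <- numeric(n_frames(traj))
  total <- 0; nmag <- 0; maxmag <- 0
  for (k in seq_len(n_frames(traj))) {
    P <- .traj_frame(traj, k)
    d <- P[wp, , drop = FALSE] - P[wm, , drop = FALSE]
    mag <- sqrt(rowSums(d^2)) * q * .DEBYE
    counts <- counts + graphics::hist(pmin(mag, max(breaks)), breaks = breaks,
                                      plot = FALSE)$counts
    frame_means[k] <- mean(mag)
    total <- total + sum(mag); nmag <- nmag + length(mag)
    maxmag <- max(maxmag, mag)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dens <- counts / (nmag * diff(breaks))
  structure(list(mean = total / nmag, max = maxmag,
                 histogram = tibble::tibble(dipole = mids, density = dens),
                 per_frame = tibble::tibble(time = traj$times,
                                            mean_dipole = frame_means)),
            class = "cg_dipole_stats")
}

#' @export
print.cg_dipole_stats <- function(x, ...) {
  cat("<cg_dipole_stats> mean:", round(x$mean, 2), "Debye | max observed:",
      round(x$max, 2), "Debye\n")
  invisible(x)
}

#' Dielectric constant from total-dipole fluctuations
#'
#' Clausius-Mosotti-type fluctuation estimate in the
#' \eqn{\epsilon_{rf} = \infty} limit:
#' \deqn{\epsilon = 1 + (\langle M^2\rangle - \langle M\rangle^2) /
#'   (3 \epsilon_0 V k_B T)}
#' evaluated in md units where \eqn{1/\epsilon_0 = 4\pi f_{elec}}. The
#' run-time screening constant is not inserted into the fluctuation formula.
#'
#' @param traj a \code{cg_trajectory} whose log carries the total dipole M.
#' @param temperature temperature (K).
#' @param n_blocks number of blocks for the error estimate (>= 5 recommended).
#' @return tibble with \code{epsilon}, \code{error}, \code{n_records}.
#' @export
dielectric_constant <- function(traj, temperature = 300, n_blocks = 5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  log <- traj$log
  if (nrow(log) < 2) stop("data error: need at least 2 records with stored dipole",
                          call. = FALSE)
  if (any(log$volume <= 0)) stop("data error: zero-volume frame", call. = FALSE)
  M <- cbind(log$M_x, log$M_y, log$M_z)
  eps_of <- function(rows) {
    m <- M[rows, , drop = FALSE]
    fluct <- mean(rowSums(m^2)) - sum(colMeans(m)^2)
    1 + 4 * pi * .F_ELEC * fluct / (3 * mean(log$volume[rows]) * .KB * temperature)
  }
  eps <- eps_of(seq_len(nrow(log)))
  idx <- cut(seq_len(nrow(log)), n_blocks, labels = FALSE)
  be <- vapply(split(seq_len(nrow(log)), idx), eps_of, numeric(1))
  tibble::tibble(epsilon = eps, error = stats::sd(be) / sqrt(n_blocks),
                 n_records = nrow(log))
}

#' Mean mass density of a trajectory
#'
#' Total mass over instantaneous box volume, averaged over log records, with
#' a block-averaged error bar.
#'
#' @param traj a \code{cg_trajectory}.
#' @param n_blocks number of blocks for the error estimate.
#' @return tibble with \code{density} (kg/m^3), \code{error}, \code{n_records}.
#' @export
mass_density <- function(traj, n_blocks = 5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  mass <- sum(traj$sites$mass)
  rho <- mass * .AMU_DENS / traj$log$volume
  be <- .block_mean_err(rho, n_blocks)
  tibble::tibble(density = be[["mean"]], error = be[["error"]],
                 n_records = length(rho))
}

.select_sites <- function(traj, species) {
  type <- .norm_type(traj$sites$type)
  sel <- which(type %in% .norm_type(species))
  if (length(sel) == 0) stop("no sites of species ", paste(species, collapse = ","),
                             call. = FALSE)
  sel
}

#' Radial distribution function
#'
#' Shell-normalized pair-distance histogram with minimum-image distances,
#' averaged over frames; the same-species case excludes self-pairs.
#'
#' @param traj a \code{cg_trajectory}.
#' @param species_a,species_b bead-type names (e.g. \code{"POL-W"}, \code{"Qd"}).
#' @param bin_width histogram bin (nm).
#' @param r_max maximum distance (nm); must not exceed half the smallest box
#'   edge. Default: half the smallest box edge.
#' @return tibble with \code{r} (bin midpoints, nm) and \code{g}.
#' @export
rdf <- function(traj, species_a, species_b = species_a, bin_width = 0.02,
                r_max = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  boxes <- traj$boxes
  if (is.null(r_max)) r_max <- min(boxes) / 2
  if (r_max > min(boxes) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge", call. = FALSE)
  sel_a <- .select_sites(traj, species_a)
  sel_b <- .select_sites(traj, species_b)
  same <- setequal(sel_a, sel_b)
  nbins <- floor(r_max / bin_width)
  counts <- numeric(nbins)
  vsum <- 0
  for (k in seq_len(n_frames(traj))) {
    P <- .traj_frame(traj, k)
    b <- boxes[k, ]
    counts <- counts + rdf_accum_cpp(P, b, sel_a - 1L, sel_b - 1L,
                                     bin_width, nbins, same)
    vsum <- vsum + prod(b)
  }
  nf <- n_frames(traj)
  Vbar <- vsum / nf
  edges <- seq(0, nbins) * bin_width
  shell <- 4 / 3 * pi * diff(edges^3)
  nb_eff <- if (same) length(sel_b) - 1 else length(sel_b)
  ideal <- length(sel_a) * nb_eff / Vbar * shell * nf
  tibble::tibble(r = (edges[-1] + edges[-(nbins + 1)]) / 2,
                 g = counts / ideal)
}

#' Surface tension from pressure-tensor anisotropy
#'
#' For a slab with its normal along z,
#' \deqn{\gamma = \frac{L_z}{2}\left(\langle P_{zz}\rangle -
#'   \frac{\langle P_{xx}\rangle + \langle P_{yy}\rangle}{2}\right)}
#' with the factor 2 accounting for the two interfaces; converted with
#' 1 bar nm = 0.1 mN/m.
#'
#' @param traj a \code{cg_trajectory} with the pressure tensor in the log.
#' @param n_blocks number of blocks for the error estimate.
#' @return tibble with \code{gamma} (mN/m), \code{error}, \code{n_records}.
#' @export
surface_tension <- function(traj, n_blocks = 5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  log <- traj$log
  g <- log$box_z / 2 * (log$P_zz - (log$P_xx + log$P_yy) / 2) * 0.1
  be <- .block_mean_err(g, n_blocks)
  tibble::tibble(gamma = be[["mean"]], error = be[["error"]],
                 n_records = length(g))
}

#' Self-diffusion coefficient from the mean-square displacement
#'
#' Computes the MSD of the selected sites with multiple time origins and fits
#' its slope over the configured window. Coarse-grained dynamics are faster
#' than atomistic dynamics on the smoothed energy landscape; kinetic
#' quantities are therefore reported against the effective time
#' \eqn{t_{eff} = 4 t} (factor configurable). The per-bead value
#' \code{D_CG} uses effective time; \code{D_molecular} \eqn{= 4 D_{CG}} is the
#' equivalent single-molecule diffusion coefficient.
#'
#' @param traj a \code{cg_trajectory} with unwrapped coordinates (the engine
#'   propagates coordinates without wrapping, so periodic jumps never occur).
#' @param fit_window time window for the slope fit (ps, actual time). Must not
#'   exceed the trajectory length.
#' @param effective_time_factor the effective-time multiplier (default 4).
#' @param species site selection (default the water LJ core).
#' @return tibble with \code{D_CG} and \code{D_molecular} (cm^2/s), the
#'   \code{effective_time_factor} used, and the fit slope (nm^2/ps).
#' @export
diffusion_coefficient <- function(traj, fit_window = NULL,
                                  effective_time_factor = 4,
                                  species = c("POL-W", "P4")) {
  stopifnot(inherits(traj, "cg_trajectory"))
  times <- traj$times
  nf <- length(times)
  if (nf < 3) stop("trajectory too short for an msd fit", call. = FALSE)
  dt <- times[2] - times[1]
  span <- times[nf] - times[1]
  if (is.null(fit_window)) fit_window <- span / 2
  if (fit_window > span + 1e-9)
    stop("fit window exceeds trajectory length", call. = FALSE)
  sel <- .select_sites(traj, intersect(.norm_type(species),
                                       .norm_type(traj$sites$type)))
  nlag <- max(2L, floor(fit_window / dt))
  origin_stride <- max(1L, floor(nlag / 10))
  origins <- seq(1L, nf - nlag, by = origin_stride)
  msd <- numeric(nlag)
  P <- lapply(seq_len(nf), function(k) .traj_frame(traj, k)[sel, , drop = FALSE])
  for (lag in seq_len(nlag)) {
    acc <- 0
    for (o in origins) acc <- acc + mean(rowSums((P[[o + lag]] - P[[o]])^2))
    msd[lag] <- acc / length(origins)
  }
  tau <- seq_len(nlag) * dt
  slope <- stats::coef(stats::lm(msd ~ tau))[["tau"]]           # nm^2/ps
  D_cg <- slope / (6 * effective_time_factor) * 1e-2            # cm^2/s
  tibble::tibble(D_CG = D_cg,
                 D_molecular = effective_time_factor * D_cg,
                 effective_time_factor = effective_time_factor,
                 slope_nm2_ps = slope, fit_window_ps = fit_window)
}

#' Charge-density and electrostatic-potential profile
#'
#' Bins the charge density along the given axis and integrates Poisson's
#' equation twice, with the potential and the field set to zero at the lower
#' box boundary.
#'
#' @param traj a \code{cg_trajectory}.
#' @param axis profile axis, only \code{"z"} is meaningful for the slab
#'   systems built by this package.
#' @param bin_width bin size (nm).
#' @return tibble with \code{z} (nm), \code{rho} (e/nm^3), \code{phi} (V).
#' @export
potential_profile <- function(traj, axis = "z", bin_width = 0.1) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (!identical(axis, "z"))
    stop("usage error: profiles are computed along the slab normal z",
         call. = FALSE)
  ax <- 3L
  q <- traj$sites$charge
  nf <- n_frames(traj)
  Lz <- mean(traj$boxes[, ax])
  nbins <- max(2L, floor(Lz / bin_width))
  h <- Lz / nbins
  rho <- numeric(nbins)
  for (k in seq_len(nf)) {
    zc <- .traj_frame(traj, k)[, ax] %% traj$boxes[k, ax]
    bins <- pmin(nbins, floor(zc / traj$boxes[k, ax] * nbins) + 1L)
    rho <- rho + vapply(seq_len(nbins), function(b) sum(q[bins == b]),
                        numeric(1))
  }
  area <- mean(traj$boxes[, 1] * traj$boxes[, 2])
  rho <- rho / (nf * area * h)                       # e / nm^3
  # Poisson: d2(phi)/dz2 = -rho/eps0 ; phi(0) = 0, dphi/dz(0) = 0
  efield <- cumsum(rho) * h * 4 * pi * .F_ELEC       # kJ/mol/e/nm
  phi <- -cumsum(efield) * h                         # kJ/mol/e
  tibble::tibble(z = (seq_len(nbins) - 0.5) * h, rho = rho,
                 phi = phi * 0.0103643)
}
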