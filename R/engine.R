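# R surface of the MD core: protocol objects, force evaluation, constraint
# solver, and the leapfrog/Berendsen driver implemented in C++.

.ENSEMBLES <- c(NVE = 0L, NVT = 1L, NPT = 2L, NP_zAT = 3L, NP_zP_xyT = 4L)

#' Define a simulation protocol
#'
#' Collects ensemble, coupling and cutoff settings. Defaults follow the
#' standard coarse-grained setup: 20 fs time step, Berendsen weak coupling
#' with \eqn{\tau_T} = 0.3 ps and \eqn{\tau_p} = 3.0 ps, compressibility
#' 4.5e-5 1/bar, LJ shift from 0.9 nm, cutoff 1.2 nm, Verlet skin 0.2 nm.
#'
#' @param ensemble one of \code{"NVE"}, \code{"NVT"}, \code{"NPT"} (isotropic),
#'   \code{"NP_zAT"} (z-only barostat, fixed area), \code{"NP_zP_xyT"}
#'   (independent z and xy coupling).
#' @param n_steps number of integration steps.
#' @param temperature thermostat target (K).
#' @param pressure barostat target (bar).
#' @param dt time step (ps).
#' @param tau_t,tau_p coupling time constants (ps).
#' @param compressibility isothermal compressibility used by the barostat (1/bar).
#' @param r_cut nonbonded cutoff (nm).
#' @param r_shift_lj onset of the LJ shift (nm).
#' @param skin Verlet-list skin (nm), used when \code{nstlist = 0}.
#' @param nstlist neighbor-list update interval in steps with list radius
#'   equal to the cutoff (the parameterization protocol; default 10). Set 0
#'   for displacement-triggered Verlet lists with the \code{skin}, which
#'   never miss a pair and suit microcanonical checks.
#' @param field_z uniform external electric field along z (V/nm).
#' @param coulomb_gating \code{"group"} (default) gates electrostatics by the
#'   distance between bead centers (charge-group centers), the convention the
#'   model was parameterized with; \code{"site"} gates each charged site pair
#'   by its own distance, which is strictly energy conserving.
#' @param lambda solute-solvent coupling parameter (1 = fully coupled).
#' @param sc_alpha soft-core alpha.
#' @param umbrella_k,umbrella_z0 harmonic z-restraint on the solute
#'   center of mass (kJ/mol/nm^2, nm); 0 disables the bias.
#' @param log_stride,traj_stride output strides (steps).
#' @param com_stride stride for center-of-mass motion removal (steps).
#' @param shake_tol,shake_maxit constraint-solver tolerance (nm) and
#'   iteration cap.
#' @param seed integer seed (recorded for provenance; the integrator itself is
#'   deterministic, randomness enters through the builders).
#' @return object of class \code{cg_protocol}.
#' @export
md_protocol <- function(ensemble = "NPT", n_steps = 1000, temperature = 300,
                        pressure = 1, dt = 0.02, tau_t = 0.3, tau_p = 3.0,
                        compressibility = 4.5e-5, r_cut = 1.2,
                        r_shift_lj = 0.9, skin = 0.2, nstlist = 10L,
                        field_z = 0,
                        coulomb_gating = c("group", "site"),
                        lambda = 1, sc_alpha = 0.5,
                        umbrella_k = 0, umbrella_z0 = 0,
                        log_stride = 10, traj_stride = 200, com_stride = 10,
                        shake_tol = 1e-6, shake_maxit = 100, seed = 1L) {
  ensemble <- match.arg(ensemble, names(.ENSEMBLES))
  coulomb_gating <- match.arg(coulomb_gating)
  stopifnot(dt > 0, n_steps >= 0, tau_t >= dt, tau_p >= dt,
            r_shift_lj < r_cut, lambda >= 0, lambda <= 1)
  structure(list(ensemble = ensemble, n_steps = as.integer(n_steps),
                 temperature = temperature, pressure = pressure, dt = dt,
                 tau_t = tau_t, tau_p = tau_p,
                 compressibility = compressibility, r_cut = r_cut,
                 r_shift_lj = r_shift_lj, skin = skin,
                 nstlist = as.integer(nstlist), field_z = field_z,
                 coulomb_gating = coulomb_gating,
                 lambda = lambda, sc_alpha = sc_alpha,
                 umbrella_k = umbrella_k, umbrella_z0 = umbrella_z0,
                 log_stride = as.integer(log_stride),
                 traj_stride = as.integer(traj_stride),
                 com_stride = as.integer(com_stride),
                 shake_tol = shake_tol, shake_maxit = as.integer(shake_maxit),
                 seed = as.integer(seed)),
            class = "cg_protocol")
}

#' @export
print.cg_protocol <- function(x, ...) {
  cat("<cg_protocol>", x$ensemble, "| steps:", x$n_steps, "| dt:", x$dt,
      "ps | T:", x$temperature, "K | P:", x$pressure, "bar\n")
  invisible(x)
}

# Encode a cg_system + forcefield into the flat list the C++ core consumes.
# solute: molecule ids treated as the decoupling/bias group.
.encode_sys <- function(system, ff, solute = integer()) {
  s <- system$sites
  type <- .norm_type(s$type)
  ljname <- .lj_name(type)
  has_lj <- ff$beads$has_lj[match(type, ff$beads$name)]
  if (anyNA(has_lj)) stop("unknown bead type in system", call. = FALSE)
  lj_types <- sort(unique(ljname[has_lj]))
  ljt <- ifelse(has_lj, match(ljname, lj_types), 0L) - 1L
  ljt[is.na(ljt)] <- -1L
  nlj <- length(lj_types)
  eps <- ff$epsilon[lj_types, lj_types, drop = FALSE]
  sig <- ff$sigma[lj_types, lj_types, drop = FALSE]
  list(pos = cbind(s$x, s$y, s$z), vel = cbind(s$vx, s$vy, s$vz),
       box = as.numeric(system$box), mass = s$mass, charge = s$charge,
       ljt = as.integer(ljt), nlj = nlj,
       eps = as.numeric(t(eps)), sig = as.numeric(t(sig)),
       coni = as.integer(system$constraints$i - 1L),
       conj = as.integer(system$constraints$j - 1L),
       cond = as.numeric(system$constraints$length),
       angi = as.integer(system$angles$i - 1L),
       angj = as.integer(system$angles$j - 1L),
       angk = as.integer(system$angles$k - 1L),
       ang0 = as.numeric(system$angles$theta0),
       angK = as.numeric(system$angles$k_theta),
       angf = if (is.null(system$angles$funct)) rep(2L, nrow(system$angles))
              else as.integer(system$angles$funct),
       bndi = as.integer(system$bonds$i - 1L),
       bndj = as.integer(system$bonds$j - 1L),
       bnd0 = as.numeric(system$bonds$b0),
       bndk = as.numeric(system$bonds$kb),
       molid = as.integer(s$mol_id - 1L),
       solute = s$mol_id %in% solute,
       excl_i = as.integer(system$exclusions$i - 1L),
       excl_j = as.integer(system$exclusions$j - 1L))
}

.encode_opts <- function(protocol, ff) {
  list(r_cut = protocol$r_cut, r_shift_lj = protocol$r_shift_lj,
       eps_r = ff$eps_r, field_z = protocol$field_z,
       lambda = protocol$lambda, sc_alpha = protocol$sc_alpha,
       sc_sigma_q = 0.47,
       site_gating = identical(protocol$coulomb_gating, "site"),
       umbrella_k = protocol$umbrella_k, umbrella_z0 = protocol$umbrella_z0)
}

#' Evaluate forces, energies and the virial for one configuration
#'
#' Sums shifted LJ over LJ-bearing pairs, shifted Coulomb over charged pairs,
#' harmonic bonds and angles, minus the declared exclusions; an external field
#' adds \eqn{q E_z} on every charged site. The pressure tensor is computed
#' from the kinetic term and the pair virial.
#'
#' @param system a \code{cg_system}.
#' @param ff a \code{cg_forcefield}.
#' @param protocol a \code{cg_protocol} (cutoffs, field, coupling settings).
#' @param solute molecule ids forming the soft-core-decoupled group (TI runs).
#' @return list of class \code{cg_forces}: \code{forces} (n x 3, kJ/mol/nm),
#'   \code{energies} (named, kJ/mol), \code{virial} (3 x 3, kJ/mol),
#'   \code{pressure} (3 x 3, bar), \code{dHdl} (kJ/mol).
#' @export
compute_forces <- function(system, ff, protocol = md_protocol(), solute = integer()) {
  stopifnot(inherits(system, "cg_system"), inherits(ff, "cg_forcefield"))
  enc <- .encode_sys(system, ff, solute)
  out <- compute_forces_cpp(enc, .encode_opts(protocol, ff))
  V <- prod(system$box)
  vel <- cbind(system$sites$vx, system$sites$vy, system$sites$vz)
  K <- t(vel * system$sites$mass) %*% vel
  P <- (K + out$virial) / V * .PRESFAC
  structure(list(forces = out$forces, energies = out$energies,
                 virial = out$virial, pressure = P, dHdl = out$dHdl),
            class = "cg_forces")
}

#' Project positions back onto the constraint manifold
#'
#' Iterative SHAKE-style pair corrections: each constrained distance is
#' restored to its target length by mass-weighted displacements of the two
#' partners along the reference bond direction, iterated to convergence.
#'
#' @param ref_positions n x 3 matrix satisfying the constraints (reference
#'   geometry defining correction directions).
#' @param new_positions n x 3 matrix to correct.
#' @param system a \code{cg_system} providing constraints, masses and box.
#' @param tol convergence tolerance on each distance (nm).
#' @param maxit iteration cap.
#' @return corrected n x 3 matrix.
#' @export
apply_constraints <- function(ref_positions, new_positions, system,
                              tol = 1e-6, maxit = 100) {
  stopifnot(inherits(system, "cg_system"))
  if (nrow(system$constraints) == 0) return(new_positions)
  shake_cpp(ref_positions, new_positions, as.numeric(system$box),
            as.integer(system$constraints$i - 1L),
            as.integer(system$constraints$j - 1L),
            as.numeric(system$constraints$length),
            system$sites$mass, tol, as.integer(maxit))
}

.LOG_COLS <- c("time", "E_lj", "E_coulomb", "E_bond", "E_angle", "E_field",
               "E_bias", "E_pot", "E_kin", "temperature", "P_xx", "P_yy",
               "P_zz", "pressure", "volume", "box_x", "box_y", "box_z",
               "M_x", "M_y", "M_z", "dHdl")

#' Run molecular dynamics
#'
#' Leapfrog integration with SHAKE constraints, Berendsen weak-coupling
#' thermostat/barostat, neighbor lists with periodic boundaries, optional
#' uniform external field and soft-core solute decoupling. The integrator is
#' deterministic; all randomness enters through the seeded builders.
#'
#' @param system a \code{cg_system} (positions in nm, velocities in nm/ps).
#' @param ff a \code{cg_forcefield}.
#' @param protocol a \code{cg_protocol}.
#' @param solute molecule ids of the decoupling/bias group (TI and umbrella runs).
#' @return object of class \code{cg_run}: \code{system} (final state),
#'   \code{trajectory} (a \code{cg_trajectory}: frames, times, boxes, site
#'   metadata), \code{log} (tibble, one row per log stride with per-term
#'   energies in kJ/mol, kinetic temperature in K, pressure tensor diagonal in
#'   bar, volume in nm^3 and the total dipole M in e nm), \code{protocol}.
#' @export
run_md <- function(system, ff, protocol, solute = integer()) {
  stopifnot(inherits(system, "cg_system"), inherits(ff, "cg_forcefield"),
            inherits(protocol, "cg_protocol"))
  if (protocol$r_cut >= min(system$box) / 2)
    stop("r_cut must be below half the smallest box edge", call. = FALSE)
  enc <- .encode_sys(system, ff, solute)
  prot <- c(.encode_opts(protocol, ff),
            list(dt = protocol$dt, n_steps = protocol$n_steps,
                 ensemble_code = .ENSEMBLES[[protocol$ensemble]],
                 temperature = protocol$temperature, tau_t = protocol$tau_t,
                 pressure = protocol$pressure, tau_p = protocol$tau_p,
                 compressibility = protocol$compressibility,
                 skin = protocol$skin, nstlist = protocol$nstlist,
                 log_stride = protocol$log_stride,
                 traj_stride = protocol$traj_stride,
                 com_stride = protocol$com_stride,
                 shake_tol = protocol$shake_tol,
                 shake_maxit = protocol$shake_maxit))
  out <- run_md_cpp(enc, prot)
  final <- system
  final$sites$x <- out$pos[, 1]; final$sites$y <- out$pos[, 2]
  final$sites$z <- out$pos[, 3]
  final$sites$vx <- out$vel[, 1]; final$sites$vy <- out$vel[, 2]
  final$sites$vz <- out$vel[, 3]
  final$box <- as.numeric(out$box)
  log <- tibble::as_tibble(stats::setNames(as.data.frame(out$log), .LOG_COLS))
  traj <- structure(list(frames = out$frames,
                         times = as.numeric(out$frame_times),
                         boxes = out$frame_boxes,
                         sites = system$sites[, c("type", "mass", "charge",
                                                  "mol_id", "mol_name")],
                         log = log, ndf = out$ndf),
                    class = "cg_trajectory")
  structure(list(system = final, trajectory = traj, log = log,
                 protocol = protocol, ndf = out$ndf),
            class = "cg_run")
}

#' @export
print.cg_run <- function(x, ...) {
  cat("<cg_run>", x$protocol$ensemble, "|", x$protocol$n_steps, "steps x",
      x$protocol$dt, "ps |", length(x$trajectory$times), "frames,",
      nrow(x$log), "log records\n")
  invisible(x)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", length(x$times), "frames,", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{cg_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Summary statistics of a run
#'
#' @param x a \code{cg_run}.
#' @param ... unused.
#' @return one-row tibble with mean temperature, pressure, volume, density and
#'   potential energy over the logged records.
#' @method glance cg_run
#' @export
glance.cg_run <- function(x, ...) {
  mass <- sum(x$system$sites$mass)
  tibble::tibble(
    n_steps = x$protocol$n_steps,
    time_ps = x$protocol$n_steps * x$protocol$dt,
    mean_temperature = mean(x$log$temperature),
    mean_pressure = mean(x$log$pressure),
    mean_volume = mean(x$log$volume),
    mean_density = mean(mass * .AMU_DENS / x$log$volume),
    mean_E_pot = mean(x$log$E_pot))
}

#' Steepest-descent energy minimization
#'
#' Relaxes close contacts before dynamics: sites move along the force
#' direction with an adaptive step, constraints are re-projected after every
#' move, and uphill moves are rejected with a halved step. Intended for
#' freshly built slab systems whose lattice packing leaves tight contacts.
#'
#' @param system a \code{cg_system}.
#' @param ff a \code{cg_forcefield}.
#' @param protocol a \code{cg_protocol} (cutoffs); the ensemble is ignored.
#' @param max_steps iteration cap.
#' @param initial_step largest per-coordinate displacement (nm).
#' @param force_tol stop once the largest force component (kJ/mol/nm) falls
#'   below this value.
#' @return the relaxed \code{cg_system} (velocities untouched).
#' @export
minimize_energy <- function(system, ff, protocol = md_protocol(),
                            max_steps = 200, initial_step = 0.02,
                            force_tol = 50) {
  stopifnot(inherits(system, "cg_system"))
  pos <- cbind(system$sites$x, system$sites$y, system$sites$z)
  f <- compute_forces(system, ff, protocol)
  E <- sum(f$energies)
  step <- initial_step
  for (it in seq_len(max_steps)) {
    fmax <- max(abs(f$forces))
    if (fmax < force_tol) break
    cand <- pos + f$forces * (step / fmax)
    cand <- apply_constraints(pos, cand, system,
                              tol = protocol$shake_tol,
                              maxit = protocol$shake_maxit)
    trial <- system
    trial$sites$x <- cand[, 1]; trial$sites$y <- cand[, 2]
    trial$sites$z <- cand[, 3]
    ftrial <- compute_forces(trial, ff, protocol)
    Etrial <- sum(ftrial$energies)
    if (Etrial < E) {
      pos <- cand; f <- ftrial; E <- Etrial
      step <- min(step * 1.2, 0.05)
    } else {
      step <- step / 2
      if (step < 1e-6) break
    }
  }
  system$sites$x <- pos[, 1]; system$sites$y <- pos[, 2]
  system$sites$z <- pos[, 3]
  system
}
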