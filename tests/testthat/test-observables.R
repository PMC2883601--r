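# Property estimators against closed-form and synthetic oracles.

test_that("bead dipole conversion reproduces the analytic bounds", {
  # coincident satellites: zero dipole
  expect_equal(bead_dipole(c(1, 1, 1), c(1, 1, 1))$magnitude, 0)
  # antipodal satellites at l = 0.14 nm: 2ql = 0.1288 e nm = 6.2 Debye
  d <- bead_dipole(c(0.14, 0, 0), c(-0.14, 0, 0), q = 0.46)
  expect_equal(d$mu_x, 2 * 0.46 * 0.14, tolerance = 1e-12)
  expect_equal(round(d$magnitude, 1), 6.2)
  # four aligned dipoles of 2.35 Debye sum to 9.4 Debye
  one <- 2.35 / 48.0321                     # e nm along x
  expect_equal(round(4 * one * 48.0321, 1), 9.4)
})

test_that("dielectric constant recovers a known Gaussian dipole variance", {
  set.seed(101)
  nrec <- 20000
  V <- 50; Tk <- 300; s <- 2.5              # per-component sd, e nm
  M <- matrix(rnorm(3 * nrec, sd = s), nrec, 3)
  log <- tibble::tibble(time = seq_len(nrec), volume = V,
                        M_x = M[, 1], M_y = M[, 2], M_z = M[, 3])
  traj <- synthetic_traj(log)
  got <- dielectric_constant(traj, temperature = Tk)
  want <- 1 + 4 * pi * 138.935485 * 3 * s^2 / (3 * V * 0.00831446 * Tk)
  expect_equal(got$epsilon, want, tolerance = 0.05)
  # no fluctuations: vacuum limit
  log0 <- tibble::tibble(time = 1:10, volume = V, M_x = 0, M_y = 0, M_z = 0)
  expect_equal(dielectric_constant(synthetic_traj(log0))$epsilon, 1)
  # preconditions surface as data errors
  expect_error(dielectric_constant(synthetic_traj(log0[1, ])), "data error")
})

test_that("mass density averages instantaneous mass over volume", {
  edge <- (400 * 72 * 1.66054 / 1000)^(1 / 3)
  sites <- tibble::tibble(type = rep("P4", 400), mass = 72, charge = 0,
                          mol_id = 1:400, mol_name = "standard_water")
  log <- tibble::tibble(time = 1:10, volume = edge^3)
  got <- mass_density(synthetic_traj(log, sites = sites))
  expect_equal(got$density, 1000, tolerance = 1e-9)
  expect_equal(got$error, 0)
})

test_that("rdf is flat for an ideal gas and sharp for a fixed pair", {
  set.seed(33)
  L <- 5; n <- 600
  sites <- tibble::tibble(type = rep("P4", n), mass = 72, charge = 0,
                          mol_id = seq_len(n), mol_name = "standard_water")
  frames <- lapply(1:20, function(k) matrix(runif(3 * n, 0, L), n, 3))
  traj <- synthetic_traj(tibble::tibble(time = 1:20, volume = L^3),
                         sites = sites, frames = frames,
                         boxes = matrix(L, 20, 3))
  g <- rdf(traj, "P4", bin_width = 0.1)
  mid <- g[g$r > 0.5 & g$r < 2.2, ]
  expect_true(all(abs(mid$g - 1) < 0.15))
  expect_equal(mean(mid$g), 1, tolerance = 0.02)
  # two fixed particles at 0.5 nm: a single occupied bin
  two <- synthetic_traj(tibble::tibble(time = 1, volume = L^3),
                        sites = sites[1:2, ],
                        frames = list(rbind(c(1, 1, 1), c(1.5, 1, 1))),
                        boxes = matrix(L, 1, 3))
  g2 <- rdf(two, "P4", bin_width = 0.02)
  expect_equal(g2$r[which(g2$g > 0)], 0.51, tolerance = 0.011)
  expect_equal(sum(g2$g > 0), 1)
  expect_error(rdf(two, "P4", bin_width = -1), "bin_width")
  expect_error(rdf(two, "P4", r_max = 10), "half the smallest box edge")
})

test_that("surface tension follows the pressure-anisotropy formula", {
  # isotropic tensor: gamma = 0
  iso <- tibble::tibble(time = 1:10, P_xx = 5, P_yy = 5, P_zz = 5, box_z = 10)
  expect_equal(surface_tension(synthetic_traj(iso))$gamma, 0)
  # hand-worked case: Pzz = 1, Pxx = Pyy = -1 bar, Lz = 10 nm -> 1.0 mN/m
  aniso <- tibble::tibble(time = 1:10, P_xx = -1, P_yy = -1, P_zz = 1,
                          box_z = 10)
  expect_equal(surface_tension(synthetic_traj(aniso))$gamma, 1.0)
})

test_that("diffusion estimator recovers a Brownian walk and handles edge cases", {
  set.seed(55)
  n <- 150; nf <- 400; dt <- 1             # ps frames
  D0 <- 2e-3                               # nm^2/ps
  sites <- tibble::tibble(type = rep("P4", n), mass = 72, charge = 0,
                          mol_id = seq_len(n), mol_name = "standard_water")
  steps <- lapply(seq_len(nf), function(k)
    matrix(rnorm(3 * n, sd = sqrt(2 * D0 * dt)), n, 3))
  frames <- Reduce(`+`, steps, accumulate = TRUE)
  traj <- synthetic_traj(tibble::tibble(time = seq_len(nf), volume = 1000),
                         sites = sites, frames = frames,
                         boxes = matrix(10, nf, 3),
                         times = seq_len(nf) * dt)
  got <- diffusion_coefficient(traj, fit_window = 100,
                               effective_time_factor = 4)
  # D_molecular = 4 D_CG equals the plain slope/6 over actual time
  expect_equal(got$D_molecular, D0 * 1e-2, tolerance = 0.05)
  expect_equal(got$D_CG * 4, got$D_molecular)
  # frozen trajectory diffuses nowhere
  frozen <- synthetic_traj(tibble::tibble(time = 1:50, volume = 1000),
                           sites = sites,
                           frames = rep(frames[1], 50),
                           boxes = matrix(10, 50, 3), times = 1:50)
  expect_equal(diffusion_coefficient(frozen, fit_window = 20)$D_CG, 0)
  expect_error(diffusion_coefficient(traj, fit_window = 1e5),
               "exceeds trajectory length")
})

test_that("potential profile matches the parallel-plate closed form", {
  # two opposite uniform charge sheets at z = 2 and z = 6 in a 10 nm box
  L <- 10; nq <- 400
  set.seed(9)
  mk <- function(z, q) tibble::tibble(type = if (q > 0) "Qd" else "Qa",
                                      mass = 72, charge = q,
                                      mol_id = NA_integer_,
                                      mol_name = "ion")
  sites <- dplyr::bind_rows(lapply(seq_len(nq), function(i) mk(2, 1)),
                            lapply(seq_len(nq), function(i) mk(6, -1)))
  sites$mol_id <- seq_len(2 * nq)
  pos <- rbind(cbind(runif(nq, 0, 4), runif(nq, 0, 4), 2),
               cbind(runif(nq, 0, 4), runif(nq, 0, 4), 6))
  traj <- synthetic_traj(tibble::tibble(time = 1, volume = 4 * 4 * L),
                         sites = sites, frames = list(pos),
                         boxes = matrix(c(4, 4, L), 1, 3, byrow = TRUE))
  prof <- potential_profile(traj, bin_width = 0.2)
  # field between the plates: E = sigma/eps0; potential drop = E * d
  sigma <- nq / (4 * 4)                               # e nm^-2
  drop_volts <- 4 * pi * 138.935485 * sigma * 4 * 0.0103643
  outside_hi <- prof$phi[prof$z > 6.5]
  expect_equal(mean(outside_hi), -drop_volts, tolerance = 0.05)
  # constant potential beyond the second plate
  expect_lt(diff(range(outside_hi)), 1e-6)
  # linearity between the plates: interpolate between the end bins
  lin <- prof[prof$z > 2.5 & prof$z < 5.5, ]
  pred <- lin$phi[1] + (lin$z - lin$z[1]) *
    (lin$phi[nrow(lin)] - lin$phi[1]) / (lin$z[nrow(lin)] - lin$z[1])
  expect_lt(max(abs(lin$phi - pred)), 1e-3 * abs(drop_volts))
  # zero charge everywhere: identically zero potential
  zero <- traj
  zero$sites$charge <- 0
  expect_true(all(potential_profile(zero)$phi == 0))
  expect_error(potential_profile(traj, axis = "x"), "usage error")
})

test_that("dipole statistics stay within the analytic bound over a run", {
  sys <- build_water_box(125, seed = 3)
  run <- run_md(sys, ff_pol, md_protocol(ensemble = "NVT", n_steps = 1500,
                                         traj_stride = 100))
  ds <- dipole_stats(run$trajectory)
  expect_lte(ds$max, 6.2 + 0.01)
  expect_gt(ds$mean, 0)
  # total dipole in the log is consistent with positions and charges
  k <- n_frames(run$trajectory)
  P <- run$trajectory$frames[[k]]
  q <- run$system$sites$charge
  Mx <- sum(q * P[, 1])
  logrow <- run$log[nrow(run$log), ]
  expect_equal(logrow$M_x, Mx, tolerance = 1e-10)
})

test_that("polarizable and standard salt solutions give matching water RDFs", {
  # reduced ionic-solution comparison: the revised Q rows + polarizable water
  # should leave the water-water structure essentially unchanged
  g_of <- function(model, ffx, core) {
    sys <- insert_ions(build_water_box(150, model = model, temperature = 325,
                                       seed = 61), 8, 8, seed = 62)
    run <- run_md(sys, ffx, md_protocol(ensemble = "NPT", temperature = 325,
                                        n_steps = 20000, log_stride = 50,
                                        traj_stride = 200))
    traj <- run$trajectory
    keep <- traj$times > 100
    traj$frames <- traj$frames[keep]
    traj$times <- traj$times[keep]
    traj$boxes <- traj$boxes[keep, , drop = FALSE]
    rdf(traj, core, bin_width = 0.05, r_max = 1.1)
  }
  g_pol <- g_of("polarizable", ff_pol, "POL-W")
  g_std <- g_of("standard", ff_std, "P4")
  peak_pol <- max(g_pol$g)
  peak_std <- max(g_std$g)
  # first peaks at the same position and comparable height
  expect_equal(g_pol$r[which.max(g_pol$g)], g_std$r[which.max(g_std$g)],
               tolerance = 0.06)
  expect_lt(abs(peak_pol - peak_std) / peak_std, 0.15)
})
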