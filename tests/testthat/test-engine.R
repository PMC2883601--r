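# MD core: force correctness, constraints, integration, coupling schemes.

test_that("forces match numerical gradients of the total energy", {
  sys <- small_water(10, seed = 13)
  # randomize satellite orientations away from the coincident start
  withr::with_seed(5, {
    wp <- which(sys$sites$type == "POL-WP")
    for (i in wp) {
      u <- rnorm(3); u <- 0.14 * u / sqrt(sum(u^2))
      w <- sys$sites[i - 1, c("x", "y", "z")]
      sys$sites[i, c("x", "y", "z")] <- w + u
    }
  })
  err <- numeric_force_error(sys, ff_pol, sites = seq_len(12), h = 1e-5)
  expect_lt(err, 1e-5)
})

test_that("field and bias forces are gradients too, and obey superposition", {
  sys <- small_water(6, seed = 3)
  prot <- md_protocol(field_z = 0.5, umbrella_k = 100, umbrella_z0 = 1.0)
  sol <- 2L
  f <- compute_forces(sys, ff_pol, prot, solute = sol)
  h <- 1e-5
  for (i in c(2, 5)) {
    sp <- sys; sp$sites$z[i] <- sp$sites$z[i] + h
    sm <- sys; sm$sites$z[i] <- sm$sites$z[i] - h
    fn <- -(pot_energy(sp, ff_pol, prot, solute = sol) -
              pot_energy(sm, ff_pol, prot, solute = sol)) / (2 * h)
    expect_equal(f$forces[i, 3], fn, tolerance = 1e-5)
  }
})

test_that("forces sum to zero without an external field", {
  sys <- small_water(25, seed = 21)
  f <- compute_forces(sys, ff_pol)
  expect_lt(max(abs(colSums(f$forces))), 1e-8)
  # with a field, the residual equals the field force on the net charge (zero
  # net charge here, but per-site field forces are nonzero)
  fE <- compute_forces(sys, ff_pol, md_protocol(field_z = 1))
  expect_lt(max(abs(colSums(fE$forces))), 1e-8)
  expect_false(isTRUE(all.equal(fE$forces, f$forces)))
})

test_that("well-separated waters interact only through their own angles", {
  top <- molecule_topology("polarizable_water")
  mk <- function(center) {
    u <- c(1, 0, 0)
    list(top = top, pos = rbind(center, center + 0.14 * u, center - 0.14 * u))
  }
  sys <- polwater:::.assemble_system(list(mk(c(1, 1, 1)), mk(c(3.6, 3.6, 3.6))),
                                     box = c(6, 6, 6))
  f <- compute_forces(sys, ff_pol)
  expect_equal(f$energies[["lj"]], 0)
  expect_equal(f$energies[["coulomb"]], 0)
  # satellites antipodal: theta = pi, cosine-harmonic E = 2 * K/2 (cos pi - 1)^2
  expect_equal(f$energies[["angle"]], 2 * 0.5 * 4.2 * 4, tolerance = 1e-9)
  # coincident satellites sit at the angle equilibrium
  sys0 <- polwater:::.assemble_system(list(list(top = top,
    pos = rbind(c(1, 1, 1), c(1.14, 1, 1), c(1.14, 1, 1)))), box = c(6, 6, 6))
  expect_equal(compute_forces(sys0, ff_pol)$energies[["angle"]], 0)
})

test_that("overlapping sites raise a singularity error naming the pair", {
  top <- molecule_topology("cation")
  sys <- polwater:::.assemble_system(list(
    list(top = top, pos = matrix(c(1, 1, 1), 1)),
    list(top = top, pos = matrix(c(1, 1, 1 + 1e-7), 1))), box = c(4, 4, 4))
  expect_error(compute_forces(sys, ff_pol), "overlapping")
})

test_that("constraint projection is exact, mass-weighted and idempotent", {
  sys <- build_water_box(4, seed = 6)
  pos <- as.matrix(sys$sites[, c("x", "y", "z")])
  # already satisfied: returned unchanged
  expect_lt(max(abs(apply_constraints(pos, pos, sys) - pos)), 1e-12)
  # stretch an isolated constrained pair to 0.15 nm: the closed-form two-body
  # correction pulls both partners symmetrically along the reference bond
  pair <- list(top = list(name = "pair",
    sites = tibble::tibble(type = c("POL-W", "POL-WP"), mass = c(24, 24),
                           charge = c(0, 0)),
    constraints = tibble::tibble(i = 1L, j = 2L, length = 0.14),
    bonds = tibble::tibble(i = integer(), j = integer(), b0 = numeric(),
                           kb = numeric()),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                            theta0 = numeric(), k_theta = numeric(),
                            funct = integer()),
    exclusions = tibble::tibble(i = 1L, j = 2L)),
    pos = rbind(c(1, 1, 1), c(1.14, 1, 1)))
  psys <- polwater:::.assemble_system(list(pair), box = c(4, 4, 4))
  ppos <- as.matrix(psys$sites[, c("x", "y", "z")])
  pnew <- ppos
  pnew[2, 1] <- ppos[1, 1] + 0.15
  pcorr <- apply_constraints(ppos, pnew, psys, tol = 1e-10)
  expect_equal(sqrt(sum((pcorr[2, ] - pcorr[1, ])^2)), 0.14, tolerance = 1e-9)
  # equal masses: pair center of mass preserved
  expect_equal(unname((pcorr[1, ] + pcorr[2, ]) / 2),
               unname((pnew[1, ] + pnew[2, ]) / 2), tolerance = 1e-9)
  # both bonds of one molecule perturbed -> both restored
  new2 <- pos
  new2[2, ] <- new2[2, ] + c(0.02, -0.01, 0.015)
  new2[3, ] <- new2[3, ] + c(-0.01, 0.02, 0.005)
  corr2 <- apply_constraints(pos, new2, sys, tol = 1e-10)
  d1 <- sqrt(sum((corr2[2, ] - corr2[1, ])^2))
  d2 <- sqrt(sum((corr2[3, ] - corr2[1, ])^2))
  expect_equal(c(d1, d2), c(0.14, 0.14), tolerance = 1e-9)
})

test_that("a zero-velocity, zero-force configuration is a fixed point", {
  top <- molecule_topology("polarizable_water")
  sat <- c(1.14, 1, 1)
  sys <- polwater:::.assemble_system(list(list(top = top,
    pos = rbind(c(1, 1, 1), sat, sat))), box = c(4, 4, 4))
  run <- run_md(sys, ff_pol, md_protocol(ensemble = "NVE", n_steps = 50,
                                         com_stride = 0, traj_stride = 10))
  expect_equal(as.matrix(run$system$sites[, c("x", "y", "z")]),
               as.matrix(sys$sites[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("run_md is deterministic and removes center-of-mass motion", {
  sys <- small_water(20, seed = 31)
  prot <- md_protocol(ensemble = "NVT", n_steps = 200, traj_stride = 50,
                      r_cut = 0.6, r_shift_lj = 0.45)
  r1 <- run_md(sys, ff_pol, prot)
  r2 <- run_md(sys, ff_pol, prot)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$system$sites, r2$system$sites)
  m <- r1$system$sites$mass
  p <- c(sum(m * r1$system$sites$vx), sum(m * r1$system$sites$vy),
         sum(m * r1$system$sites$vz))
  expect_lt(max(abs(p)), 1e-8)
})

test_that("NVE total energy is conserved at a reduced time step", {
  # site-gated electrostatics: the strictly conservative cutoff (the default
  # bead-center gating, like any group-scheme cutoff, trades conservation for
  # fidelity to the parameterization and is meant for thermostatted runs)
  sys <- build_water_box(125, temperature = 300, seed = 17)
  prot_site <- function(...) md_protocol(..., coulomb_gating = "site",
                                         nstlist = 0)
  eq <- run_md(sys, ff_pol, prot_site(ensemble = "NVT", n_steps = 1500,
                                      traj_stride = 0))
  run <- run_md(eq$system, ff_pol,
                prot_site(ensemble = "NVE", dt = 0.002, n_steps = 10000,
                          log_stride = 20, traj_stride = 0))
  etot <- run$log$E_pot + run$log$E_kin
  fit <- stats::lm(etot ~ run$log$time)
  drift <- abs(stats::coef(fit)[[2]]) * 1000 / 125   # kJ/mol per bead per ns
  expect_lt(drift, 0.05)
  # and the fluctuation around the mean stays tiny relative to E_kin
  expect_lt(stats::sd(etot), 0.02 * mean(run$log$E_kin))
})

test_that("NVT kinetic temperature matches equipartition at the target", {
  sys <- build_water_box(125, temperature = 300, seed = 23)
  run <- run_md(sys, ff_pol, md_protocol(ensemble = "NVT", n_steps = 5000,
                                         traj_stride = 0))
  late <- run$log[run$log$time > 20, ]
  expect_lt(abs(mean(late$temperature) - 300), 3)
  # the estimator uses 3N - Ncons - 3 degrees of freedom
  expect_equal(run$ndf, 3 * 375 - 250 - 3)
})

test_that("virial pressure matches -dU/dV by box-scaling finite differences", {
  # LJ-only fluid (standard water) so the pair virial is probed directly
  sys <- build_water_box(60, density = 900, model = "standard", seed = 12)
  f <- compute_forces(sys, ff_std)
  virial_p <- sum(diag(f$virial)) / 3 / prod(sys$box) * 16.6054
  U_of_scale <- function(s) {
    scaled <- sys
    scaled$box <- sys$box * s
    scaled$sites$x <- sys$sites$x * s
    scaled$sites$y <- sys$sites$y * s
    scaled$sites$z <- sys$sites$z * s
    pot_energy(scaled, ff_std)
  }
  h <- 1e-5
  V <- prod(sys$box)
  dUdV <- (U_of_scale(1 + h) - U_of_scale(1 - h)) / (2 * h * 3 * V)
  expect_equal(virial_p, -dUdV * 16.6054, tolerance = 0.02)
})

test_that("the isotropic barostat converges from either side", {
  runs <- lapply(c(900, 1100), function(rho) {
    sys <- build_water_box(150, density = rho, seed = 41)
    run_md(sys, ff_pol, md_protocol(ensemble = "NPT", n_steps = 12000,
                                    traj_stride = 0, log_stride = 20))
  })
  dens <- lapply(runs, function(r) {
    late <- r$log[r$log$time > 120, ]
    mass <- total_mass(r$system)
    polwater:::.block_mean_err(mass * 1.66054 / late$volume)
  })
  gap <- abs(dens[[1]]["mean"] - dens[[2]]["mean"])
  se <- sqrt(dens[[1]]["error"]^2 + dens[[2]]["error"]^2)
  expect_lt(unname(gap), unname(3 * se + 0.01 * dens[[1]]["mean"]))
})

test_that("semi-isotropic coupling only scales the coupled dimensions", {
  sys <- build_water_box(150, density = 950, seed = 7)
  run <- run_md(sys, ff_pol, md_protocol(ensemble = "NP_zAT", n_steps = 300,
                                         traj_stride = 0))
  expect_equal(run$system$box[1:2], sys$box[1:2])
  expect_false(isTRUE(all.equal(run$system$box[3], sys$box[3])))
})

test_that("temperature blow-up is caught", {
  top <- molecule_topology("cation")
  sys <- polwater:::.assemble_system(list(
    list(top = top, pos = matrix(c(1, 1, 1), 1)),
    list(top = top, pos = matrix(c(1.05, 1, 1), 1))), box = c(4, 4, 4))
  # two bare like charges at close range under a huge time step
  expect_error(
    run_md(sys, ff_pol, md_protocol(ensemble = "NVT", temperature = 1,
                                    dt = 1, tau_t = 1, n_steps = 500)),
    "blow-up|overlapping")
})
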