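# Soft-core coupling, thermodynamic integration, WHAM.

test_that("soft-core endpoints reproduce the plain kernels and full decoupling", {
  lj <- lookup_lj_params(ff_pol, "POL-W", "POL-W")
  r <- seq(0.25, 1.3, by = 0.05)
  full <- softcore_pair(r, lambda = 1, lj = lj, q_a = 0.46, q_b = -0.46)
  ref_lj <- lj_shifted(r, lj$epsilon, lj$sigma)
  ref_cl <- coulomb_shifted(r, 0.46, -0.46)
  expect_equal(full$energy, ref_lj$energy + ref_cl$energy, tolerance = 1e-14)
  expect_equal(full$force, ref_lj$force + ref_cl$force, tolerance = 1e-14)
  off <- softcore_pair(c(0.01, 0.3, 1), lambda = 0, lj = lj, q_a = 1, q_b = 1)
  expect_true(all(off$energy == 0))
  expect_true(all(off$force == 0))
  # finite energy at r -> 0 for intermediate coupling
  near0 <- softcore_pair(1e-6, lambda = 0.5, lj = lj)
  expect_true(is.finite(near0$energy))
  expect_error(softcore_pair(0.5, lambda = 1.5, lj = lj), "lambda")
})

test_that("dH/dlambda matches the numerical lambda-derivative", {
  lj <- lookup_lj_params(ff_pol, "C1", "POL-W")
  d <- 1e-5
  for (lam in c(0.2, 0.5, 0.8)) for (r in c(0.3, 0.5, 0.9)) {
    mid <- softcore_pair(r, lam, lj = lj, q_a = 0.3, q_b = -0.2)
    hp <- softcore_pair(r, lam + d, lj = lj, q_a = 0.3, q_b = -0.2)$energy
    hm <- softcore_pair(r, lam - d, lj = lj, q_a = 0.3, q_b = -0.2)$energy
    num <- (hp - hm) / (2 * d)
    expect_equal(mid$dHdl, num, tolerance = 1e-6)
  }
})

test_that("the coupled engine at lambda = 1 equals the unmodified engine", {
  sys <- small_water(8, seed = 19)
  f_plain <- compute_forces(sys, ff_pol)
  f_l1 <- compute_forces(sys, ff_pol, md_protocol(lambda = 1), solute = 3L)
  expect_equal(f_l1$forces, f_plain$forces, tolerance = 1e-14)
  expect_equal(sum(f_l1$energies), sum(f_plain$energies), tolerance = 1e-14)
  # at lambda = 0 the solute exerts and feels no nonbonded force
  f_l0 <- compute_forces(sys, ff_pol, md_protocol(lambda = 0), solute = 3L)
  sol <- which(sys$sites$mol_id == 3)
  wsol <- sol[sys$sites$type[sol] == "POL-W"]
  # the solute core has no bonded terms with other molecules
  expect_lt(max(abs(f_l0$forces[wsol, ])), 1e-10)
})

test_that("trapezoidal integration is exact for constants and linear data", {
  grid <- seq(0, 1, length.out = 22)
  const <- tibble::tibble(lambda = c(0, 0.5, 1), dHdl = 7, error = 0)
  expect_equal(ti_integrate(const)$delta_G, 7)
  lin <- tibble::tibble(lambda = c(0, 0.5, 1), dHdl = c(0, 0.5, 1), error = 0)
  expect_equal(ti_integrate(lin)$delta_G, 0.5)
  quad <- tibble::tibble(lambda = grid, dHdl = 3 * grid^2, error = 0)
  h <- grid[2] - grid[1]
  expect_equal(ti_integrate(quad)$delta_G, 1, tolerance = h^2)
  # error propagation: equal weights except the endpoints
  werr <- tibble::tibble(lambda = c(0, 0.5, 1), dHdl = 0, error = c(1, 1, 1))
  expect_equal(ti_integrate(werr)$error, sqrt(0.25^2 + 0.5^2 + 0.25^2))
})

test_that("decoupling an ideal-gas solute costs nothing", {
  # solvent with which the solute has no interactions at all: a bare cation
  # solute among neutral LJ-less ghosts is impossible to build, so use the
  # zero-charge limit: one butane bead in a box with a single far-away water
  top_b <- molecule_topology("butane")
  top_w <- molecule_topology("standard_water")
  sys <- polwater:::.assemble_system(list(
    list(top = top_w, pos = matrix(c(0.5, 0.5, 0.5), 1)),
    list(top = top_b, pos = matrix(c(2.5, 2.5, 2.5), 1))), box = c(5, 5, 5))
  prot <- md_protocol(ensemble = "NVT", n_steps = 200, log_stride = 5,
                      traj_stride = 0, temperature = 0.001, tau_t = 0.3)
  res <- ti_run(sys, ff_std, prot, solute = 2,
                lambdas = seq(0, 1, length.out = 5))
  # separation stays ~3.5 nm (beyond the cutoff): every window integrand is 0
  expect_equal(res$delta_G, 0, tolerance = 1e-10)
})

test_that("TI reproduces the analytic insertion free energy of a dilute pair", {
  # one C1 solute + one P4 solvent particle in a small periodic box:
  # Delta G = -kT ln[ (1/V) int exp(-beta U(r)) dV ]
  # with the minimum-image integral V + int_0^rc (e^{-beta U} - 1) 4 pi r^2 dr
  kT <- 0.00831446 * 300
  lj <- lookup_lj_params(ff_std, "P4", "C1")
  L <- 2.6; V <- L^3
  mayer <- integrate(function(r) {
    U <- lj_shifted(r, lj$epsilon, lj$sigma)$energy
    (exp(-U / kT) - 1) * 4 * pi * r^2
  }, 1e-3, 1.2, rel.tol = 1e-10)$value
  dg_exact <- -kT * log(1 + mayer / V)
  top_b <- molecule_topology("butane")
  top_w <- molecule_topology("standard_water")
  sys <- polwater:::.assemble_system(list(
    list(top = top_w, pos = matrix(c(0.5, 0.5, 0.5), 1)),
    list(top = top_b, pos = matrix(c(1.8, 0.5, 0.5), 1))), box = rep(L, 3))
  prot <- md_protocol(ensemble = "NVT", n_steps = 60000, log_stride = 10,
                      traj_stride = 0, com_stride = 10, seed = 5)
  res <- ti_run(sys, ff_std, prot, solute = 2,
                lambdas = seq(0, 1, length.out = 12), equil_fraction = 0.1)
  expect_equal(res$delta_G, dg_exact, tolerance = 0.15,
               info = sprintf("TI %.3f vs exact %.3f", res$delta_G, dg_exact))
  # grid refinement changes the estimate by less than the statistical error
  expect_lt(abs(ti_integrate(res$windows[seq(1, 12, by = 2), ])$delta_G -
                  res$delta_G), max(3 * res$error, 0.2))
})

test_that("WHAM recovers a generating double-well potential", {
  # overdamped Brownian dynamics in U(z) = a (z^2 - 1)^2 with harmonic windows
  kT <- 0.00831446 * 300
  a <- 10
  U <- function(z) a * (z^2 - 1)^2
  dU <- function(z) 4 * a * z * (z^2 - 1)
  D0 <- 0.1; dt <- 1e-3
  set.seed(77)
  centers <- seq(-1.6, 1.6, length.out = 24)
  kbias <- 60
  windows <- lapply(centers, function(z0) {
    z <- z0
    n <- 12000
    out <- numeric(n)
    noise <- sqrt(2 * D0 * dt) * rnorm(n)
    for (i in seq_len(n)) {
      force <- -dU(z) - kbias * (z - z0)
      z <- z + D0 * force / kT * dt + noise[i]
      out[i] <- z
    }
    list(samples = out[-(1:2000)], z0 = z0, k = kbias)
  })
  res <- umbrella_pmf(windows, temperature = 300, bin_width = 0.05)
  expect_lt(res$residual, 1e-8)
  pr <- res$profile[res$profile$covered & abs(res$profile$z) < 1.4, ]
  ref <- U(pr$z)
  # PMFs are defined up to a constant: compare after removing the offset
  diffs <- pr$pmf - ref
  rmse <- sqrt(mean((diffs - mean(diffs))^2))
  expect_lt(rmse, 0.3 * kT)
  # invariance to window ordering
  res2 <- umbrella_pmf(rev(windows), temperature = 300, bin_width = 0.05)
  expect_equal(res2$profile$pmf, res$profile$pmf, tolerance = 1e-6)
})

test_that("single unbiased window reduces to -kT ln(histogram)", {
  set.seed(3)
  z <- rnorm(20000, sd = 0.5)
  res <- umbrella_pmf(list(list(samples = z, z0 = 0, k = 0)),
                      temperature = 300, bin_width = 0.1)
  kT <- 0.00831446 * 300
  pr <- res$profile[abs(res$profile$z) < 1, ]
  # a Gaussian sample generates a quadratic PMF z^2 kT / (2 sd^2)
  ref <- kT * pr$z^2 / (2 * 0.5^2)
  expect_lt(max(abs(pr$pmf - min(res$profile$pmf) - (ref - min(ref)))), 0.2 * kT)
})

test_that("disjoint window histograms raise a coverage error naming the gap", {
  w <- list(list(samples = rnorm(500, -2, 0.1), z0 = -2, k = 100),
            list(samples = rnorm(500, 2, 0.1), z0 = 2, k = 100))
  expect_error(umbrella_pmf(w, bin_width = 0.05), "coverage error")
})
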