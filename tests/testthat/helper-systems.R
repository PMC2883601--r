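# Shared fixtures: all built in code, seeded.

ff_pol <- martini_forcefield("polarizable")
ff_std <- martini_forcefield("standard")

small_water <- function(n = 10, seed = 42, model = "polarizable")
  build_water_box(n, density = 800, model = model, seed = seed)

# total potential energy of a configuration (for numerical gradients)
pot_energy <- function(system, ff, protocol = md_protocol(), solute = integer()) {
  f <- compute_forces(system, ff, protocol, solute = solute)
  sum(f$energies)
}

# central-difference force check; returns max relative error over all
# coordinates of `sites`
numeric_force_error <- function(system, ff, sites, h = 1e-6,
                                protocol = md_protocol()) {
  f <- compute_forces(system, ff, protocol)
  maxrel <- 0
  for (i in sites) for (d in c("x", "y", "z")) {
    sp <- system; sp$sites[[d]][i] <- sp$sites[[d]][i] + h
    sm <- system; sm$sites[[d]][i] <- sm$sites[[d]][i] - h
    fn <- -(pot_energy(sp, ff, protocol) - pot_energy(sm, ff, protocol)) / (2 * h)
    fa <- f$forces[i, match(d, c("x", "y", "z"))]
    maxrel <- max(maxrel, abs(fn - fa) / max(abs(fa), 1))
  }
  maxrel
}

# synthetic trajectory carrying only a log (for estimator unit tests)
synthetic_traj <- function(log, sites = NULL, frames = list(),
                           boxes = NULL, times = NULL) {
  if (is.null(times)) times <- seq_len(max(length(frames), nrow(log)))
  if (is.null(boxes)) boxes <- matrix(rep(c(3, 3, 3), length(times)),
                                      ncol = 3, byrow = TRUE)
  if (is.null(sites))
    sites <- tibble::tibble(type = character(), mass = numeric(),
                            charge = numeric(), mol_id = integer(),
                            mol_name = character())
  structure(list(frames = frames, times = times, boxes = boxes,
                 sites = sites, log = log, ndf = NA_integer_),
            class = "cg_trajectory")
}
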