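# Molecule topologies and the cg_system container.
#
# A cg_system holds a sites tibble (one row per interaction site), bonded-term
# tibbles with 1-based site indices, and the orthorhombic box (nm).

#' Molecule topology templates
#'
#' Returns the per-molecule topology used by the builders.
#' Polarizable water is a three-site molecule: a neutral LJ core (POL-W) with
#' two satellite charges (POL-WP/POL-WM, charge \eqn{\pm q}) each constrained
#' at l = 0.14 nm from the core, a harmonic WP-W-WM angle with \eqn{\theta_0 =
#' 0} and \eqn{K_\theta} = 4.2 kJ/mol/rad^2, and all three intra-bead nonbonded
#' pairs excluded. Standard water is a single P4 site. Alkanes follow the 4:1
#' mapping: butane = 1 C1 bead, octane = 2, hexadecane = 4, bonded by harmonic
#' bonds (b0 = 0.47 nm, kb = 1250 kJ/mol/nm^2) and, for hexadecane,
#' cosine-harmonic angles (\eqn{\theta_0 = \pi}, K = 25 kJ/mol). Ions are single Qd/Qa
#' beads of mass 72 amu with charge +1/-1.
#'
#' @param molecule one of \code{"polarizable_water"}, \code{"standard_water"},
#'   \code{"butane"}, \code{"octane"}, \code{"hexadecane"}, \code{"cation"},
#'   \code{"anion"}.
#' @param q satellite charge magnitude for polarizable water (e).
#' @return list with fields \code{name}, \code{sites} (tibble: type, mass,
#'   charge), \code{constraints}, \code{bonds}, \code{angles},
#'   \code{exclusions} (site-pair tibbles, indices local to the molecule).
#' @export
molecule_topology <- function(molecule = c("polarizable_water", "standard_water",
                                           "butane", "octane", "hexadecane",
                                           "cation", "anion"),
                              q = 0.46) {
  molecule <- match.arg(molecule)
  emptyp <- tibble::tibble(i = integer(), j = integer())
  top <- switch(molecule,
    polarizable_water = list(
      sites = tibble::tibble(type = c("POL-W", "POL-WP", "POL-WM"),
                             mass = c(24, 24, 24), charge = c(0, q, -q)),
      constraints = tibble::tibble(i = c(1L, 1L), j = c(2L, 3L),
                                   length = c(0.14, 0.14)),
      bonds = tibble::tibble(i = integer(), j = integer(),
                             b0 = numeric(), kb = numeric()),
      angles = tibble::tibble(i = 2L, j = 1L, k = 3L, theta0 = 0,
                              k_theta = 4.2, funct = 2L),
      exclusions = tibble::tibble(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L))),
    standard_water = list(
      sites = tibble::tibble(type = "P4", mass = 72, charge = 0),
      constraints = tibble::tibble(i = integer(), j = integer(),
                                   length = numeric()),
      bonds = tibble::tibble(i = integer(), j = integer(),
                             b0 = numeric(), kb = numeric()),
      angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                              theta0 = numeric(), k_theta = numeric(),
                              funct = integer()),
      exclusions = emptyp),
    butane = .alkane_top(1L),
    octane = .alkane_top(2L),
    hexadecane = .alkane_top(4L),
    cation = .ion_top("Qd", 1),
    anion = .ion_top("Qa", -1))
  top$name <- molecule
  top
}

.alkane_top <- function(nbeads) {
  nb <- max(nbeads - 1L, 0L)
  na <- max(nbeads - 2L, 0L)
  list(
    sites = tibble::tibble(type = rep("C1", nbeads), mass = rep(72, nbeads),
                           charge = rep(0, nbeads)),
    constraints = tibble::tibble(i = integer(), j = integer(), length = numeric()),
    bonds = tibble::tibble(i = seq_len(nb), j = seq_len(nb) + 1L,
                           b0 = rep(0.47, nb), kb = rep(1250, nb)),
    angles = tibble::tibble(i = seq_len(na), j = seq_len(na) + 1L,
                            k = seq_len(na) + 2L,
                            theta0 = rep(pi, na), k_theta = rep(25, na),
                            funct = rep(2L, na)),
    exclusions = tibble::tibble(i = seq_len(nb), j = seq_len(nb) + 1L))
}

.ion_top <- function(type, charge) {
  list(
    sites = tibble::tibble(type = type, mass = 72, charge = charge),
    constraints = tibble::tibble(i = integer(), j = integer(), length = numeric()),
    bonds = tibble::tibble(i = integer(), j = integer(), b0 = numeric(),
                           kb = numeric()),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                            theta0 = numeric(), k_theta = numeric(),
                            funct = integer()),
    exclusions = tibble::tibble(i = integer(), j = integer()))
}

# Assemble a cg_system from a list of molecule instances.
# mols: list of lists(top = topology, pos = matrix nsites x 3)
.assemble_system <- function(mols, box, velocities = NULL) {
  sites <- list(); cons <- list(); bnds <- list(); angs <- list(); excl <- list()
  off <- 0L
  for (m in seq_along(mols)) {
    top <- mols[[m]]$top
    ns <- nrow(top$sites)
    s <- top$sites
    s$mol_id <- m
    s$mol_name <- top$name
    s$x <- mols[[m]]$pos[, 1]; s$y <- mols[[m]]$pos[, 2]; s$z <- mols[[m]]$pos[, 3]
    sites[[m]] <- s
    if (nrow(top$constraints))
      cons[[length(cons) + 1L]] <- dplyr::mutate(top$constraints,
                                                 i = i + off, j = j + off)
    if (nrow(top$bonds))
      bnds[[length(bnds) + 1L]] <- dplyr::mutate(top$bonds,
                                                 i = i + off, j = j + off)
    if (nrow(top$angles))
      angs[[length(angs) + 1L]] <- dplyr::mutate(top$angles, i = i + off,
                                                 j = j + off, k = k + off)
    if (nrow(top$exclusions))
      excl[[length(excl) + 1L]] <- dplyr::mutate(top$exclusions,
                                                 i = i + off, j = j + off)
    off <- off + ns
  }
  sites <- dplyr::bind_rows(sites)
  sites$vx <- 0; sites$vy <- 0; sites$vz <- 0
  sys <- structure(list(
    sites = tibble::as_tibble(sites),
    constraints = if (length(cons)) dplyr::bind_rows(cons) else
      tibble::tibble(i = integer(), j = integer(), length = numeric()),
    bonds = if (length(bnds)) dplyr::bind_rows(bnds) else
      tibble::tibble(i = integer(), j = integer(), b0 = numeric(), kb = numeric()),
    angles = if (length(angs)) dplyr::bind_rows(angs) else
      tibble::tibble(i = integer(), j = integer(), k = integer(),
                     theta0 = numeric(), k_theta = numeric(),
                     funct = integer()),
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(i = integer(), j = integer()),
    box = box), class = "cg_system")
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  comp <- dplyr::count(dplyr::distinct(x$sites, .data$mol_id, .data$mol_name),
                       .data$mol_name)
  cat("<cg_system>", nrow(x$sites), "sites,",
      length(unique(x$sites$mol_id)), "molecules; box =",
      paste(signif(x$box, 5), collapse = " x "), "nm\n")
  for (k in seq_len(nrow(comp)))
    cat("  ", comp$mol_name[k], ":", comp$n[k], "\n")
  invisible(x)
}

#' Composition summary of a system
#'
#' @param system a \code{cg_system}.
#' @return tibble with one row per molecule species: count, sites per molecule,
#'   molecular mass (amu) and charge (e).
#' @export
composition <- function(system) {
  stopifnot(inherits(system, "cg_system"))
  system$sites |>
    dplyr::group_by(.data$mol_id, .data$mol_name) |>
    dplyr::summarise(n_sites = dplyr::n(), mass = sum(.data$mass),
                     charge = sum(.data$charge), .groups = "drop") |>
    dplyr::count(.data$mol_name, .data$n_sites, .data$mass, .data$charge,
                 name = "n_molecules")
}

#' Total mass of a system (amu)
#' @param system a \code{cg_system}.
#' @return numeric scalar.
#' @export
total_mass <- function(system) sum(system$sites$mass)

# Seeded Maxwell-Boltzmann velocities, COM removed, exact rescale to T.
.mb_velocities <- function(sys, temperature) {
  n <- nrow(sys$sites)
  if (temperature <= 0 || n == 0) {
    sys$sites$vx <- sys$sites$vy <- sys$sites$vz <- rep(0, n)
    return(sys)
  }
  m <- sys$sites$mass
  sd <- sqrt(.KB * temperature / m)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # remove center-of-mass motion
  v <- sweep(v, 2, colSums(v * m) / sum(m))
  ndf <- 3 * n - nrow(sys$constraints) - 3
  ke <- 0.5 * sum(m * rowSums(v^2))
  target <- 0.5 * ndf * .KB * temperature
  if (ke > 0) v <- v * sqrt(target / ke)
  sys$sites$vx <- v[, 1]; sys$sites$vy <- v[, 2]; sys$sites$vz <- v[, 3]
  sys
}

# Lattice points filling a cubic box of edge L: picks the cubic arrangement
# (simple, body-centered or face-centered) holding at least n points with the
# largest nearest-neighbor distance, so random sub-selection stays well spread.
.lattice_points <- function(n, L) {
  basis <- list(sc = rbind(c(0, 0, 0)),
                bcc = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
                fcc = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                            c(0, 0.5, 0.5)))
  nnfac <- c(sc = 1, bcc = sqrt(3) / 2, fcc = 1 / sqrt(2))
  best <- NULL; best_nn <- -Inf
  for (kind in names(basis)) {
    nb <- nrow(basis[[kind]])
    m <- max(1L, ceiling((n / nb)^(1 / 3) - 1e-9))
    while (nb * m^3 < n) m <- m + 1L
    nn <- L / m * nnfac[[kind]]
    if (nn > best_nn) { best <- list(kind = kind, m = m); best_nn <- nn }
  }
  b <- basis[[best$kind]]; m <- best$m
  g <- as.matrix(expand.grid(x = 0:(m - 1), y = 0:(m - 1), z = 0:(m - 1)))
  pts <- do.call(rbind, lapply(seq_len(nrow(b)), function(k)
    sweep(g, 2, b[k, ], "+")))
  attr(pts, "nn_dist") <- best_nn
  sweep(pts, 2, L / m, "*")
}

#' Build a bulk water box
#'
#' Places \code{n_beads} water molecules on a jittered fcc lattice in a cubic
#' box sized to the requested initial mass density, with coincident satellites
#' along a random direction (the angle-potential equilibrium, so each bead
#' starts with zero dipole) and
#' seeded Maxwell-Boltzmann velocities.
#'
#' @param n_beads number of water beads (each 72 amu).
#' @param density initial mass density (kg/m^3).
#' @param model \code{"polarizable"} (3-site) or \code{"standard"} (1-site P4).
#' @param temperature velocity-seeding temperature (K).
#' @param seed integer seed; identical arguments give identical systems.
#' @param q satellite charge magnitude (e), polarizable model only.
#' @param k_theta angle force constant (kJ/mol/rad^2), polarizable model only.
#' @return a \code{cg_system}.
#' @export
build_water_box <- function(n_beads, density = 1000,
                            model = c("polarizable", "standard"),
                            temperature = 300, seed = 1, q = 0.46,
                            k_theta = 4.2) {
  model <- match.arg(model)
  stopifnot(n_beads >= 1, density > 0)
  withr::local_seed(seed)
  mass <- n_beads * 72                       # amu
  V <- mass * .AMU_DENS / density            # nm^3
  L <- V^(1 / 3)
  pts <- .lattice_points(n_beads, L)
  nn_dist <- attr(pts, "nn_dist")
  jitter_max <- min(0.05, max(0, (nn_dist - 0.4) / 2 * 0.9))
  if (n_beads > 1 && nn_dist <= 0.4)
    stop("packing error: requested density leaves water cores closer than 0.4 nm",
         call. = FALSE)
  sel <- sample.int(nrow(pts), n_beads)
  centers <- pts[sel, , drop = FALSE] +
    matrix(stats::runif(3 * n_beads, -jitter_max, jitter_max), n_beads, 3)
  top <- if (model == "polarizable") {
    t0 <- molecule_topology("polarizable_water", q = q)
    t0$angles$k_theta <- k_theta
    t0
  } else molecule_topology("standard_water")
  mols <- lapply(seq_len(n_beads), function(i) {
    if (model == "polarizable") {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      sat <- centers[i, ] + 0.14 * u
      pos <- rbind(centers[i, ], sat, sat)
    } else pos <- centers[i, , drop = FALSE]
    list(top = top, pos = pos)
  })
  sys <- .assemble_system(mols, box = rep(L, 3))
  .mb_velocities(sys, temperature)
}

# Interleaved (bcc-style) lattice fill of a rectangular region: two offset
# grids keep the nearest-neighbor distance near (2V/n)^(1/3)/2 * sqrt(3) even
# in thin slabs, where a single cubic grid would pack one dimension too hard.
.region_points <- function(n, lower, upper, jitter = 0.015) {
  ext <- upper - lower
  ctar <- (2 * prod(ext) / n)^(1 / 3)
  nd <- pmax(1L, round(ext / ctar))
  while (2 * prod(nd) < n) {
    d <- which.max(ext / nd)
    nd[d] <- nd[d] + 1L
  }
  cd <- ext / nd
  g <- as.matrix(expand.grid(x = seq_len(nd[1]) - 0.5, y = seq_len(nd[2]) - 0.5,
                             z = seq_len(nd[3]) - 0.5))
  base <- sweep(g, 2, cd, "*")
  off <- sweep(base, 2, cd / 2, "+")
  off <- sweep(off, 2, ext, function(x, e) x %% e)
  pts <- sweep(rbind(base, off), 2, lower, "+")
  sel <- sample.int(nrow(pts), n)
  pts[sel, , drop = FALSE] +
    matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
}

#' Build a slab system (water/vacuum or water/alkane)
#'
#' Species are segregated into slabs along z inside a box of fixed lateral
#' area. Water/vacuum systems get an empty z-region at least as thick as the
#' water slab; alkanes are built as C1-bead chains (octane 2, hexadecane 4
#' beads) at a liquid-alkane packing density.
#'
#' @param composition \code{"water/vacuum"}, \code{"water/hexadecane"} or
#'   \code{"water/octane"}.
#' @param n_water number of water beads.
#' @param n_alkane number of alkane molecules (ignored for water/vacuum).
#' @param box_xy lateral box edge (nm); the same value is used for x and y.
#' @param model water model, as in \code{\link{build_water_box}}.
#' @param temperature velocity-seeding temperature (K).
#' @param seed integer seed.
#' @return a \code{cg_system} with slab geometry along z.
#' @export
build_slab_system <- function(composition = c("water/vacuum", "water/hexadecane",
                                              "water/octane"),
                              n_water, n_alkane = 0, box_xy = 4.0,
                              model = c("polarizable", "standard"),
                              temperature = 300, seed = 1) {
  composition <- match.arg(composition)
  model <- match.arg(model)
  if (composition == "water/vacuum") n_alkane <- 0L
  stopifnot(n_water + n_alkane > 0)
  withr::local_seed(seed)
  area <- box_xy^2
  wtop <- if (model == "polarizable") molecule_topology("polarizable_water")
          else molecule_topology("standard_water")
  # water slab thickness from ~1000 kg/m3
  z_w <- if (n_water > 0) n_water * 72 * .AMU_DENS / 1000 / area else 0
  alk <- switch(composition, "water/octane" = "octane",
                "water/hexadecane" = "hexadecane", NULL)
  nb_alk <- switch(composition, "water/octane" = 2L, "water/hexadecane" = 4L, 0L)
  # alkane slab thickness from ~750 kg/m3 of CG bead mass
  z_a <- if (n_alkane > 0) n_alkane * nb_alk * 72 * .AMU_DENS / 750 / area else 0
  z_vac <- if (composition == "water/vacuum") max(3, z_w) else 0
  Lz <- z_w + z_a + z_vac
  mols <- list()
  if (n_water > 0) {
    centers <- .region_points(n_water, c(0.25, 0.25, 0.25),
                              c(box_xy - 0.25, box_xy - 0.25, max(z_w - 0.25, 0.3)))
    for (i in seq_len(n_water)) {
      if (model == "polarizable") {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        sat <- centers[i, ] + 0.14 * u
        pos <- rbind(centers[i, ], sat, sat)
      } else pos <- centers[i, , drop = FALSE]
      mols[[length(mols) + 1L]] <- list(top = wtop, pos = pos)
    }
  }
  if (n_alkane > 0) {
    atop <- molecule_topology(alk)
    heads <- .region_points(n_alkane, c(0.25, 0.25, z_w + 0.25),
                            c(box_xy - 0.25, box_xy - 0.25, z_w + max(z_a - 0.25, 0.3)))
    for (i in seq_len(n_alkane)) {
      # chain laid along a random in-plane direction, wrapped into the slab
      phi <- stats::runif(1, 0, 2 * pi)
      d <- c(cos(phi), sin(phi), 0)
      pos <- t(vapply(seq_len(nb_alk) - 1, function(k) heads[i, ] + 0.47 * k * d,
                      numeric(3)))
      mols[[length(mols) + 1L]] <- list(top = atop, pos = pos)
    }
  }
  sys <- .assemble_system(mols, box = c(box_xy, box_xy, Lz))
  # wrap x,y into the box
  sys$sites$x <- sys$sites$x %% box_xy
  sys$sites$y <- sys$sites$y %% box_xy
  .mb_velocities(sys, temperature)
}

#' Replace water beads by monovalent CG ions
#'
#' Randomly chosen water molecules are replaced by single-site ions placed at
#' the former core position: cations of type Qd (+1) and anions of type Qa
#' (-1), mass 72 amu.
#'
#' @param system a \code{cg_system} containing water molecules.
#' @param n_cation,n_anion numbers of ions to insert.
#' @param seed integer seed.
#' @return a new \code{cg_system}.
#' @export
insert_ions <- function(system, n_cation, n_anion, seed = 1) {
  stopifnot(inherits(system, "cg_system"), n_cation >= 0, n_anion >= 0)
  if (n_cation + n_anion == 0) return(system)
  withr::local_seed(seed)
  wmols <- unique(system$sites$mol_id[system$sites$mol_name %in%
                                        c("polarizable_water", "standard_water")])
  ntot <- n_cation + n_anion
  if (ntot > length(wmols))
    stop("composition error: not enough water molecules to replace", call. = FALSE)
  picked <- sample(wmols, ntot)
  cat_ids <- picked[seq_len(n_cation)]
  an_ids <- setdiff(picked, cat_ids)
  # rebuild molecule list
  mol_ids <- unique(system$sites$mol_id)
  tops <- list(cation = molecule_topology("cation"),
               anion = molecule_topology("anion"))
  vel_keep <- list()
  mols <- lapply(mol_ids, function(m) {
    rows <- system$sites[system$sites$mol_id == m, ]
    if (m %in% cat_ids || m %in% an_ids) {
      core <- rows[rows$type %in% c("POL-W", "P4"), ][1, ]
      top <- if (m %in% cat_ids) tops$cation else tops$anion
      list(top = top, pos = matrix(c(core$x, core$y, core$z), 1, 3),
           vel = matrix(c(core$vx, core$vy, core$vz), 1, 3))
    } else {
      top <- switch(rows$mol_name[1],
                    polarizable_water = molecule_topology("polarizable_water"),
                    standard_water = molecule_topology("standard_water"),
                    butane = molecule_topology("butane"),
                    octane = molecule_topology("octane"),
                    hexadecane = molecule_topology("hexadecane"),
                    cation = tops$cation, anion = tops$anion)
      list(top = top, pos = as.matrix(rows[, c("x", "y", "z")]),
           vel = as.matrix(rows[, c("vx", "vy", "vz")]))
    }
  })
  sys <- .assemble_system(mols, box = system$box)
  vel <- do.call(rbind, lapply(mols, function(m) m$vel))
  sys$sites$vx <- vel[, 1]; sys$sites$vy <- vel[, 2]; sys$sites$vz <- vel[, 3]
  sys
}
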