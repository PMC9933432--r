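#' Load molecule templates from a parameter file
#'
#' The side-car parameter format is YAML: one top-level entry per species
#' with fields \code{sites} (list of label/mass/charge/epsilon/sigma),
#' \code{geometry} (n x 3 reference coordinates, required for multi-site
#' species), optional \code{primary} (site index for region membership)
#' and optional \code{resname} (PDB residue name).
#'
#' @param path Path to the YAML parameter file.
#' @return Named list of [mol_template()] objects (with a \code{resname}
#'   attribute each).
#' @export
read_templates <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    sites <- do.call(rbind, lapply(e$sites, as.data.frame))
    geom <- if (!is.null(e$geometry)) {
      do.call(rbind, lapply(e$geometry, as.numeric))
    } else NULL
    tpl <- mol_template(nm, sites, geometry = geom,
                        primary = if (is.null(e$primary)) 1L else e$primary)
    tpl$resname <- if (is.null(e$resname)) toupper(substr(nm, 1, 3)) else e$resname
    tpl
  })
  names(out) <- names(raw)
  out
}

#' TIP3P water template
#'
#' Loads the packaged, versioned TIP3P parameter file.
#'
#' @return A [mol_template()] for rigid 3-site water.
#' @export
water_template <- function() {
  read_templates(system.file("extdata", "tip3p.yaml", package = "grandmc"))$water
}

single_site_template <- function(name, mass = 18, charge = 0, epsilon = 0,
                                 sigma = 0, resname = NULL) {
  tpl <- mol_template(name, data.frame(label = toupper(substr(name, 1, 2)),
                                       mass = mass, charge = charge,
                                       epsilon = epsilon, sigma = sigma))
  tpl$resname <- if (is.null(resname)) toupper(substr(name, 1, 3)) else resname
  tpl
}

# place n points in the box with a minimum pairwise (minimum-image)
# separation; simple rejection sampling
place_nonoverlapping <- function(n, box, min_dist, max_tries = 200 * n + 1000) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (t in seq_len(max_tries)) {
    p <- stats::runif(3) * box
    ok <- TRUE
    if (placed > 0) {
      d <- minimum_image(sweep(pts[seq_len(placed), , drop = FALSE], 2, p), box)
      ok <- all(rowSums(d * d) >= min_dist^2)
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- p
      if (placed == n) return(pts)
    }
  }
  stop("packing failed: could not place ", n, " particles at min_dist ", min_dist)
}

#' Ideal-gas fixture
#'
#' Non-interacting single-site particles (epsilon = charge = 0): every
#' energy is exactly zero, making the grand canonical chain analytically
#' solvable.
#'
#' @param n Number of particles.
#' @param box Cubic box edge (A).
#' @param temperature Temperature (K).
#' @param seed Optional RNG seed (deterministic generation).
#' @return A [particle_system()].
#' @export
make_ideal_gas <- function(n = 1, box = 20, temperature = 298, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- single_site_template("gas")
  box3 <- rep(box, 3)
  pos <- matrix(stats::runif(3 * n), n, 3) %*% diag(box3)
  vel <- matrix(stats::rnorm(3 * n), n, 3) *
    sqrt(UNITS$kB * temperature * UNITS$accel / tpl$sites$mass)
  particle_system(list(gas = tpl),
                  data.frame(template = rep("gas", n)),
                  pos, vel, box = box3, cutoff = box / 4,
                  temperature = temperature)
}

#' Lennard-Jones fluid fixture
#'
#' Single-site LJ particles at random non-overlapping positions with
#' Maxwell-Boltzmann velocities.
#'
#' @param n Number of particles.
#' @param box Cubic box edge (A).
#' @param epsilon Well depth (kcal/mol).
#' @param sigma LJ diameter (A).
#' @param temperature Temperature (K).
#' @param cutoff,switch_start Nonbonded truncation (A).
#' @param seed Optional RNG seed.
#' @return A [particle_system()].
#' @export
make_lj_fluid <- function(n = 30, box = 20, epsilon = 0.2, sigma = 3,
                          temperature = 298, cutoff = 8,
                          switch_start = 6.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- single_site_template("lj", mass = 18, epsilon = epsilon, sigma = sigma)
  box3 <- rep(box, 3)
  pos <- place_nonoverlapping(n, box3, 0.85 * sigma)
  vel <- matrix(stats::rnorm(3 * n), n, 3) *
    sqrt(UNITS$kB * temperature * UNITS$accel / tpl$sites$mass)
  particle_system(list(lj = tpl), data.frame(template = rep("lj", n)),
                  pos, vel, box = box3, cutoff = cutoff,
                  switch_start = switch_start, temperature = temperature)
}

#' Rigid water box fixture
#'
#' Rigid 3-site TIP3P-parameterized waters at random non-overlapping poses
#' (oxygen-oxygen separation at least 2 A) with constraint-projected
#' Maxwell-Boltzmann velocities.
#'
#' @param n Number of waters.
#' @param box Cubic box edge (A).
#' @param temperature Temperature (K).
#' @param cutoff,switch_start Nonbonded truncation (A).
#' @param min_dist Minimum O-O packing distance (A).
#' @param seed Optional RNG seed.
#' @return A [particle_system()].
#' @export
make_water_box <- function(n = 20, box = 20, temperature = 298, cutoff = 8,
                           switch_start = 6.5, min_dist = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- water_template()
  box3 <- rep(box, 3)
  centers <- place_nonoverlapping(n, box3, min_dist)
  pos <- matrix(0, 3 * n, 3)
  vel <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    R <- quat_rotation(stats::rnorm(4))
    g <- tpl$geometry %*% t(R)
    g <- sweep(g, 2, g[1, ] - centers[i, ], "-")
    idx <- (3 * i - 2):(3 * i)
    pos[idx, ] <- g
    vel[idx, ] <- maxwell_boltzmann_velocities(tpl, g, temperature)
  }
  particle_system(list(water = tpl),
                  data.frame(template = rep("water", n)),
                  pos, vel, box = box3, cutoff = cutoff,
                  switch_start = switch_start, temperature = temperature)
}

# tetrahedron vertex directions (unit)
tetra_dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
                     byrow = TRUE) / sqrt(3)

#' Toy binding-pocket fixture
#'
#' A desk-scale analog of a protein hydration-site system: a static
#' scaffold of fixed LJ sites forms 1-3 attractive wells (tetrahedral
#' cages of attractive sites, each with a point potential minimum at its
#' center by symmetry) inside a 6 A spherical move region, with a shell of
#' mobile solvent outside the region. The returned reference sites are the
#' scaffold-potential minima near the cage centers, refined numerically,
#' and serve as ground truth for [match_to_reference()].
#'
#' The solvent is a single-site LJ species; the fixture's declared excess
#' chemical potential (-3.5 kcal/mol) with the sphere volume gives the
#' suggested equilibrium Adams parameter \code{B}.
#'
#' @param n_wells Number of attractive wells (1-3).
#' @param n_shell Mobile solvent molecules placed outside the region.
#' @param box Cubic box edge (A).
#' @param radius Region radius (A).
#' @param temperature Temperature (K).
#' @param seed Optional RNG seed.
#' @return List: \code{sys}, \code{region} ([gc_region()]),
#'   \code{reference} (well minima, n_wells x 3), \code{adams}
#'   (suggested [adams_parameters()]), \code{mu_excess}.
#' @export
make_toy_pocket <- function(n_wells = 2, n_shell = 8, box = 26, radius = 6,
                            temperature = 298, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_wells >= 1, n_wells <= 3)
  box3 <- rep(box, 3)
  center <- box3 / 2
  eps_s <- 0.2; sig_s <- 3.0
  solv <- single_site_template("solv", mass = 18, epsilon = eps_s, sigma = sig_s)
  # a well is a tetrahedral cage of four attractive sites whose center is
  # a deep point minimum by symmetry; the reference coordinates returned
  # are the numerically refined minima of the full scaffold potential
  well <- single_site_template("well", mass = 50, epsilon = 12.0, sigma = 3.0)
  anchor <- single_site_template("anch", mass = 50, epsilon = 0, sigma = 0)
  r_cage <- 2^(1 / 6) * (sig_s + 3.0) / 2
  well_centers <- switch(n_wells,
    matrix(c(0, 0, 0), 1, 3),
    rbind(c(2.5, 0, 0), c(-2.5, 0, 0)),
    rbind(c(2.5, 0, 0), c(-1.6, 2.2, 0), c(-1.6, -2.2, 0))
  )
  well_centers <- sweep(well_centers, 2, center, "+")
  molecules <- data.frame(template = c("anch", "anch",
                                       rep("well", 4 * n_wells)),
                          fixed = TRUE)
  pos <- rbind(center + c(1, 0, 0), center - c(1, 0, 0))
  for (w in seq_len(n_wells)) {
    pos <- rbind(pos, sweep(tetra_dirs * r_cage, 2, well_centers[w, ], "+"))
  }
  # mobile solvent shell outside the region
  shell <- matrix(NA_real_, max(n_shell, 0), 3)
  placed <- 0L
  while (placed < n_shell) {
    p <- stats::runif(3) * box3
    d2 <- sum(minimum_image(p - center, box3)^2)
    if (d2 < (radius + 1.5)^2) next
    ok <- TRUE
    if (placed > 0) {
      dd <- minimum_image(sweep(shell[seq_len(placed), , drop = FALSE], 2, p), box3)
      ok <- all(rowSums(dd * dd) >= (0.9 * sig_s)^2)
    }
    if (!ok) next
    placed <- placed + 1L
    shell[placed, ] <- p
  }
  if (n_shell > 0) {
    molecules <- rbind(molecules,
                       data.frame(template = rep("solv", n_shell),
                                  fixed = FALSE))
    pos <- rbind(pos, shell)
  }
  vel <- matrix(0, nrow(pos), 3)
  if (n_shell > 0) {
    sv <- sqrt(UNITS$kB * temperature * UNITS$accel / solv$sites$mass)
    vel[(nrow(pos) - n_shell + 1):nrow(pos), ] <-
      matrix(stats::rnorm(3 * n_shell), n_shell, 3) * sv
  }
  sys <- particle_system(
    list(anch = anchor, well = well, solv = solv),
    molecules, pos, vel, box = box3, cutoff = 9, switch_start = 7.5,
    temperature = temperature)
  region <- gc_region("solv", "sphere", center_sites = c(1L, 2L),
                      radius = radius)
  # refine well minima against the scaffold potential with a probe
  reference <- t(apply(well_centers, 1, function(wc) {
    probe_energy <- function(p) scaffold_probe_energy(sys, p)
    stats::optim(wc, probe_energy, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 500))$par
  }))
  mu_ex <- -3.5
  adams <- adams_parameters(mu_excess = mu_ex, v_gcmc = region$volume,
                            temperature = temperature)
  list(sys = sys, region = region, reference = reference,
       adams = adams, mu_excess = mu_ex)
}

# interaction energy of a solvent probe site at position p with the fixed
# scaffold of a toy-pocket system
scaffold_probe_energy <- function(sys, p) {
  eg <- ensure_ghost(sys, gc_region("solv", "box", box = sys$box))
  sys2 <- eg$sys
  idx <- mol_sites(sys2, eg$mol)
  sys2$pos[idx, ] <- matrix(p, 1, 3)
  sys2$real[eg$mol] <- TRUE
  # only the fixed scaffold: temporarily ghost the mobile solvent
  mobile <- which(sys2$real & !sys2$fixed)
  mobile <- setdiff(mobile, eg$mol)
  sys2$real[mobile] <- FALSE
  molecule_interaction_energy(sys2, eg$mol, 1)
}
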