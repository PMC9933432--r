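#' Equilibrium Adams parameter
#'
#' The Adams parameter that places the simulated region in equilibrium
#' with bulk solvent: \code{B = mu_excess / (kB T) + log(V_gcmc / V_std)}.
#'
#' @param mu_excess Excess chemical potential (kcal/mol); the default,
#'   -6.09 kcal/mol, is the TIP3P water hydration free energy.
#' @param v_gcmc Volume of the move region (A^3): sphere volume or box
#'   volume in whole-box mode.
#' @param v_std Standard-state volume (A^3); default 30.345 A^3 for water.
#' @param temperature Temperature (K).
#' @return Dimensionless Adams parameter B.
#' @export
adams_equilibrium <- function(mu_excess = -6.09, v_gcmc, v_std = 30.345,
                              temperature = 298) {
  if (v_gcmc <= 0 || v_std <= 0) stop("volumes must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  mu_excess / (UNITS$kB * temperature) + log(v_gcmc / v_std)
}

#' Adams-formulation thermodynamic parameters
#'
#' Bundles the Adams parameter B (fixed for the whole run, computed from
#' the nominal region volume) with the temperature. Either supply \code{B}
#' directly or the inputs of [adams_equilibrium()].
#'
#' @param B Adams parameter; if \code{NULL}, derived from the other inputs.
#' @param mu_excess Excess chemical potential (kcal/mol).
#' @param v_gcmc Region volume (A^3).
#' @param v_std Standard-state volume (A^3).
#' @param temperature Temperature (K).
#' @return An object of class \code{adams_parameters}.
#' @export
adams_parameters <- function(B = NULL, mu_excess = -6.09, v_gcmc = NULL,
                             v_std = 30.345, temperature = 298) {
  if (is.null(B)) {
    if (is.null(v_gcmc)) stop("need either B or v_gcmc")
    B <- adams_equilibrium(mu_excess, v_gcmc, v_std, temperature)
  }
  structure(list(B = B, mu_excess = mu_excess, v_std = v_std,
                 temperature = temperature,
                 beta = 1 / (UNITS$kB * temperature)),
            class = "adams_parameters")
}

#' Define the insertion/deletion region
#'
#' Either a sphere whose center is the midpoint of one or two named
#' reference sites (recomputed from current coordinates at every move), or
#' the whole box. Membership uses the molecule's primary site under the
#' minimum-image convention and is strict (\code{distance < radius}).
#'
#' @param species Template name of the movable species.
#' @param mode \code{"sphere"} or \code{"box"}.
#' @param center_sites Integer site indices (length 1 or 2) defining the
#'   sphere center (sphere mode).
#' @param radius Sphere radius (A).
#' @param box Box edges (A), required in box mode to fix the nominal volume.
#' @return An object of class \code{gc_region}.
#' @export
gc_region <- function(species, mode = c("sphere", "box"), center_sites = NULL,
                      radius = NULL, box = NULL) {
  mode <- match.arg(mode)
  if (mode == "sphere") {
    if (is.null(center_sites) || is.null(radius) || radius <= 0) {
      stop("sphere mode needs center_sites and a positive radius")
    }
    volume <- 4 / 3 * pi * radius^3
  } else {
    if (is.null(box)) stop("box mode needs the box to fix the nominal volume")
    volume <- prod(box)
  }
  structure(list(species = species, mode = mode,
                 center_sites = as.integer(center_sites), radius = radius,
                 volume = volume),
            class = "gc_region")
}

region_center <- function(sys, region) {
  if (region$mode == "box") return(sys$box / 2)
  colMeans(sys$pos[region$center_sites, , drop = FALSE])
}

# molecule indices of the movable species (any status)
species_molecules <- function(sys, region) {
  tid <- match(region$species, names(sys$templates))
  if (is.na(tid)) stop("region species not in system templates")
  which(sys$mol_template == tid)
}

#' Molecules currently inside the move region
#'
#' @param sys A [particle_system()].
#' @param region A [gc_region()].
#' @return Integer vector of molecule indices (real molecules of the
#'   movable species whose primary site lies strictly inside the region).
#' @export
region_members <- function(sys, region) {
  cand <- species_molecules(sys, region)
  cand <- cand[sys$real[cand]]
  if (length(cand) == 0 || region$mode == "box") return(cand)
  ctr <- region_center(sys, region)
  pp <- primary_positions(sys, cand)
  d <- minimum_image(sweep(pp, 2, ctr), sys$box)
  cand[rowSums(d * d) < region$radius^2]
}

# quaternion -> rotation matrix
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Sample an insertion pose
#'
#' The primary site is placed uniformly in the region (uniform in the
#' sphere, or uniform in the box) and the rigid template geometry is
#' rotated by a uniform random rotation (uniform quaternion). Single-site
#' templates skip the orientation draw.
#'
#' @param sys A [particle_system()].
#' @param region A [gc_region()].
#' @param template A [mol_template()].
#' @return n x 3 site coordinate matrix (A).
#' @export
sample_insertion_pose <- function(sys, region, template) {
  if (region$mode == "sphere") {
    ctr <- region_center(sys, region)
    # uniform in sphere: direction uniform, radius ~ R * U^(1/3)
    u <- stats::runif(3)
    r <- region$radius * u[1]^(1 / 3)
    phi <- 2 * pi * u[2]
    ct <- 2 * u[3] - 1
    st <- sqrt(1 - ct^2)
    p <- ctr + r * c(st * cos(phi), st * sin(phi), ct)
  } else {
    p <- stats::runif(3) * sys$box
  }
  g <- template$geometry
  if (template$n_sites > 1) {
    R <- quat_rotation(stats::rnorm(4))
    g <- g %*% t(R)
  }
  sweep(g, 2, g[template$primary, ] - p, "-")
}

#' Instantaneous GCMC acceptance probabilities
#'
#' Adams-formulation Metropolis probabilities. Insertion:
#' \code{min(1, exp(B) exp(-beta dU) / (N + 1))}; deletion:
#' \code{min(1, N exp(-B) exp(-beta dU))}, where \code{dU} is the
#' potential-energy change of the proposed move and \code{N} the number of
#' region members before it.
#'
#' @param dU Energy change of the move (kcal/mol).
#' @param B Adams parameter.
#' @param N Region occupancy before the move.
#' @param temperature Temperature (K).
#' @return Acceptance probability in [0, 1].
#' @export
gcmc_insertion_acceptance <- function(dU, B, N, temperature = 298) {
  if (N < 0) stop("N must be >= 0")
  beta <- 1 / (UNITS$kB * temperature)
  min(1, exp(B - beta * dU) / (N + 1))
}

#' @rdname gcmc_insertion_acceptance
#' @export
gcmc_deletion_acceptance <- function(dU, B, N, temperature = 298) {
  if (N < 1) stop("deletion proposed with no molecule present")
  beta <- 1 / (UNITS$kB * temperature)
  min(1, N * exp(-B - beta * dU))
}

# find a ghost molecule of the species, or append one parked at the origin
ensure_ghost <- function(sys, region) {
  cand <- species_molecules(sys, region)
  ghosts <- cand[!sys$real[cand]]
  if (length(ghosts) > 0) return(list(sys = sys, mol = ghosts[1]))
  tid <- match(region$species, names(sys$templates))
  tpl <- sys$templates[[tid]]
  n <- tpl$n_sites
  sys$mol_template <- c(sys$mol_template, tid)
  sys$mol_first <- c(sys$mol_first, nrow(sys$pos) + 1L)
  sys$mol_nsites <- c(sys$mol_nsites, n)
  sys$pos <- rbind(sys$pos, tpl$geometry)
  sys$vel <- rbind(sys$vel, matrix(0, n, 3))
  sys$real <- c(sys$real, FALSE)
  sys$fixed <- c(sys$fixed, FALSE)
  sys <- cache_site_params(sys)
  list(sys = sys, mol = n_molecules(sys))
}

# park a deleted molecule as a ghost at the box origin with zero velocity
ghostify <- function(sys, mol) {
  idx <- mol_sites(sys, mol)
  tpl <- sys$templates[[sys$mol_template[mol]]]
  sys$pos[idx, ] <- tpl$geometry
  sys$vel[idx, ] <- 0
  sys$real[mol] <- FALSE
  sys
}

# Common proposal for both instantaneous and NCMC moves. Draws, in order:
# move kind, pose or deletion candidate, insertion velocities, and the
# acceptance uniform. Drawing the acceptance uniform here (before any
# propagation) keeps degenerate NCMC protocols stream-identical to
# instantaneous moves and lets rejected NCMC moves rewind propagation
# draws without replaying the proposal.
propose_gc_move <- function(sys, region, adams) {
  kind <- if (stats::runif(1) < 0.5) "insert" else "delete"
  members <- region_members(sys, region)
  N <- length(members)
  prop <- list(kind = kind, n_before = N)
  if (kind == "insert") {
    eg <- ensure_ghost(sys, region)
    sys <- eg$sys
    tpl <- sys$templates[[sys$mol_template[eg$mol]]]
    pose <- sample_insertion_pose(sys, region, tpl)
    vel <- maxwell_boltzmann_velocities(tpl, pose, adams$temperature)
    prop$mol <- eg$mol
    prop$pose <- pose
    prop$vel <- vel
  } else {
    if (N > 0) {
      prop$mol <- members[floor(stats::runif(1) * N) + 1]
    } else {
      prop$mol <- NA_integer_
    }
  }
  prop$u_acc <- stats::runif(1)
  list(sys = sys, prop = prop)
}

new_move_record <- function(kind, method) {
  list(kind = kind, method = method, accepted = FALSE, auto_rejected = FALSE,
       reason = "", work = NA_real_, n_before = NA_integer_,
       n0 = NA_integer_, nT = NA_integer_, prob = NA_real_,
       mol = NA_integer_, force_evals = 0L)
}

#' Attempt one instantaneous GCMC move
#'
#' Chooses insertion or deletion with equal probability. An insertion
#' teleports a ghost molecule to a uniformly sampled pose and evaluates the
#' energy change at full coupling; a deletion picks a uniform region member.
#' The Metropolis test of [gcmc_insertion_acceptance()] /
#' [gcmc_deletion_acceptance()] is applied; rejected moves leave the system
#' exactly unchanged. A deletion attempted on an empty region is recorded
#' as an automatically rejected move.
#'
#' @param sys A [particle_system()].
#' @param region A [gc_region()].
#' @param adams An [adams_parameters()].
#' @return List with elements \code{sys} and \code{record}.
#' @export
attempt_instantaneous_move <- function(sys, region, adams) {
  pg <- propose_gc_move(sys, region, adams)
  prop <- pg$prop
  rec <- new_move_record(prop$kind, "instantaneous")
  rec$n_before <- prop$n_before
  rec$n0 <- prop$n_before
  rec$force_evals <- 1L
  if (prop$kind == "insert") {
    sys2 <- pg$sys
    idx <- mol_sites(sys2, prop$mol)
    sys2$pos[idx, ] <- prop$pose
    sys2$vel[idx, ] <- prop$vel
    sys2$real[prop$mol] <- TRUE
    dU <- molecule_interaction_energy(sys2, prop$mol, 1)
    p <- gcmc_insertion_acceptance(dU, adams$B, prop$n_before, adams$temperature)
    rec$work <- dU; rec$prob <- p; rec$mol <- prop$mol
    rec$nT <- prop$n_before + 1L
    if (prop$u_acc < p) {
      rec$accepted <- TRUE
      sys2$energy <- sys2$energy + dU
      return(list(sys = sys2, record = rec))
    }
    # rejected: keep the (possibly grown) ghost pool but nothing else;
    # reverting to the pre-proposal system restores it exactly
    return(list(sys = sys, record = rec))
  }
  # deletion
  if (prop$n_before == 0) {
    rec$auto_rejected <- TRUE
    rec$reason <- "empty region"
    return(list(sys = sys, record = rec))
  }
  dU <- -molecule_interaction_energy(sys, prop$mol, 1)
  p <- gcmc_deletion_acceptance(dU, adams$B, prop$n_before, adams$temperature)
  rec$work <- dU; rec$prob <- p; rec$mol <- prop$mol
  rec$nT <- prop$n_before - 1L
  if (prop$u_acc < p) {
    rec$accepted <- TRUE
    sys <- ghostify(sys, prop$mol)
    sys$energy <- sys$energy + dU
  }
  list(sys = sys, record = rec)
}
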