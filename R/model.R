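#' Define a rigid molecule template
#'
#' A template describes one molecular species: its interaction sites
#' (mass, partial charge and Lennard-Jones parameters per site) and, for
#' multi-site species, the fixed intramolecular distances that define the
#' rigid body. A 3-site template must close its constraint network with
#' exactly 3 pairwise distances.
#'
#' @param name Species name (e.g. \code{"water"}).
#' @param sites Data frame with columns \code{label}, \code{mass} (amu),
#'   \code{charge} (e), \code{epsilon} (kcal/mol), \code{sigma} (A).
#' @param geometry Reference site coordinates, an n x 3 matrix (A), used to
#'   derive the rigid constraint distances and to generate insertion poses.
#'   May be \code{NULL} for single-site species.
#' @param primary Index of the primary site used for region-membership
#'   tests (the oxygen for water; the single site otherwise).
#' @return An object of class \code{mol_template}.
#' @export
mol_template <- function(name, sites, geometry = NULL, primary = 1L) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1)
  req <- c("label", "mass", "charge", "epsilon", "sigma")
  if (!all(req %in% names(sites))) {
    stop("template sites need columns: ", paste(req, collapse = ", "))
  }
  if (any(sites$mass <= 0)) stop("all site masses must be > 0")
  if (any(sites$sigma < 0) || any(sites$epsilon < 0)) {
    stop("sigma and epsilon must be >= 0")
  }
  n <- nrow(sites)
  if (n > 1) {
    if (is.null(geometry)) stop("multi-site templates need reference geometry")
    geometry <- as.matrix(geometry)
    stopifnot(nrow(geometry) == n, ncol(geometry) == 3)
    pairs <- utils::combn(n, 2)
    constraints <- data.frame(
      i = pairs[1, ], j = pairs[2, ],
      dist = apply(pairs, 2, function(p) {
        sqrt(sum((geometry[p[1], ] - geometry[p[2], ])^2))
      })
    )
    if (n == 3 && nrow(constraints) != 3) stop("3-site rigid body needs 3 distances")
  } else {
    geometry <- matrix(0, 1, 3)
    constraints <- data.frame(i = integer(), j = integer(), dist = numeric())
  }
  structure(list(
    name = name, sites = sites, geometry = geometry,
    constraints = constraints, primary = as.integer(primary),
    n_sites = n, mass_total = sum(sites$mass),
    # plain-vector caches for the integrator inner loops
    site_mass = as.numeric(sites$mass),
    cons_i = as.integer(constraints$i), cons_j = as.integer(constraints$j),
    cons_d = as.numeric(constraints$dist)
  ), class = "mol_template")
}

#' Assemble a particle system
#'
#' The central container: an orthorhombic periodic box of rigid molecules,
#' each an instance of a [mol_template()]. Molecules are either \emph{real}
#' (interacting, propagated) or \emph{ghost} (fully decoupled insertion
#' reservoir, contributing zero energy and force and never propagated).
#' \emph{Fixed} molecules interact but are never moved (static scaffolds).
#'
#' @param templates Named list of [mol_template()] objects.
#' @param molecules Data frame with columns \code{template} (name) and
#'   optional \code{real}, \code{fixed} logicals.
#' @param pos Site coordinate matrix, (total sites) x 3, in A, ordered by
#'   molecule then site.
#' @param vel Site velocity matrix of the same shape, A/ps. Defaults to 0.
#' @param box Numeric length-3 orthorhombic edge lengths (A).
#' @param cutoff Nonbonded cutoff (A); box edges must exceed 2*cutoff.
#' @param switch_start Distance at which the Lennard-Jones switching
#'   function begins (A); must be < cutoff.
#' @param temperature Reference temperature (K).
#' @return An object of class \code{particle_system}.
#' @export
particle_system <- function(templates, molecules, pos, vel = NULL,
                            box, cutoff, switch_start = 0.85 * cutoff,
                            temperature = 298) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive edge lengths")
  if (any(box <= 2 * cutoff)) stop("box edges must exceed 2*cutoff")
  if (switch_start >= cutoff) stop("switch_start must be < cutoff")
  stopifnot(is.list(templates), length(templates) >= 1)
  tnames <- names(templates)
  mol_template_id <- match(molecules$template, tnames)
  if (anyNA(mol_template_id)) stop("unknown template in molecules")
  nsites <- vapply(templates, function(t) t$n_sites, integer(1))
  mol_nsites <- unname(nsites[mol_template_id])
  S <- sum(mol_nsites)
  pos <- as.matrix(pos)
  if (nrow(pos) != S || ncol(pos) != 3) stop("pos must be (total sites) x 3")
  if (is.null(vel)) vel <- matrix(0, S, 3) else vel <- as.matrix(vel)
  real <- if (!is.null(molecules$real)) as.logical(molecules$real) else rep(TRUE, nrow(molecules))
  fixed <- if (!is.null(molecules$fixed)) as.logical(molecules$fixed) else rep(FALSE, nrow(molecules))
  sys <- structure(list(
    templates = templates,
    mol_template = mol_template_id,
    mol_first = cumsum(c(1L, mol_nsites))[seq_along(mol_template_id)],
    mol_nsites = mol_nsites,
    pos = pos, vel = vel,
    real = real, fixed = fixed,
    box = box, cutoff = cutoff, switch_start = switch_start,
    temperature = temperature,
    alch = NULL,
    energy = NA_real_
  ), class = "particle_system")
  sys <- cache_site_params(sys)
  sys$energy <- total_energy(sys)
  sys
}

# rebuild flat per-site parameter vectors (called whenever molecules change)
cache_site_params <- function(sys) {
  tpl <- sys$templates[sys$mol_template]
  sys$site_mol <- rep(seq_along(sys$mol_template), sys$mol_nsites)
  sys$site_mass <- unlist(lapply(tpl, function(t) t$sites$mass), use.names = FALSE)
  sys$site_charge <- unlist(lapply(tpl, function(t) t$sites$charge), use.names = FALSE)
  sys$site_eps <- unlist(lapply(tpl, function(t) t$sites$epsilon), use.names = FALSE)
  sys$site_sig <- unlist(lapply(tpl, function(t) t$sites$sigma), use.names = FALSE)
  sys$has_interactions <- any(sys$site_eps > 0) || any(sys$site_charge != 0)
  sys
}

n_molecules <- function(sys) length(sys$mol_template)

mol_sites <- function(sys, m) {
  seq.int(sys$mol_first[m], length.out = sys$mol_nsites[m])
}

#' Primary-site coordinates of molecules
#' @param sys A [particle_system()].
#' @param mols Molecule indices (default all).
#' @return Matrix length(mols) x 3.
#' @export
primary_positions <- function(sys, mols = seq_along(sys$mol_template)) {
  idx <- sys$mol_first[mols] +
    vapply(sys$templates[sys$mol_template[mols]], function(t) t$primary, integer(1)) - 1L
  sys$pos[idx, , drop = FALSE]
}

#' Minimum-image displacement
#'
#' Wraps a displacement vector into the primary image of an orthorhombic
#' box. Ties at exactly half a box edge are resolved to the negative image.
#'
#' @param d Displacement, a numeric 3-vector or an n x 3 matrix (A).
#' @param box Length-3 box edges (A).
#' @return Same shape as \code{d}, each component of magnitude at most half
#'   the corresponding box edge.
#' @export
minimum_image <- function(d, box) {
  if (any(box <= 0)) stop("box edges must be positive")
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    d
  } else {
    d - box * floor(d / box + 0.5)
  }
}

#' Split alchemical coupling parameter
#'
#' The single coupling parameter lambda in [0, 1] is split so that the
#' Lennard-Jones interactions switch on over the first half and the
#' electrostatics over the second half:
#' \code{lambda_vdw = min(2*lambda, 1)}, \code{lambda_elec = max(2*lambda - 1, 0)}.
#'
#' @param lambda Coupling parameter in [0, 1].
#' @return Named numeric vector \code{c(vdw =, elec =)}.
#' @export
split_lambda <- function(lambda) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  c(vdw = pmin(2 * lambda, 1), elec = pmax(2 * lambda - 1, 0))
}

#' Soft-core Lennard-Jones pair energy
#'
#' Beutler-style soft-core potential used during alchemical coupling:
#' \deqn{U = 4 \epsilon \lambda [(\sigma/r_{eff})^{12} - (\sigma/r_{eff})^6]}
#' with the effective distance
#' \deqn{r_{eff} = (\tfrac{1}{2}\sigma^6 (1-\lambda) + r^6)^{1/6}.}
#' The energy is finite for all separations (including r = 0) whenever
#' \code{lambda_vdw < 1}, vanishes identically at \code{lambda_vdw = 0} and
#' reduces exactly to the standard 12-6 potential at \code{lambda_vdw = 1}.
#'
#' @param r Site separation (A), scalar or vector.
#' @param lambda_vdw Lennard-Jones coupling in [0, 1].
#' @param epsilon Well depth (kcal/mol).
#' @param sigma LJ diameter (A).
#' @return Energy in kcal/mol.
#' @export
softcore_pair_energy <- function(r, lambda_vdw, epsilon, sigma) {
  if (any(lambda_vdw < 0 | lambda_vdw > 1)) stop("lambda_vdw must lie in [0, 1]")
  if (any(r < 0)) stop("r must be >= 0")
  if (lambda_vdw == 0 || epsilon == 0 || sigma == 0) return(r * 0)
  reff6 <- 0.5 * sigma^6 * (1 - lambda_vdw) + r^6
  s6 <- sigma^6 / reff6
  4 * epsilon * lambda_vdw * (s6 * (s6 - 1))
}

#' Shifted-Coulomb electrostatic pair energy
#'
#' Cutoff Coulomb interaction, linearly scaled by the electrostatic
#' coupling parameter and shifted so the energy is continuous (zero) at
#' the cutoff: \code{U = ke q1 q2 lambda_elec (1/r - 1/rc)} for r < rc.
#'
#' @param r Separation (A).
#' @param q1,q2 Partial charges (e).
#' @param lambda_elec Electrostatic coupling in [0, 1].
#' @param cutoff Cutoff distance (A).
#' @return Energy in kcal/mol.
#' @export
electrostatic_pair_energy <- function(r, q1, q2, lambda_elec, cutoff) {
  if (any(lambda_elec < 0 | lambda_elec > 1)) stop("lambda_elec must lie in [0, 1]")
  if (lambda_elec == 0 || q1 == 0 || q2 == 0) return(r * 0)
  if (any(r == 0)) stop("electrostatic singularity at r = 0 with lambda_elec > 0")
  u <- UNITS$coulomb * q1 * q2 * lambda_elec * (1 / r - 1 / cutoff)
  u[r >= cutoff] <- 0
  u
}

# LJ switching function S(r) and its radial derivative: S = 1 below
# switch_start, 0 beyond cutoff, quintic smoothstep between.
switch_fn <- function(r, rs, rc, deriv = FALSE) {
  x <- pmin(pmax((r - rs) / (rc - rs), 0), 1)
  if (!deriv) {
    1 - x^3 * (10 - 15 * x + 6 * x^2)
  } else {
    inside <- r > rs & r < rc
    d <- -30 * x^2 * (1 - x)^2 / (rc - rs)
    d[!inside] <- 0
    d
  }
}

# Core nonbonded kernel between site index sets I and J (no double
# counting performed here; intramolecular and ghost exclusion are the
# caller's responsibility via the masks). Returns energy and, optionally,
# forces on the I sites (and equal/opposite on J accumulated by caller).
#
# lam_vdw/lam_elec are scalars applied to every I-J pair (1 for fully
# coupled interactions).
pair_block <- function(sys, I, J, lam_vdw = 1, lam_elec = 1, forces = FALSE) {
  nI <- length(I); nJ <- length(J)
  if (nI == 0 || nJ == 0) {
    return(list(energy = 0,
                fI = matrix(0, nI, 3), fJ = matrix(0, nJ, 3)))
  }
  rc <- sys$cutoff; rs <- sys$switch_start
  posI <- sys$pos[I, , drop = FALSE]
  posJ <- sys$pos[J, , drop = FALSE]
  # pairwise minimum-image displacements, nI x nJ per component
  dx <- outer(posI[, 1], posJ[, 1], "-")
  dy <- outer(posI[, 2], posJ[, 2], "-")
  dz <- outer(posI[, 3], posJ[, 3], "-")
  bx <- sys$box
  dx <- dx - bx[1] * floor(dx / bx[1] + 0.5)
  dy <- dy - bx[2] * floor(dy / bx[2] + 0.5)
  dz <- dz - bx[3] * floor(dz / bx[3] + 0.5)
  r2 <- dx * dx + dy * dy + dz * dz
  within <- r2 < rc * rc
  # exclude same-molecule pairs (and identical sites) if sets overlap;
  # fixed-fixed pairs are a constant and are excluded from bookkeeping
  molI <- sys$site_mol[I]; molJ <- sys$site_mol[J]
  within <- within & (outer(molI, molJ, "!="))
  fixI <- sys$fixed[molI]; fixJ <- sys$fixed[molJ]
  if (any(fixI) && any(fixJ)) within <- within & !outer(fixI, fixJ, "&")
  if (!any(within)) {
    return(list(energy = 0, fI = matrix(0, nI, 3), fJ = matrix(0, nJ, 3)))
  }
  r <- sqrt(r2)
  epsI <- sys$site_eps[I]; epsJ <- sys$site_eps[J]
  sigI <- sys$site_sig[I]; sigJ <- sys$site_sig[J]
  qI <- sys$site_charge[I]; qJ <- sys$site_charge[J]
  eps_ij <- sqrt(outer(epsI, epsJ))            # Lorentz-Berthelot
  sig_ij <- outer(sigI, sigJ, "+") / 2
  q_ij <- outer(qI, qJ)

  act <- which(within)
  rr <- r[act]
  e_lj <- numeric(length(act))
  dudr <- if (forces) numeric(length(act)) else NULL

  ee <- eps_ij[act]; ss <- sig_ij[act]
  lj_on <- lam_vdw > 0 & ee > 0 & ss > 0
  if (any(lj_on)) {
    s6w <- ss[lj_on]^6
    u6 <- 0.5 * s6w * (1 - lam_vdw) + rr[lj_on]^6
    s6 <- s6w / u6
    # written as s6*(s6-1) so an exact overlap at full coupling gives +Inf
    # (clean rejection) rather than Inf - Inf = NaN
    ulj <- 4 * ee[lj_on] * lam_vdw * (s6 * (s6 - 1))
    sw <- switch_fn(rr[lj_on], rs, rc)
    e_lj[lj_on] <- ulj * sw
    if (forces) {
      # dU/du * du/dr with u = r_eff^6
      dUdu <- 4 * ee[lj_on] * lam_vdw * (s6w / u6^2) * (1 - 2 * s6)
      dUdr <- dUdu * 6 * rr[lj_on]^5
      dsw <- switch_fn(rr[lj_on], rs, rc, deriv = TRUE)
      dudr[lj_on] <- dUdr * sw + ulj * dsw
    }
  }
  e_el <- numeric(length(act))
  qq <- q_ij[act]
  el_on <- lam_elec > 0 & qq != 0
  if (any(el_on)) {
    ke <- UNITS$coulomb
    e_el[el_on] <- ke * qq[el_on] * lam_elec * (1 / rr[el_on] - 1 / rc)
    if (forces) dudr[el_on] <- dudr[el_on] - ke * qq[el_on] * lam_elec / rr[el_on]^2
  }
  energy <- sum(e_lj) + sum(e_el)
  fI <- matrix(0, nI, 3); fJ <- matrix(0, nJ, 3)
  if (forces && length(act)) {
    # force on i along +d (d = xi - xj): f = -(dU/dr) * d/r
    coef <- matrix(0, nI, nJ)
    coef[act] <- -dudr / rr
    fx <- coef * dx; fy <- coef * dy; fz <- coef * dz
    fI <- cbind(rowSums(fx), rowSums(fy), rowSums(fz))
    fJ <- -cbind(colSums(fx), colSums(fy), colSums(fz))
  }
  list(energy = energy, fI = fI, fJ = fJ)
}

# molecules currently interacting (real), as site index vector
real_sites <- function(sys, exclude_mol = NULL) {
  mols <- which(sys$real)
  if (!is.null(exclude_mol)) mols <- setdiff(mols, exclude_mol)
  if (length(mols) == 0) return(integer())
  unlist(lapply(mols, function(m) mol_sites(sys, m)), use.names = FALSE)
}

#' Interaction energy of one molecule with the rest of the system
#'
#' Sum over all (molecule site, other real-molecule site) pairs within the
#' cutoff of the soft-core van der Waals and scaled electrostatic terms at
#' the molecule's alchemical state. Ghost molecules are excluded.
#'
#' @param sys A [particle_system()].
#' @param mol Molecule index.
#' @param lambda Coupling parameter in [0, 1]; 1 means fully coupled.
#' @return Energy in kcal/mol.
#' @export
molecule_interaction_energy <- function(sys, mol, lambda = 1) {
  if (mol < 1 || mol > n_molecules(sys)) stop("no such molecule")
  if (!sys$has_interactions) return(0)
  lam <- split_lambda(lambda)
  if (lam[["vdw"]] == 0 && lam[["elec"]] == 0) return(0)
  I <- mol_sites(sys, mol)
  J <- real_sites(sys, exclude_mol = mol)
  lj <- pair_block(sys, I, J, lam_vdw = lam[["vdw"]], lam_elec = 0)$energy
  el <- if (lam[["elec"]] > 0) {
    pair_block(sys, I, J, lam_vdw = 0, lam_elec = lam[["elec"]])$energy
  } else 0
  lj + el
}

#' Total potential energy of the system
#'
#' Half the sum over real molecules of their interaction energy with the
#' rest of the system at full coupling; if an alchemical state is active
#' (\code{sys$alch}), that molecule contributes at its current lambda.
#'
#' @param sys A [particle_system()].
#' @return Energy in kcal/mol.
#' @export
total_energy <- function(sys) {
  if (!sys$has_interactions) return(0)
  alch <- sys$alch
  mols <- which(sys$real)
  if (!is.null(alch)) mols <- setdiff(mols, alch$mol)
  if (length(mols) < 2 && is.null(alch)) return(0)
  J <- unlist(lapply(mols, function(m) mol_sites(sys, m)), use.names = FALSE)
  e <- 0
  if (length(mols) >= 2) {
    # full symmetric pass (each pair seen twice, halved); chunked over
    # rows to bound memory on large systems
    rows <- max(16L, floor(5e5 / length(J)))
    starts <- seq(1L, length(J), by = rows)
    for (s in starts) {
      I <- J[s:min(s + rows - 1L, length(J))]
      e <- e + pair_block(sys, I, J, 1, 1)$energy / 2
    }
  }
  if (!is.null(alch) && sys$real[alch$mol]) {
    e <- e + molecule_interaction_energy(sys, alch$mol, alch$lambda)
  }
  e
}

#' Forces on all sites
#'
#' Negative gradient of the potential of [total_energy()], including the
#' active alchemical state if present. Ghost sites receive zero force.
#'
#' @param sys A [particle_system()].
#' @return (total sites) x 3 matrix, kcal/mol/A.
#' @export
compute_forces <- function(sys) {
  S <- nrow(sys$pos)
  F <- matrix(0, S, 3)
  if (!sys$has_interactions) return(F)
  alch <- sys$alch
  mols <- which(sys$real)
  if (!is.null(alch)) mols <- setdiff(mols, alch$mol)
  J <- unlist(lapply(mols, function(m) mol_sites(sys, m)), use.names = FALSE)
  if (length(J) > 1) {
    # full symmetric block: row sums give the correct force on each row
    # site; chunked over rows to bound memory on large systems
    rows <- max(16L, floor(5e5 / length(J)))
    starts <- seq(1L, length(J), by = rows)
    for (s in starts) {
      I <- J[s:min(s + rows - 1L, length(J))]
      pb <- pair_block(sys, I, J, 1, 1, forces = TRUE)
      F[I, ] <- F[I, ] + pb$fI
    }
  }
  if (!is.null(alch) && sys$real[alch$mol]) {
    lam <- split_lambda(alch$lambda)
    I <- mol_sites(sys, alch$mol)
    if (lam[["vdw"]] > 0) {
      pb <- pair_block(sys, I, J, lam_vdw = lam[["vdw"]], lam_elec = 0, forces = TRUE)
      F[I, ] <- F[I, ] + pb$fI
      F[J, ] <- F[J, ] + pb$fJ
    }
    if (lam[["elec"]] > 0) {
      pb <- pair_block(sys, I, J, lam_vdw = 0, lam_elec = lam[["elec"]], forces = TRUE)
      F[I, ] <- F[I, ] + pb$fI
      F[J, ] <- F[J, ] + pb$fJ
    }
  }
  if (any(!is.finite(F))) {
    bad <- which(!is.finite(rowSums(F)))[1]
    stop("force overflow at site ", bad, " (overlapping unsoftened sites?)")
  }
  F
}
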