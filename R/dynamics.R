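#' Langevin integrator settings
#'
#' @param timestep Time step (ps); default 0.002 (2 fs).
#' @param friction Collision frequency gamma (1/ps); default 1.0.
#' @param temperature Thermostat temperature (K); default 298.
#' @return An object of class \code{integrator_settings}.
#' @export
integrator_settings <- function(timestep = 0.002, friction = 1.0,
                                temperature = 298) {
  if (timestep <= 0) stop("timestep must be > 0")
  if (friction < 0) stop("friction must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature),
            class = "integrator_settings")
}

#' Project coordinates and velocities onto rigid distance constraints
#'
#' Iterative SHAKE/RATTLE-style projection: coordinates are corrected until
#' every constrained distance matches the template to a relative tolerance
#' of 1e-8, then velocity components along the constrained bonds are
#' removed. Corrections are mass-weighted, so the molecule's linear
#' momentum is conserved.
#'
#' @param template A [mol_template()] with constraint distances.
#' @param positions n x 3 site coordinates (A).
#' @param velocities n x 3 site velocities (A/ps); may be \code{NULL} to
#'   skip the velocity projection.
#' @param tol Relative tolerance on constrained distances.
#' @param max_iter Maximum sweeps before failing.
#' @return List with corrected \code{positions} and \code{velocities}.
#' @export
apply_constraints <- function(template, positions, velocities = NULL,
                              tol = 1e-10, max_iter = 500) {
  nc <- length(template$cons_i)
  if (nc == 0) {
    return(list(positions = positions, velocities = velocities))
  }
  ci <- template$cons_i; cj <- template$cons_j; cd <- template$cons_d
  m <- template$site_mass
  rmu <- 1 / m[ci] + 1 / m[cj]          # reduced-mass factors per constraint
  x <- positions
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (k in seq_len(nc)) {
      i <- ci[k]; j <- cj[k]; d0 <- cd[k]
      d <- x[i, ] - x[j, ]
      r2 <- d[1] * d[1] + d[2] * d[2] + d[3] * d[3]
      diff <- r2 - d0 * d0
      worst <- max(worst, abs(sqrt(r2) - d0) / d0)
      if (diff != 0) {
        # SHAKE correction along the current bond vector
        g <- diff / (2 * r2 * rmu[k])
        x[i, ] <- x[i, ] - g * d / m[i]
        x[j, ] <- x[j, ] + g * d / m[j]
      }
    }
    if (worst < tol) break
    if (iter == max_iter) stop("constraint projection did not converge")
  }
  v <- velocities
  if (!is.null(v)) {
    for (sweep in 1:50) {
      worst <- 0
      for (k in seq_len(nc)) {
        i <- ci[k]; j <- cj[k]
        d <- x[i, ] - x[j, ]
        r2 <- d[1] * d[1] + d[2] * d[2] + d[3] * d[3]
        vr <- sum((v[i, ] - v[j, ]) * d)
        worst <- max(worst, abs(vr) / sqrt(r2))
        g <- vr / (r2 * rmu[k])
        v[i, ] <- v[i, ] - g * d / m[i]
        v[j, ] <- v[j, ] + g * d / m[j]
      }
      if (worst < 1e-12) break
    }
  }
  list(positions = x, velocities = v)
}

# apply position (and velocity) constraints to every mobile multi-site
# molecule of the system
constrain_system <- function(sys, mols = NULL, velocities = TRUE) {
  if (is.null(mols)) mols <- which(sys$real & !sys$fixed & sys$mol_nsites > 1)
  for (m in mols) {
    if (sys$mol_nsites[m] == 1) next
    idx <- mol_sites(sys, m)
    res <- apply_constraints(sys$templates[[sys$mol_template[m]]],
                             sys$pos[idx, , drop = FALSE],
                             if (velocities) sys$vel[idx, , drop = FALSE] else NULL)
    sys$pos[idx, ] <- res$positions
    if (velocities) sys$vel[idx, ] <- res$velocities
  }
  sys
}

# low-level BAOAB core on flat arrays with an arbitrary force function;
# used directly by unit tests (e.g. harmonic oscillators) and by
# baoab_step. x, v: n x d matrices; m: length-n masses; force_fn(x) -> n x d.
baoab_core <- function(x, v, m, force_fn, n_steps, dt, gamma, temperature,
                       constrain = NULL, sample_fn = NULL) {
  kB <- UNITS$kB; acc <- UNITS$accel
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  sd_v <- sqrt(kB * temperature * acc / m)
  f <- force_fn(x)
  half <- dt / 2
  out <- if (!is.null(sample_fn)) vector("list", n_steps) else NULL
  for (s in seq_len(n_steps)) {
    v <- v + (f / m) * acc * half            # B
    x2 <- x + v * half                        # A
    if (!is.null(constrain)) { r <- constrain(x2, v, half); x2 <- r$x; v <- r$v }
    x <- x2
    z <- matrix(stats::rnorm(length(v)), nrow(v), ncol(v))
    v <- c1 * v + c2 * sd_v * z               # O
    if (!is.null(constrain)) { r <- constrain(x, v, NULL); x <- r$x; v <- r$v }
    x2 <- x + v * half                        # A
    if (!is.null(constrain)) { r <- constrain(x2, v, half); x2 <- r$x; v <- r$v }
    x <- x2
    f <- force_fn(x)
    v <- v + (f / m) * acc * half            # B
    if (!is.null(constrain)) { r <- constrain(x, v, NULL); x <- r$x; v <- r$v }
    if (!is.null(sample_fn)) out[[s]] <- sample_fn(x, v)
  }
  list(x = x, v = v, samples = out)
}

#' One (or several) BAOAB Langevin steps on a particle system
#'
#' Applies the B-A-O-A-B splitting to all real, non-fixed molecules. Ghost
#' and fixed molecules are not propagated. Rigid-molecule distance
#' constraints are re-satisfied after each position update and velocity
#' components along constrained bonds are removed. Trajectories are
#' deterministic given the R random-number stream.
#'
#' @param sys A [particle_system()].
#' @param settings An [integrator_settings()].
#' @param n_steps Number of steps to take.
#' @return The propagated system (tracked energy refreshed).
#' @export
baoab_step <- function(sys, settings, n_steps = 1) {
  mobile <- which(sys$real & !sys$fixed)
  if (length(mobile) == 0 || n_steps == 0) return(sys)
  if (all(sys$mol_nsites[mobile] == 1L)) {
    idx <- sys$mol_first[mobile]
  } else {
    idx <- unlist(lapply(mobile, function(m) mol_sites(sys, m)), use.names = FALSE)
  }
  masses <- sys$site_mass[idx]
  # constraint projector over mobile multi-site molecules, in the reduced
  # index space; position corrections during A half-steps are fed back
  # into the velocities so the constraint manifold is preserved
  multi <- mobile[sys$mol_nsites[mobile] > 1]
  constrain <- NULL
  if (length(multi) > 0) {
    loc <- split(seq_along(idx), rep(mobile, sys$mol_nsites[mobile]))
    tpls <- sys$templates
    mol_tpl <- sys$mol_template
    constrain <- function(x, v, half_dt) {
      for (m in multi) {
        li <- loc[[as.character(m)]]
        x0 <- x[li, , drop = FALSE]
        res <- apply_constraints(tpls[[mol_tpl[m]]], x0,
                                 if (is.null(half_dt)) v[li, , drop = FALSE] else NULL)
        if (!is.null(half_dt)) {
          # fold the position correction into the velocity (RATTLE)
          v[li, ] <- v[li, ] + (res$positions - x0) / half_dt
        } else {
          v[li, ] <- res$velocities
        }
        x[li, ] <- res$positions
      }
      list(x = x, v = v)
    }
  }
  force_fn <- if (!sys$has_interactions) {
    Z <- matrix(0, length(idx), 3)
    function(x) Z
  } else {
    function(x) {
      sys$pos[idx, ] <- x
      compute_forces(sys)[idx, , drop = FALSE]
    }
  }
  res <- baoab_core(sys$pos[idx, , drop = FALSE], sys$vel[idx, , drop = FALSE],
                    masses, force_fn, n_steps,
                    settings$timestep, settings$friction, settings$temperature,
                    constrain = constrain)
  sys$pos[idx, ] <- res$x
  sys$vel[idx, ] <- res$v
  sys
}

#' Instantaneous kinetic temperature
#'
#' \code{2 KE / (kB N_dof)} over the real, non-fixed molecules, with one
#' degree of freedom removed per rigid distance constraint.
#'
#' @param sys A [particle_system()].
#' @return Temperature in K.
#' @export
instantaneous_temperature <- function(sys) {
  mobile <- which(sys$real & !sys$fixed)
  if (length(mobile) == 0) stop("no mobile molecules")
  idx <- unlist(lapply(mobile, function(m) mol_sites(sys, m)), use.names = FALSE)
  ncons <- sum(vapply(sys$templates[sys$mol_template[mobile]],
                      function(t) nrow(t$constraints), integer(1)))
  ndof <- 3 * length(idx) - ncons
  if (ndof <= 0) stop("zero degrees of freedom")
  ke <- 0.5 * sum(sys$site_mass[idx] * rowSums(sys$vel[idx, , drop = FALSE]^2)) *
    UNITS$kcal_per_amu_A2_ps2
  2 * ke / (UNITS$kB * ndof)
}

#' Draw Maxwell-Boltzmann velocities for a molecule
#'
#' Site velocities are drawn independently at the requested temperature and
#' then projected onto the constraint manifold for multi-site molecules.
#'
#' @param template A [mol_template()].
#' @param positions Current n x 3 site coordinates (needed for constraint
#'   projection).
#' @param temperature Temperature (K).
#' @return n x 3 velocity matrix (A/ps).
#' @export
maxwell_boltzmann_velocities <- function(template, positions, temperature) {
  n <- template$n_sites
  sd_v <- sqrt(UNITS$kB * temperature * UNITS$accel / template$sites$mass)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  if (n > 1) {
    v <- apply_constraints(template, positions, v)$velocities
  }
  v
}
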