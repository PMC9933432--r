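#' Construct an NCMC switching protocol
#'
#' A nonequilibrium move consists of a propagation segment followed by
#' \code{n_pert} (perturbation, propagation) pairs, so the switching time
#' tau relates to the perturbation count by
#' \code{tau = (n_pert + 1) * n_prop * dt}. The lambda schedule is the
#' ordered list of \code{n_pert + 1} equally spaced values from 0 to 1
#' inclusive (reversed for deletions).
#'
#' @param tau Switching time (ps).
#' @param n_prop MD steps per propagation segment (>= 1); \code{n_prop = 0}
#'   is permitted only as the instantaneous-limit testing degenerate.
#' @param dt Time step (ps).
#' @param n_pert Alternatively, give the perturbation count directly
#'   (with \code{tau = NULL}).
#' @return An object of class \code{ncmc_protocol}.
#' @export
ncmc_protocol <- function(tau = NULL, n_prop = 10, dt = 0.002, n_pert = NULL) {
  if (is.null(n_pert)) {
    if (is.null(tau) || tau <= 0) stop("tau must be > 0")
    if (n_prop < 1 || dt <= 0) stop("n_prop >= 1 and dt > 0 required")
    seg <- n_prop * dt
    k <- tau / seg
    if (abs(k - round(k)) > 1e-9) {
      stop(sprintf(
        "tau = %g ps is not divisible by n_prop*dt = %g ps; nearest valid tau: %g ps",
        tau, seg, round(k) * seg))
    }
    n_pert <- as.integer(round(k)) - 1L
    if (n_pert < 0) stop("tau must be at least n_prop*dt")
  } else {
    n_pert <- as.integer(n_pert)
    if (n_pert < 1) stop("n_pert must be >= 1")
    if (n_prop < 0) stop("n_prop must be >= 0")
    tau <- (n_pert + 1) * n_prop * dt
  }
  structure(list(tau = tau, n_pert = n_pert, n_prop = as.integer(n_prop),
                 dt = dt, lambdas = seq(0, 1, length.out = n_pert + 1)),
            class = "ncmc_protocol")
}

#' GCNCMC acceptance probabilities
#'
#' The instantaneous-move probabilities with the energy change replaced by
#' the accumulated protocol work and the particle counts replaced by the
#' sphere occupancies that account for diffusion during the protocol.
#' Insertion: \code{min(1, exp(B) exp(-beta W) / N_T)}, where \code{N_T}
#' counts region members in the proposed (final) state, including the
#' inserted molecule. Deletion: \code{min(1, N_0 exp(-B) exp(-beta W))},
#' where \code{N_0} counts members in the initial state.
#'
#' @param W Protocol work (kcal/mol).
#' @param B Adams parameter.
#' @param N_T,N_0 Region occupancy in the proposed / initial state.
#' @param temperature Temperature (K).
#' @return Acceptance probability in [0, 1].
#' @export
gcncmc_insertion_acceptance <- function(W, B, N_T, temperature = 298) {
  if (N_T < 1) stop("N_T must be >= 1 (it includes the inserted molecule)")
  beta <- 1 / (UNITS$kB * temperature)
  min(1, exp(B - beta * W) / N_T)
}

#' @rdname gcncmc_insertion_acceptance
#' @export
gcncmc_deletion_acceptance <- function(W, B, N_0, temperature = 298) {
  if (N_0 < 1) stop("N_0 must be >= 1")
  beta <- 1 / (UNITS$kB * temperature)
  min(1, N_0 * exp(-B - beta * W))
}

# capture/restore the R random number stream
get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  get(".Random.seed", envir = globalenv())
}
set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

#' Take / restore a full system snapshot
#'
#' The snapshot holds the complete system state plus the random-number
#' stream; restoring reproduces both bitwise. The stream is included so a
#' rejected nonequilibrium move rewinds its propagation draws.
#'
#' @param sys A [particle_system()].
#' @return An object of class \code{system_snapshot}.
#' @export
take_snapshot <- function(sys) {
  structure(list(sys = sys, rng = get_rng_state()), class = "system_snapshot")
}

#' @rdname take_snapshot
#' @param snap A snapshot from [take_snapshot()].
#' @export
restore_snapshot <- function(snap) {
  set_rng_state(snap$rng)
  snap$sys
}

#' Run one nonequilibrium switching trajectory
#'
#' Gradually couples (\code{direction = "couple"}) or decouples a molecule
#' over the protocol's lambda schedule: a propagation segment, then
#' \code{n_pert} (perturbation, propagation) pairs. The protocol work is
#' the sum of the potential-energy changes of the perturbation steps,
#' evaluated at fixed coordinates; shadow work from the propagation is
#' neglected. During propagation the whole system relaxes with the
#' molecule at its current lambda.
#'
#' @param sys A [particle_system()].
#' @param mol Molecule index (a ghost for coupling; a real member for
#'   decoupling).
#' @param direction \code{"couple"} or \code{"decouple"}.
#' @param protocol An [ncmc_protocol()].
#' @param region A [gc_region()] (for the occupancy counts).
#' @param settings An [integrator_settings()].
#' @return List: \code{sys} (molecule at final lambda, alchemical state
#'   still attached), \code{work}, \code{dU} (per-perturbation energy
#'   changes), \code{n0}, \code{nT}, \code{md_steps}.
#' @export
run_switch <- function(sys, mol, direction = c("couple", "decouple"),
                       protocol, region, settings) {
  direction <- match.arg(direction)
  lams <- protocol$lambdas
  if (direction == "decouple") lams <- rev(lams)
  n0 <- length(region_members(sys, region))
  sys$alch <- list(mol = mol, lambda = lams[1])
  dU <- numeric(protocol$n_pert)
  md <- 0L
  for (k in seq_len(protocol$n_pert + 1)) {
    if (protocol$n_prop > 0) {
      sys <- baoab_step(sys, settings, protocol$n_prop)
      md <- md + protocol$n_prop
    }
    if (k <= protocol$n_pert) {
      u_old <- molecule_interaction_energy(sys, mol, lams[k])
      u_new <- molecule_interaction_energy(sys, mol, lams[k + 1])
      dU[k] <- u_new - u_old
      sys$alch$lambda <- lams[k + 1]
    }
  }
  nT <- length(region_members(sys, region))
  list(sys = sys, work = sum(dU), dU = dU, n0 = n0, nT = nT, md_steps = md)
}

#' Attempt one GCNCMC move
#'
#' Proposal as in [attempt_instantaneous_move()], but the insertion or
#' deletion is performed gradually by [run_switch()]. An insertion whose
#' molecule lies outside the sphere at the end of the protocol is
#' automatically rejected (the move is non-reversible). Otherwise the
#' acceptance test is applied to the accumulated work with the final
#' (insertion) or initial (deletion) sphere count. Rejected moves restore
#' the pre-move snapshot bitwise, including the propagation random draws.
#'
#' @param sys A [particle_system()].
#' @param region A [gc_region()].
#' @param adams An [adams_parameters()].
#' @param protocol An [ncmc_protocol()].
#' @param settings An [integrator_settings()].
#' @return List with elements \code{sys} and \code{record}.
#' @export
attempt_ncmc_move <- function(sys, region, adams, protocol, settings) {
  pg <- propose_gc_move(sys, region, adams)
  prop <- pg$prop
  rec <- new_move_record(prop$kind, "ncmc")
  rec$n_before <- prop$n_before
  if (prop$kind == "delete" && prop$n_before == 0) {
    rec$auto_rejected <- TRUE
    rec$reason <- "empty region"
    rec$n0 <- 0L
    return(list(sys = sys, record = rec))
  }
  snap <- take_snapshot(sys)
  sys2 <- pg$sys
  if (prop$kind == "insert") {
    idx <- mol_sites(sys2, prop$mol)
    sys2$pos[idx, ] <- prop$pose
    sys2$vel[idx, ] <- prop$vel
    sys2$real[prop$mol] <- TRUE
    direction <- "couple"
  } else {
    direction <- "decouple"
  }
  sw <- run_switch(sys2, prop$mol, direction, protocol, region, settings)
  sys2 <- sw$sys
  rec$work <- sw$work
  rec$dU <- sw$dU
  rec$n0 <- sw$n0
  rec$nT <- sw$nT
  rec$mol <- prop$mol
  rec$force_evals <- sw$md_steps + protocol$n_pert
  if (prop$kind == "insert") {
    inside <- prop$mol %in% region_members(sys2, region)
    if (!inside) {
      rec$auto_rejected <- TRUE
      rec$reason <- "left region (non-reversible)"
      return(list(sys = restore_snapshot(snap), record = rec))
    }
    p <- gcncmc_insertion_acceptance(sw$work, adams$B, sw$nT, adams$temperature)
  } else {
    p <- gcncmc_deletion_acceptance(sw$work, adams$B, sw$n0, adams$temperature)
  }
  rec$prob <- p
  if (prop$u_acc < p) {
    rec$accepted <- TRUE
    sys2$alch <- NULL
    if (prop$kind == "delete") sys2 <- ghostify(sys2, prop$mol)
    sys2$energy <- total_energy(sys2)
    return(list(sys = sys2, record = rec))
  }
  list(sys = restore_snapshot(snap), record = rec)
}
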