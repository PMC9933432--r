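#' Campaign configuration
#'
#' Validates and bundles everything needed for a reproducible GCMC/MD or
#' GCNCMC/MD campaign. A GCMC campaign alternates batches of instantaneous
#' moves with MD; a GCNCMC campaign alternates single nonequilibrium moves
#' with MD.
#'
#' @param method \code{"gcmc"} or \code{"gcncmc"}.
#' @param iterations Number of (move block + MD) iterations.
#' @param moves_per_batch Instantaneous moves per iteration (gcmc only).
#' @param md_steps MD steps between move blocks.
#' @param protocol An [ncmc_protocol()] (gcncmc only).
#' @param settings An [integrator_settings()].
#' @param region A [gc_region()].
#' @param adams An [adams_parameters()].
#' @param seed Integer RNG seed, or \code{NULL} to continue the current
#'   stream (used when chaining campaigns).
#' @return An object of class \code{campaign_config}.
#' @export
campaign_config <- function(method = c("gcmc", "gcncmc"), iterations,
                            moves_per_batch = 20, md_steps = 0,
                            protocol = NULL,
                            settings = integrator_settings(),
                            region, adams, seed = NULL) {
  method <- match.arg(method)
  if (iterations < 0) stop("iterations must be >= 0")
  if (method == "gcncmc") {
    if (is.null(protocol)) stop("gcncmc campaigns need an ncmc_protocol")
    if (!inherits(protocol, "ncmc_protocol")) stop("protocol must be an ncmc_protocol")
  }
  if (method == "gcmc" && moves_per_batch < 1) stop("moves_per_batch must be >= 1")
  stopifnot(inherits(region, "gc_region"), inherits(adams, "adams_parameters"),
            inherits(settings, "integrator_settings"))
  structure(list(method = method, iterations = as.integer(iterations),
                 moves_per_batch = as.integer(moves_per_batch),
                 md_steps = as.integer(md_steps), protocol = protocol,
                 settings = settings, region = region, adams = adams,
                 seed = seed),
            class = "campaign_config")
}

# preallocated move-record accumulator
record_accumulator <- function(n) {
  list(kind = character(n), method = character(n), accepted = logical(n),
       auto_rejected = logical(n), reason = character(n), work = numeric(n),
       n_before = integer(n), n0 = integer(n), nT = integer(n),
       prob = numeric(n), mol = integer(n), force_evals = integer(n),
       iteration = integer(n), i = 0L)
}

acc_push <- function(acc, rec, iter) {
  i <- acc$i + 1L
  acc$kind[i] <- rec$kind; acc$method[i] <- rec$method
  acc$accepted[i] <- rec$accepted; acc$auto_rejected[i] <- rec$auto_rejected
  acc$reason[i] <- rec$reason
  acc$work[i] <- rec$work
  acc$n_before[i] <- rec$n_before
  acc$n0[i] <- if (is.null(rec$n0) || is.na(rec$n0)) NA_integer_ else rec$n0
  acc$nT[i] <- if (is.null(rec$nT) || is.na(rec$nT)) NA_integer_ else rec$nT
  acc$prob[i] <- rec$prob; acc$mol[i] <- rec$mol
  acc$force_evals[i] <- rec$force_evals
  acc$iteration[i] <- iter
  acc$i <- i
  acc
}

acc_finish <- function(acc) {
  i <- seq_len(acc$i)
  data.frame(iteration = acc$iteration[i], kind = acc$kind[i],
             method = acc$method[i], accepted = acc$accepted[i],
             auto_rejected = acc$auto_rejected[i], reason = acc$reason[i],
             work = acc$work[i], n_before = acc$n_before[i],
             n0 = acc$n0[i], nT = acc$nT[i], prob = acc$prob[i],
             mol = acc$mol[i], force_evals = acc$force_evals[i],
             stringsAsFactors = FALSE)
}

# capture one analysis frame: region occupancy, member primary-site
# coordinates, alignment reference coordinates and bulk bookkeeping
capture_frame <- function(sys, region, iter) {
  members <- region_members(sys, region)
  sp <- species_molecules(sys, region)
  real_sp <- sp[sys$real[sp]]
  tid <- match(region$species, names(sys$templates))
  ctr <- region_center(sys, region)
  member_xyz <- if (length(members)) {
    # wrap into the image nearest the region center so pooled positions
    # from different frames are directly comparable
    pp <- primary_positions(sys, members)
    sweep(minimum_image(sweep(pp, 2, ctr), sys$box), 2, ctr, "+")
  } else matrix(0, 0, 3)
  list(iteration = iter,
       box = sys$box,
       n_region = length(members),
       region_xyz = member_xyz,
       ref_xyz = if (region$mode == "sphere") sys$pos[region$center_sites, , drop = FALSE] else NULL,
       species_count = length(real_sp),
       mass_total = length(real_sp) * sys$templates[[tid]]$mass_total)
}

#' Run a GCMC/MD or GCNCMC/MD campaign
#'
#' Alternates move blocks with MD as configured, writing one analysis
#' frame at the end of every iteration (whether or not moves were
#' accepted). Fully reproducible from the seed.
#'
#' @param config A [campaign_config()].
#' @param sys The starting [particle_system()].
#' @return An object of class \code{campaign_stats}: move \code{records}
#'   (data frame), \code{frames} (list), counters, and the final
#'   \code{system}.
#' @export
run_campaign <- function(config, sys) {
  if (!inherits(config, "campaign_config")) stop("config must be a campaign_config")
  if (!inherits(sys, "particle_system")) stop("sys must be a particle_system")
  if (!is.null(config$seed)) set.seed(config$seed)
  region <- config$region; adams <- config$adams
  n_it <- config$iterations
  mpb <- if (config$method == "gcmc") config$moves_per_batch else 1L
  acc <- record_accumulator(n_it * mpb)
  frames <- vector("list", n_it)
  md_sampled <- 0L; md_all <- 0L; pert_evals <- 0L; inst_moves <- 0L
  for (it in seq_len(n_it)) {
    if (config$method == "gcmc") {
      for (k in seq_len(mpb)) {
        res <- attempt_instantaneous_move(sys, region, adams)
        sys <- res$sys
        acc <- acc_push(acc, res$record, it)
        inst_moves <- inst_moves + 1L
      }
    } else {
      res <- attempt_ncmc_move(sys, region, adams, config$protocol,
                               config$settings)
      sys <- res$sys
      rec <- res$record
      acc <- acc_push(acc, rec, it)
      pert_done <- min(config$protocol$n_pert, rec$force_evals)
      prop_md <- rec$force_evals - pert_done
      md_all <- md_all + prop_md
      pert_evals <- pert_evals + pert_done
      if (rec$accepted) md_sampled <- md_sampled + prop_md
    }
    if (config$md_steps > 0) {
      sys <- baoab_step(sys, config$settings, config$md_steps)
      md_sampled <- md_sampled + config$md_steps
      md_all <- md_all + config$md_steps
    }
    frames[[it]] <- capture_frame(sys, region, it)
  }
  sys$energy <- total_energy(sys)
  structure(list(
    records = acc_finish(acc),
    frames = frames,
    md_steps_sampled = md_sampled,
    md_steps_total = md_all,
    instantaneous_moves = inst_moves,
    perturbation_evals = pert_evals,
    force_evaluations = md_all + inst_moves + pert_evals,
    config = config,
    system = sys
  ), class = "campaign_stats")
}

#' Acceptance rate of recorded moves
#'
#' Accepted over attempted, with automatically rejected moves counted as
#' attempts.
#'
#' @param stats A \code{campaign_stats} object (or a move-record data
#'   frame).
#' @param method Optional filter, \code{"instantaneous"} or \code{"ncmc"}.
#' @param kind Optional filter, \code{"insert"} or \code{"delete"}.
#' @return Fraction in [0, 1], or \code{NA} if no moves match.
#' @export
acceptance_rate <- function(stats, method = NULL, kind = NULL) {
  rec <- if (is.data.frame(stats)) stats else stats$records
  if (!is.null(method)) rec <- rec[rec$method == method, ]
  if (!is.null(kind)) rec <- rec[rec$kind == kind, ]
  if (nrow(rec) == 0) return(NA_real_)
  mean(rec$accepted)
}

#' Staged equilibration schedule
#'
#' The staged schedule: an initial block of instantaneous GCMC moves, a
#' block of (GCMC batch + 10 fs MD) iterations, an NPT stage of Langevin
#' MD with Monte Carlo volume moves at 1 bar, and a final block of
#' (1 ps MD + GCMC batch) iterations. At \code{reduction = 1} the move
#' counts are exactly 10,000 + 100 x 1000 + 500 x 200; every count scales
#' linearly with \code{reduction} (rounded, minimum 0).
#'
#' @param reduction Scale factor in [0, 1]; 0 skips everything.
#' @param dt Time step (ps), used to convert the MD durations to steps.
#' @return A list of stage counts.
#' @export
equilibration_schedule <- function(reduction = 1, dt = 0.002) {
  f <- reduction
  list(
    stage1_moves = round(10000 * f),
    stage2_iters = round(100 * f), stage2_moves = round(1000 * f),
    stage2_md = if (f > 0) max(1L, round(0.010 / dt)) else 0L,   # 10 fs
    npt_md = round(250000 * f),                                   # 500 ps
    npt_vol_interval = 25L,
    stage4_iters = round(500 * f), stage4_moves = round(200 * f),
    stage4_md = if (f > 0) max(1L, round(1.0 / dt * f)) else 0L   # 1 ps, scaled
  )
}

# isotropic Monte Carlo volume move at the given pressure (bar); molecule
# centers of mass are scaled, internal geometry preserved
mc_volume_move <- function(sys, pressure_bar = 1, max_dlnV = 0.02) {
  V <- prod(sys$box)
  lnV2 <- log(V) + (stats::runif(1) - 0.5) * max_dlnV
  V2 <- exp(lnV2)
  s <- (V2 / V)^(1 / 3)
  box2 <- sys$box * s
  if (any(box2 <= 2 * sys$cutoff)) return(sys)  # keep the cutoff valid
  u_acc <- stats::runif(1)
  old <- sys
  for (m in which(sys$real)) {
    idx <- mol_sites(sys, m)
    com <- colMeans(sys$pos[idx, , drop = FALSE])
    sys$pos[idx, ] <- sweep(sys$pos[idx, , drop = FALSE], 2, com * (s - 1), "+")
  }
  sys$box <- box2
  u2 <- total_energy(sys)
  n <- sum(sys$real & !sys$fixed)
  beta <- 1 / (UNITS$kB * sys$temperature)
  p_int <- pressure_bar * UNITS$bar_to_kcal_mol_A3
  arg <- -beta * (u2 - old$energy + p_int * (V2 - V)) + (n + 1) * log(V2 / V)
  if (log(u_acc) < arg) {
    sys$energy <- u2
    sys
  } else {
    old
  }
}

#' Staged GCMC equilibration
#'
#' Executes [equilibration_schedule()]: instantaneous-move hydration of
#' the region, short-MD refinement, an optional NPT stage (isotropic MC
#' volume moves at 1 bar), and a final MD + GCMC stage.
#'
#' @param sys A [particle_system()].
#' @param region A [gc_region()].
#' @param adams An [adams_parameters()].
#' @param seed Integer RNG seed, or \code{NULL} to continue the stream.
#' @param reduction Scale factor for all stage counts; 0 returns the
#'   system unchanged.
#' @param settings An [integrator_settings()].
#' @param npt Logical; run the NPT volume stage (requires a bulk system).
#' @return List: \code{sys}, \code{moves_attempted}, \code{md_steps},
#'   \code{records} (data frame of all moves).
#' @export
equilibrate <- function(sys, region, adams, seed = NULL, reduction = 1,
                        settings = integrator_settings(temperature = adams$temperature),
                        npt = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sch <- equilibration_schedule(reduction, settings$timestep)
  total_moves <- sch$stage1_moves + sch$stage2_iters * sch$stage2_moves +
    sch$stage4_iters * sch$stage4_moves
  if (total_moves == 0 && sch$npt_md == 0) {
    return(list(sys = sys, moves_attempted = 0L, md_steps = 0L,
                records = acc_finish(record_accumulator(0))))
  }
  acc <- record_accumulator(total_moves)
  md <- 0L
  run_moves <- function(sys, n, stage) {
    for (k in seq_len(n)) {
      res <- attempt_instantaneous_move(sys, region, adams)
      sys <- res$sys
      acc <<- acc_push(acc, res$record, stage)
    }
    sys
  }
  sys <- run_moves(sys, sch$stage1_moves, 1L)
  for (it in seq_len(sch$stage2_iters)) {
    sys <- run_moves(sys, sch$stage2_moves, 2L)
    sys <- baoab_step(sys, settings, sch$stage2_md)
    md <- md + sch$stage2_md
  }
  if (npt && sch$npt_md > 0) {
    done <- 0L
    while (done < sch$npt_md) {
      chunk <- min(sch$npt_vol_interval, sch$npt_md - done)
      sys <- baoab_step(sys, settings, chunk)
      done <- done + chunk
      sys <- mc_volume_move(sys)
    }
    md <- md + sch$npt_md
  }
  for (it in seq_len(sch$stage4_iters)) {
    sys <- baoab_step(sys, settings, sch$stage4_md)
    md <- md + sch$stage4_md
    sys <- run_moves(sys, sch$stage4_moves, 4L)
  }
  sys$energy <- total_energy(sys)
  list(sys = sys, moves_attempted = acc$i, md_steps = md,
       records = acc_finish(acc))
}
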