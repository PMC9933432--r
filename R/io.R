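#' Read a particle system from a PDB file
#'
#' ATOM/HETATM records are parsed with \pkg{bio3d}; molecules are grouped
#' by residue (chain + residue number) and matched to templates by residue
#' name. The box is taken from the CRYST1 record if present, otherwise it
#' must be supplied.
#'
#' @param path PDB file path.
#' @param templates Named list of templates from [read_templates()].
#' @param box Length-3 box edges (A); required when the file has no
#'   CRYST1 record.
#' @param cutoff,switch_start,temperature Passed to [particle_system()].
#' @return A [particle_system()].
#' @export
read_pdb_system <- function(path, templates, box = NULL, cutoff,
                            switch_start = 0.85 * cutoff, temperature = 298) {
  if (!file.exists(path)) stop("no such file: ", path)
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst) >= 1) {
    box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33)))
  } else if (is.null(box)) {
    stop("no CRYST1 record in ", path, "; supply box explicitly")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  resnames <- vapply(templates, function(t) {
    if (is.null(t$resname)) toupper(substr(t$name, 1, 3)) else t$resname
  }, character(1))
  grp <- paste(at$chain, at$resno, sep = "/")
  order_keys <- unique(grp)
  mol_tpl <- character(0)
  pos <- NULL
  for (g in order_keys) {
    rows <- which(grp == g)
    rn <- at$resid[rows[1]]
    tid <- which(resnames == rn)
    if (length(tid) != 1) {
      stop("residue ", rn, " (", g, ") matches no unique template")
    }
    tpl <- templates[[tid]]
    if (length(rows) != tpl$n_sites) {
      stop("residue ", g, " has ", length(rows), " atoms; template ",
           names(templates)[tid], " expects ", tpl$n_sites)
    }
    mol_tpl <- c(mol_tpl, names(templates)[tid])
    pos <- rbind(pos, cbind(at$x[rows], at$y[rows], at$z[rows]))
  }
  particle_system(templates, data.frame(template = mol_tpl), pos,
                  box = box, cutoff = cutoff, switch_start = switch_start,
                  temperature = temperature)
}

#' Write a particle system to a PDB file
#'
#' Standard fixed-column PDB via \pkg{bio3d}, one residue per molecule,
#' occupancy 1.00, with a CRYST1 record for the box. Ghost molecules are
#' omitted unless requested.
#'
#' @param sys A [particle_system()].
#' @param path Output path.
#' @param include_ghosts Also write decoupled molecules (debug aid).
#' @export
write_pdb_system <- function(sys, path, include_ghosts = FALSE) {
  mols <- which(sys$real | include_ghosts)
  if (length(mols) == 0) stop("nothing to write")
  idx <- unlist(lapply(mols, function(m) mol_sites(sys, m)), use.names = FALSE)
  tpl <- sys$templates[sys$mol_template[mols]]
  elety <- unlist(lapply(tpl, function(t) t$sites$label), use.names = FALSE)
  resid <- unlist(lapply(tpl, function(t) {
    rep(if (is.null(t$resname)) toupper(substr(t$name, 1, 3)) else t$resname,
        t$n_sites)
  }), use.names = FALSE)
  resno <- rep(seq_along(mols), sys$mol_nsites[mols])
  xyz <- as.numeric(t(sys$pos[idx, , drop = FALSE]))
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   eleno = seq_along(idx), elety = elety,
                   chain = rep("A", length(idx)),
                   o = rep(1, length(idx)), b = rep(0, length(idx)))
  lines <- readLines(path, warn = FALSE)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   sys$box[1], sys$box[2], sys$box[3])
  writeLines(c(cryst, lines), path)
  invisible(path)
}

#' Append a frame to an XYZ trajectory
#'
#' @param sys A [particle_system()].
#' @param path Output path (appended to).
#' @param comment Comment-line text.
#' @export
write_xyz_frame <- function(sys, path, comment = "") {
  mols <- which(sys$real)
  idx <- unlist(lapply(mols, function(m) mol_sites(sys, m)), use.names = FALSE)
  labels <- unlist(lapply(sys$templates[sys$mol_template[mols]],
                          function(t) t$sites$label), use.names = FALSE)
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(c(as.character(length(idx)), comment), con)
  writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", labels,
                     sys$pos[idx, 1], sys$pos[idx, 2], sys$pos[idx, 3]), con)
  invisible(path)
}

#' Write the move log as a tab-separated table
#'
#' One attempted move per line.
#'
#' @param stats A \code{campaign_stats} object or move-record data frame.
#' @param path Output path.
#' @export
write_move_log <- function(stats, path) {
  rec <- if (is.data.frame(stats)) stats else stats$records
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary report of a campaign
#'
#' Counters, acceptance rates by move kind, and the mean region occupancy.
#'
#' @param stats A \code{campaign_stats} object.
#' @param path Output path.
#' @export
write_summary_report <- function(stats, path) {
  occ <- vapply(stats$frames, function(f) f$n_region, numeric(1))
  rep <- list(
    method = stats$config$method,
    iterations = stats$config$iterations,
    moves_attempted = nrow(stats$records),
    acceptance_rate = acceptance_rate(stats),
    acceptance_rate_insert = acceptance_rate(stats, kind = "insert"),
    acceptance_rate_delete = acceptance_rate(stats, kind = "delete"),
    mean_region_occupancy = if (length(occ)) mean(occ) else NA,
    md_steps_sampled = stats$md_steps_sampled,
    md_steps_total = stats$md_steps_total,
    force_evaluations = stats$force_evaluations,
    force_evaluation_counting = paste(
      "one per MD step (plain or propagation), one per instantaneous move,",
      "one per NCMC perturbation energy evaluation")
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write cluster representatives as a PDB file
#'
#' One pseudo-atom per hydration site with the occupancy in the B-factor
#' column.
#'
#' @param report A [cluster_hydration_sites()] report.
#' @param path Output path.
#' @export
write_cluster_pdb <- function(report, path) {
  n <- nrow(report)
  if (n == 0) stop("empty cluster report")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(report[, c("x", "y", "z")]))),
                   resno = seq_len(n), resid = rep("HOH", n),
                   eleno = seq_len(n), elety = rep("O", n),
                   chain = rep("W", n), o = rep(1, n),
                   b = round(report$occupancy, 2))
  invisible(path)
}

#' Reference configuration of the bulk-water study
#'
#' The full-scale bulk-water campaign: a 64.02 nm^3 box of 2094 rigid
#' TIP3P waters in equilibrium with bulk (B = -2.630 from the excess
#' chemical potential -6.09 kcal/mol and standard-state volume
#' 30.345 A^3 at 298 K), sampled either by batches of 20 instantaneous
#' moves with 4 ps of MD between batches, or by single nonequilibrium
#' moves (switching times 1-25 ps, 10-50 MD steps per perturbation)
#' separated by 10 ps of MD. These runs take days of compute and their
#' expected long-run acceptance rates (about 0.028\% for instantaneous
#' sampling and up to about 40\% for the nonequilibrium protocols, under
#' Ewald electrostatics) are retained here as documentation, not as
#' desk-scale checks; this package's cutoff electrostatics will also shift
#' them quantitatively.
#'
#' @return A list describing the system, both campaign layouts and the
#'   long-run expectations.
#' @export
bulk_water_reference_config <- function() {
  v_box <- 64.02e3                      # A^3
  edge <- v_box^(1 / 3)
  list(
    system = list(n_waters = 2094, n_atoms = 6282, box = rep(edge, 3),
                  volume_A3 = v_box, temperature = 298),
    adams = list(mu_excess = -6.09, v_std = 30.345,
                 B = adams_equilibrium(-6.09, v_box, 30.345, 298)),
    gcmc = list(moves_per_batch = 20, md_between_batches_ps = 4),
    gcncmc = list(md_between_moves_ps = 10,
                  switching_times_ps = c(1, 2, 5, 10, 15, 20, 25),
                  n_prop = c(10, 20, 50),
                  example_protocol = ncmc_protocol(tau = 15, n_prop = 50,
                                                   dt = 0.002)),
    long_run_expectations = list(
      gcmc_acceptance = 0.00028,
      gcncmc_acceptance_max = 0.40,
      density_g_cm3 = 0.978,
      note = paste("long-run, full-scale stochastic targets;",
                   "not reproducible at desk scale or with cutoff",
                   "electrostatics"))
  )
}
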