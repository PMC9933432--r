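#' @export
print.particle_system <- function(x, ...) {
  n_real <- sum(x$real)
  cat("particle_system:", n_real, "real /", sum(!x$real), "ghost molecules,",
      nrow(x$pos), "sites\n")
  cat("  box:", paste(sprintf("%.2f", x$box), collapse = " x "),
      "A, cutoff:", x$cutoff, "A (switch from", x$switch_start, "A)\n")
  cat("  species:", paste(names(x$templates), collapse = ", "),
      "| T =", x$temperature, "K | U =",
      sprintf("%.4f", x$energy), "kcal/mol\n")
  invisible(x)
}

#' @export
print.ncmc_protocol <- function(x, ...) {
  cat(sprintf(
    "ncmc_protocol: tau = %g ps, n_pert = %d, n_prop = %d, dt = %g ps\n",
    x$tau, x$n_pert, x$n_prop, x$dt))
  invisible(x)
}

#' @export
print.adams_parameters <- function(x, ...) {
  cat(sprintf("adams_parameters: B = %.4f (T = %g K)\n", x$B, x$temperature))
  invisible(x)
}

#' @export
print.campaign_stats <- function(x, ...) {
  cat("campaign_stats:", x$config$method, "|", x$config$iterations,
      "iterations,", nrow(x$records), "moves attempted\n")
  ar <- acceptance_rate(x)
  cat(sprintf("  acceptance: %.4f (insert %.4f, delete %.4f)\n", ar,
              acceptance_rate(x, kind = "insert"),
              acceptance_rate(x, kind = "delete")))
  occ <- vapply(x$frames, function(f) f$n_region, numeric(1))
  if (length(occ)) {
    cat(sprintf("  region occupancy: mean %.2f (range %d-%d)\n",
                mean(occ), min(occ), max(occ)))
  }
  cat("  force evaluations:", x$force_evaluations,
      "| MD steps sampled:", x$md_steps_sampled, "\n")
  invisible(x)
}
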