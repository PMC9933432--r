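# Independent oracles used across the suite.

# O(N^2) double-loop energy of a single-site LJ system (switched, no
# charges), written independently of the vectorized implementation.
brute_force_lj_energy <- function(sys, epsilon, sigma) {
  n <- length(sys$mol_template)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!sys$real[i] || !sys$real[j]) next
      d <- sys$pos[i, ] - sys$pos[j, ]
      d <- d - sys$box * floor(d / sys$box + 0.5)
      r <- sqrt(sum(d^2))
      if (r >= sys$cutoff) next
      x <- (r - sys$switch_start) / (sys$cutoff - sys$switch_start)
      x <- min(max(x, 0), 1)
      s <- 1 - x^3 * (10 - 15 * x + 6 * x^2)
      e <- e + 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6) * s
    }
  }
  e
}

# brute-force agglomerative average-linkage clustering: repeatedly merge
# the pair of clusters with the smallest mean inter-point distance until
# that distance exceeds the cutoff; returns a membership vector
brute_force_average_linkage <- function(xyz, cutoff) {
  n <- nrow(xyz)
  members <- as.list(seq_len(n))
  D <- as.matrix(stats::dist(xyz))
  repeat {
    k <- length(members)
    if (k == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- mean(D[members[[a]], members[[b]]])
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    if (best_d > cutoff) break
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (c_id in seq_along(members)) out[members[[c_id]]] <- c_id
  out
}

# are two flat clusterings the same partition (up to label permutation)?
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a))[order(vapply(unname(split(seq_along(a), a)), min, 1L))],
            unname(split(seq_along(b), b))[order(vapply(unname(split(seq_along(b), b)), min, 1L))])
}

# stationary distribution of the ideal-gas insertion/deletion chain with
# occupancy capped at n_max, built from the package acceptance
# probabilities (energy change zero) and solved exactly
birth_death_stationary <- function(B, n_max = 50) {
  states <- 0:n_max
  P <- matrix(0, n_max + 1, n_max + 1)
  for (N in states) {
    up <- if (N < n_max) 0.5 * gcmc_insertion_acceptance(0, B, N) else 0
    down <- if (N > 0) 0.5 * gcmc_deletion_acceptance(0, B, N) else 0
    i <- N + 1
    if (N < n_max) P[i, i + 1] <- up
    if (N > 0) P[i, i - 1] <- down
    P[i, i] <- 1 - up - down
  }
  A <- rbind(t(P) - diag(n_max + 1), rep(1, n_max + 1))
  b <- c(rep(0, n_max + 1), 1)
  as.numeric(qr.solve(A, b))
}

# standard error of the mean of a correlated series via batch means
batch_se <- function(x, n_batches = 25) {
  b <- split(x, cut(seq_along(x), n_batches, labels = FALSE))
  m <- vapply(b, mean, numeric(1))
  stats::sd(m) / sqrt(length(m))
}

# run a sweep of moves on a system, returning the occupancy trace
run_move_trace <- function(sys, region, adams, n_moves,
                           method = c("instantaneous", "ncmc"),
                           protocol = NULL, settings = NULL) {
  method <- match.arg(method)
  n_trace <- integer(n_moves)
  for (i in seq_len(n_moves)) {
    r <- if (method == "instantaneous") {
      attempt_instantaneous_move(sys, region, adams)
    } else {
      attempt_ncmc_move(sys, region, adams, protocol, settings)
    }
    sys <- r$sys
    n_trace[i] <- length(region_members(sys, region))
  }
  list(sys = sys, n = n_trace)
}
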