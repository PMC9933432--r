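test_that("protocol arithmetic links switching time, perturbations and step", {
  p <- ncmc_protocol(tau = 10, n_prop = 10, dt = 0.002)
  expect_identical(p$n_pert, 499L)
  expect_length(p$lambdas, 500)
  expect_identical(range(p$lambdas), c(0, 1))
  p2 <- ncmc_protocol(tau = 15, n_prop = 50, dt = 0.002)
  expect_identical(p2$n_pert, 149L)
  # degenerate single-propagation protocol
  p3 <- ncmc_protocol(tau = 10 * 0.002, n_prop = 10, dt = 0.002)
  expect_identical(p3$n_pert, 0L)
  expect_error(ncmc_protocol(tau = 10.01, n_prop = 10, dt = 0.002),
               "nearest valid")
  # directly specified perturbation count back-computes tau
  p4 <- ncmc_protocol(n_pert = 4, n_prop = 5, dt = 0.002)
  expect_equal(p4$tau, 5 * 5 * 0.002)
  expect_equal(diff(p4$lambdas), rep(0.25, 4))
})

test_that("nonequilibrium acceptance reduces to the instantaneous forms", {
  expect_identical(gcncmc_insertion_acceptance(0, 0, 1), 1)
  expect_lt(gcncmc_insertion_acceptance(1e6, 0, 1), 1e-300)
  expect_identical(gcncmc_deletion_acceptance(0, 0, 1), 1)
  expect_error(gcncmc_deletion_acceptance(0, 0, 0), "N_0")
  set.seed(80)
  for (k in 1:100) {
    W <- stats::rnorm(1, 0, 5)
    B <- stats::runif(1, -4, 2)
    N <- sample(0:6, 1)
    # with no diffusion N_T = N + 1 and N_0 = N
    expect_equal(gcncmc_insertion_acceptance(W, B, N + 1),
                 gcmc_insertion_acceptance(W, B, N))
    if (N >= 1) {
      expect_equal(gcncmc_deletion_acceptance(W, B, N),
                   gcmc_deletion_acceptance(W, B, N))
    }
  }
})

test_that("switching work telescopes and is path-symmetric at fixed coordinates", {
  lj <- make_lj_fluid(n = 12, seed = 81)
  reg <- gc_region("lj", "box", box = lj$box)
  st <- integrator_settings()
  prot <- ncmc_protocol(n_pert = 8, n_prop = 0, dt = 0.002)
  # place a ghost at a known pose
  eg <- grandmc:::ensure_ghost(lj, reg)
  sys <- eg$sys
  sys$pos[sys$mol_first[eg$mol], ] <- matrix(c(10, 10, 10), 1, 3)
  sys$real[eg$mol] <- TRUE
  sys$alch <- NULL
  up <- run_switch(sys, eg$mol, "couple", prot, reg, st)
  dU_direct <- molecule_interaction_energy(sys, eg$mol, 1)
  expect_equal(up$work, dU_direct, tolerance = 1e-10)
  expect_equal(sum(up$dU), up$work, tolerance = 1e-12)
  # reverse path from the coupled state gives the negated work
  down <- run_switch(up$sys, eg$mol, "decouple", prot, reg, st)
  expect_equal(down$work, -up$work, tolerance = 1e-10)
})

test_that("ideal-gas switching accumulates exactly zero work", {
  sys <- make_ideal_gas(n = 3, box = 20, seed = 82)
  reg <- gc_region("gas", "box", box = sys$box)
  st <- integrator_settings()
  ad <- adams_parameters(B = 0)
  set.seed(83)
  for (prot in list(ncmc_protocol(n_pert = 1, n_prop = 0),
                    ncmc_protocol(n_pert = 3, n_prop = 4),
                    ncmc_protocol(n_pert = 10, n_prop = 2))) {
    res <- attempt_ncmc_move(sys, reg, ad, prot, st)
    if (!res$record$auto_rejected) expect_identical(res$record$work, 0)
    # acceptance probability is exactly min(1, 1/N_T) or min(1, N_0) at B=0
    rec <- res$record
    if (!rec$auto_rejected) {
      if (rec$kind == "insert") expect_identical(rec$prob, min(1, 1 / rec$nT))
      else expect_identical(rec$prob, min(1, rec$n0))
    }
    sys <- res$sys
  }
})

test_that("rejected nonequilibrium moves restore the snapshot bitwise", {
  lj <- make_lj_fluid(n = 20, seed = 84)
  reg <- gc_region("lj", "box", box = lj$box)
  ad <- adams_parameters(B = -60)   # essentially guaranteed rejection
  st <- integrator_settings()
  prot <- ncmc_protocol(n_pert = 3, n_prop = 3)
  set.seed(85)
  n_rej <- 0
  for (i in 1:15) {
    pre <- lj
    res <- attempt_ncmc_move(lj, reg, ad, prot, st)
    if (!res$record$accepted) {
      n_rej <- n_rej + 1
      expect_identical(res$sys, pre)
    }
    lj <- res$sys
  }
  expect_gt(n_rej, 0)
})

test_that("snapshots restore the random stream so propagation draws rewind", {
  sys <- make_ideal_gas(n = 2, box = 20, seed = 86)
  set.seed(87)
  stats::runif(3)
  snap <- take_snapshot(sys)
  u1 <- stats::runif(5)
  sys2 <- restore_snapshot(snap)
  u2 <- stats::runif(5)
  expect_identical(u1, u2)
  expect_identical(sys2, sys)
})

test_that("insertions that diffuse out of the sphere are auto-rejected", {
  # small sphere, long propagation, non-interacting solvent: the inserted
  # particle free-streams and frequently exits before the protocol ends
  anchor <- grandmc:::single_site_template("anch", mass = 50)
  gas <- grandmc:::single_site_template("gas")
  sys <- particle_system(
    list(anch = anchor, gas = gas),
    data.frame(template = c("anch", "anch"), fixed = TRUE),
    rbind(c(11, 10, 10), c(9, 10, 10)),
    box = c(20, 20, 20), cutoff = 5, temperature = 298)
  reg <- gc_region("gas", "sphere", center_sites = c(1L, 2L), radius = 1.5)
  ad <- adams_parameters(B = 4)
  st <- integrator_settings()
  prot <- ncmc_protocol(n_pert = 2, n_prop = 40)
  set.seed(88)
  auto <- 0; checked <- 0
  for (i in 1:120) {
    pre <- sys
    res <- attempt_ncmc_move(sys, reg, ad, prot, st)
    rec <- res$record
    if (rec$kind == "insert" && rec$auto_rejected) {
      auto <- auto + 1
      expect_match(rec$reason, "left region")
      expect_identical(res$sys, pre)
    }
    if (rec$kind == "insert" && !rec$auto_rejected && rec$accepted) {
      checked <- checked + 1
      expect_true(rec$mol %in% region_members(res$sys, reg))
    }
    sys <- res$sys
  }
  expect_gt(auto, 0)
})

test_that("per-move work equals the re-summed perturbation energy changes", {
  lj <- make_lj_fluid(n = 15, seed = 89)
  reg <- gc_region("lj", "box", box = lj$box)
  ad <- adams_parameters(B = 2)
  st <- integrator_settings()
  prot <- ncmc_protocol(n_pert = 5, n_prop = 2)
  set.seed(90)
  for (i in 1:25) {
    res <- attempt_ncmc_move(lj, reg, ad, prot, st)
    rec <- res$record
    if (!is.null(rec$dU)) {
      expect_length(rec$dU, prot$n_pert)
      expect_lt(abs(sum(rec$dU) - rec$work), 1e-10)
    }
    lj <- res$sys
  }
})

test_that("the degenerate protocol reproduces instantaneous decisions move for move", {
  lj <- make_lj_fluid(n = 30, seed = 91)
  reg <- gc_region("lj", "box", box = lj$box)
  ad <- adams_parameters(B = 2)
  st <- integrator_settings()
  prot <- ncmc_protocol(n_pert = 1, n_prop = 0)
  run <- function(method) {
    set.seed(92)
    sys <- lj
    recs <- vector("list", 400)
    for (i in 1:400) {
      r <- if (method == "inst") attempt_instantaneous_move(sys, reg, ad)
           else attempt_ncmc_move(sys, reg, ad, prot, st)
      sys <- r$sys
      recs[[i]] <- r$record
    }
    list(sys = sys, recs = recs)
  }
  a <- run("inst"); b <- run("ncmc")
  expect_identical(vapply(a$recs, `[[`, logical(1), "accepted"),
                   vapply(b$recs, `[[`, logical(1), "accepted"))
  expect_identical(vapply(a$recs, `[[`, character(1), "kind"),
                   vapply(b$recs, `[[`, character(1), "kind"))
  expect_equal(vapply(a$recs, `[[`, numeric(1), "work"),
               vapply(b$recs, `[[`, numeric(1), "work"))
  expect_identical(a$sys$real, b$sys$real)
  expect_identical(a$sys$pos, b$sys$pos)
})
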