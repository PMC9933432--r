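test_that("equilibrium Adams parameter reproduces reference values", {
  # bulk water box: mu_ex = -6.09 kcal/mol, V = 64.02 nm^3, V0 = 30.345 A^3
  expect_equal(round(adams_equilibrium(-6.09, 64020, 30.345, 298), 3), -2.630)
  expect_identical(adams_equilibrium(0, 30.345, 30.345, 298), 0)
  # 6 A sphere: independent scalar evaluation of the same relation
  v_sph <- 4 / 3 * pi * 6^3
  b_ref <- -6.09 / (0.0019872041 * 298) + log(v_sph / 30.345)
  expect_equal(adams_equilibrium(-6.09, v_sph, 30.345, 298), b_ref)
  expect_equal(round(b_ref, 3), -6.889)
  expect_error(adams_equilibrium(-6.09, -1, 30.345, 298), "positive")
  expect_error(adams_equilibrium(-6.09, 100, 30.345, 0), "positive")
})

test_that("region membership uses the primary site with a strict boundary", {
  tp <- make_toy_pocket(seed = 2, n_shell = 0)
  sys <- tp$sys
  reg <- tp$region
  expect_identical(region_members(sys, reg), integer(0))
  ctr <- sys$box / 2
  place <- function(sys, p) {
    eg <- grandmc:::ensure_ghost(sys, reg)
    s <- eg$sys
    s$pos[s$mol_first[eg$mol], ] <- matrix(p, 1, 3)
    s$real[eg$mol] <- TRUE
    s
  }
  expect_length(region_members(place(sys, ctr), reg), 1)
  expect_length(region_members(place(sys, ctr + c(reg$radius + 0.01, 0, 0)), reg), 0)
  # exactly on the boundary is outside (strict inequality)
  expect_length(region_members(place(sys, ctr + c(reg$radius, 0, 0)), reg), 0)
  expect_length(region_members(place(sys, ctr + c(reg$radius - 1e-9, 0, 0)), reg), 1)
})

test_that("insertion poses are uniform in the sphere with uniform orientations", {
  tp <- make_toy_pocket(seed = 3, n_shell = 0)
  wt <- water_template()
  set.seed(40)
  n <- 20000
  ctr <- tp$sys$box / 2
  r3 <- numeric(n)
  axes <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    pose <- sample_insertion_pose(tp$sys, tp$region, wt)
    r3[i] <- sum((pose[1, ] - ctr)^2)^1.5
    ax <- pose[2, ] - pose[1, ]
    axes[i, ] <- ax / sqrt(sum(ax^2))
  }
  # radius^3 of a uniform-in-sphere point is uniform on [0, R^3]
  target <- tp$region$radius^3 / 2
  se <- tp$region$radius^3 / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(r3) - target), 3 * se)
  # molecular axis uniform on the unit sphere: component means ~ 0,
  # component second moments ~ 1/3
  expect_true(all(abs(colMeans(axes)) < 3 / sqrt(3 * n) + 3 * sqrt(1 / 3) / sqrt(n)))
  expect_true(all(abs(colMeans(axes^2) - 1 / 3) < 3 * sqrt(2 / 9) / sqrt(n)))
  # rigid geometry preserved under the random rotation
  pose <- sample_insertion_pose(tp$sys, tp$region, wt)
  expect_equal(sqrt(sum((pose[1, ] - pose[2, ])^2)), 0.9572, tolerance = 1e-10)
  # single-site template: pose is just the sampled point
  st <- grandmc:::single_site_template("s")
  expect_identical(dim(sample_insertion_pose(tp$sys, tp$region, st)), c(1L, 3L))
})

test_that("instantaneous acceptance probabilities follow the Adams forms", {
  expect_identical(gcmc_insertion_acceptance(0, 0, 0), 1)
  expect_equal(gcmc_insertion_acceptance(0, -2.630, 0), exp(-2.630))
  expect_lt(gcmc_insertion_acceptance(1e6, 0, 0), 1e-300)
  expect_identical(gcmc_deletion_acceptance(0, 0, 1), 1)
  # scalar evaluation with beta = 1/(kB * 298)
  beta <- 1 / (0.0019872041 * 298)
  expect_equal(gcmc_deletion_acceptance(4, -2.630, 3, 298),
               3 * exp(2.630 - beta * 4))
  expect_equal(round(gcmc_deletion_acceptance(4, -2.630, 3, 298), 4), 0.0485)
  # min clamp
  expect_identical(gcmc_deletion_acceptance(-10, 0, 5), 1)
  expect_error(gcmc_deletion_acceptance(0, 0, 0), "no molecule")
})

test_that("instantaneous moves reject cleanly and update the ghost registry", {
  sys <- make_ideal_gas(n = 0, box = 20, seed = 50)
  reg <- gc_region("gas", "box", box = sys$box)
  ad <- adams_parameters(B = 0)
  set.seed(51)
  # deletions on an empty region are recorded as auto-rejected attempts
  seen_auto <- FALSE
  for (i in 1:20) {
    res <- attempt_instantaneous_move(sys, reg, ad)
    rec <- res$record
    if (rec$kind == "delete" && rec$n_before == 0) {
      seen_auto <- TRUE
      expect_true(rec$auto_rejected)
      expect_false(rec$accepted)
      expect_identical(res$sys, sys)
    }
    sys <- res$sys
  }
  expect_true(seen_auto)
  # a hopeless insertion into an LJ clash leaves the system bitwise intact
  lj <- make_lj_fluid(n = 20, seed = 52)
  regl <- gc_region("lj", "box", box = lj$box)
  adl <- adams_parameters(B = -60)
  set.seed(53)
  for (i in 1:30) {
    res <- attempt_instantaneous_move(lj, regl, adl)
    if (!res$record$accepted) expect_identical(res$sys, lj)
    lj <- res$sys
  }
})

test_that("ideal-gas occupancy follows the Adams birth-death chain", {
  sys <- make_ideal_gas(n = 1, box = 20, seed = 60)
  reg <- gc_region("gas", "box", box = sys$box)
  ad <- adams_parameters(B = 0)
  set.seed(61)
  tr <- run_move_trace(sys, reg, ad, 30000)
  n <- tr$n[5001:30000]
  se <- batch_se(n)
  expect_lt(abs(mean(n) - exp(0)), 3 * se)
  # empirical stationary ratios match e^B / (N+1)
  tab <- table(factor(n, levels = 0:10))
  p <- as.numeric(tab) / length(n)
  for (N in 0:2) {
    expect_equal(p[N + 2] / p[N + 1], exp(0) / (N + 1), tolerance = 0.12)
  }
})

test_that("accepted insert and delete flows between adjacent states balance", {
  sys <- make_ideal_gas(n = 1, box = 20, seed = 62)
  reg <- gc_region("gas", "box", box = sys$box)
  ad <- adams_parameters(B = 0.5)
  set.seed(63)
  up <- integer(12); down <- integer(12)
  for (i in 1:40000) {
    nb <- sum(sys$real)
    r <- attempt_instantaneous_move(sys, reg, ad)
    if (r$record$accepted) {
      if (r$record$kind == "insert") up[nb + 1] <- up[nb + 1] + 1
      else down[nb] <- down[nb] + 1
    }
    sys <- r$sys
  }
  # stationarity: upward flow N -> N+1 equals downward flow N+1 -> N
  for (N in 0:3) {
    tot <- up[N + 1] + down[N + 1]
    expect_gt(tot, 50)
    # binomial fluctuation around 1/2
    expect_lt(abs(up[N + 1] / tot - 0.5), 3.5 * sqrt(0.25 / tot))
  }
})

test_that("decoupled ghosts contribute nothing to the energy", {
  lj <- make_lj_fluid(n = 15, seed = 70)
  reg <- gc_region("lj", "box", box = lj$box)
  ad <- adams_parameters(B = 2)
  set.seed(71)
  for (i in 1:400) lj <- attempt_instantaneous_move(lj, reg, ad)$sys
  expect_gt(sum(!lj$real), 0)  # some ghosts exist after deletions
  live <- which(lj$real)
  idx <- unlist(lapply(live, function(m) grandmc:::mol_sites(lj, m)))
  rebuilt <- particle_system(lj$templates,
                             data.frame(template = rep("lj", length(live))),
                             lj$pos[idx, , drop = FALSE], box = lj$box,
                             cutoff = lj$cutoff, switch_start = lj$switch_start)
  expect_equal(total_energy(lj), total_energy(rebuilt), tolerance = 1e-10)
})
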