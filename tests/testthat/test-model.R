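test_that("minimum image wraps into the primary cell with negative-tie convention", {
  box <- c(20, 20, 20)
  expect_identical(minimum_image(c(0, 0, 0), box), c(0, 0, 0))
  expect_identical(minimum_image(c(11, 0, 0), box), c(-9, 0, 0))
  # exact half-box tie resolved to the negative image
  expect_identical(minimum_image(c(10, 10, 10), box), c(-10, -10, -10))
  expect_identical(minimum_image(c(-10, 0, 0), box), c(-10, 0, 0))
  set.seed(1)
  box2 <- c(15, 22, 31)
  d <- matrix(stats::runif(300, -100, 100), 100, 3)
  w <- minimum_image(d, box2)
  expect_true(all(abs(w) <= rep(box2, each = 100) / 2 + 1e-12))
  # wrapped displacement differs from the original by whole box lengths
  expect_true(all(abs((d - w) %% rep(box2, each = 100)) < 1e-9 |
                    abs((d - w) %% rep(box2, each = 100) - rep(box2, each = 100)) < 1e-9))
  expect_error(minimum_image(c(1, 1, 1), c(10, 0, 10)), "positive")
})

test_that("lambda split switches vdW then electrostatics", {
  expect_identical(split_lambda(0), c(vdw = 0, elec = 0))
  expect_identical(split_lambda(1), c(vdw = 1, elec = 1))
  expect_identical(split_lambda(0.5), c(vdw = 1, elec = 0))
  expect_equal(split_lambda(0.25), c(vdw = 0.5, elec = 0))
  expect_equal(split_lambda(0.75), c(vdw = 1, elec = 0.5))
  ls <- seq(0, 1, by = 0.01)
  vals <- vapply(ls, function(l) split_lambda(l), numeric(2))
  expect_true(all(diff(vals[1, ]) >= 0) && all(diff(vals[2, ]) >= 0))
  expect_error(split_lambda(1.2), "lambda")
})

test_that("soft-core potential has exact endpoint identities and finite core", {
  set.seed(42)
  for (k in 1:1000) {
    r <- stats::runif(1, 0.1, 10)
    eps <- stats::runif(1, 0.01, 1)
    sig <- stats::runif(1, 1, 5)
    expect_identical(softcore_pair_energy(r, 0, eps, sig), 0)
    lj <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
    expect_equal(softcore_pair_energy(r, 1, eps, sig), lj, tolerance = 1e-12)
  }
  # standard zero crossing at r = sigma
  expect_equal(softcore_pair_energy(3.15, 1, 0.152, 3.15), 0)
  # finite at zero separation when partially coupled: with lambda = 1/2 the
  # effective distance at r = 0 is (sigma^6/4)^(1/6), giving 24 * epsilon
  expect_equal(softcore_pair_energy(0, 0.5, 0.152, 3.15), 3.648)
  expect_true(is.finite(softcore_pair_energy(0, 0.999, 0.152, 3.15)))
  expect_error(softcore_pair_energy(3, 1.5, 0.1, 3), "lambda")
})

test_that("shifted-coulomb electrostatics scale linearly and vanish at cutoff", {
  expect_identical(electrostatic_pair_energy(5, 1, -1, 0, 12), 0)
  expect_equal(electrostatic_pair_energy(12, 1, 1, 1, 12), 0)
  # hand evaluation: ke * (1/3 - 1/12) = ke / 4
  expect_equal(electrostatic_pair_energy(3, 1, 1, 1, 12), 332.0636 / 4,
               tolerance = 1e-10)
  e1 <- electrostatic_pair_energy(4, 0.5, -0.8, 1, 10)
  expect_equal(electrostatic_pair_energy(4, 0.5, -0.8, 0.3, 10), 0.3 * e1)
  expect_error(electrostatic_pair_energy(0, 1, 1, 1, 12), "singularity")
})

test_that("molecule interaction energy matches pair expectations", {
  tpl <- mol_template("p", data.frame(label = "P", mass = 10, charge = 0,
                                      epsilon = 0.2, sigma = 3))
  mk <- function(pos) particle_system(list(p = tpl),
    data.frame(template = rep("p", nrow(pos))), pos, box = c(30, 30, 30),
    cutoff = 10, switch_start = 8.5)
  lone <- mk(matrix(c(5, 5, 5), 1, 3))
  expect_identical(molecule_interaction_energy(lone, 1, 1), 0)
  rmin <- 2^(1 / 6) * 3
  pair <- mk(rbind(c(5, 5, 5), c(5 + rmin, 5, 5)))
  expect_equal(molecule_interaction_energy(pair, 1, 1), -0.2, tolerance = 1e-12)
  expect_identical(molecule_interaction_energy(pair, 1, 0), 0)
  # total energy of the two-particle system equals either molecule's view
  expect_equal(total_energy(pair), molecule_interaction_energy(pair, 2, 1))
})

test_that("total energy matches a brute-force double loop on an LJ fluid", {
  sys <- make_lj_fluid(n = 10, seed = 5)
  expect_equal(total_energy(sys), brute_force_lj_energy(sys, 0.2, 3),
               tolerance = 1e-10)
  # relabeling invariance: rebuild with molecules in reverse order
  rev_sys <- particle_system(sys$templates,
                             data.frame(template = rep("lj", 10)),
                             sys$pos[10:1, ], box = sys$box,
                             cutoff = sys$cutoff,
                             switch_start = sys$switch_start)
  expect_equal(total_energy(rev_sys), total_energy(sys), tolerance = 1e-12)
})

test_that("total energy is invariant under rigid translation", {
  sys <- make_lj_fluid(n = 12, seed = 8)
  e0 <- total_energy(sys)
  set.seed(9)
  for (k in 1:5) {
    shift <- stats::runif(3, -40, 40)
    s2 <- sys
    s2$pos <- sweep(sys$pos, 2, shift, "+")
    expect_equal(total_energy(s2), e0, tolerance = 1e-10)
  }
})

test_that("forces are the negative gradient of the energy", {
  sys <- make_lj_fluid(n = 8, seed = 3)
  f <- compute_forces(sys)
  h <- 1e-6
  for (site in c(1, 4, 8)) {
    for (dim in 1:3) {
      sp <- sys; sp$pos[site, dim] <- sp$pos[site, dim] + h
      sm <- sys; sm$pos[site, dim] <- sm$pos[site, dim] - h
      num <- -(total_energy(sp) - total_energy(sm)) / (2 * h)
      expect_equal(f[site, dim], num, tolerance = 1e-5)
    }
  }
})

test_that("water-water energetics include electrostatics and stay finite", {
  wb <- make_water_box(n = 6, box = 18, cutoff = 7, switch_start = 6, seed = 2)
  e <- total_energy(wb)
  expect_true(is.finite(e))
  # scaling all charges to zero leaves pure (switched) LJ: energy changes
  wb0 <- wb
  wb0$site_charge <- wb0$site_charge * 0
  expect_false(isTRUE(all.equal(total_energy(wb0), e)))
})

test_that("incremental energy bookkeeping tracks recomputation through moves", {
  sys <- make_lj_fluid(n = 15, seed = 21)
  reg <- gc_region("lj", "box", box = sys$box)
  ad <- adams_parameters(B = 2)
  set.seed(77)
  for (i in 1:300) {
    res <- attempt_instantaneous_move(sys, reg, ad)
    sys <- res$sys
  }
  expect_equal(sys$energy, total_energy(sys), tolerance = 1e-8)
})

test_that("system constructor enforces its invariants", {
  tpl <- mol_template("p", data.frame(label = "P", mass = 1, charge = 0,
                                      epsilon = 0, sigma = 0))
  pos <- matrix(0, 1, 3)
  expect_error(particle_system(list(p = tpl), data.frame(template = "p"),
                               pos, box = c(10, 10, -1), cutoff = 3), "box")
  expect_error(particle_system(list(p = tpl), data.frame(template = "p"),
                               pos, box = c(10, 10, 10), cutoff = 6),
               "exceed")
  expect_error(mol_template("bad", data.frame(label = "X", mass = -1,
                                              charge = 0, epsilon = 0,
                                              sigma = 0)), "mass")
})
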