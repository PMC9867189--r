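test_that("FENE force has the unit-fixed form and diverges at L_max", {
  expect_equal(fene_force(0), 0)
  expect_equal(fene_force(1.35), 1.35 / (1 - 0.2025), tolerance = 1e-12)
  expect_gt(fene_force(2.9), 10 * fene_force(1.5))
  expect_error(fene_force(3), "overstretch")
  expect_error(fene_force(-0.1), "non-negative")
  # force is d/dR of the energy in these units (factor 1/2 of kT gradient)
  h <- 1e-7
  expect_equal(fene_force(2), (fene_energy(2 + h) - fene_energy(2 - h)) / (4 * h),
               tolerance = 1e-5)
})

test_that("pair potential branches join continuously at contact", {
  ff <- forcefield(eps = 1.3)
  for (pair in list(c("H", "H"), c("P", "P"), c("H", "P"),
                    c("+", "-"), c("+", "+"), c("H", "+"))) {
    b <- if (all(pair == c("+", "-"))) (2.44 + 2.29) / 2 else NULL
    b <- idpcg:::pair_contact_b(pair[1], pair[2], ff)
    lo <- pair_potential(b * (1 - 1e-9), pair[1], pair[2], ff)
    hi <- pair_potential(b * (1 + 1e-9), pair[1], pair[2], ff)
    expect_lt(abs(lo - hi), 1e-6)
  }
})

test_that("cohesive pair has depth -eps/3 at contact and a tiny 4b tail", {
  ff <- forcefield(eps = 1.5)
  b <- 1.5
  expect_equal(pair_potential(b, "H", "H", ff), -ff$eps / 3, tolerance = 1e-9)
  # zero radial force at contact (minimum of the joined potential)
  h <- 1e-6
  grad <- (pair_potential(b + h, "H", "H", ff) -
           pair_potential(b - h, "H", "H", ff)) / (2 * h)
  expect_lt(abs(grad), 1e-4)
  expect_lt(abs(pair_potential(4 * b * (1 - 1e-9), "H", "H", ff)),
            1e-3 * ff$eps / 3)
})

test_that("neutral pair is purely repulsive and vanishes beyond contact", {
  ff <- forcefield()
  expect_equal(pair_potential(1.5, "P", "P", ff), 0, tolerance = 1e-12)
  expect_equal(pair_potential(2.1, "P", "P", ff), 0)
  expect_gt(pair_potential(1.2, "P", "P", ff), 0)
  expect_error(pair_potential(0, "P", "P", ff), "positive")
})

test_that("screened Coulomb term matches direct evaluation", {
  ff <- forcefield()
  b <- (2.44 + 2.29) / 2
  # at r = L_D = 4 > b the only contribution is electrostatic
  expect_equal(pair_potential(4, "+", "-", ff), -2 * exp(-1) / 4,
               tolerance = 1e-12)
  expect_equal(pair_potential(4, "+", "+", ff), 2 * exp(-1) / 4,
               tolerance = 1e-12)
  # truncated beyond 5 L_D
  expect_equal(pair_potential(21, "+", "-", ff), 0)
})

test_that("equilibrium bond length of a bonded neutral pair is about 1.35", {
  ff <- forcefield()
  u <- function(r) fene_energy(r) + pair_potential(r, "P", "P", ff, bonded = TRUE)
  opt <- stats::optimize(u, c(0.5, 2.9))
  expect_gt(opt$minimum, 1.30)
  expect_lt(opt$minimum, 1.40)
})

test_that("total forces obey Newton's third law and match the energy gradient", {
  set.seed(12)
  seq <- cg_sequence(sample(c("P", "H", "+", "-"), 10, replace = TRUE))
  ff <- forcefield(eps = 0.8)
  for (rep in 1:3) {
    pos <- init_saw(seq, seed = rep)
    F <- total_forces(pos, seq, ff)
    expect_lt(max(abs(colSums(F))), 1e-10)
    h <- 1e-6
    num <- matrix(0, 10, 3)
    for (i in 1:10) {
      for (d in 1:3) {
        p1 <- pos; p1[i, d] <- p1[i, d] + h
        p2 <- pos; p2[i, d] <- p2[i, d] - h
        num[i, d] <- -(total_energy(p1, seq, ff) - total_energy(p2, seq, ff)) /
          (2 * h) / 2
      }
    }
    expect_lt(max(abs(F - num)) / max(abs(F)), 1e-5)
  }
})

test_that("two bonded neutral beads feel FENE plus bonded repulsion", {
  ff <- forcefield()
  pos <- rbind(c(0, 0, 0), c(1.35, 0, 0))
  F <- total_forces(pos, cg_sequence(c("P", "P")), ff)
  # bead 1 feels the bonded repulsion pushing it to -x and the FENE
  # attraction pulling it to +x; at 1.35 (just beyond the minimum) the
  # FENE term wins slightly
  h <- 1e-7
  rep_force <- -(pair_potential(1.35 + h, "P", "P", ff, bonded = TRUE) -
                 pair_potential(1.35 - h, "P", "P", ff, bonded = TRUE)) / (2 * h) / 2
  expect_equal(F[1, 1], fene_force(1.35) - rep_force, tolerance = 1e-6)
  expect_equal(F[2, 1], -F[1, 1])
})

test_that("invalid configurations are rejected", {
  seq <- cg_sequence(c("P", "P", "P"))
  pos <- rbind(c(0, 0, 0), c(NaN, 0, 0), c(2, 0, 0))
  expect_error(total_forces(pos, seq, forcefield()), "finite")
})
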