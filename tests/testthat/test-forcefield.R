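# Interaction model: Coulomb, purely repulsive LJ with hard-core shift,
# harmonic terms, and force-energy consistency.

test_that("Bjerrum length matches the first-principles constant combination", {
  # e^2 / (4 pi eps0 * 78 * kB * 298 K), computed independently from CODATA
  # constants: 7.1890 A
  expect_equal(bjerrum_length(78, 298), 7.18899, tolerance = 1e-5)
  # two unit charges separated by l_B interact with exactly 1 kT
  p <- ff_params()
  expect_equal(coulomb_energy(1, 1, p$bjerrum_length, p), 1)
  expect_equal(coulomb_energy(1, 1, 2 * p$bjerrum_length, p), 0.5)
  expect_equal(coulomb_energy(0, 1, 3.3, p), 0)
  expect_error(coulomb_energy(1, 1, 0, p), "positive")
})

test_that("repulsive LJ has the WCA shape on the hard-core-shifted distance", {
  p <- ff_params()
  xc <- 2^(1 / 6) * p$sigma
  # zero at and beyond the cutoff, 1 kT at x = sigma
  expect_equal(lj_repulsive_energy(1.5 + 2 + xc, 1.5, 2, p), 0)
  expect_equal(lj_repulsive_energy(1.5 + 2 + xc + 5, 1.5, 2, p), 0)
  expect_equal(lj_repulsive_energy(1.5 + 2 + p$sigma, 1.5, 2, p),
               p$epsilon_lj)
  # continuity at the cutoff
  expect_lt(lj_repulsive_energy(3.5 + xc - 1e-6, 1.5, 2, p), 1e-5)
  # strictly decreasing on (0, xc]
  xs <- seq(0.4 * p$sigma, xc, length.out = 200)
  u <- lj_repulsive_energy(3.5 + xs, 1.5, 2, p)
  expect_true(all(diff(u) < 0))
  # overlap: finite, flagged
  expect_warning(uo <- lj_repulsive_energy(3.0, 1.5, 2, p), "overlap")
  expect_true(is.finite(uo) && uo > p$overlap_cap)
})

test_that("harmonic terms vanish at equilibrium and are symmetric", {
  expect_equal(bond_energy(3, 5, 3), 0)
  expect_equal(bond_energy(3.5, 5, 3), bond_energy(2.5, 5, 3))
  expect_equal(bond_energy(4, 5, 3), 2.5)   # (5/2) * 1^2
  expect_equal(angle_energy(2, 100, 2), 0)
  expect_equal(angle_energy(2.1, 100, 2), angle_energy(1.9, 100, 2))
  expect_error(bond_energy(-1, 5, 3), "positive")
  expect_error(angle_energy(4, 100, 2), "0, pi")
})

random_test_system <- function(seed, n = 30) {
  set.seed(seed)
  xyz <- matrix(runif(n * 3, 0, 20), n, 3)
  beads <- bead_row(n, xyz, charge = sample(c(-1, 0, 1), n, TRUE),
                    hard_radius = sample(c(0, 0.5, 1), n, TRUE))
  bonds <- tibble::tibble(i = 1:10, j = 11:20, k_b = 5, r_0 = 3, type = "b")
  angles <- tibble::tibble(i = 1:5, j = 6:10, k = 11:15, k_a = 10,
                           phi_0 = 2, type = "a")
  tiny_model(beads, bonds, angles)
}

test_that("forces match central finite differences of the energy", {
  m <- random_test_system(7)
  xyz <- as.matrix(m$beads[, c("x", "y", "z")])
  p <- ff_params(electrostatics = "direct")
  r0 <- total_energy_forces(xyz, m, p, box_edge = 0)
  h <- 1e-5
  for (i in c(1, 8, 16, 25, 30)) {
    for (d in 1:3) {
      xp <- xyz; xp[i, d] <- xp[i, d] + h
      xm <- xyz; xm[i, d] <- xm[i, d] - h
      fd <- -(total_energy_forces(xp, m, p, 0)$energy -
                total_energy_forces(xm, m, p, 0)$energy) / (2 * h)
      expect_equal(r0$forces[i, d], fd,
                   tolerance = 1e-4 * max(1, abs(fd)))
    }
  }
  # periodic cutoff route too
  p2 <- ff_params(electrostatics = "cutoff", coulomb_cutoff = 8)
  r2 <- total_energy_forces(xyz, m, p2, box_edge = 40)
  for (i in c(3, 17)) {
    for (d in 1:3) {
      xp <- xyz; xp[i, d] <- xp[i, d] + h
      xm <- xyz; xm[i, d] <- xm[i, d] - h
      fd <- -(total_energy_forces(xp, m, p2, 40)$energy -
                total_energy_forces(xm, m, p2, 40)$energy) / (2 * h)
      expect_equal(r2$forces[i, d], fd,
                   tolerance = 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("energy is invariant under rigid motion and forces sum to zero", {
  m <- random_test_system(13)
  xyz <- as.matrix(m$beads[, c("x", "y", "z")])
  p <- ff_params(electrostatics = "direct")
  e0 <- total_energy_forces(xyz, m, p, 0)
  expect_lt(max(abs(colSums(e0$forces))), 1e-9)
  # translation
  e1 <- total_energy_forces(sweep(xyz, 2, c(13.7, -4.2, 99), `+`), m, p, 0)
  expect_equal(e1$energy, e0$energy, tolerance = 1e-12)
  # rotation: forces transform covariantly
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e2 <- total_energy_forces(xyz %*% t(R), m, p, 0)
  expect_equal(e2$energy, e0$energy, tolerance = 1e-12)
  expect_equal(e2$forces, e0$forces %*% t(R), tolerance = 1e-9)
})

test_that("pair terms are even under particle exchange", {
  xyz <- rbind(c(0, 0, 0), c(4.4, 0, 0))
  b1 <- bead_row(2, xyz, charge = c(1, -1), hard_radius = c(0, 1))
  b2 <- bead_row(2, xyz[2:1, ], charge = c(-1, 1), hard_radius = c(1, 0))
  p <- ff_params(electrostatics = "direct")
  e1 <- total_energy_forces(model = tiny_model(b1), params = p)
  e2 <- total_energy_forces(model = tiny_model(b2), params = p)
  expect_equal(e1$energy, e2$energy)
})

test_that("bonded pairs are excluded from repulsion but keep their Coulomb term", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))   # well inside contact for R = 1 + 1
  beads <- bead_row(2, xyz, charge = c(1, 1), hard_radius = 1)
  bonds <- tibble::tibble(i = 1L, j = 2L, k_b = 5, r_0 = 2, type = "b")
  m <- tiny_model(beads, bonds)
  p <- ff_params(electrostatics = "direct")
  r <- total_energy_forces(model = m, params = p)
  expect_equal(r$terms[["repulsion"]], 0)
  expect_equal(r$terms[["coulomb"]], p$bjerrum_length / 2)
  expect_equal(r$terms[["bond"]], 0)
  # with the exclusion switched off the overlap is flagged and capped
  p2 <- ff_params(electrostatics = "direct", exclude_bonded_lj = FALSE)
  r2 <- total_energy_forces(model = m, params = p2)
  expect_true(r2$overlap)
  expect_true(is.finite(r2$energy))
})

test_that("parameter files override defaults with CLI-style precedence", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "sigma = 5", "electrostatics = direct"), f)
  p <- read_ff_params(f)
  expect_equal(p$sigma, 5)
  expect_equal(p$electrostatics, "direct")
  expect_equal(p$epsilon_r, 78)
  inc <- withr::local_tempfile(fileext = ".cfg")
  writeLines("epsilon_lj = 2", inc)
  writeLines(c(paste("[include]", inc), "sigma = 6"), f)
  p2 <- read_ff_params(f)
  expect_equal(p2$sigma, 6)
  expect_equal(p2$epsilon_lj, 2)
})
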