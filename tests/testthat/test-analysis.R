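# Observables: RDF, body-frame SDF, P(r)/Rg/Dmax, RMSD, DNA distances,
# stacking geometry and bulk concentration.

test_that("RDF of two Poisson gases is unity within counting error", {
  set.seed(77)
  box <- 100
  frames <- replicate(40, matrix(runif(3 * 300, 0, box), 300, 3),
                      simplify = FALSE)
  tr <- cg_trajectory(frames, steps = seq_len(40), box_edge = box)
  r <- rdf(tr, 1:150, 151:300, bin_width = 0.5)
  keep <- r$count > 50
  expect_true(any(keep))
  # 3 sigma of the Poisson counting error, expressed on g
  sigma_g <- 3 * sqrt(r$count[keep]) / r$count[keep]
  expect_true(all(abs(r$g[keep] - 1) < pmax(sigma_g, 0.05)))
  # self-RDF on a Poisson configuration behaves the same
  rs <- rdf(tr, 1:300, 1:300, bin_width = 0.5)
  keep <- rs$count > 50
  sigma_g <- 3 * sqrt(rs$count[keep]) / rs$count[keep]
  expect_true(all(abs(rs$g[keep] - 1) < pmax(sigma_g, 0.05)))
})

test_that("two fixed particles give a single occupied RDF bin at their distance", {
  fr <- list(rbind(c(0, 0, 0), c(50, 0, 0)))
  tr <- cg_trajectory(fr, 1L, box_edge = 200)
  r <- rdf(tr, 1L, 2L, bin_width = 0.1)
  expect_equal(sum(r$count), 1)
  expect_equal(r$r[which(r$count == 1)], 5.05)  # 5 nm falls in the [5, 5.1) bin
  expect_error(rdf(tr, 1L, 2L, bin_width = 0), "positive")
})

test_that("centre-of-mass selections give the distance between group centroids", {
  fr <- list(rbind(c(0, 0, 0), c(2, 0, 0), c(60, 0, 0), c(62, 0, 0)))
  tr <- cg_trajectory(fr, 1L, box_edge = 200)
  r <- rdf(tr, list(1:2), list(3:4), bin_width = 0.2)
  expect_equal(sum(r$count), 1)
  expect_equal(r$r[which(r$count == 1)], 6.1)   # centroids 1 and 61 -> 6 nm
})

test_that("local frames are right-handed and rigid-motion covariant", {
  set.seed(8)
  xyz <- matrix(rnorm(60, sd = 10), 20, 3)
  fr <- local_frame(xyz, c(1, 5, 9))
  expect_equal(det(fr$rotation), 1, tolerance = 1e-12)
  expect_equal(crossprod(fr$rotation), diag(3), tolerance = 1e-12)
  # identity placement: local coordinates recover the originals
  loc0 <- sweep(xyz, 2, fr$origin) %*% fr$rotation
  for (rep in 1:5) {
    R <- nucleocg:::.random_rotation()
    t <- rnorm(3, sd = 50)
    xyz2 <- sweep(xyz %*% t(R), 2, t, `+`)
    fr2 <- local_frame(xyz2, c(1, 5, 9))
    loc2 <- sweep(xyz2, 2, fr2$origin) %*% fr2$rotation
    expect_equal(loc2, loc0, tolerance = 1e-6)
  }
  collinear <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), xyz[4:20, ])
  expect_error(local_frame(collinear, c(1, 2, 3)), "collinear")
})

test_that("a particle co-moving with the body stays in one SDF voxel", {
  set.seed(9)
  base <- matrix(rnorm(30, sd = 10), 10, 3)
  extra <- c(12, 3, -4)
  frames <- lapply(1:15, function(i) {
    R <- nucleocg:::.random_rotation()
    t <- rnorm(3, sd = 30)
    sweep(rbind(base, extra) %*% t(R), 2, t, `+`)
  })
  tr <- cg_trajectory(frames, seq_len(15), box_edge = 400)
  g <- sdf(tr, frame_sites = c(1, 4, 8), species = 11L, voxel = 4,
           extent = 40)
  expect_equal(sum(g$counts > 0), 1)
  expect_equal(sum(g$counts), 15)
  expect_error(sdf(tr, c(1, 4, 8), 11L, voxel = 0), "positive")
})

test_that("a uniform gas gives a flat SDF at density N/V and exact count conservation", {
  set.seed(10)
  box <- 60
  n <- 4000
  frames <- replicate(10, matrix(runif(3 * n, -box / 2, box / 2), n, 3),
                      simplify = FALSE)
  # anchor sites fixed so the frame is the identity
  anchor <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  frames <- lapply(frames, function(f) rbind(anchor, f))
  tr <- cg_trajectory(frames, seq_len(10), box_edge = 400)
  g <- sdf(tr, frame_sites = c(1, 2, 3), species = 3 + seq_len(n),
           voxel = 10, extent = 20)
  # grid lies fully inside the gas cloud: flat density
  expect_equal(mean(g$density), n / box^3, tolerance = 0.05)
  expect_lt(max(abs(g$density / (n / box^3) - 1)), 0.5)
  # conservation: grid integral equals the mean in-grid count per frame
  expect_equal(sum(g$counts) / g$n_observations,
               sum(g$density) * g$voxel^3)
})

test_that("P(r) of two beads is a delta with Rg = d/2 and Dmax = d", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  p <- pr_rg_dmax(xyz, 1:2, bin_width = 1)
  expect_equal(sum(p$p > 0), 1)
  expect_equal(attr(p, "Rg"), 10.5 / 2, tolerance = 1e-9)
  expect_equal(attr(p, "Dmax"), 11)   # bin upper edge containing d = 10
  expect_equal(sum(p$p) * 1, 1)       # unit area
  expect_error(pr_rg_dmax(xyz, 1L), "two beads")
})

test_that("P(r) of a uniform ball recovers Rg = sqrt(3/5) R within 1%", {
  set.seed(11)
  R <- 40
  n <- 4000
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * R * runif(n)^(1 / 3)
  p <- pr_rg_dmax(u, seq_len(n), bin_width = 0.5)
  expect_equal(attr(p, "Rg"), sqrt(3 / 5) * R, tolerance = 0.01)
  expect_lte(attr(p, "Dmax"), 2 * R + 1)
  # P vanishes beyond Dmax
  expect_true(all(p$p[p$r > attr(p, "Dmax")] == 0))
  g <- glance(p)
  expect_named(g, c("Rg", "Dmax", "bin_width"))
})

test_that("optimal-superposition RMSD removes rigid motion exactly", {
  set.seed(12)
  a <- matrix(rnorm(45, sd = 8), 15, 3)
  expect_equal(rmsd_optimal(a, a), 0, tolerance = 1e-10)
  R <- nucleocg:::.random_rotation()
  b <- sweep(a %*% t(R), 2, c(5, -3, 11), `+`)
  expect_lt(rmsd_optimal(a, b), 1e-6)
  expect_equal(rmsd_optimal(a, b), rmsd_optimal(b, a), tolerance = 1e-9)
  expect_error(rmsd_optimal(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(rmsd_optimal(a, a[1:10, ]), "sizes differ")
  # independent reference implementation on a noisy copy
  bn <- b + matrix(rnorm(45, sd = 0.5), 15, 3)
  expect_equal(rmsd_optimal(a, bn),
               bio3d::rmsd(as.vector(t(a)), as.vector(t(bn)), fit = TRUE),
               tolerance = 1e-3)   # the reference rounds to 1e-3
})

test_that("RMSD after fitting a single displaced point beats the naive bound", {
  set.seed(13)
  n <- 12
  a <- matrix(rnorm(3 * n, sd = 6), n, 3)
  delta <- 2
  b <- a; b[4, 1] <- b[4, 1] + delta
  r <- rmsd_optimal(a, b)
  expect_lte(r, delta / sqrt(n) + 1e-9)
  # brute-force oracle: random rotations + optimal translation can do no better
  best <- Inf
  centred_a <- sweep(a, 2, colMeans(a))
  centred_b <- sweep(b, 2, colMeans(b))
  for (k in 1:500) {
    R <- nucleocg:::.random_rotation()
    best <- min(best, sqrt(mean(rowSums((centred_b %*% t(R) - centred_a)^2))))
  }
  expect_lte(r, best + 1e-9)
})

test_that("frozen straight duplex reproduces construction distances with zero spread", {
  d <- build_dna(74)
  m <- tiny_model(d$beads, d$bonds, d$angles)
  dd <- distance_distributions(one_frame_traj(m), m)
  # intra- and inter-unit strand distances at the unit-cell minimum differ
  # by < 1e-3 A; spreads are zero at that resolution
  expect_equal(dd$sd, rep(0, 3), tolerance = 1e-3)
  expect_equal(dd$mean[dd$pair == "dd"], 6.8, tolerance = 1e-9)
  expect_equal(dd$mean[dd$pair == "cross_strand"], 18.06, tolerance = 0.01)
  expect_equal(dd$mean[dd$pair == "strand_pp"], 6.76, tolerance = 0.01)
})

test_that("superhelical wrapping preserves intra-unit geometry, curvature strains inter-unit spacings only mildly", {
  m <- make_synthetic_ncp(1)
  dd <- distance_distributions(one_frame_traj(m), m)
  # intra-unit pairs ride the rigid unit frame: exact
  expect_equal(dd$mean[dd$pair == "cross_strand"], 18.06, tolerance = 0.01)
  expect_lt(dd$sd[dd$pair == "cross_strand"], 1e-6)
  expect_equal(dd$mean[dd$pair == "dd"], 6.8, tolerance = 1e-9)
  # strand continuity across units: bending of the path perturbs the
  # construction distance by a fraction of an Angstrom at most
  expect_equal(dd$mean[dd$pair == "strand_pp"], 6.76, tolerance = 0.15 / 6.76)
  expect_lt(dd$sd[dd$pair == "strand_pp"], 0.5)
})

test_that("coaxial identically oriented NCPs are detected as stacked with zero dyad angle", {
  m <- two_stacked_ncps(separation = 60)
  tr <- one_frame_traj(m)
  st <- stacking_pairs(tr, m, cutoff = 70)
  expect_equal(nrow(st), 1)
  expect_equal(st$distance, 60, tolerance = 1e-6)
  expect_equal(st$dyad_angle, 0, tolerance = 1e-6)
  expect_equal(st$contact, "stacked")
  # symmetry: pair ordering does not change the angle
  expect_equal(st$ncp_a, 1)
  st2 <- stacking_pairs(tr, m, cutoff = 200)
  expect_equal(st2$dyad_angle[1], st$dyad_angle[1])
  m_bad <- m
  m_bad$groups$dyad_sites_2 <- NULL
  expect_error(stacking_pairs(tr, m_bad, cutoff = 70), "dyad")
})

test_that("bulk concentration of a uniform ion gas equals N/V", {
  set.seed(14)
  m <- make_synthetic_ncp(1)
  m <- place_counterions(m, "K", box_edge = 400, seed = 15)
  n_ion <- length(m$groups$ions)
  xyz <- as.matrix(m$beads[, c("x", "y", "z")])
  # overwrite ion positions with a uniform gas to make the expected value exact
  frames <- replicate(25, {
    f <- xyz
    f[m$groups$ions, ] <- matrix(runif(3 * n_ion, 0, 400), n_ion, 3)
    f
  }, simplify = FALSE)
  tr <- cg_trajectory(frames, seq_len(25), box_edge = 400)
  b <- bulk_concentration(tr, m, probe_radius = 60)
  expected_mM <- n_ion / (400^3 * 6.02214076e-7)
  expect_equal(b$concentration_mM, expected_mM, tolerance = 0.25)
  # region devoid of ions
  frames0 <- lapply(frames, function(f) {
    f[m$groups$ions, ] <- matrix(rep(c(1, 1, 1), n_ion), n_ion, 3, byrow = TRUE)
    f
  })
  # ions piled at the corner far from the probe point near the NCP-free centre
  tr0 <- cg_trajectory(frames0, seq_len(25), box_edge = 400)
  b0 <- bulk_concentration(tr0, m, probe_radius = 30)
  expect_true(b0$concentration_mM == 0 || b0$concentration_mM < expected_mM)
})

test_that("tidiers expose results as tibbles and autoplot returns ggplot objects", {
  m <- make_synthetic_ncp(1)
  tr <- one_frame_traj(m)
  r <- rdf(tr, list(m$groups$core), m$groups$dna_p, bin_width = 0.2)
  expect_s3_class(tidy(r), "tbl_df")
  expect_s3_class(autoplot(r), "ggplot")
  p <- pr_rg_dmax(tr, seq_len(50))
  expect_s3_class(glance(p), "tbl_df")
  expect_s3_class(autoplot(p), "ggplot")
})
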