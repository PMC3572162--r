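# Construction of the coarse-grained NCP: charge rules, elastic network,
# tails, helical DNA and superhelical wrapping.

test_that("residue charges follow the basic/acidic rules", {
  expect_equal(assign_residue_charge(c("LYS", "ARG")), c(1, 1))
  expect_equal(assign_residue_charge(c("ASP", "GLU")), c(-1, -1))
  expect_equal(assign_residue_charge(c("GLY", "SER", "TRP", "HIS")), rep(0, 4))
  expect_error(assign_residue_charge("XYZ"), "unknown residue")
})

test_that("four collinear residues force the complete elastic-network graph", {
  gr <- data.frame(residue_name = "GLY", x = c(0, 1, 2, 3), y = 0, z = 0)
  core <- build_core(gr)
  expect_equal(nrow(core$bonds), 6)   # complete graph on 4 vertices
  expect_error(build_core(gr[1:3, ]), "at least 4")
})

test_that("elastic network equals the brute-force 3-nearest-neighbour union", {
  set.seed(99)
  xyz <- matrix(runif(60, 0, 30), 20, 3)
  gr <- data.frame(residue_name = "GLY", x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3])
  core <- build_core(gr)
  d <- as.matrix(dist(xyz)); diag(d) <- Inf
  oracle <- matrix(0L, 0, 2)
  for (i in 1:20) {
    nb <- order(d[i, ])[1:3]
    oracle <- rbind(oracle, cbind(pmin(i, nb), pmax(i, nb)))
  }
  oracle <- unique(oracle)
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), ]
  got <- as.matrix(core$bonds[, c("i", "j")])
  got <- got[order(got[, 1], got[, 2]), ]
  dimnames(got) <- NULL
  expect_equal(got, oracle)
  # bond lengths are the input distances
  expect_equal(core$bonds$r_0,
               sqrt(rowSums((xyz[core$bonds$i, ] - xyz[core$bonds$j, ])^2)))
})

test_that("synthetic octamer core reproduces the 116/64/530 charge mosaic", {
  core <- build_core(nucleocg:::.synthetic_core_residues(1))
  expect_equal(sum(core$beads$charge == 1), 116)
  expect_equal(sum(core$beads$charge == -1), 64)
  expect_equal(sum(core$beads$charge == 0), 530)
  expect_equal(sum(core$beads$charge), 52)
  expect_true(all(core$beads$hard_radius == 0))
})

test_that("ten tails carry 270 beads, +94e and simple chain topology", {
  m <- make_synthetic_ncp(1)
  tails <- m$beads[m$beads$role == "tail", ]
  expect_equal(nrow(tails), 270)
  expect_equal(sum(tails$charge), 94)
  expect_equal(sort(as.integer(table(tails$sub_label))),
               sort(2L * c(20L, 35L, 43L, 24L, 13L)))
  # charged tail beads carry the larger hard radius
  expect_true(all(tails$hard_radius[tails$charge != 0] == 0.6))
  expect_true(all(tails$hard_radius[tails$charge == 0] == 0))
  # chain topology: interior beads have 2 chain bonds, termini 1
  tb <- m$bonds[m$bonds$type == "tail", ]
  deg <- table(c(tb$i, tb$j))
  expect_true(all(deg <= 2))
  expect_equal(sum(deg == 1), 20)   # 2 ends x 10 tails
})

test_that("tail length mismatches are rejected", {
  anchors <- matrix(rnorm(30), 10, 3)
  td <- nucleocg:::TAIL_DEF
  seqs <- lapply(seq_len(nrow(td)), function(t)
    synthetic_tail_sequence(td$length[t], td$net_charge[t]))
  names(seqs) <- td$type
  all10 <- c(seqs, seqs)
  names(all10) <- paste0(names(all10), c(rep(".1", 5), rep(".2", 5)))
  all10[[1]] <- all10[[1]][-1]   # shorten one tail
  expect_error(build_tails(all10, anchors), "expected")
})

test_that("straight DNA has the stated composition and helical geometry", {
  d <- build_dna(74)
  expect_equal(nrow(d$beads), 370)
  expect_equal(sum(d$beads$role == "P"), 296)
  expect_equal(sum(d$beads$charge), -296)
  expect_equal(unique(d$beads$mass[d$beads$role == "D"]), 4)
  expect_equal(unique(d$beads$mass[d$beads$role == "P"]), 1)
  xyz <- as.matrix(d$beads[, c("x", "y", "z")])
  dix <- which(d$beads$site == "D")
  dd <- sqrt(rowSums(diff(xyz[dix, ])^2))
  expect_equal(dd, rep(6.8, 73), tolerance = 1e-12)
  p1 <- xyz[d$beads$site == "P1", ]
  ang <- diff(atan2(p1[, 2], p1[, 1])) %% (2 * pi)
  expect_equal(ang * 180 / pi, rep(72, 73), tolerance = 1e-9)
  # cross-strand same-base-pair separation close to the ideal 18.2 A
  p3 <- xyz[d$beads$site == "P3", ]
  cross <- sqrt(rowSums((p1 - p3)^2))
  expect_true(all(abs(cross - 18.2) < 0.2))
  expect_error(build_dna(1), "at least 2")
})

test_that("DNA-core links use the nearest core bead (brute-force oracle)", {
  set.seed(5)
  core_xyz <- matrix(runif(90, -20, 20), 30, 3)
  path_pos <- matrix(runif(150, -25, 25), 50, 3)
  d <- build_dna(50)
  w <- wrap_dna_on_core(d, core_xyz,
                        path = nucleocg:::path_from_positions(path_pos),
                        link_cutoff = 100)
  expect_equal(nrow(w$link_bonds), 50)
  for (u in seq_len(50)) {
    oracle <- which.min(sqrt(rowSums(sweep(core_xyz, 2, path_pos[u, ])^2)))
    expect_equal(w$link_bonds$i[u], oracle)
  }
  expect_error(wrap_dna_on_core(d, core_xyz + 1000,
                                path = nucleocg:::path_from_positions(path_pos)),
               "geometry mismatch")
})

test_that("wrapped DNA winds 1.75 turns about the superhelical axis", {
  m <- make_synthetic_ncp(1)
  Dxyz <- as.matrix(m$beads[m$groups$dna_d, c("x", "y", "z")])
  th <- atan2(Dxyz[, 2], Dxyz[, 1])
  dth <- diff(th)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  expect_equal(abs(sum(dth)) / (2 * pi), 1.75, tolerance = 1e-6)
  # D-D chord spacing preserved on the superhelix
  dd <- sqrt(rowSums(diff(Dxyz)^2))
  expect_equal(dd, rep(6.8, 73), tolerance = 1e-9)
})

test_that("assembled NCP passes all inventory invariants for several seeds", {
  for (seed in c(1, 7, 23)) {
    m <- assemble_ncp("synthetic", seed = seed)
    expect_equal(nrow(m$beads), 1350)
    expect_equal(sum(m$beads$charge), -150)
    cs <- ncp_charge_summary(m)
    expect_equal(cs$charge[match(c("core", "tails", "dna"), cs$component)],
                 c(52, 94, -296))
    expect_equal(nrow(m$bonds[m$bonds$type == "dna_link", ]), 74)
    # elastic-network bond lengths inside the sanity envelope
    cn <- m$bonds[m$bonds$type == "core_net", ]
    expect_true(all(cn$r_0 > 2 & cn$r_0 < 15))
    expect_length(m$groups$dyad_sites, 2)
    expect_length(m$groups$sdf_frame_sites, 3)
  }
})

test_that("same seed gives a bit-identical synthetic model", {
  m1 <- make_synthetic_ncp(seed = 11)
  m2 <- make_synthetic_ncp(seed = 11)
  expect_identical(m1$beads, m2$beads)
  expect_identical(m1$bonds, m2$bonds)
  m3 <- make_synthetic_ncp(seed = 12)
  expect_false(identical(m1$beads$charge, m3$beads$charge))
})

test_that("PDB-derived and synthetic builds agree in inventory and term counts", {
  ref <- make_synthetic_ncp(seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ncp_pdb(ref, f)
  m <- assemble_ncp("pdb", pdb_path = f)
  expect_equal(nrow(m$beads), nrow(ref$beads))
  expect_equal(ncp_charge_summary(m), ncp_charge_summary(ref))
  tm <- table(m$bonds$type); tr <- table(ref$bonds$type)
  expect_equal(names(tm), names(tr))
  # the PDB stores coordinates to 1e-3 A; that rounding can flip a handful
  # of near-degenerate 3rd-neighbour choices in the elastic network
  expect_lte(abs(tm[["core_net"]] - tr[["core_net"]]), 3)
  other <- setdiff(names(tm), "core_net")
  expect_equal(as.integer(tm[other]), as.integer(tr[other]))
  expect_equal(table(m$angles$type), table(ref$angles$type))
  expect_equal(sum(m$beads$charge), -150)
})

test_that("relaxing the straight duplex leaves its local geometry at construction", {
  d <- build_dna(74)
  m <- tiny_model(d$beads, d$bonds, d$angles)
  xyz <- as.matrix(d$beads[, c("x", "y", "z")])
  # construction is the screw-symmetric minimum of the bonded terms; the
  # finite chain additionally relaxes a soft long-wavelength end mode, so
  # the global RMSD stays sub-Angstrom while every bonded distance is
  # preserved to hundredths of an Angstrom
  p <- ff_params(electrostatics = "none", sigma = 1e-6)
  r <- minimize_model(m, params = p, maxit = 5000)
  expect_lt(rmsd_optimal(xyz, r$positions), 0.5)
  bo <- d$bonds
  len0 <- sqrt(rowSums((xyz[bo$i, ] - xyz[bo$j, ])^2))
  len1 <- sqrt(rowSums((r$positions[bo$i, ] - r$positions[bo$j, ])^2))
  expect_lt(max(abs(len1 - len0)), 0.05)
})

test_that("replication offsets indices and preserves per-copy inventory", {
  one <- make_synthetic_ncp(1)
  m <- replicate_ncp_model(one, 3, box_edge = 500, seed = 2)
  expect_equal(nrow(m$beads), 3 * 1350)
  expect_equal(sum(m$beads$charge), 3 * -150)
  expect_equal(length(m$groups$core_2), 710)
  expect_silent(validate_ncp_model(m))
})
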