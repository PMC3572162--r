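# Fixtures are generated programmatically: small random models for I/O
# round trips, ad-hoc bead systems for force/integrator checks, and a
# synthetic nucleosome crystal structure written as a PDB file.

empty_bonds <- function() {
  tibble::tibble(i = integer(), j = integer(), k_b = numeric(),
                 r_0 = numeric(), type = character())
}
empty_angles <- function() {
  tibble::tibble(i = integer(), j = integer(), k = integer(),
                 k_a = numeric(), phi_0 = numeric(), type = character())
}

# bare-bones model from a bead table (+ optional bonded terms)
tiny_model <- function(beads, bonds = empty_bonds(), angles = empty_angles(),
                       groups = list()) {
  beads$index <- seq_len(nrow(beads))
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 groups = groups, n_ncp = 1L,
                 meta = list(version = "1.0", source = "synthetic", seed = 0L)),
            class = "ncp_model")
}

bead_row <- function(n, xyz, charge = 0, hard_radius = 0, mass = 1,
                     role = "ion", sub_label = "K") {
  tibble::tibble(index = seq_len(n), role = role, sub_label = sub_label,
                 site = as.character(seq_len(n)), unit = NA_integer_,
                 charge = charge, hard_radius = hard_radius, mass = mass,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

random_small_model <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  xyz <- matrix(runif(3 * n, -50, 50), n, 3)
  beads <- tibble::tibble(
    index = seq_len(n),
    role = sample(c("core", "tail", "D", "P", "ion"), n, TRUE),
    sub_label = sample(c("H2A", "DNA", "K"), n, TRUE),
    site = as.character(seq_len(n)),
    unit = sample(c(NA_integer_, 1L, 2L), n, TRUE),
    charge = as.numeric(sample(-1:1, n, TRUE)),
    hard_radius = round(runif(n, 0, 2), 3),
    mass = as.numeric(sample(c(1, 4), n, TRUE)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  nb <- sample(0:3, 1)
  bonds <- if (nb > 0) {
    pr <- t(replicate(nb, sort(sample(n, 2))))
    tibble::tibble(i = as.integer(pr[, 1]), j = as.integer(pr[, 2]),
                   k_b = round(runif(nb, 1, 10), 4),
                   r_0 = round(runif(nb, 1, 5), 4),
                   type = sample(c("core_net", "tail"), nb, TRUE))
  } else empty_bonds()
  na_ <- if (n >= 3) sample(0:2, 1) else 0
  angles <- if (na_ > 0) {
    tr <- t(replicate(na_, sample(n, 3)))
    tibble::tibble(i = as.integer(tr[, 1]), j = as.integer(tr[, 2]),
                   k = as.integer(tr[, 3]),
                   k_a = round(runif(na_, 1, 100), 4),
                   phi_0 = round(runif(na_, 0.5, pi), 4),
                   type = "dna_strand")
  } else empty_angles()
  groups <- list(a = sort(sample(n, min(2, n))),
                 b = sort(sample(n, min(3, n))))
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 groups = groups, n_ncp = 1L,
                 meta = list(version = "1.0", source = "synthetic",
                             seed = as.integer(seed))),
            class = "ncp_model")
}

expect_model_equal <- function(a, b, tol = 1e-6) {
  expect_equal(nrow(a$beads), nrow(b$beads))
  for (cl in c("index", "role", "sub_label", "site", "charge", "hard_radius",
               "mass")) {
    expect_equal(a$beads[[cl]], b$beads[[cl]], tolerance = tol)
  }
  expect_identical(is.na(a$beads$unit), is.na(b$beads$unit))
  expect_equal(a$beads$unit[!is.na(a$beads$unit)],
               b$beads$unit[!is.na(b$beads$unit)])
  for (cl in c("x", "y", "z")) {
    expect_equal(a$beads[[cl]], b$beads[[cl]], tolerance = tol)
  }
  expect_equal(as.data.frame(a$bonds), as.data.frame(b$bonds), tolerance = tol)
  expect_equal(as.data.frame(a$angles), as.data.frame(b$angles), tolerance = tol)
  expect_equal(a$groups, b$groups)
  expect_equal(a$n_ncp, b$n_ncp)
}

# synthetic nucleosome "crystal structure": one CA pseudo-atom per protein
# residue (positions of a built synthetic model) and single-atom nucleotides
# whose two-base-pair means reproduce the DNA central-bead path
write_ncp_pdb <- function(model, path) {
  b <- model$beads
  con <- file(path, "w"); on.exit(close(con))
  serial <- 0
  emit <- function(name, resname, chain, resno, p) {
    serial <<- serial + 1
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       serial, name, resname, chain, resno,
                       p[1], p[2], p[3]), con)
  }
  res_of_charge <- function(q) c("GLU", "GLY", "LYS")[q + 2]
  chain_types <- c(A = "H3", B = "H4", C = "H2A", D = "H2B",
                   E = "H3", F = "H4", G = "H2A", H = "H2B")
  glob_per <- c(H3 = 100, H4 = 78, H2A = 89, H2B = 88)
  core_rows <- which(b$role == "core")
  ptr <- 1
  for (ch in names(chain_types)) {
    ty <- chain_types[[ch]]
    copy <- if (ch %in% c("A", "B", "C", "D")) 1 else 2
    resno <- 0
    n_tail <- function(i) {       # one pseudo-atom per tail residue
      resno <<- resno + 1
      emit("CA", res_of_charge(b$charge[i]), ch, resno,
           c(b$x[i], b$y[i], b$z[i]))
    }
    tix <- model$groups[[paste0("tail_", ty, ".", copy)]]
    for (i in rev(tix)) n_tail(i)                # N-tail: distal residue first
    for (k in seq_len(glob_per[[ty]])) {
      i <- core_rows[ptr]; ptr <- ptr + 1
      resno <- resno + 1
      emit("CA", b$sub_label[i], ch, resno, c(b$x[i], b$y[i], b$z[i]))
    }
    if (ty == "H2A") {
      cix <- model$groups[[paste0("tail_H2A-C.", copy)]]
      for (i in cix) n_tail(i)                   # C-tail: anchor residue first
    }
  }
  d_rows <- model$groups$dna_d
  nu <- length(d_rows)
  for (u in seq_len(nu)) {
    D <- c(b$x[d_rows[u]], b$y[d_rows[u]], b$z[d_rows[u]])
    emit("P", "DA", "I", 2 * u - 1, D + c(3, 0, 0))
    emit("P", "DT", "I", 2 * u, D + c(-3, 0, 0))
  }
  for (u in seq_len(nu)) {
    D <- c(b$x[d_rows[u]], b$y[d_rows[u]], b$z[d_rows[u]])
    emit("P", "DT", "J", 2 * nu - (2 * u - 1) + 1, D + c(0, 3, 0))
    emit("P", "DA", "J", 2 * nu - 2 * u + 1, D + c(0, -3, 0))
  }
  writeLines("END", con)
  invisible(path)
}

# two identically oriented NCP copies along +z (controlled stacking geometry)
two_stacked_ncps <- function(separation = 60, seed = 1) {
  one <- make_synthetic_ncp(seed)
  m <- replicate_ncp_model(one, 2, box_edge = 400, seed = seed)
  nb <- nrow(one$beads)
  xyz1 <- as.matrix(one$beads[, c("x", "y", "z")])
  xyz1 <- sweep(xyz1, 2, colMeans(xyz1))
  m$beads[seq_len(nb), c("x", "y", "z")] <- as.data.frame(xyz1)
  m$beads[nb + seq_len(nb), c("x", "y", "z")] <-
    as.data.frame(sweep(xyz1, 2, c(0, 0, separation), `+`))
  m
}

one_frame_traj <- function(model, box_edge = 400) {
  cg_trajectory(list(as.matrix(model$beads[, c("x", "y", "z")])),
                steps = 0L, box_edge = box_edge)
}
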