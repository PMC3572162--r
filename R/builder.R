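# Construction of the coarse-grained nucleosome core particle: octamer core
# with elastic network, ten charged tails, five-bead/two-bp helical DNA
# wrapped on a superhelix, and DNA-core link bonds.

#' Charge of an amino-acid residue in the coarse-grained model
#'
#' Lysine and arginine carry +1e, aspartate and glutamate -1e, all other
#' standard residues are neutral.
#'
#' @param residue_name character vector of 3-letter amino-acid codes.
#' @return integer charges in units of e.
#' @examples
#' assign_residue_charge(c("LYS", "GLU", "GLY"))
#' @export
assign_residue_charge <- function(residue_name) {
  nm <- toupper(residue_name)
  q <- .AA_CHARGE[nm]
  if (anyNA(q)) {
    stop("unknown residue code(s): ",
         paste(unique(nm[is.na(q)]), collapse = ", "), call. = FALSE)
  }
  unname(q)
}

.bead_tibble <- function(role, sub_label, site, unit, charge, hard_radius,
                         mass, xyz) {
  tibble::tibble(
    role = role, sub_label = sub_label, site = site, unit = unit,
    charge = charge, hard_radius = hard_radius, mass = mass,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# union of 3-nearest-neighbour bonds, deduplicated; ties broken by lower index
.knn_bonds <- function(xyz, k = 3) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  diag(d2) <- Inf
  pairs <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))   # secondary key: lower index wins ties
    nb <- ord[seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# connectivity of an undirected bead graph by breadth-first search
.is_connected <- function(n, pairs) {
  if (n == 1) return(TRUE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

.component_labels <- function(n, pairs) {
  lab <- integer(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0) next
    comp <- comp + 1L; lab[s] <- comp; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (lab[w] == 0) { lab[w] <- comp; queue <- c(queue, w) }
    }
  }
  lab
}

#' Build the octamer core elastic network
#'
#' Each core bead is bonded to its three nearest neighbours (bond set
#' deduplicated, so a bead may end up with more than three bonds).  Bond
#' equilibrium lengths are the input centre-of-mass distances; the force
#' constant is 5 kT/A^2.  Should the 3-nearest-neighbour union leave the graph
#' disconnected (possible for artificial inputs), minimal bridging bonds are
#' added so the core moves as one body.
#'
#' @param globular_residues data frame with columns `residue_name`, `x`, `y`,
#'   `z` (one row per globular residue, coordinates in Angstrom).
#' @return list with `beads` and `bonds` tibbles.
#' @export
build_core <- function(globular_residues) {
  gr <- globular_residues
  stopifnot(all(c("residue_name", "x", "y", "z") %in% names(gr)))
  if (nrow(gr) < 4) stop("need at least 4 residues to build a core", call. = FALSE)
  xyz <- as.matrix(gr[, c("x", "y", "z")])
  pairs <- .knn_bonds(xyz, 3)
  while (!.is_connected(nrow(xyz), pairs)) {
    lab <- .component_labels(nrow(xyz), pairs)
    a <- which(lab == 1); b <- which(lab != 1)
    d <- cg_pair_distances_cpp(xyz[a, , drop = FALSE], xyz[b, , drop = FALSE], 0)
    m <- arrayInd(which.min(d), c(length(b), length(a)))  # filled by b fastest
    i <- a[m[2]]; j <- b[m[1]]
    pairs <- rbind(pairs, c(min(i, j), max(i, j)))
  }
  r0 <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                        xyz[pairs[, 2], , drop = FALSE])^2))
  beads <- .bead_tibble(
    role = "core", sub_label = gr$residue_name, site = as.character(seq_len(nrow(gr))),
    unit = NA_integer_, charge = assign_residue_charge(gr$residue_name),
    hard_radius = 0, mass = 1, xyz = xyz)
  bonds <- tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                          k_b = CORE_BOND_K, r_0 = r0, type = "core_net")
  list(beads = beads, bonds = bonds)
}

#' Build the ten histone tails
#'
#' Tails are linear chains of one bead per residue, bond length 3.25 A,
#' force constant 5 kT/A^2.  Charged tail beads get hard radius 0.6 A,
#' neutral ones 0.  The first bead of each chain sits at the anchor position;
#' remaining beads are laid outward along the anchor direction (they
#' equilibrate freely in dynamics).
#'
#' @param tail_sequences named list of ten character vectors of 3-letter
#'   residue codes; names must start with the tail type
#'   (H2A, H2B, H3, H4, H2A-C).
#' @param anchor_positions 10 x 3 matrix of anchor coordinates, Angstrom.
#' @param directions optional 10 x 3 matrix of outward unit vectors; default
#'   radially outward from the vertical axis through the origin.
#' @return list with `beads`, `bonds` tibbles and `tail_index` (list of bead
#'   row ranges per tail).
#' @export
build_tails <- function(tail_sequences, anchor_positions, directions = NULL) {
  stopifnot(length(tail_sequences) == 10, nrow(anchor_positions) == 10)
  types <- sub("^(H2A-C|H2A|H2B|H3|H4).*$", "\\1", names(tail_sequences))
  if (!all(types %in% TAIL_DEF$type)) {
    stop("tail names must identify the type (H2A, H2B, H3, H4, H2A-C)",
         call. = FALSE)
  }
  exp_len <- TAIL_DEF$length[match(types, TAIL_DEF$type)]
  got_len <- lengths(tail_sequences)
  if (!all(got_len == exp_len)) {
    bad <- which(got_len != exp_len)[1]
    stop(sprintf("tail %s has %d residues, expected %d for type %s",
                 names(tail_sequences)[bad], got_len[bad], exp_len[bad],
                 types[bad]), call. = FALSE)
  }
  if (is.null(directions)) {
    directions <- anchor_positions
    directions[, 3] <- 0
    nrm <- sqrt(rowSums(directions^2))
    directions <- directions / ifelse(nrm > 0, nrm, 1)
  }
  beads <- NULL; bonds <- NULL; tail_index <- list()
  offset <- 0L
  for (t in seq_len(10)) {
    seqs <- toupper(tail_sequences[[t]])
    L <- length(seqs)
    q <- assign_residue_charge(seqs)
    xyz <- matrix(rep(anchor_positions[t, ], each = L), L, 3) +
      outer((seq_len(L) - 1) * TAIL_BOND_R0, directions[t, ])
    beads <- rbind(beads, .bead_tibble(
      role = "tail", sub_label = types[t], site = as.character(seq_len(L)),
      unit = NA_integer_, charge = q,
      hard_radius = ifelse(q != 0, TAIL_CHARGED_RADIUS, 0), mass = 1, xyz = xyz))
    if (L > 1) {
      bonds <- rbind(bonds, tibble::tibble(
        i = offset + seq_len(L - 1), j = offset + seq_len(L - 1) + 1L,
        k_b = TAIL_BOND_K, r_0 = TAIL_BOND_R0, type = "tail"))
    }
    tail_index[[names(tail_sequences)[t]]] <- offset + seq_len(L)
    offset <- offset + L
  }
  list(beads = beads, bonds = bonds, tail_index = tail_index)
}

#' Synthetic tail sequence with prescribed length and net charge
#'
#' Charged residues (alternating LYS/ARG) are spread evenly along a neutral
#' (GLY) backbone.
#'
#' @param length number of residues.
#' @param net_charge number of +1e residues.
#' @return character vector of 3-letter codes.
#' @export
synthetic_tail_sequence <- function(length, net_charge) {
  stopifnot(net_charge >= 0, net_charge <= length)
  s <- rep("GLY", length)
  if (net_charge > 0) {
    at <- unique(round(seq(1, length, length.out = net_charge)))
    # rounding can merge positions; pad deterministically
    while (length(at) < net_charge) at <- sort(union(at, setdiff(seq_len(length), at)[1]))
    s[at] <- rep(c("LYS", "ARG"), length.out = net_charge)
  }
  s
}

#' Build a straight coarse-grained DNA duplex
#'
#' One unit per two base pairs: a central bead D (charge 0, hard radius 4 A,
#' mass 4) and four phosphates (charge -1e, hard radius 1 A).  Consecutive
#' units advance 6.8 A along the axis with a 72 degree twist of the phosphate
#' frame.  Bond and angle terms maintain the duplex geometry.
#'
#' @param n_units number of two-base-pair units (>= 2).
#' @return list with `beads`, `bonds`, `angles` tibbles.  Beads are ordered
#'   D, P1, P2, P3, P4 per unit; P1/P2 belong to strand 1, P3/P4 to strand 2.
#' @export
build_dna <- function(n_units) {
  if (n_units < 2) stop("need at least 2 DNA units", call. = FALSE)
  unitP <- dna_unit_geometry()
  d_idx <- function(u) (u - 1L) * 5L + 1L
  p_idx <- function(u, k) (u - 1L) * 5L + 1L + k
  xyz <- matrix(0, n_units * 5, 3)
  for (u in seq_len(n_units)) {
    R <- rot_z((u - 1) * deg2rad(DNA_TWIST))
    z <- c(0, 0, (u - 1) * DNA_RISE)
    xyz[d_idx(u), ] <- z
    xyz[p_idx(u, 1:4), ] <- sweep(unitP %*% t(R), 2, z, `+`)
  }
  role <- rep(c("D", "P", "P", "P", "P"), n_units)
  site <- rep(c("D", "P1", "P2", "P3", "P4"), n_units)
  beads <- .bead_tibble(
    role = role, sub_label = "DNA", site = site,
    unit = rep(seq_len(n_units), each = 5),
    charge = ifelse(role == "P", DNA_P_CHARGE, 0),
    hard_radius = ifelse(role == "P", DNA_P_RADIUS, DNA_D_RADIUS),
    mass = ifelse(role == "D", DNA_D_MASS, 1), xyz = xyz)
  bt <- DNA_BOND_TABLE; at <- DNA_ANGLE_TABLE
  bonds <- list()
  for (u in seq_len(n_units)) {
    bonds[[length(bonds) + 1]] <- tibble::tibble(
      i = d_idx(u), j = p_idx(u, 1:4), k_b = bt$d_p[["k"]],
      r_0 = bt$d_p[["r0"]], type = "dna_dp")
    bonds[[length(bonds) + 1]] <- tibble::tibble(
      i = p_idx(u, c(1, 3)), j = p_idx(u, c(2, 4)), k_b = bt$strand_pp[["k"]],
      r_0 = bt$strand_pp[["r0"]], type = "dna_strand")
    if (u < n_units) {
      bonds[[length(bonds) + 1]] <- tibble::tibble(
        i = c(d_idx(u), p_idx(u, 2), p_idx(u, 4), p_idx(u, 1), p_idx(u, 2)),
        j = c(d_idx(u + 1), p_idx(u + 1, 1), p_idx(u + 1, 3),
              p_idx(u + 1, 3), p_idx(u + 1, 4)),
        k_b = c(bt$d_d[["k"]], bt$strand_pp[["k"]], bt$strand_pp[["k"]],
                bt$minor_pp[["k"]], bt$minor_pp[["k"]]),
        r_0 = c(bt$d_d[["r0"]], bt$strand_pp[["r0"]], bt$strand_pp[["r0"]],
                bt$minor_pp[["r0"]], bt$minor_pp[["r0"]]),
        type = c("dna_dd", "dna_strand", "dna_strand", "dna_minor", "dna_minor"))
    }
  }
  bonds <- dplyr::bind_rows(bonds)
  angles <- list()
  for (u in seq_len(n_units)) {
    angles[[length(angles) + 1]] <- tibble::tibble(
      i = p_idx(u, c(1, 2)), j = d_idx(u), k = p_idx(u, c(3, 4)),
      k_a = at$pdp[["k"]], phi_0 = deg2rad(at$pdp[["phi0"]]), type = "dna_pdp")
    if (u < n_units - 1) {
      angles[[length(angles) + 1]] <- tibble::tibble(
        i = d_idx(u), j = d_idx(u + 1), k = d_idx(u + 2),
        k_a = at$ddd[["k"]], phi_0 = deg2rad(at$ddd[["phi0"]]), type = "dna_ddd")
    }
    if (u < n_units) {
      # consecutive triples along each phosphate strand
      angles[[length(angles) + 1]] <- tibble::tibble(
        i = c(p_idx(u, 1), p_idx(u, 2), p_idx(u, 3), p_idx(u, 4)),
        j = c(p_idx(u, 2), p_idx(u + 1, 1), p_idx(u, 4), p_idx(u + 1, 3)),
        k = c(p_idx(u + 1, 1), p_idx(u + 1, 2), p_idx(u + 1, 3), p_idx(u + 1, 4)),
        k_a = at$strand[["k"]], phi_0 = deg2rad(at$strand[["phi0"]]),
        type = "dna_strand")
    }
  }
  angles <- dplyr::bind_rows(angles)
  list(beads = beads, bonds = bonds, angles = angles)
}

# local frames along an arbitrary D-bead path (parallel transport + twist)
path_from_positions <- function(pos) {
  n <- nrow(pos)
  tangents <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    tv <- pos[hi, ] - pos[lo, ]
    tangents[i, ] <- tv / sqrt(sum(tv^2))
  }
  ref <- c(0, 0, 1)
  if (abs(sum(ref * tangents[1, ])) > 0.9) ref <- c(1, 0, 0)
  nrm <- ref - sum(ref * tangents[1, ]) * tangents[1, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1) {
      a <- tangents[i - 1, ]; b <- tangents[i, ]
      v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
      s <- sqrt(sum(v^2)); c0 <- sum(a * b)
      if (s > 1e-12) {
        vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
        R <- diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
        nrm <- as.vector(R %*% nrm)
      }
      nrm <- nrm - sum(nrm * b) * b
      nrm <- nrm / sqrt(sum(nrm^2))
    }
    tw <- (i - 1) * deg2rad(DNA_TWIST)
    b3 <- tangents[i, ]
    b2 <- c(b3[2] * nrm[3] - b3[3] * nrm[2], b3[3] * nrm[1] - b3[1] * nrm[3],
            b3[1] * nrm[2] - b3[2] * nrm[1])
    base <- cbind(nrm, b2, b3)
    twist <- rbind(c(cos(tw), -sin(tw), 0), c(sin(tw), cos(tw), 0), c(0, 0, 1))
    frames[[i]] <- base %*% twist
  }
  list(positions = pos, frames = frames)
}

#' Wrap a DNA duplex on the octamer core
#'
#' Repositions the D beads onto the supplied path (a 1.75-turn left-handed
#' superhelix by default), carries the phosphate frame along it with the
#' 72 degree per-unit twist, and adds one harmonic link bond from every D bead
#' to its nearest core bead (force constant 5 kT/A^2, equilibrium length equal
#' to the distance at construction).  Equidistant nearest-core candidates are
#' resolved to the lower bead index.
#'
#' @param dna result of [build_dna()].
#' @param core_xyz matrix of core bead coordinates.
#' @param path optional list with `positions` (n_units x 3) and `frames`
#'   (list of 3x3 rotations); default [superhelix_path()].
#' @param link_cutoff maximal admissible D-to-core distance, Angstrom.
#' @return `dna` with updated coordinates plus `link_bonds` (core index `i`
#'   refers to rows of `core_xyz`; `j` to DNA bead rows).
#' @export
wrap_dna_on_core <- function(dna, core_xyz, path = NULL, link_cutoff = 30) {
  n_units <- max(dna$beads$unit)
  if (is.null(path)) path <- superhelix_path(n_units)
  stopifnot(nrow(path$positions) == n_units)
  unitP <- dna_unit_geometry()
  xyz <- as.matrix(dna$beads[, c("x", "y", "z")])
  for (u in seq_len(n_units)) {
    rows <- which(dna$beads$unit == u)
    d_row <- rows[dna$beads$site[rows] == "D"]
    p_rows <- rows[dna$beads$site[rows] != "D"]
    xyz[d_row, ] <- path$positions[u, ]
    xyz[p_rows, ] <- sweep(unitP %*% t(path$frames[[u]]), 2,
                           path$positions[u, ], `+`)
  }
  dna$beads$x <- xyz[, 1]; dna$beads$y <- xyz[, 2]; dna$beads$z <- xyz[, 3]
  d_rows <- which(dna$beads$site == "D")
  dmat <- matrix(cg_pair_distances_cpp(xyz[d_rows, , drop = FALSE],
                                       core_xyz, 0),
                 nrow = length(d_rows), byrow = TRUE)
  nearest <- apply(dmat, 1, which.min)     # which.min takes the first = lowest index
  dmin <- dmat[cbind(seq_along(d_rows), nearest)]
  if (any(dmin > link_cutoff)) {
    stop(sprintf("D bead of unit %d is %.1f A from the nearest core bead (cutoff %.1f): geometry mismatch",
                 which.max(dmin), max(dmin), link_cutoff), call. = FALSE)
  }
  dna$link_bonds <- tibble::tibble(
    i = as.integer(nearest), j = d_rows, k_b = CORE_LINK_K, r_0 = dmin,
    type = "dna_link")
  dna
}

# deterministic synthetic octamer core: low-discrepancy filling of a wedge
# cylinder, charge mosaic 116/64/530 with positives enriched near the surface
.synthetic_core_residues <- function(seed) {
  n <- NCP_INVENTORY$n_core
  # consume the Halton stream with a minimum-separation filter so that
  # elastic-network bonds stay in a physical range (residue centres of mass
  # are never closer than ~3 A)
  min_sep <- 3
  n_draw <- 6 * n
  u1 <- .halton(n_draw, 2); u2 <- .halton(n_draw, 3); u3 <- .halton(n_draw, 5)
  r_all <- SYNTH_CORE_RADIUS * sqrt(u1)
  th_all <- 2 * pi * u2
  h_all <- SYNTH_CORE_HEIGHT * (1 - SYNTH_WEDGE_FACTOR * (1 + cos(th_all)) / 2)
  cand <- cbind(r_all * cos(th_all), r_all * sin(th_all),
                (u3 - 0.5) * h_all)
  xyz <- matrix(NA_real_, n, 3)
  kept <- 0L
  for (k in seq_len(n_draw)) {
    if (kept > 0) {
      d2 <- (xyz[seq_len(kept), 1] - cand[k, 1])^2 +
        (xyz[seq_len(kept), 2] - cand[k, 2])^2 +
        (xyz[seq_len(kept), 3] - cand[k, 3])^2
      if (min(d2) < min_sep^2) next
    }
    kept <- kept + 1L
    xyz[kept, ] <- cand[k, ]
    if (kept == n) break
  }
  if (kept < n) stop("synthetic core packing failed", call. = FALSE)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed %% .Machine$integer.max)
  w <- (r / SYNTH_CORE_RADIUS)^2 + 0.2
  pos_idx <- sample(n, NCP_INVENTORY$n_core_positive, prob = w)
  rest <- setdiff(seq_len(n), pos_idx)
  neg_idx <- sample(rest, NCP_INVENTORY$n_core_negative)
  residue <- rep("GLY", n)
  residue[pos_idx] <- rep(c("LYS", "ARG"), length.out = length(pos_idx))
  residue[neg_idx] <- rep(c("GLU", "ASP"), length.out = length(neg_idx))
  data.frame(residue_name = residue, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# anchor sites of the ten tails on the synthetic core, cylindrical coords.
# H3, H2B and the H2A C-tail exit between the DNA gyres on the lateral
# surface; H4 and H2A exit near the flat faces.
.synthetic_tail_anchors <- function() {
  R <- SYNTH_CORE_RADIUS + 1
  H <- SYNTH_CORE_HEIGHT / 2
  spec <- rbind(
    data.frame(name = "H3.1",    th = 25,  z = 2,      r = R),
    data.frame(name = "H3.2",    th = 205, z = -2,     r = R),
    data.frame(name = "H2B.1",   th = 80,  z = 5,      r = R),
    data.frame(name = "H2B.2",   th = 260, z = -5,     r = R),
    data.frame(name = "H2A-C.1", th = 140, z = 3,      r = R),
    data.frame(name = "H2A-C.2", th = 320, z = -3,     r = R),
    data.frame(name = "H4.1",    th = 55,  z = H - 4,  r = R * 0.6),
    data.frame(name = "H4.2",    th = 235, z = -H + 4, r = R * 0.6),
    data.frame(name = "H2A.1",   th = 110, z = H - 6,  r = R * 0.7),
    data.frame(name = "H2A.2",   th = 290, z = -H + 6, r = R * 0.7))
  xyz <- cbind(spec$r * cos(deg2rad(spec$th)), spec$r * sin(deg2rad(spec$th)),
               spec$z)
  rownames(xyz) <- spec$name
  xyz
}

# three maximally separated core beads (greedy, deterministic): used as the
# body-fixed frame sites for spatial distribution functions
.pick_frame_sites <- function(xyz) {
  com <- colMeans(xyz)
  d0 <- sqrt(rowSums(sweep(xyz, 2, com)^2))
  s1 <- which.max(d0)
  d1 <- sqrt(rowSums(sweep(xyz, 2, xyz[s1, ])^2))
  s2 <- which.max(d1)
  d2 <- sqrt(rowSums(sweep(xyz, 2, xyz[s2, ])^2))
  s3 <- which.max(pmin(d1, d2))
  c(s1, s2, s3)
}

#' Assemble a complete coarse-grained NCP
#'
#' Builds the octamer core with its elastic network, the ten tails, the
#' 74-unit DNA wrapped on the superhelix, the DNA-core link bonds and the
#' tail anchor bonds, then validates the model invariants (1350 beads, net
#' charge -150e, component charges +52/+94/-296e).
#'
#' @param source `"synthetic"` for the bundled generator, or `"pdb"` to build
#'   from a nucleosome crystal structure.
#' @param seed integer seed controlling the synthetic charge mosaic.
#' @param pdb_path path to a PDB file when `source = "pdb"`.
#' @param validate check model invariants after assembly (default TRUE).
#' @return an object of class `ncp_model`.
#' @examples
#' m <- assemble_ncp("synthetic", seed = 1)
#' ncp_charge_summary(m)
#' @export
assemble_ncp <- function(source = c("synthetic", "pdb"), seed = 1,
                         pdb_path = NULL, validate = TRUE) {
  source <- match.arg(source)
  if (source == "synthetic") {
    core_res <- .synthetic_core_residues(seed)
    anchors <- .synthetic_tail_anchors()
    tail_seqs <- list()
    for (t in seq_len(nrow(TAIL_DEF))) {
      s <- synthetic_tail_sequence(TAIL_DEF$length[t], TAIL_DEF$net_charge[t])
      tail_seqs[[paste0(TAIL_DEF$type[t], ".1")]] <- s
      tail_seqs[[paste0(TAIL_DEF$type[t], ".2")]] <- s
    }
    tail_seqs <- tail_seqs[rownames(anchors)]
    directions <- NULL
    path <- NULL
  } else {
    if (is.null(pdb_path)) stop("pdb_path required for source = 'pdb'", call. = FALSE)
    parts <- split_ncp_residues(read_pdb_residues(pdb_path))
    core_res <- parts$globular
    anchors <- parts$anchors
    tail_seqs <- parts$tail_sequences
    directions <- parts$directions
    path <- if (!is.null(parts$d_positions)) path_from_positions(parts$d_positions)
  }
  core <- build_core(core_res)
  core_xyz <- as.matrix(core$beads[, c("x", "y", "z")])
  tails <- build_tails(tail_seqs, anchors, directions)
  dna <- build_dna(NCP_INVENTORY$n_dna_units)
  dna <- wrap_dna_on_core(dna, core_xyz, path = path)

  n_core <- nrow(core$beads); n_tail <- nrow(tails$beads)
  beads <- dplyr::bind_rows(core$beads, tails$beads, dna$beads)
  beads$index <- seq_len(nrow(beads))
  beads <- beads[, c("index", setdiff(names(beads), "index"))]

  shift <- function(b, off_i, off_j = off_i) {
    b$i <- b$i + off_i; b$j <- b$j + off_j; b
  }
  tail_bonds <- shift(tails$bonds, n_core)
  dna_off <- n_core + n_tail
  dna_bonds <- shift(dna$bonds, dna_off)
  link_bonds <- dna$link_bonds
  link_bonds$j <- link_bonds$j + dna_off      # i already indexes core beads
  # anchor bond: first bead of each tail to its nearest core bead
  anchor_rows <- vapply(tails$tail_index, function(ix) ix[1], 0L) + n_core
  axyz <- as.matrix(beads[anchor_rows, c("x", "y", "z")])
  dmat <- matrix(cg_pair_distances_cpp(axyz, core_xyz, 0),
                 nrow = nrow(axyz), byrow = TRUE)
  near <- apply(dmat, 1, which.min)
  anchor_bonds <- tibble::tibble(
    i = as.integer(near), j = as.integer(anchor_rows), k_b = TAIL_BOND_K,
    r_0 = dmat[cbind(seq_along(near), near)], type = "tail_anchor")
  bonds <- dplyr::bind_rows(core$bonds, tail_bonds, dna_bonds, link_bonds,
                            anchor_bonds)
  angles <- dna$angles
  angles$i <- angles$i + dna_off; angles$j <- angles$j + dna_off
  angles$k <- angles$k + dna_off

  groups <- list(core = seq_len(n_core))
  for (nm in names(tails$tail_index)) {
    groups[[paste0("tail_", nm)]] <- tails$tail_index[[nm]] + n_core
  }
  groups$tails <- (n_core + 1L):(n_core + n_tail)
  dna_rows <- dna_off + seq_len(nrow(dna$beads))
  groups$dna <- dna_rows
  groups$dna_d <- dna_rows[dna$beads$site == "D"]
  groups$dna_p <- dna_rows[dna$beads$site %in% c("P1", "P2", "P3", "P4")]
  groups$dna_strand1 <- dna_rows[dna$beads$site %in% c("P1", "P2")]
  groups$dna_strand2 <- dna_rows[dna$beads$site %in% c("P3", "P4")]
  mid_unit <- ceiling(NCP_INVENTORY$n_dna_units / 2)
  com <- colMeans(core_xyz)
  centre_bead <- which.min(rowSums(sweep(core_xyz, 2, com)^2))
  groups$dyad_sites <- c(dna_rows[dna$beads$site == "D" &
                                    dna$beads$unit == mid_unit], centre_bead)
  groups$sdf_frame_sites <- .pick_frame_sites(core_xyz)

  model <- structure(list(
    beads = beads, bonds = bonds, angles = angles, groups = groups,
    n_ncp = 1L,
    meta = list(version = MODEL_CONSTANTS_VERSION, source = source,
                seed = seed)),
    class = "ncp_model")
  if (validate) validate_ncp_model(model)
  model
}

#' Deterministic synthetic NCP
#'
#' Convenience wrapper around [assemble_ncp()] with the bundled generator:
#' same seed, same model, bit for bit.
#'
#' @inheritParams assemble_ncp
#' @return an `ncp_model`.
#' @export
make_synthetic_ncp <- function(seed = 1) assemble_ncp("synthetic", seed = seed)

#' Validate NCP model invariants
#'
#' Checks the bead inventory (1350 beads per NCP), net charge (-150e per NCP),
#' component charges (+52e core, +94e tails, -296e DNA), tail chain topology,
#' one link bond per D bead, and core connectivity.  All failures are listed.
#'
#' @param model an `ncp_model`.
#' @return invisibly TRUE; stops with the list of failed checks otherwise.
#' @export
validate_ncp_model <- function(model) {
  fails <- character()
  chk <- function(cond, msg) if (!cond) fails <<- c(fails, msg)
  b <- model$beads
  n <- model$n_ncp
  model_beads <- b[b$role != "ion", ]
  inv <- NCP_INVENTORY
  chk(nrow(model_beads) == n * inv$n_total,
      sprintf("bead count %d != %d", nrow(model_beads), n * inv$n_total))
  chk(sum(model_beads$charge) == n * inv$total_charge,
      sprintf("net charge %+d != %+d", sum(model_beads$charge),
              n * inv$total_charge))
  chk(sum(b$charge[b$role == "core"]) == n * inv$core_charge, "core charge != +52e/NCP")
  chk(sum(b$charge[b$role == "tail"]) == n * inv$tail_charge, "tail charge != +94e/NCP")
  chk(sum(b$charge[b$role %in% c("D", "P")]) == n * inv$dna_charge,
      "DNA charge != -296e/NCP")
  chk(all(b$charge[b$role != "ion"] %in% -1:1), "model bead charge outside {-1,0,+1}")
  d_beads <- which(b$role == "D")
  link <- model$bonds[model$bonds$type == "dna_link", ]
  chk(all(sort(link$j) == d_beads), "not exactly one link bond per D bead")
  core_rows <- which(b$role == "core")
  cb <- model$bonds[model$bonds$type == "core_net", ]
  for (k in seq_len(n)) {
    rows <- core_rows[((k - 1) * inv$n_core + 1):(k * inv$n_core)]
    sub <- cb[cb$i %in% rows & cb$j %in% rows, ]
    chk(.is_connected(length(rows),
                      cbind(match(sub$i, rows), match(sub$j, rows))),
        sprintf("core elastic network of NCP %d is disconnected", k))
  }
  # every tail: simple chain anchored at exactly one end
  tb <- model$bonds[model$bonds$type == "tail", ]
  ab <- model$bonds[model$bonds$type == "tail_anchor", ]
  tgroups <- grep("^tail_", names(model$groups), value = TRUE)
  tgroups <- setdiff(tgroups, "tails")
  if (n > 1) {
    # replicated models also carry aggregated cross-copy groups; check the
    # per-copy chains only
    tgroups <- grep("_[0-9]+$", tgroups, value = TRUE)
  }
  for (g in tgroups) {
    ix <- model$groups[[g]]
    deg <- table(factor(c(tb$i[tb$i %in% ix], tb$j[tb$j %in% ix]), levels = ix))
    chk(sum(deg == 1) == 2 && all(deg <= 2), sprintf("%s is not a simple chain", g))
    chk(sum(ab$j %in% ix) == 1, sprintf("%s not anchored exactly once", g))
  }
  if (length(fails)) {
    stop("NCP model invariant violation:\n  - ",
         paste(fails, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-component charge summary of a model
#'
#' @param model an `ncp_model`.
#' @return tibble with one row per component and its total charge in e.
#' @export
ncp_charge_summary <- function(model) {
  b <- model$beads
  comp <- dplyr::case_when(
    b$role == "core" ~ "core", b$role == "tail" ~ "tails",
    b$role %in% c("D", "P") ~ "dna", TRUE ~ "ions")
  out <- dplyr::summarise(dplyr::group_by(tibble::tibble(component = comp,
                                                         charge = b$charge),
                                          component),
                          n_beads = dplyr::n(), charge = sum(charge),
                          .groups = "drop")
  out[order(match(out$component, c("core", "tails", "dna", "ions"))), ]
}

#' Replicate an NCP into a multi-particle system
#'
#' Places `n` rigid copies of a one-NCP model on a cubic sublattice of the
#' periodic cell with seeded random orientations, offsetting bead indices and
#' group definitions (`core_1` ... `core_n`, etc.).
#'
#' @param model a one-NCP `ncp_model`.
#' @param n number of copies.
#' @param box_edge cubic cell edge, Angstrom.
#' @param seed integer seed for the orientations.
#' @return an `ncp_model` with `n_ncp = n`.
#' @export
replicate_ncp_model <- function(model, n, box_edge, seed = 1) {
  stopifnot(model$n_ncp == 1, n >= 1)
  if (n == 1) return(model)
  k <- ceiling(n^(1 / 3))
  spacing <- box_edge / k
  if (spacing < 130) warning("NCP lattice spacing below ~130 A; initial copies may clash")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed %% .Machine$integer.max)
  centres <- as.matrix(expand.grid(seq_len(k), seq_len(k), seq_len(k)))[seq_len(n), , drop = FALSE]
  centres <- (centres - 0.5) * spacing
  xyz0 <- as.matrix(model$beads[, c("x", "y", "z")])
  xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
  beads <- NULL; bonds <- NULL; angles <- NULL
  groups <- list()
  nb <- nrow(model$beads)
  for (i in seq_len(n)) {
    R <- .random_rotation()
    b <- model$beads
    xyz <- sweep(xyz0 %*% t(R), 2, centres[i, ], `+`)
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    off <- (i - 1L) * nb
    b$index <- b$index + off
    beads <- rbind(beads, b)
    bo <- model$bonds; bo$i <- bo$i + off; bo$j <- bo$j + off
    bonds <- rbind(bonds, bo)
    an <- model$angles; an$i <- an$i + off; an$j <- an$j + off; an$k <- an$k + off
    angles <- rbind(angles, an)
    for (g in names(model$groups)) {
      groups[[paste0(g, "_", i)]] <- model$groups[[g]] + off
      groups[[g]] <- c(groups[[g]], model$groups[[g]] + off)
    }
  }
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 groups = groups, n_ncp = as.integer(n),
                 meta = c(model$meta, list(replicate_seed = seed,
                                           box_edge = box_edge))),
            class = "ncp_model")
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' @export
print.ncp_model <- function(x, ...) {
  cat(sprintf("<ncp_model> %d NCP(s), %d beads, net charge %+de\n",
              x$n_ncp, nrow(x$beads), sum(x$beads$charge)))
  cat(sprintf("  bonds: %d  angles: %d  groups: %s\n", nrow(x$bonds),
              nrow(x$angles), paste(head(names(x$groups), 6), collapse = ", ")))
  invisible(x)
}
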