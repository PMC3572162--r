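# File I/O: residue-level PDB reading, and the package's self-describing
# topology and XYZ-dialect trajectory formats (plain text, diffable).

TOPOLOGY_FORMAT_VERSION <- "1"

#' Read a PDB file into residue-level records
#'
#' Parses ATOM/HETATM records (via bio3d) and reduces each (chain, residue)
#' to a single record holding the unweighted mean of its atom coordinates
#' (the residue "centre of mass" of the coarse-grained construction; a
#' mass-weighted variant is available).
#'
#' @param path PDB file path.
#' @param mass_weighted weight atom coordinates by element mass (default
#'   FALSE: unweighted mean, reproducible without element assignment).
#' @return tibble with columns `chain_id`, `residue_index`, `residue_name`,
#'   `x`, `y`, `z` (Angstrom) and `n_atoms`, ordered by chain then residue.
#' @export
read_pdb_residues <- function(path, mass_weighted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("no atoms: file contains no ATOM/HETATM records",
                         call. = FALSE)
  for (ln in rec) {
    xyz_txt <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz_txt)))) {
      stop("malformed coordinate field at line ", ln, call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  w <- rep(1, nrow(at))
  if (mass_weighted) {
    masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                S = 32.06)
    el <- toupper(substr(trimws(at$elety), 1, 1))
    w <- masses[el]
    w[is.na(w)] <- 12.011
  }
  key <- paste(at$chain, at$resno, sep = "\r")
  ord <- !duplicated(key)
  agg <- function(v) {
    s <- rowsum(v * w, key, reorder = FALSE)
    n <- rowsum(w, key, reorder = FALSE)
    as.vector(s / n)
  }
  out <- tibble::tibble(
    chain_id = at$chain[ord],
    residue_index = at$resno[ord],
    residue_name = toupper(trimws(at$resid[ord])),
    x = agg(at$x), y = agg(at$y), z = agg(at$z),
    n_atoms = as.vector(rowsum(rep(1, nrow(at)), key, reorder = FALSE)))
  out[order(out$chain_id, out$residue_index), ]
}

#' Split nucleosome residues into tails, globular core and DNA
#'
#' Applies the positional tail/core split: the first 20/35/43/24 residues of
#' each H2A/H2B/H3/H4 chain form the N-terminal tail and the last 13 residues
#' of each H2A chain the C-terminal tail; the remainder is the globular core.
#' N-tail sequences are returned anchor-first (the residue adjacent to the
#' globular part leads the chain).  DNA chains, when present, are paired
#' antiparallel into two-base-pair units whose mean coordinates give the
#' central-bead path.
#'
#' @param records residue records from [read_pdb_residues()].
#' @param chain_map named vector mapping chain ids to histone types;
#'   default the 1KX5 convention (A/E = H3, B/F = H4, C/G = H2A, D/H = H2B).
#' @return list with `globular` (data frame), `tail_sequences`, `anchors`,
#'   and `d_positions` (NULL when no DNA chains are present).
#' @export
split_ncp_residues <- function(records, chain_map = HISTONE_CHAIN_MAP) {
  is_prot <- records$residue_name %in% names(.AA_CHARGE)
  prot <- records[is_prot, ]
  chains <- intersect(names(chain_map), unique(prot$chain_id))
  if (!length(chains)) stop("no histone chains matching the chain map", call. = FALSE)
  glob <- NULL; tail_seqs <- list(); anchors <- NULL
  copy_count <- stats::setNames(integer(length(TAIL_DEF$type)), TAIL_DEF$type)
  for (ch in chains) {
    type <- chain_map[[ch]]
    cr <- prot[prot$chain_id == ch, ]
    cr <- cr[order(cr$residue_index), ]
    L <- TAIL_DEF$length[TAIL_DEF$type == type]
    if (nrow(cr) <= L) stop("chain ", ch, " shorter than its tail definition", call. = FALSE)
    n_rows <- seq_len(L)
    copy_count[type] <- copy_count[type] + 1L
    nm <- paste0(type, ".", copy_count[type])
    tail_seqs[[nm]] <- rev(cr$residue_name[n_rows])   # anchor-first
    anchors <- rbind(anchors, as.matrix(cr[L, c("x", "y", "z")]))
    rownames(anchors)[nrow(anchors)] <- nm
    rest <- cr[-n_rows, ]
    if (type == "H2A") {
      Lc <- TAIL_SPLIT_RULE$h2a_c_length
      nc <- nrow(rest)
      c_rows <- (nc - Lc + 1):nc
      copy_count["H2A-C"] <- copy_count[["H2A-C"]] + 1L
      nmc <- paste0("H2A-C.", copy_count[["H2A-C"]])
      tail_seqs[[nmc]] <- rest$residue_name[c_rows]
      anchors <- rbind(anchors, as.matrix(rest[c_rows[1], c("x", "y", "z")]))
      rownames(anchors)[nrow(anchors)] <- nmc
      rest <- rest[-c_rows, ]
    }
    glob <- rbind(glob, rest)
  }
  # order tails to the canonical layout used by the synthetic generator
  nuc <- records[records$residue_name %in% .NUC_RESIDUES, ]
  d_positions <- NULL
  if (nrow(nuc) > 0) {
    dch <- unique(nuc$chain_id)
    if (length(dch) == 2) {
      s1 <- nuc[nuc$chain_id == dch[1], ]
      s1 <- s1[order(s1$residue_index), ]
      s2 <- nuc[nuc$chain_id == dch[2], ]
      s2 <- s2[order(s2$residue_index, decreasing = TRUE), ]
      nbp <- min(nrow(s1), nrow(s2))
      nu <- nbp %/% 2
      d_positions <- matrix(0, nu, 3)
      for (u in seq_len(nu)) {
        rows1 <- s1[(2 * u - 1):(2 * u), c("x", "y", "z")]
        rows2 <- s2[(2 * u - 1):(2 * u), c("x", "y", "z")]
        d_positions[u, ] <- colMeans(as.matrix(rbind(rows1, rows2)))
      }
    }
  }
  core_com <- colMeans(as.matrix(glob[, c("x", "y", "z")]))
  dirs <- sweep(anchors, 2, core_com)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(globular = data.frame(residue_name = glob$residue_name,
                             x = glob$x, y = glob$y, z = glob$z,
                             stringsAsFactors = FALSE),
       tail_sequences = tail_seqs, anchors = anchors, directions = dirs,
       d_positions = d_positions)
}

#' Write / read the topology text format
#'
#' Self-describing plain-text format: a version header, bead table, bond
#' table, angle table and group table.  The round trip is lossless (positions
#' kept to 10 significant figures).
#'
#' @param model an `ncp_model`.
#' @param path file path.
#' @return `write_topology` the path invisibly; `read_topology` an `ncp_model`.
#' @export
write_topology <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# nucleocg topology v%s", TOPOLOGY_FORMAT_VERSION), con)
  writeLines(sprintf("nncp %d", model$n_ncp), con)
  meta <- model$meta
  writeLines(sprintf("meta %s %s %s", meta$version %||% "NA",
                     meta$source %||% "NA", meta$seed %||% "NA"), con)
  b <- model$beads
  writeLines(sprintf("beads %d", nrow(b)), con)
  writeLines(sprintf("%d %s %s %s %s %d %.10g %.10g %.10g %.10g %.10g",
                     b$index, b$role, b$sub_label, b$site,
                     ifelse(is.na(b$unit), ".", as.character(b$unit)),
                     b$charge, b$hard_radius, b$mass, b$x, b$y, b$z), con)
  bo <- model$bonds
  writeLines(sprintf("bonds %d", nrow(bo)), con)
  writeLines(sprintf("%d %d %.10g %.10g %s", bo$i, bo$j, bo$k_b, bo$r_0,
                     bo$type), con)
  an <- model$angles
  writeLines(sprintf("angles %d", nrow(an)), con)
  if (nrow(an)) {
    writeLines(sprintf("%d %d %d %.10g %.10g %s", an$i, an$j, an$k, an$k_a,
                       an$phi_0, an$type), con)
  }
  writeLines(sprintf("groups %d", length(model$groups)), con)
  for (g in names(model$groups)) {
    writeLines(paste(g, paste(model$groups[[g]], collapse = " ")), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# nucleocg topology v", lines[1])) {
    stop("not a nucleocg topology file", call. = FALSE)
  }
  ver <- sub("^# nucleocg topology v", "", lines[1])
  if (ver != TOPOLOGY_FORMAT_VERSION) {
    stop("topology format version mismatch: file v", ver, ", reader v",
         TOPOLOGY_FORMAT_VERSION, call. = FALSE)
  }
  pos <- 2
  take <- function() { l <- lines[pos]; pos <<- pos + 1; l }
  expect_count <- function(kw) {
    l <- take()
    if (is.na(l) || !startsWith(l, kw)) stop("truncated topology file: expected '",
                                             kw, "' section", call. = FALSE)
    as.integer(strsplit(l, " ")[[1]][2])
  }
  nncp <- expect_count("nncp")
  meta_l <- strsplit(take(), " ")[[1]]
  nb <- expect_count("beads")
  if (pos + nb - 1 > length(lines)) stop("truncated topology file (beads)", call. = FALSE)
  bl <- do.call(rbind, strsplit(lines[pos:(pos + nb - 1)], " ")); pos <- pos + nb
  beads <- tibble::tibble(
    index = as.integer(bl[, 1]), role = bl[, 2], sub_label = bl[, 3],
    site = bl[, 4],
    unit = suppressWarnings(as.integer(ifelse(bl[, 5] == ".", NA, bl[, 5]))),
    charge = as.numeric(bl[, 6]), hard_radius = as.numeric(bl[, 7]),
    mass = as.numeric(bl[, 8]), x = as.numeric(bl[, 9]),
    y = as.numeric(bl[, 10]), z = as.numeric(bl[, 11]))
  nbo <- expect_count("bonds")
  if (nbo > 0) {
    if (pos + nbo - 1 > length(lines)) stop("truncated topology file (bonds)", call. = FALSE)
    bol <- do.call(rbind, strsplit(lines[pos:(pos + nbo - 1)], " ")); pos <- pos + nbo
    bonds <- tibble::tibble(i = as.integer(bol[, 1]), j = as.integer(bol[, 2]),
                            k_b = as.numeric(bol[, 3]), r_0 = as.numeric(bol[, 4]),
                            type = bol[, 5])
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(), k_b = numeric(),
                            r_0 = numeric(), type = character())
  }
  nan <- expect_count("angles")
  if (nan > 0) {
    if (pos + nan - 1 > length(lines)) stop("truncated topology file (angles)", call. = FALSE)
    al <- do.call(rbind, strsplit(lines[pos:(pos + nan - 1)], " ")); pos <- pos + nan
    angles <- tibble::tibble(i = as.integer(al[, 1]), j = as.integer(al[, 2]),
                             k = as.integer(al[, 3]), k_a = as.numeric(al[, 4]),
                             phi_0 = as.numeric(al[, 5]), type = al[, 6])
  } else {
    angles <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                             k_a = numeric(), phi_0 = numeric(), type = character())
  }
  ng <- expect_count("groups")
  groups <- list()
  for (k in seq_len(ng)) {
    l <- take()
    if (is.na(l)) stop("truncated topology file (groups)", call. = FALSE)
    parts <- strsplit(l, " ")[[1]]
    groups[[parts[1]]] <- as.integer(parts[-1])
  }
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 groups = groups, n_ncp = nncp,
                 meta = list(version = meta_l[2], source = meta_l[3],
                             seed = suppressWarnings(as.integer(meta_l[4])))),
            class = "ncp_model")
}

#' Trajectory container
#'
#' A list of per-frame coordinate matrices with step indices and the periodic
#' box edge.
#'
#' @param frames list of n_beads x 3 matrices, Angstrom.
#' @param steps integer step index of each frame.
#' @param box_edge cubic cell edge, Angstrom.
#' @param potential,kinetic optional per-frame energies, kT.
#' @return object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, steps, box_edge, potential = NULL,
                          kinetic = NULL) {
  if (!length(frames)) stop("empty frame list", call. = FALSE)
  nb <- vapply(frames, nrow, 0L)
  if (length(unique(nb)) != 1) stop("inconsistent bead count across frames", call. = FALSE)
  stopifnot(length(steps) == length(frames), box_edge > 0)
  structure(list(frames = frames, steps = as.integer(steps),
                 box_edge = box_edge, potential = potential, kinetic = kinetic),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames x %d beads, box %.0f A, steps %d..%d\n",
              length(x$frames), nrow(x$frames[[1]]), x$box_edge,
              min(x$steps), max(x$steps)))
  invisible(x)
}

#' Write / read trajectories (XYZ dialect)
#'
#' Frames are stored as XYZ blocks whose comment line carries the step index
#' and box edge (`# step N box B`); bead order is preserved.
#'
#' @param traj a `cg_trajectory` (or list of frame matrices for `write`).
#' @param path file path.
#' @param labels optional per-bead labels (default bead roles or "X").
#' @return `write_trajectory` the path invisibly; `read_trajectory` a
#'   `cg_trajectory`.
#' @export
write_trajectory <- function(traj, path, labels = NULL) {
  if (!inherits(traj, "cg_trajectory")) {
    stop("write_trajectory expects a cg_trajectory", call. = FALSE)
  }
  n <- nrow(traj$frames[[1]])
  if (is.null(labels)) labels <- rep("X", n)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("# step %d box %.10g", traj$steps[f], traj$box_edge), con)
    m <- traj$frames[[f]]
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); steps <- integer(); box <- NA_real_
  pos <- 1
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[pos]))
    if (is.na(n)) stop("malformed trajectory at line ", pos, call. = FALSE)
    hdr <- lines[pos + 1]
    m <- regmatches(hdr, regexec("# step (\\d+) box ([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) != 3) stop("malformed frame header at line ", pos + 1, call. = FALSE)
    steps <- c(steps, as.integer(m[2])); box <- as.numeric(m[3])
    rows <- lines[(pos + 2):(pos + 1 + n)]
    sp <- do.call(rbind, strsplit(rows, " +"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(sp[, 2:4]), ncol = 3)
    pos <- pos + 2 + n
  }
  cg_trajectory(frames, steps, box)
}
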