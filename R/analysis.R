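# Observables: radial and spatial distribution functions, pair-distance
# spectra P(r) with Rg/Dmax, optimal-superposition RMSD, DNA distance
# statistics, stacking geometry and bulk ion concentration.

.frame_xyz <- function(traj, f) traj$frames[[f]]

# centers from a selection: an integer vector (each bead a centre) or a list
# of index sets (each set contributes its centre of mass)
.centers <- function(xyz, selection) {
  if (is.list(selection)) {
    t(vapply(selection, function(ix) colMeans(xyz[ix, , drop = FALSE]),
             numeric(3)))
  } else {
    xyz[selection, , drop = FALSE]
  }
}

#' Radial distribution function between two centre sets
#'
#' Centres are either individual beads (integer selection) or centres of mass
#' of index sets (list selection, e.g. the 710-bead globular core of each
#' NCP).  Distances use the periodic minimum image; normalization is by shell
#' volume against the mean density of B centres, so an ideal gas gives
#' g(r) = 1.
#'
#' @param traj a `cg_trajectory` (production frames).
#' @param centers_a,centers_b selections (integer vector or list of integer
#'   vectors).
#' @param bin_width bin width in nm.
#' @param r_max histogram range in nm; default half the box edge.
#' @return tibble of class `rdf_result`: `r` (nm, bin centres), `g`, `count`.
#' @export
rdf <- function(traj, centers_a, centers_b, bin_width = 0.1, r_max = NULL) {
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  box <- traj$box_edge
  if (is.null(r_max)) r_max <- box / 2 / 10   # nm
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  counts <- numeric(length(edges) - 1)
  n_a <- if (is.list(centers_a)) length(centers_a) else length(centers_a)
  n_b <- if (is.list(centers_b)) length(centers_b) else length(centers_b)
  same <- identical(centers_a, centers_b)
  n_fr <- length(traj$frames)
  for (f in seq_len(n_fr)) {
    xyz <- .frame_xyz(traj, f)
    A <- .centers(xyz, centers_a)
    B <- if (same) A else .centers(xyz, centers_b)
    d <- cg_pair_distances_cpp(A, B, box) / 10    # nm
    if (same) {
      m <- matrix(d, n_a, n_b, byrow = TRUE)
      d <- m[upper.tri(m)]
    }
    d <- d[d > 0 & d < max(edges)]
    counts <- counts + tabulate(findInterval(d, edges), length(edges) - 1)
  }
  pair_norm <- if (same) n_a * (n_a - 1) / 2 else n_a * n_b
  vol_nm3 <- (box / 10)^3
  shell <- 4 / 3 * pi * diff(edges^3)
  expected <- pair_norm / vol_nm3 * shell * n_fr
  out <- tibble::tibble(r = (head(edges, -1) + tail(edges, -1)) / 2,
                        g = ifelse(expected > 0, counts / expected, 0),
                        count = counts)
  class(out) <- c("rdf_result", class(out))
  attr(out, "n_frames") <- n_fr
  attr(out, "labels") <- c(deparse(substitute(centers_a))[1],
                           deparse(substitute(centers_b))[1])
  out
}

#' Body-fixed local frame from three sites
#'
#' Builds a right-handed orthonormal frame from three non-collinear sites:
#' origin at their centroid, x along site1 -> site2, z normal to the
#' site plane.  Rigid motion of the body leaves coordinates expressed in this
#' frame unchanged.
#'
#' @param xyz coordinate matrix of the body.
#' @param site_indices integer vector of three row indices.
#' @return list with `origin` (3-vector) and `rotation` (3 x 3, columns =
#'   frame axes in lab coordinates, determinant +1).
#' @export
local_frame <- function(xyz, site_indices) {
  stopifnot(length(site_indices) == 3)
  s <- xyz[site_indices, , drop = FALSE]
  v1 <- s[2, ] - s[1, ]; v2 <- s[3, ] - s[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  ncr <- sqrt(sum(cr^2))
  if (ncr < 1e-9 * sqrt(sum(v1^2)) * sqrt(sum(v2^2)) || ncr == 0) {
    stop("frame sites are collinear", call. = FALSE)
  }
  e1 <- v1 / sqrt(sum(v1^2))
  e3 <- cr / ncr
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(origin = colMeans(s), rotation = unname(cbind(e1, e2, e3)))
}

#' Spatial distribution function in the NCP body frame
#'
#' Bins the positions of the selected species, expressed in the body-fixed
#' frame of the host NCP, into a cubic voxel grid, averaged over frames (and
#' over NCP copies when several frame-site triplets are given).
#'
#' @param traj a `cg_trajectory` (production frames).
#' @param frame_sites integer vector of three site indices, or a list of such
#'   vectors (one per NCP copy to average over).
#' @param species integer vector of bead indices to bin, or a list parallel
#'   to `frame_sites` (per-copy selections, e.g. "own tails").
#' @param voxel voxel edge, Angstrom.
#' @param extent half-width of the grid, Angstrom.
#' @return object of class `sdf_grid`: 3-D density array (counts per A^3 per
#'   frame), voxel size, axis coordinates and frame spec.
#' @export
sdf <- function(traj, frame_sites, species, voxel = 5, extent = 100) {
  if (voxel <= 0) stop("voxel edge must be positive", call. = FALSE)
  if (!is.list(frame_sites)) frame_sites <- list(frame_sites)
  if (!is.list(species)) species <- rep(list(species), length(frame_sites))
  stopifnot(length(species) == length(frame_sites))
  nbin <- 2 * ceiling(extent / voxel)
  lo <- -nbin / 2 * voxel
  dens <- array(0, dim = c(nbin, nbin, nbin))
  n_obs <- 0L
  for (f in seq_along(traj$frames)) {
    xyz <- .frame_xyz(traj, f)
    for (c_i in seq_along(frame_sites)) {
      fr <- local_frame(xyz, frame_sites[[c_i]])
      p <- sweep(xyz[species[[c_i]], , drop = FALSE], 2, fr$origin) %*%
        fr$rotation
      ix <- floor((p - lo) / voxel) + 1
      keep <- rowSums(ix >= 1 & ix <= nbin) == 3
      ix <- ix[keep, , drop = FALSE]
      if (nrow(ix)) {
        for (r in seq_len(nrow(ix))) {
          dens[ix[r, 1], ix[r, 2], ix[r, 3]] <-
            dens[ix[r, 1], ix[r, 2], ix[r, 3]] + 1
        }
      }
      n_obs <- n_obs + 1L
    }
  }
  ax <- lo + (seq_len(nbin) - 0.5) * voxel
  structure(list(density = dens / (n_obs * voxel^3), counts = dens,
                 voxel = voxel, axes = ax, n_observations = n_obs,
                 frame_sites = frame_sites),
            class = "sdf_grid")
}

#' @export
print.sdf_grid <- function(x, ...) {
  cat(sprintf("<sdf_grid> %s voxels of %.1f A, %d frame observations\n",
              paste(dim(x$density), collapse = "x"), x$voxel,
              x$n_observations))
  invisible(x)
}

#' Export an SDF grid as plain text
#'
#' Header (grid shape, voxel, origin) followed by one `ix iy iz density`
#' line per non-empty voxel.
#'
#' @param grid an `sdf_grid`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sdf_grid <- function(grid, path) {
  con <- file(path, "w"); on.exit(close(con))
  d <- dim(grid$density)
  writeLines(sprintf("# nucleocg sdf grid %d %d %d voxel %.6g origin %.6g",
                     d[1], d[2], d[3], grid$voxel, grid$axes[1]), con)
  nz <- which(grid$density > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    writeLines(sprintf("%d %d %d %.8g", nz[, 1], nz[, 2], nz[, 3],
                       grid$density[nz]), con)
  }
  invisible(path)
}

#' Pair-distance distribution P(r), radius of gyration and maximum dimension
#'
#' P(r) is the normalized histogram of all intra-particle pairwise distances
#' (equal bead weights), ensemble-averaged over frames.  Rg follows from the
#' second moment, Rg^2 = (1/2) sum P(r) r^2 dr; Dmax is the smallest r beyond
#' which P(r) stays below 1e-3 of its maximum.
#'
#' @param traj a `cg_trajectory`, or a single coordinate matrix.
#' @param selection integer vector of bead indices (>= 2).
#' @param bin_width histogram bin width, Angstrom (default 1).
#' @return object of class `pr_curve`: tibble (`r` in Angstrom, `p` with unit
#'   area) with `Rg` and `Dmax` attributes (see [glance.pr_curve()]).
#' @export
pr_rg_dmax <- function(traj, selection, bin_width = 1) {
  if (length(selection) < 2) stop("need at least two beads", call. = FALSE)
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else list(traj)
  dmax_obs <- 0
  all_counts <- NULL
  dists <- lapply(frames, function(m) {
    as.vector(stats::dist(m[selection, , drop = FALSE]))
  })
  dmax_obs <- max(vapply(dists, max, 0))
  edges <- seq(0, dmax_obs + bin_width, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (d in dists) {
    counts <- counts + tabulate(findInterval(d, edges), length(edges) - 1)
  }
  p <- counts / (sum(counts) * bin_width)            # unit area
  r <- (head(edges, -1) + tail(edges, -1)) / 2
  # Dmax: smallest r beyond which P stays below 1e-3 of its maximum; the
  # sub-threshold far tail (outlier pairs) is zeroed so that P(r) = 0 holds
  # exactly beyond Dmax, then the curve is renormalized
  thr <- 1e-3 * max(p)
  above <- which(p > thr)
  dmax <- if (length(above)) edges[max(above) + 1] else 0
  p[r > dmax] <- 0
  p <- p / (sum(p) * bin_width)
  # second moment over distinct pairs; the (N-1)/(2N) factor makes the
  # estimator exact at all N (it tends to the SAXS convention 1/2 for large N)
  nsel <- length(selection)
  rg <- sqrt((nsel - 1) / (2 * nsel) * sum(p * r^2 * bin_width))
  out <- tibble::tibble(r = r, p = p)
  class(out) <- c("pr_curve", class(out))
  attr(out, "Rg") <- rg
  attr(out, "Dmax") <- dmax
  attr(out, "bin_width") <- bin_width
  out
}

#' Optimal-superposition RMSD
#'
#' Root-mean-square deviation between two coordinate sets after removing the
#' optimal rigid-body rotation and translation (Kabsch least-squares
#' superposition via SVD).
#'
#' @param reference,coords n x 3 coordinate matrices.
#' @param selection optional integer vector of rows to compare.
#' @return RMSD in Angstrom.
#' @export
rmsd_optimal <- function(reference, coords, selection = NULL) {
  if (!is.null(selection)) {
    reference <- reference[selection, , drop = FALSE]
    coords <- coords[selection, , drop = FALSE]
  }
  if (nrow(reference) != nrow(coords)) stop("selection sizes differ", call. = FALSE)
  if (nrow(reference) < 3) stop("need at least 3 points", call. = FALSE)
  a <- sweep(reference, 2, colMeans(reference))
  b <- sweep(coords, 2, colMeans(coords))
  s <- svd(crossprod(b, a))                     # t(b) %*% a
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((b %*% t(R) - a)^2)))
}

#' Per-frame RMSD trace of a selection
#'
#' @param traj a `cg_trajectory`.
#' @param reference reference coordinate matrix (full bead set).
#' @param selection integer vector of bead indices (e.g. the globular core).
#' @return tibble with `step` and `rmsd` (Angstrom).
#' @export
rmsd_trace <- function(traj, reference, selection) {
  tibble::tibble(
    step = traj$steps,
    rmsd = vapply(traj$frames, function(m)
      rmsd_optimal(reference, m, selection), 0))
}

# named DNA bead pair sets of one NCP copy
.dna_pair_sets <- function(model, ncp = 1) {
  b <- model$beads
  nb1 <- nrow(b[b$role != "ion", ]) / model$n_ncp
  off <- (ncp - 1) * nb1
  dna <- which(b$role %in% c("D", "P") & b$index > off & b$index <= off + nb1)
  sub <- b[dna, ]
  ix <- function(site, unit) dna[sub$site == site & sub$unit == unit]
  n_units <- max(sub$unit)
  pairs <- list(cross_strand = NULL, strand_pp = NULL, dd = NULL)
  for (u in seq_len(n_units)) {
    pairs$cross_strand <- rbind(pairs$cross_strand,
                                c(ix("P1", u), ix("P3", u)),
                                c(ix("P2", u), ix("P4", u)))
    pairs$strand_pp <- rbind(pairs$strand_pp,
                             c(ix("P1", u), ix("P2", u)),
                             c(ix("P3", u), ix("P4", u)))
    if (u < n_units) {
      pairs$strand_pp <- rbind(pairs$strand_pp,
                               c(ix("P2", u), ix("P1", u + 1)),
                               c(ix("P4", u), ix("P3", u + 1)))
      pairs$dd <- rbind(pairs$dd, c(ix("D", u), ix("D", u + 1)))
    }
  }
  pairs
}

#' DNA distance distributions
#'
#' Means and standard deviations, over production frames, of named DNA bead
#' pair distances: `cross_strand` (opposite phosphates of the same base
#' pair), `strand_pp` (neighbouring phosphates along a strand) and `dd`
#' (consecutive central beads).
#'
#' @param traj a `cg_trajectory` or a single coordinate matrix.
#' @param model the `ncp_model`.
#' @param pair_sets subset of the three pair-set names.
#' @return tibble with `pair`, `mean`, `sd` (Angstrom) and `n` samples.
#' @export
distance_distributions <- function(traj, model,
                                   pair_sets = c("cross_strand", "strand_pp",
                                                 "dd")) {
  pair_sets <- match.arg(pair_sets, several.ok = TRUE)
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else list(traj)
  res <- list()
  for (ncp in seq_len(model$n_ncp)) {
    sets <- .dna_pair_sets(model, ncp)
    for (ps in pair_sets) {
      pr <- sets[[ps]]
      vals <- unlist(lapply(frames, function(m) {
        sqrt(rowSums((m[pr[, 1], , drop = FALSE] - m[pr[, 2], , drop = FALSE])^2))
      }))
      res[[paste(ps, ncp)]] <- tibble::tibble(
        pair = ps, ncp = ncp, mean = mean(vals),
        sd = if (length(vals) > 1) sd(vals) else 0, n = length(vals))
    }
  }
  out <- dplyr::bind_rows(res)
  dplyr::summarise(dplyr::group_by(out, pair),
                   mean = stats::weighted.mean(mean, n),
                   sd = sqrt(stats::weighted.mean(sd^2 + mean^2, n) -
                               stats::weighted.mean(mean, n)^2),
                   n = sum(n), .groups = "drop")
}

# principal axis with the smallest spread of the D beads = superhelix axis
.ncp_axis <- function(xyz, d_idx) {
  p <- xyz[d_idx, , drop = FALSE]
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  ev$vectors[, 3]
}

.dyad_axis <- function(xyz, dyad_sites) {
  v <- xyz[dyad_sites[1], ] - xyz[dyad_sites[2], ]
  v / sqrt(sum(v^2))
}

#' Detect stacked NCP pairs and dyad-angle statistics
#'
#' For every pair of NCPs whose core centres (centre of mass of the globular
#' part) fall within the cutoff, reports the core-centre distance, the angle
#' between the two dyad axes, the angle between the two superhelix axes, and
#' a face-face classification: `"stacked"` when the cylinder axes are within
#' 30 degrees of parallel, `"perpendicular"` within 30 degrees of orthogonal,
#' otherwise `"oblique"`.
#'
#' @param traj a `cg_trajectory`.
#' @param model a multi-NCP `ncp_model`.
#' @param cutoff core-centre contact cutoff, Angstrom (default 70 A = 7 nm,
#'   the first minimum of the core-core RDF).
#' @return tibble with one row per contacting pair per frame.
#' @export
stacking_pairs <- function(traj, model, cutoff = 70) {
  if (model$n_ncp < 2) stop("need at least two NCPs", call. = FALSE)
  for (k in seq_len(model$n_ncp)) {
    if (is.null(model$groups[[paste0("dyad_sites_", k)]])) {
      stop("model lacks dyad reference sites", call. = FALSE)
    }
  }
  box <- traj$box_edge
  out <- list()
  for (f in seq_along(traj$frames)) {
    xyz <- .frame_xyz(traj, f)
    centres <- t(vapply(seq_len(model$n_ncp), function(k)
      colMeans(xyz[model$groups[[paste0("core_", k)]], , drop = FALSE]),
      numeric(3)))
    for (a in seq_len(model$n_ncp - 1)) for (b in (a + 1):model$n_ncp) {
      dv <- centres[a, ] - centres[b, ]
      dv <- dv - box * round(dv / box)
      dist <- sqrt(sum(dv^2))
      if (dist >= cutoff) next
      ax_a <- .ncp_axis(xyz, model$groups[[paste0("dna_d_", a)]])
      ax_b <- .ncp_axis(xyz, model$groups[[paste0("dna_d_", b)]])
      dy_a <- .dyad_axis(xyz, model$groups[[paste0("dyad_sites_", a)]])
      dy_b <- .dyad_axis(xyz, model$groups[[paste0("dyad_sites_", b)]])
      ang_ax <- acos(min(1, abs(sum(ax_a * ax_b)))) * 180 / pi
      ang_dy <- acos(min(1, abs(sum(dy_a * dy_b)))) * 180 / pi
      out[[length(out) + 1]] <- tibble::tibble(
        frame = f, ncp_a = a, ncp_b = b, distance = dist,
        dyad_angle = ang_dy, axis_angle = ang_ax,
        contact = if (ang_ax <= 30) "stacked"
        else if (ang_ax >= 60) "perpendicular" else "oblique")
    }
  }
  if (!length(out)) {
    return(tibble::tibble(frame = integer(), ncp_a = integer(),
                          ncp_b = integer(), distance = numeric(),
                          dyad_angle = numeric(), axis_angle = numeric(),
                          contact = character()))
  }
  dplyr::bind_rows(out)
}

#' Bulk ion concentration
#'
#' Estimates the "bulk" ion concentration in the probe region of the cell at
#' maximal distance from every NCP core centre (where the electric field is
#' approximately zero): a sphere around the cell point maximizing the
#' minimum image distance to all core centres.
#'
#' @param traj a `cg_trajectory`.
#' @param model the `ncp_model` (with ions placed).
#' @param species ion species name (e.g. `"K"`); default all ions.
#' @param probe_radius probe sphere radius, Angstrom.
#' @param grid_n grid resolution per axis used to locate the probe point.
#' @return tibble with the probe centre, mean ion count and concentration (mM).
#' @export
bulk_concentration <- function(traj, model, species = NULL, probe_radius = 50,
                               grid_n = 16) {
  ion_ix <- if (is.null(species)) model$groups$ions else
    model$groups[[paste0("ions_", species)]]
  if (is.null(ion_ix) || !length(ion_ix)) stop("no ions of that species in the model", call. = FALSE)
  box <- traj$box_edge
  core_groups <- lapply(seq_len(model$n_ncp), function(k)
    model$groups[[if (model$n_ncp == 1) "core" else paste0("core_", k)]])
  # probe point from the first frame (NCPs barely move on analysis windows)
  xyz1 <- traj$frames[[1]]
  centres <- t(vapply(core_groups, function(ix)
    colMeans(xyz1[ix, , drop = FALSE]), numeric(3)))
  g <- (seq_len(grid_n) - 0.5) / grid_n * box
  cand <- as.matrix(expand.grid(g, g, g))
  dmin <- matrix(cg_pair_distances_cpp(cand, centres, box),
                 nrow = nrow(cand), byrow = TRUE)
  dmin <- apply(dmin, 1, min)
  probe <- cand[which.max(dmin), ]
  counts <- vapply(traj$frames, function(m) {
    d <- cg_pair_distances_cpp(matrix(probe, 1), m[ion_ix, , drop = FALSE], box)
    sum(d < probe_radius)
  }, 0)
  if (max(dmin) < probe_radius) {
    warning("probe sphere overlaps an NCP core centre; bulk estimate unreliable")
  }
  v_A3 <- 4 / 3 * pi * probe_radius^3
  mM <- mean(counts) / (v_A3 * 6.02214076e-7)
  tibble::tibble(probe_x = probe[1], probe_y = probe[2], probe_z = probe[3],
                 mean_count = mean(counts), concentration_mM = mM)
}
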