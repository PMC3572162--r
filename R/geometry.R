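# Constructive geometry of the coarse-grained DNA duplex and the
# nucleosomal superhelix.

deg2rad <- function(x) x * pi / 180

rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta),  cos(theta), 0),
        c(0, 0, 1))
}

# screw operation of the duplex: +72 deg about z, +6.8 A along z, n times
.screw <- function(xyz, n) {
  sweep(xyz %*% t(rot_z(n * deg2rad(DNA_TWIST))), 2,
        c(0, 0, n * DNA_RISE), `+`)
}

.unit_bonded_energy <- function(p) {
  P <- matrix(p, 4, 3)
  Pp <- .screw(P, 1)
  D0 <- c(0, 0, 0)
  dd <- function(a, b) sqrt(sum((a - b)^2))
  aa <- function(a, b, c) {
    v1 <- a - b; v2 <- c - b
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }
  bt <- DNA_BOND_TABLE; at <- DNA_ANGLE_TABLE
  bond <- function(a, b, t) t[["k"]] / 2 * (dd(a, b) - t[["r0"]])^2
  angl <- function(a, b, c, t) t[["k"]] / 2 * (aa(a, b, c) - deg2rad(t[["phi0"]]))^2
  e <- sum(vapply(1:4, function(i) bond(P[i, ], D0, bt$d_p), 0))
  e <- e + bond(P[1, ], P[2, ], bt$strand_pp) + bond(P[3, ], P[4, ], bt$strand_pp) +
    bond(P[2, ], Pp[1, ], bt$strand_pp) + bond(P[4, ], Pp[3, ], bt$strand_pp) +
    bond(P[1, ], Pp[3, ], bt$minor_pp) + bond(P[2, ], Pp[4, ], bt$minor_pp)
  e + angl(P[1, ], P[2, ], Pp[1, ], at$strand) +
    angl(P[2, ], Pp[1, ], Pp[2, ], at$strand) +
    angl(P[3, ], P[4, ], Pp[3, ], at$strand) +
    angl(P[4, ], Pp[3, ], Pp[4, ], at$strand) +
    angl(P[1, ], D0, P[3, ], at$pdp) + angl(P[2, ], D0, P[4, ], at$pdp)
}

.geometry_cache <- new.env(parent = emptyenv())

#' Phosphate placement of the two-base-pair DNA unit
#'
#' Returns the coordinates of the four phosphate beads of one DNA unit in the
#' unit frame (central bead at the origin, helix axis along z).  The placement
#' minimizes the duplex bonded energy under the 72 degree / 6.8 Angstrom screw
#' symmetry, seeded from the analytic B-form construction (phosphate radius
#' sqrt(9.62^2 - 1.7^2) = 9.468 A; cross-strand azimuth set by the ideal
#' 18.2 A same-base-pair phosphate separation).  The minimization residual is
#' below 0.01 kT per unit, so a straight duplex built from this unit sits at
#' the minimum of its bonded terms.
#'
#' @return 4 x 3 matrix, rows P1, P2 (strand 1) and P3, P4 (strand 2), Angstrom.
#' @export
dna_unit_geometry <- function() {
  if (!is.null(.geometry_cache$unit)) return(.geometry_cache$unit)
  rho <- sqrt(DNA_BOND_TABLE$d_p[["r0"]]^2 - (DNA_RISE / 4)^2)
  delta <- 2 * asin(18.2 / (2 * rho))
  a1 <- deg2rad(-DNA_TWIST / 4); a2 <- deg2rad(DNA_TWIST / 4)
  z <- DNA_RISE / 4
  seed <- rbind(
    c(rho * cos(a1), rho * sin(a1), -z),
    c(rho * cos(a2), rho * sin(a2),  z),
    c(rho * cos(a1 - delta), rho * sin(a1 - delta), -z),
    c(rho * cos(a2 - delta), rho * sin(a2 - delta),  z))
  opt <- optim(as.vector(seed), .unit_bonded_energy, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt <- optim(opt$par, .unit_bonded_energy, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  unit <- matrix(opt$par, 4, 3,
                 dimnames = list(c("P1", "P2", "P3", "P4"), c("x", "y", "z")))
  .geometry_cache$unit <- unit
  unit
}

#' Nucleosomal superhelix path
#'
#' D-bead positions and local frames on a left-handed superhelix of
#' `turns` turns with consecutive beads a fixed chord distance apart.
#' The superhelix radius follows from the chord constraint; the axis is z.
#'
#' @param n_units number of DNA units (D beads) on the path.
#' @param turns total number of superhelical turns.
#' @param pitch superhelical pitch in Angstrom (axial advance per turn).
#' @param spacing chord distance between consecutive D beads, Angstrom.
#' @return list with `positions` (n x 3), `frames` (list of 3x3 rotation
#'   matrices mapping unit-frame coordinates into the lab frame) and `radius`.
#' @export
superhelix_path <- function(n_units, turns = SUPERHELIX_TURNS,
                            pitch = SUPERHELIX_PITCH, spacing = DNA_RISE) {
  stopifnot(n_units >= 2)
  dtheta <- turns * 2 * pi / (n_units - 1)
  dz <- turns * pitch / (n_units - 1)
  radius <- sqrt(spacing^2 - dz^2) / (2 * sin(dtheta / 2))
  th <- -((seq_len(n_units) - 1) * dtheta)   # left-handed: clockwise seen from +z
  pos <- cbind(radius * cos(th), radius * sin(th),
               (seq_len(n_units) - 1) * dz - turns * pitch / 2)
  # local frames: z' = path tangent, accumulated twist about it
  frames <- vector("list", n_units)
  tangents <- matrix(0, n_units, 3)
  for (i in seq_len(n_units)) {
    lo <- max(1, i - 1); hi <- min(n_units, i + 1)
    tv <- pos[hi, ] - pos[lo, ]
    tangents[i, ] <- tv / sqrt(sum(tv^2))
  }
  # parallel transport of a normal along the path, plus 72 deg/unit twist
  nrm <- c(pos[1, 1], pos[1, 2], 0); nrm <- nrm / sqrt(sum(nrm^2))
  nrm <- nrm - sum(nrm * tangents[1, ]) * tangents[1, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  for (i in seq_len(n_units)) {
    if (i > 1) {
      # rotate previous normal by the minimal rotation aligning tangents
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
    # +72 deg/unit about the local tangent keeps the phosphate strands
    # continuous, exactly as in the straight build (screw about +z)
    tw <- (i - 1) * deg2rad(DNA_TWIST)
    b3 <- tangents[i, ]
    b2 <- c(b3[2] * nrm[3] - b3[3] * nrm[2], b3[3] * nrm[1] - b3[1] * nrm[3],
            b3[1] * nrm[2] - b3[2] * nrm[1])
    base <- cbind(nrm, b2, b3)            # columns: x', y', z'
    twist <- rbind(c(cos(tw), -sin(tw), 0), c(sin(tw), cos(tw), 0), c(0, 0, 1))
    frames[[i]] <- base %*% twist
  }
  list(positions = pos, frames = frames, radius = radius)
}

# winding angle of a point set about the z axis (sum of signed azimuthal steps)
.winding_turns <- function(xy) {
  th <- atan2(xy[, 2], xy[, 1])
  dth <- diff(th)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  abs(sum(dth)) / (2 * pi)
}

# low-discrepancy Halton sequence (bases 2, 3, 5)
.halton <- function(n, base) {
  r <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; x <- 0; k <- i
    while (k > 0) { f <- f / base; x <- x + f * (k %% base); k <- k %/% base }
    r[i] <- x
  }
  r
}
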