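# Interaction model: continuum-dielectric Coulomb, purely repulsive
# (truncated-and-shifted) Lennard-Jones acting on the hard-core-shifted
# distance, and harmonic bond/angle terms.  Energies in kT, lengths in
# Angstrom.

#' Force-field parameters
#'
#' Defaults: relative permittivity 78, soft LJ length sigma = 4 A, LJ strength
#' 1 kT, T = 298 K (entering only through the Bjerrum length).  The repulsive
#' LJ acts on x = r - (R_i + R_j) and is cut and shifted at x = 2^(1/6) sigma;
#' inside the hard core the energy is capped and continued linearly so that
#' overlapping initial placements keep finite forces.  Directly bonded pairs
#' are excluded from the short-range repulsion (their equilibrium distances
#' can be below contact) but kept in the Coulomb sum; both exclusions are
#' switchable.
#'
#' @param epsilon_r relative permittivity.
#' @param sigma soft LJ length, Angstrom.
#' @param epsilon_lj LJ strength, kT.
#' @param temperature_K temperature for the Bjerrum-length conversion.
#' @param coulomb_cutoff real-space electrostics cutoff, Angstrom (methods
#'   `"cutoff"` and `"ewald"`).
#' @param electrostatics one of `"cutoff"` (truncated-shifted, minimum image),
#'   `"direct"` (no cutoff; non-periodic systems), `"ewald"` (full periodic
#'   sum) or `"none"`.
#' @param ewald_accuracy target relative force accuracy of the Ewald sum;
#'   sets the splitting parameter and reciprocal cutoff.
#' @param exclude_bonded_lj,exclude_bonded_coulomb exclusion switches for
#'   directly bonded (1-2) pairs.
#' @param overlap_cap energy (kT) at which the repulsion switches to its
#'   linear overlap continuation.
#' @return named list of class `ff_params`.
#' @export
ff_params <- function(epsilon_r = 78, sigma = 4, epsilon_lj = 1,
                      temperature_K = 298, coulomb_cutoff = 30,
                      electrostatics = c("cutoff", "direct", "ewald", "none"),
                      ewald_accuracy = 1e-4,
                      exclude_bonded_lj = TRUE, exclude_bonded_coulomb = FALSE,
                      overlap_cap = 100) {
  stopifnot(epsilon_r > 0, sigma > 0, epsilon_lj > 0, temperature_K > 0)
  electrostatics <- match.arg(electrostatics)
  p <- list(
    epsilon_r = epsilon_r, sigma = sigma, epsilon_lj = epsilon_lj,
    temperature_K = temperature_K,
    bjerrum_length = bjerrum_length(epsilon_r, temperature_K),
    coulomb_cutoff = coulomb_cutoff, electrostatics = electrostatics,
    ewald_accuracy = ewald_accuracy,
    ewald_alpha = sqrt(-log(ewald_accuracy)) / coulomb_cutoff,
    ewald_kmax = 8L,
    exclude_bonded_lj = exclude_bonded_lj,
    exclude_bonded_coulomb = exclude_bonded_coulomb,
    overlap_cap = overlap_cap)
  class(p) <- "ff_params"
  p
}

# reciprocal cutoff needed for a given box; alpha fixed by rcut+accuracy
.tune_ewald <- function(p, box_edge) {
  if (p$electrostatics != "ewald") return(p)
  kmax <- ceiling(p$ewald_alpha * box_edge * sqrt(-log(p$ewald_accuracy)) / pi)
  p$ewald_kmax <- as.integer(max(kmax, 4L))
  p
}

#' Override force-field parameters from a key=value text file
#'
#' Blank lines and `#` comments are ignored; keys match the [ff_params()]
#' argument names.
#'
#' @param path text file path.
#' @param base parameter set to override.
#' @return `ff_params` list.
#' @export
read_ff_params <- function(path, base = ff_params()) {
  kv <- .read_key_value(path)
  num <- setdiff(names(kv), "electrostatics")
  vals <- as.list(kv)
  vals[num] <- lapply(vals[num], as.numeric)
  do.call(ff_params, modifyList(
    list(epsilon_r = base$epsilon_r, sigma = base$sigma,
         epsilon_lj = base$epsilon_lj, temperature_K = base$temperature_K,
         coulomb_cutoff = base$coulomb_cutoff,
         electrostatics = base$electrostatics,
         ewald_accuracy = base$ewald_accuracy,
         exclude_bonded_lj = base$exclude_bonded_lj,
         exclude_bonded_coulomb = base$exclude_bonded_coulomb,
         overlap_cap = base$overlap_cap), vals))
}

.read_key_value <- function(path, seen = character()) {
  if (path %in% seen) stop("circular [include] in config", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- character()
  for (l in lines) {
    if (grepl("^\\[include\\]", l)) {
      inc <- trimws(sub("^\\[include\\]", "", l))
      inc_path <- if (file.exists(inc)) inc else file.path(dirname(path), inc)
      out <- c(.read_key_value(inc_path, c(seen, path)), out)
    } else {
      parts <- strsplit(l, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed config line: ", l, call. = FALSE)
      out[trimws(parts[1])] <- trimws(parts[2])
    }
  }
  out
}

#' Pairwise Coulomb energy
#'
#' U = l_B q_i q_j / r in kT, with l_B the Bjerrum length of the parameter
#' set.
#'
#' @param q_i,q_j charges in e.
#' @param r separation, Angstrom (> 0).
#' @param params [ff_params()].
#' @return energy in kT (vectorized).
#' @export
coulomb_energy <- function(q_i, q_j, r, params = ff_params()) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  params$bjerrum_length * q_i * q_j / r
}

#' Purely repulsive (WCA-style) pair energy
#'
#' Acts on the hard-core-shifted distance x = r - (R_i + R_j):
#' U = 4 eps ((sigma/x)^12 - (sigma/x)^6) + eps for x < 2^(1/6) sigma, zero
#' beyond.  Overlapping pairs (x below the cap point, including r <= R_ij)
#' return the finite linear continuation and are flagged with a warning.
#'
#' @param r separation, Angstrom.
#' @param R_i,R_j hard-core radii, Angstrom.
#' @param params [ff_params()].
#' @return energy in kT (vectorized).
#' @export
lj_repulsive_energy <- function(r, R_i, R_j, params = ff_params()) {
  sig <- params$sigma; eps <- params$epsilon_lj
  x <- r - (R_i + R_j)
  xc <- 2^(1 / 6) * sig
  s_cap <- (1 + sqrt(params$overlap_cap)) / 2
  xcap <- sig * s_cap^(-1 / 6)
  if (any(r <= R_i + R_j)) {
    warning("hard-core overlap: r <= R_i + R_j for some pair(s); capped energy returned")
  }
  u <- numeric(length(x))
  mid <- x < xc & x > xcap
  s6 <- (sig / x[mid])^6
  u[mid] <- 4 * eps * (s6^2 - s6) + eps
  low <- x <= xcap
  s6c <- (sig / xcap)^6
  ucap <- 4 * eps * (s6c^2 - s6c) + eps
  fcap <- -4 * eps * (-12 * s6c^2 + 6 * s6c) / xcap
  u[low] <- ucap + fcap * (xcap - x[low])
  u
}

#' Harmonic bond and angle energies
#'
#' U = (k_b/2)(r - r_0)^2 and U = (k_a/2)(phi - phi_0)^2; the half-prefactor
#' convention makes the thermal bond-length standard deviation
#' sqrt(kT / k_b) by equipartition.
#'
#' @param r bond length, Angstrom; `phi` angle in radians.
#' @param k_b,k_a force constants, kT/A^2 and kT/rad^2.
#' @param r_0,phi_0 equilibrium values.
#' @return energy in kT (vectorized).
#' @export
bond_energy <- function(r, k_b, r_0) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  k_b / 2 * (r - r_0)^2
}

#' @rdname bond_energy
#' @export
angle_energy <- function(phi, k_a, phi_0) {
  if (any(phi < 0 | phi > pi)) stop("phi must lie in [0, pi]", call. = FALSE)
  k_a / 2 * (phi - phi_0)^2
}

# assemble the argument list the compiled core expects
.model_ff_args <- function(model) {
  b <- model$beads
  bo <- model$bonds; an <- model$angles
  list(
    charge = as.numeric(b$charge), hard_radius = as.numeric(b$hard_radius),
    mass = as.numeric(b$mass),
    bonds = cbind(as.integer(bo$i), as.integer(bo$j)),
    bond_k = as.numeric(bo$k_b), bond_r0 = as.numeric(bo$r_0),
    angles = if (nrow(an)) cbind(as.integer(an$i), as.integer(an$j),
                                 as.integer(an$k)) else matrix(0L, 0, 3),
    angle_k = as.numeric(an$k_a), angle_phi0 = as.numeric(an$phi_0))
}

.ff_cpp_list <- function(params, box_edge = 0) {
  p <- .tune_ewald(params, box_edge)
  list(bjerrum_length = p$bjerrum_length, sigma = p$sigma,
       epsilon_lj = p$epsilon_lj, coulomb_cutoff = p$coulomb_cutoff,
       electrostatics = p$electrostatics, ewald_alpha = p$ewald_alpha,
       ewald_kmax = as.integer(p$ewald_kmax),
       exclude_bonded_lj = isTRUE(p$exclude_bonded_lj),
       exclude_bonded_coulomb = isTRUE(p$exclude_bonded_coulomb),
       overlap_cap = p$overlap_cap)
}

#' Total potential energy and forces
#'
#' Sum of Coulomb, short-range repulsion and harmonic bond/angle terms, with
#' the force on every bead (the negative energy gradient).
#'
#' @param positions n x 3 coordinate matrix, Angstrom; defaults to the model's
#'   stored coordinates.
#' @param model an `ncp_model` (supplies charges, radii and bonded terms).
#' @param params [ff_params()].
#' @param box_edge periodic cubic cell edge in Angstrom, or 0 for a
#'   non-periodic system.
#' @return list with `energy` (kT), `forces` (n x 3, kT/A), per-term `terms`
#'   and an `overlap` flag.
#' @export
total_energy_forces <- function(positions = NULL, model, params = ff_params(),
                                box_edge = 0) {
  if (is.null(positions)) {
    positions <- as.matrix(model$beads[, c("x", "y", "z")])
  }
  if (nrow(positions) != nrow(model$beads)) {
    stop("position count does not match the model bead count", call. = FALSE)
  }
  if (params$electrostatics == "ewald") {
    if (box_edge <= 0) stop("ewald electrostatics requires a periodic box", call. = FALSE)
    if (abs(sum(model$beads$charge)) > 1e-9) {
      stop("periodic electrostatics requires an electroneutral system", call. = FALSE)
    }
  }
  a <- .model_ff_args(model)
  cg_energy_forces_cpp(positions, box_edge, a$charge, a$hard_radius, a$mass,
                       a$bonds, a$bond_k, a$bond_r0, a$angles, a$angle_k,
                       a$angle_phi0, .ff_cpp_list(params, box_edge))
}

#' Zero-temperature relaxation of a model
#'
#' Minimizes the potential energy (L-BFGS-B on the compiled
#' energy/gradient), returning relaxed coordinates.
#'
#' @param model an `ncp_model`.
#' @param params [ff_params()]; default excludes electrostatics so the
#'   bonded+repulsive construction minimum is probed.
#' @param box_edge periodic cell edge or 0.
#' @param maxit iteration budget.
#' @return list with `positions`, `energy`, `convergence`.
#' @export
minimize_model <- function(model, params = ff_params(electrostatics = "none"),
                           box_edge = 0, maxit = 500) {
  a <- .model_ff_args(model)
  ffl <- .ff_cpp_list(params, box_edge)
  x0 <- as.matrix(model$beads[, c("x", "y", "z")])
  n <- nrow(x0)
  fn <- function(p) {
    cg_energy_forces_cpp(matrix(p, n, 3), box_edge, a$charge, a$hard_radius,
                         a$mass, a$bonds, a$bond_k, a$bond_r0, a$angles,
                         a$angle_k, a$angle_phi0, ffl)$energy
  }
  gr <- function(p) {
    -as.vector(cg_energy_forces_cpp(matrix(p, n, 3), box_edge, a$charge,
                                    a$hard_radius, a$mass, a$bonds, a$bond_k,
                                    a$bond_r0, a$angles, a$angle_k,
                                    a$angle_phi0, ffl)$forces)
  }
  opt <- optim(as.vector(x0), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  list(positions = matrix(opt$par, n, 3), energy = opt$value,
       convergence = opt$convergence)
}
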