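# Scripted scaled-down experiment suite: named system recipes, manifests and
# reproducible end-to-end runs (build -> ionize -> simulate -> analyse).

# Table of simulated systems: counterion species, copies, cell size.  Step
# counts reflect the reference protocol (1e8 single-NCP, 2.5e9 ten-NCP
# steps); desk runs scale them down via `scale`.
EXPERIMENT_RECIPES <- list(
  "1ncp_k"      = list(n_ncp = 1,  species = "K",     base_steps = 1e8),
  "1ncp_mg"     = list(n_ncp = 1,  species = "Mg",    base_steps = 1e8),
  "1ncp_cohex"  = list(n_ncp = 1,  species = "CoHex", base_steps = 1e8),
  "10ncp_k"     = list(n_ncp = 10, species = "K",     base_steps = 2.5e9),
  "10ncp_mg"    = list(n_ncp = 10, species = "Mg",    base_steps = 2.5e9),
  "10ncp_cohex" = list(n_ncp = 10, species = "CoHex", base_steps = 2.5e9),
  "salt_series" = list(n_ncp = 1,  species = "K",     base_steps = 1e8,
                       salt_mM = c(0, 50, 100, 400))
)

#' Run a named scaled-down experiment
#'
#' Builds the system of the requested recipe (synthetic NCP model,
#' neutralizing counterions per the published compositions, 40 nm cell),
#' runs Langevin dynamics with the step count scaled by `scale`, splits off
#' equilibration, computes the standard observables and writes a manifest.
#'
#' @param recipe one of `names(nucleocg:::EXPERIMENT_RECIPES)`.
#' @param scale step-count scale factor (1 = the full reference protocol;
#'   desk runs use 1e-4 .. 1e-3).
#' @param seed integer master seed.
#' @param out_dir output directory (created); NULL skips file output.
#' @param stride frame stride; default keeps ~500 frames.
#' @param equil_fraction equilibration fraction discarded before analysis.
#' @param relax short zero-temperature relaxation before dynamics (removes
#'   construction strain and any residual ion contacts; default TRUE).
#' @param added_salt_mM added KCl concentration; NULL takes the recipe's
#'   default (the `salt_series` recipe is run one concentration at a time:
#'   pass each member of 0/50/100/400 mM in turn).
#' @return list with `model`, `trajectory`, `analysis` (list of tibbles) and
#'   `manifest`.
#' @export
run_experiment <- function(recipe, scale = 1e-4, seed = 1, out_dir = NULL,
                           stride = NULL, equil_fraction = 0.4, relax = TRUE,
                           added_salt_mM = NULL) {
  if (!recipe %in% names(EXPERIMENT_RECIPES)) {
    stop("unknown recipe '", recipe, "'; valid: ",
         paste(names(EXPERIMENT_RECIPES), collapse = ", "), call. = FALSE)
  }
  rc <- EXPERIMENT_RECIPES[[recipe]]
  n_steps <- max(1000L, as.integer(round(rc$base_steps * scale)))
  if (is.null(stride)) stride <- max(1L, n_steps %/% 500L)
  box <- 400
  one <- make_synthetic_ncp(seed = seed)
  model <- replicate_ncp_model(one, rc$n_ncp, box, seed = seed + 1)
  salt <- if (!is.null(added_salt_mM)) added_salt_mM
  else if (!is.null(rc$salt_mM)) rc$salt_mM[1] else 0
  model <- place_counterions(model, rc$species, box, seed = seed + 2,
                             added_salt_mM = salt)
  ffp <- ff_params()
  if (relax) {
    r <- minimize_model(model, box_edge = box, maxit = 300)
    model$beads$x <- r$positions[, 1]
    model$beads$y <- r$positions[, 2]
    model$beads$z <- r$positions[, 3]
  }
  sp <- sim_params(n_steps = n_steps, box_edge = box, seed = seed + 3,
                   stride = stride)
  traj <- run_simulation(model, ffp, sp)
  prod <- equilibration_split(traj, equil_fraction)$production
  core_groups <- lapply(seq_len(model$n_ncp), function(k)
    model$groups[[if (model$n_ncp == 1) "core" else paste0("core_", k)]])
  analysis <- list(
    dna_distances = distance_distributions(prod, model),
    core_ion_rdf = rdf(prod, core_groups, model$groups$ions, bin_width = 0.2),
    temperature = glance(traj))
  if (model$n_ncp > 1) {
    analysis$core_core_rdf <- rdf(prod, core_groups, core_groups,
                                  bin_width = 0.2)
    analysis$stacking <- stacking_pairs(prod, model)
  } else {
    sel <- which(model$beads$role != "ion")
    analysis$pr <- pr_rg_dmax(prod, sel)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("nucleocg")),
    recipe = recipe, scale = scale, scaled_down = scale < 1,
    seed = seed, n_steps = n_steps, stride = stride, box_edge = box,
    n_ncp = rc$n_ncp, species = rc$species, added_salt_mM = salt,
    n_ions = length(model$groups$ions),
    equil_fraction = equil_fraction,
    ff = unclass(ff_params())[c("epsilon_r", "sigma", "epsilon_lj",
                                "temperature_K", "coulomb_cutoff",
                                "electrostatics")])
  manifest$config_hash <- .config_hash(manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_topology(model, file.path(out_dir, "model.top"))
    write_trajectory(traj, file.path(out_dir, "traj.xyz"),
                     labels = model$beads$role)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(kinetic_temperature(traj),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  list(model = model, trajectory = traj, analysis = analysis,
       manifest = manifest)
}

.config_hash <- function(x) {
  x$config_hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
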