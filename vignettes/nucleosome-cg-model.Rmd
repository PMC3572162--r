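---
title: "A coarse-grained nucleosome core particle model with explicit mobile ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained nucleosome core particle model with explicit mobile ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleocg)
```

## The model

The nucleosome core particle (NCP) — 145–147 bp of DNA wrapped as a 1.75-turn
left-handed superhelix around a histone octamer — is the repeating unit of
chromatin, and nucleosome–nucleosome interactions under varying ionic
conditions control its higher-order folding. Because the NCP is a strongly
charged polyelectrolyte (−150e net), those interactions are dominated by
long-range electrostatics, mobile-ion correlations and the flexible,
positively charged histone tails. `nucleocg` implements a bead-resolution
model that keeps all three ingredients explicit:

* **Octamer core.** One bead per globular amino acid (710 beads). Charges
  follow residue identity: +1e for lysine/arginine, −1e for
  aspartate/glutamate, 0 otherwise, giving 116 positive, 64 negative and 530
  neutral beads (+52e). The fold is held near its reference geometry by an
  elastic network: every bead is bonded to its three nearest neighbours with
  `k_b` = 5 kT/Å² at the reference distance, which leaves thermal bond
  fluctuations of √(kT/k_b) ≈ 0.45 Å while the core moves as one body.
* **Histone tails.** Ten flexible chains (two copies each of the H2A and
  H2B/H3/H4 N-tails and the short H2A C-tail; 20/35/43/24/13 beads per copy,
  270 beads, +94e total), one bead per residue, 3.25 Å bonds
  (`k_b` = 5 kT/Å²). Charged tail beads carry a 0.6 Å hard radius; neutral
  ones 0.
* **DNA.** 74 units of two base pairs each: a central bead D (bases + sugars,
  hard radius 4 Å, mass 4) and four phosphates (−1e, hard radius 1 Å) on two
  helical strands, 6.8 Å rise and 72° twist per unit, with a bond/angle table
  that maintains the B-form duplex (D–P 9.62 Å; strand P–P 6.75 Å;
  minor-groove P–P 13.2 Å; D-D-D 180°; strand angles 149°; P-D-P 140°).
  The duplex is wrapped on a 1.75-turn superhelix and each D bead is linked
  to its nearest core bead (`k_b` = 5 kT/Å²) at the construction distance.
  One NCP totals 1350 beads, −150e.
* **Nonbonded interactions.** A continuum dielectric (ε = 78) Coulomb term,
  `U = l_B q_i q_j / r` in kT with the Bjerrum length `l_B` = 7.189 Å at
  298 K, plus a purely repulsive truncated-and-shifted Lennard-Jones acting
  on the hard-core-shifted distance `x = r − (R_i + R_j)` with σ = 4 Å and
  ε_LJ = 1 kT, cut at `x = 2^{1/6}σ`. Effective radii are thus
  `R_i` + 2 Å. Mobile ions are explicit beads: K⁺ (R = 0), Mg²⁺ (0.5 Å),
  CoHex³⁺ (1.5 Å), Cl⁻ (0, a choice — no co-ion radius is published).
* **Dynamics.** Langevin dynamics (BAOAB splitting of velocity Verlet) with
  reduced units (kT = 1, masses 1 except D beads at 4), time step 0.01 and a
  deliberately weak friction γ = 0.01: only equilibrium averages are sought,
  and weak coupling samples configuration space faster. Periodic cubic cell,
  default 40 nm.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `epsilon_r` | 78 | — | solvent dielectric constant |
| `sigma` | 4 | Å | soft repulsion length (effective radius σ/2 per bead) |
| `epsilon_lj` | 1 | kT | repulsion strength |
| `temperature_K` | 298 | K | enters only through `l_B` |
| `coulomb_cutoff` | 30 | Å | real-space electrostatics range |
| `electrostatics` | `"cutoff"` | — | `cutoff`, `ewald`, `direct`, `none` |
| `dt` | 0.01 | reduced | integration step |
| `gamma` | 0.01 | reduced | thermostat friction |
| `box_edge` | 400 | Å | periodic cell |

Counterion counts are never free parameters: `place_counterions()` adds
exactly `|charge| / valence` ions (150 K⁺, 75 Mg²⁺ or 50 CoHex³⁺ per NCP;
500 CoHex³⁺ for ten NCPs), optionally plus KCl pairs at a stated mM.

## Numerical choices

**DNA unit geometry.** The published bond table over-determines the
phosphate placement (16 bonded constraints per 12 phosphate coordinates per
unit), so the unit geometry is obtained by minimizing the helical bonded
energy under the exact 72°/6.8 Å screw symmetry, seeded from the analytic
B-form construction (phosphate radius √(9.62² − 1.7²) = 9.47 Å, cross-strand
azimuth from the ideal 18.2 Å same-base-pair separation). The residual is
below 0.01 kT per unit; the emergent cross-strand distance is 18.06 Å
(ideal B-form: 18.2 Å). A finite duplex additionally relaxes a soft
long-wavelength end mode (global RMSD ≈ 0.5 Å at fixed local geometry —
every bonded distance moves by < 0.02 Å); this is a generic property of
over-determined elastic networks, not a construction error.

**Superhelix.** The wrap radius follows from the chord constraint
(74 beads, 6.8 Å spacing, 1.75 turns, 27 Å pitch → R ≈ 45 Å); unit frames
are carried along the path by parallel transport plus the 72°/unit twist, so
strand continuity matches the straight build exactly.

**Repulsion inside contact.** Below a cap point (energy 100 kT) the WCA
branch continues linearly, so random initial ion placements can never
produce non-finite forces; minimization removes the capped contacts before
production dynamics. Directly bonded pairs are excluded from the repulsion
(several equilibrium distances lie below contact) but kept in the Coulomb
sum; both switches are exposed.

**Electrostatics.** Production runs use a truncated-and-shifted minimum-image
Coulomb sum (30 Å). The package also implements the classical Ewald
summation (real + reciprocal space, accuracy-targeted splitting), which
reproduces the rock-salt Madelung constant to 10⁻⁸ and serves for
periodic-accuracy work; it is exact but too costly per step for routine
desk-scale dynamics. The truncation approximation is adequate for the
short-range structural observables validated here (bond statistics, DNA
geometry, core stability, near-field ion condensation); long-range
ion–NCP correlation features at tens of nanometres are outside its reach,
which is one reason full-scale NCP–NCP aggregation runs are not attempted at
desk scale.

**Estimators.** P(r) is the equal-weight histogram of all intra-particle
pair distances (no scattering form factors — the reference comparisons are
of shapes and trends); `Rg² = (N−1)/(2N) ∫P(r) r² dr`, where the finite-N
factor makes the estimator exact at all N and tends to the SAXS convention
½ for large N. `Dmax` is the smallest r beyond which P stays under 10⁻³ of
its maximum (1 Å bins); the sub-threshold far tail is zeroed and the curve
renormalized so `P(r > Dmax) = 0` holds exactly. RMSD uses Kabsch/SVD
optimal superposition. RDF normalization is by shell volume against the
mean partner density, so an ideal gas gives g ≡ 1. SDFs are number densities
binned in a body-fixed frame built from three maximally separated core
beads chosen at build time (the frame-site choice is a convention; any
non-collinear triple gives the same invariances). The dyad axis is taken
through the stored dyad reference sites (the mid-DNA central bead and the
centre-most core bead); stacking classification uses the superhelix axis
(smallest-spread principal axis of the D beads), with "stacked" within 30°
of parallel and "perpendicular" within 30° of orthogonal at core-centre
distances below 7 nm — thresholds that mirror the ~6 nm and ~8 nm contact
classes of condensed NCP phases, and configurable.

## The synthetic generator

`make_synthetic_ncp()` emulates the crystal-derived construction without any
input file: 710 core beads fill a wedge-shaped cylinder (radius 33 Å, height
52 Å, 15% wedge) by a low-discrepancy Halton stream with a 3 Å
minimum-separation filter (keeps elastic-network bonds in a physical range);
charges are assigned to the exact 116/64/530 inventory with positives biased
towards the surface (the DNA-facing charge mosaic); tail anchor points sit
between the DNA gyres (H3, H2B, H2A-C) and on the flat faces (H4, H2A), as
in the crystal structure. Synthetic tail sequences reproduce each tail's
length and net charge (+8/+12/+14/+9/+4 per copy — our estimates from the
histone sequences; they sum to the published +94e). Builds are
deterministic per seed.

What the generator does **not** emulate: the true spatial correlations of
the crystallographic charge mosaic (only its radial bias), sequence-specific
DNA mechanics, and the exact anchor geometry. Tests passing on synthetic
models therefore validate inventory, topology, energetics and estimator
correctness — not crystallographic detail. The PDB build path applies the
identical construction rules to a real structure when one is available; the
two paths are cross-checked structurally in the test suite.

## Scaled-down study conditions

The reference protocol runs 10⁸ steps for one NCP and 2.5×10⁹ for ten (the
first 40% discarded). Desk-scale runs in this package use the same model,
thermostat and compositions at reduced length: the acceptance script runs
one NCP + 50 CoHex³⁺ for 10⁵ steps (frames every 200, first 40% discarded)
and a bonded pair for 6×10⁶ steps; the test suite uses 2.5–4×10⁴-step NCP
runs. These lengths converge the local observables reported (bond-length
statistics equilibrate over ~1/γ = 10⁴ steps; DNA geometry and core RMSD
plateaus are reached well inside the production window). Slow collective
phenomena — ten-NCP aggregation, RDF peak structure at tens of nanometres,
added-salt conformational series — require the full protocol and are
deliberately not claimed at desk scale. What the reduced runs do verify is
the screening mechanism behind the salt-dependence: counterion condensation
around a single NCP (held at the ten-NCP number density, i.e. a 200 Å cell)
is markedly stronger for multivalent than for monovalent cations. The
Mg²⁺-vs-CoHex³⁺ distinction in aggregation behaviour is a collective
ion-correlation effect of NCP–NCP contact regions and cannot be read off
single-NCP condensed fractions; it is left to full-scale simulation.

## Known limitations

* No attractive dispersion, hydrogen bonding or solvent-structure
  oscillations — interactions are Coulomb + excluded volume only.
* DNA is permanently bonded to the core: no breathing or unwrapping.
* Truncated Coulomb in production dynamics (see above); Ewald is available
  but slow for large systems.
* The reduced time unit has no calibrated physical mapping; only equilibrium
  properties are meaningful.
* Single-structure tail/core split by residue ranges; no histone variants or
  post-translational modifications.

## A short worked run

```{r example, eval = FALSE}
model <- make_synthetic_ncp(seed = 1)
system <- place_counterions(model, "CoHex", box_edge = 400, seed = 2)
relaxed <- minimize_model(system, box_edge = 400, maxit = 300)
system$beads[, c("x", "y", "z")] <- as.data.frame(relaxed$positions)

traj <- run_simulation(system, ff_params(),
                       sim_params(n_steps = 1e5, stride = 200, seed = 3))
prod <- equilibration_split(traj, 0.4)$production

distance_distributions(prod, system)
rmsd_trace(prod, relaxed$positions, system$groups$core)
autoplot(rdf(prod, list(system$groups$core), system$groups$ions))
```
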