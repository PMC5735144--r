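---
title: "End-point binding free energies with interaction entropy: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-point binding free energies with interaction entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iebind)
```

## The model

`iebind` post-processes solute-only molecular dynamics snapshots of a
protein–ligand complex into an end-point (MM/PBSA-style) estimate of the
binding free energy,

$$\Delta G_{bind} = \Delta G_{gas} + \Delta G_{sol}, \qquad
  \Delta G_{gas} = \langle E^{int}_{pl}\rangle - T\Delta S, \qquad
  \Delta G_{sol} = \Delta G_{pb} + \Delta G_{np},$$

where $\langle E^{int}_{pl}\rangle$ is the trajectory average of the
protein–ligand Coulomb plus Lennard-Jones interaction energy, $-T\Delta S$
is the entropic contribution, $\Delta G_{pb}$ the polar solvation term, and
$\Delta G_{np}$ the nonpolar solvation term. Of these four, the package
computes three; $\Delta G_{pb}$ requires a Poisson–Boltzmann solver and is
accepted as an external per-frame input, as are normal-mode entropy values
when the user prefers them to the interaction-entropy estimator. The
recorded dielectric constants (80 exterior / 1 interior) are provenance for
such inputs, not something the package uses.

Two aggregation schemes are supported. The **single-trajectory** scheme
estimates every component from the complex trajectory alone; it treats the
complex as a rigid body, so the internal (strain) energy change is
identically zero and `fe_combine()` enforces that. The
**triple-trajectory** scheme differences per-species components from
independent complex, protein and ligand trajectories
($\Delta X = X_{complex} - X_{protein} - X_{ligand}$); the internal energy
change $\Delta E_{int}$ that appears there involves bonded terms that
cannot be derived from inter-group energies, so it is an opaque external
input to `triple_scheme()`.

### Interaction entropy

The entropic contribution is estimated from the fluctuations
$\Delta E = E - \langle E\rangle$ of the sampled interaction energy:

$$-T\Delta S = kT \ln \langle e^{\beta \Delta E}\rangle, \qquad
  \beta = 1/kT,$$

with both averages over the same frames. This is a reweighting-style
exponential average: it is nonnegative for every input series (Jensen's
inequality), invariant under an additive shift of the energies, and, for
Gaussian fluctuations of standard deviation $\sigma$, converges to the
closed form $\sigma^2 / (2kT)$ — the parameter-recovery oracle used in the
test suite. The average is always evaluated in the log domain with a
max-exponent shift, so fluctuations of hundreds of $kT$ cannot overflow;
for series whose exponent spread stays within ~10 units the log-domain
result agrees with naive exponentiation to $10^{-10}$.

The estimator has a well-known sampling pathology: the number of frames
needed grows explosively with $\sigma/kT$. Rather than hiding this,
`interaction_entropy()` warns when the sample SD exceeds $2kT$
(≈ 1.19 kcal/mol at 300 K), and `block_sd()` provides a simple contiguous
block standard deviation as an uncertainty. `running_convergence()` exposes
the running mean energy and running entropy so convergence can be judged
the usual way, by eye, against the sampled window.

Constants: $k = 0.0019872041$ kcal/(mol K) and $T = 300$ K by default,
giving $kT = 0.59616$ kcal/mol; both are user-visible in
`thermo_params()` and the config file, since published analyses rarely
state their precise constants.

### Nonbonded energies

`intergroup_energy()` sums Coulomb
($k_e q_i q_j / r_{ij}$, $k_e = 332.0637$ kcal Å/(mol e²)) and
Lennard-Jones
($4\epsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} - (\sigma_{ij}/r_{ij})^6]$)
terms over protein × ligand atom pairs with Lorentz–Berthelot combining.
Only inter-group pairs enter: the two groups share no bonds, so no 1–4
exclusion bookkeeping is needed. There is no cutoff by default — end-point
post-processing operates on the stripped solute, where the all-pairs sum is
cheap and exactly reproducible; a spherical cutoff flag exists for
sensitivity checks. Periodic electrostatics (Ewald/PME) are deliberately
out of scope. Parameters are stored in the $(\sigma, \epsilon)$ convention;
AMBER-style $R_{min}/2$ inputs must be converted by the user beforehand,
because silently guessing the convention is worse than requiring one.

`residue_decomposition()` attributes the inter-group energy to
residue–ligand pairs by accumulating the same pair energies per protein
residue; the residue totals therefore sum to the mean total exactly, which
the tests assert to $10^{-6}$. Note what this is: an exact decomposition of
the molecular-mechanics interaction energy. A per-residue split of the
*polar solvation* term would need the PB solver's decomposition machinery
and is not attempted; the nonpolar term is attributed per residue by each
residue's share of buried surface area (`attribute_np_per_residue()`),
with the constant offset reported separately rather than smeared across
residues.

### Surface area and the nonpolar term

`sasa()` implements Shrake–Rupley: per atom, quadrature points on the
expanded sphere (van der Waals radius + probe, probe 1.4 Å by default) are
classified accessible when outside every neighbour's expanded sphere. Two
numerical choices matter:

* **Deterministic quadrature.** Points lie on a Fibonacci spiral (960 per
  atom by default; halving the spacing changes a 10-atom fixture's total by
  < 0.5 %), so results are bit-reproducible — no random rotations.
* **Molecule-anchored grid.** The grid is oriented by a deterministic
  molecule-internal frame (first axis towards the atom farthest from the
  centroid, second towards the atom farthest from that axis). Because the
  frame is built from rotation-covariant quantities, the whole estimate is
  exactly invariant under rigid motion of the input, not merely up to
  quadrature error. `delta_sasa_per_atom()` reuses the complex's frame for
  the isolated-species evaluations, so atoms whose burial is unchanged by
  complexation contribute exactly zero to ΔSASA.

The nonpolar term is the standard linear law
$\Delta G_{np} = \gamma \cdot \Delta SASA + \beta$ with
$\gamma = 0.00542$ kcal/(mol Å²) and $\beta = 0.92$ kcal/mol. The offset is
applied **once per evaluation**, not once per species: the law is applied
to the binding quantity $\Delta SASA$, and applying the constant to each of
the three species would triple-count it (the `beta_per_species` flag
provides that alternative reading, which amounts to $-\beta$). Atomic
radii default to a conventional element table (C 1.7, N 1.55, O 1.52,
H 1.2, S 1.8, P 1.8 Å) and are overridable, since surface programs differ
in their radii sets; `radii_source = "topology_sigma"` derives radii from
the Lennard-Jones minima instead.

### Structural diagnostics

* **RMSD** (`rmsd_backbone()`): each frame's selection (protein N/CA/C by
  default) is superposed on the reference by the closed-form optimal
  rotation (Kabsch, via SVD with the determinant sign fix) before the
  deviation is measured. The implementation is cross-checked in the tests
  against `bio3d`'s independent superposition.
* **B-factors** (`b_factor()`): frames are superposed onto their mean
  structure, the mean recomputed and the fit repeated (two passes — a
  third pass changes nothing detectable on converged ensembles), then
  $B_i = (8\pi^2/3)\,\langle|r_i - \langle r_i\rangle|^2\rangle$. The
  $8\pi^2/3$ constant makes the output directly comparable to
  crystallographic B columns. A separate `fit_selection` lets rigid
  anchors define the superposition so that a mobile atom's fluctuation is
  not partially absorbed by the fit.
* **Hydrogen bonds** (`hbond_stats()`): a bond is formed when the
  donor–acceptor heavy-atom distance is ≤ 3.5 Å and the
  donor–hydrogen–acceptor angle is ≥ 120°. The angle vertex is the
  hydrogen: with a ~1 Å covalent D–H bond and ~2.8–3.0 Å heavy-atom
  separations, the D–H–A angle of a real hydrogen bond lives in the
  120–180° band that such a cutoff selects, whereas the donor-vertex angle
  would be small (≲ 30°); a flag selects the donor-vertex convention for
  comparison with tools that use it. Mean distance/angle are averaged over
  all frames by default (a `mean_over = "formed"` flag restricts to formed
  frames, since published tables rarely state which convention they use).
* **Fractional native hydrogen bonds** (`native_hbond_fraction()`):
  donors are protein N/O atoms with a hydrogen within 1.2 Å, acceptors any
  other protein N/O; the triples satisfying the criteria in the native
  frame define the native set, and each trajectory frame reports the
  surviving fraction. Detection is purely geometric — no bonded topology
  is consulted — which keeps the reader-independent of force-field file
  formats at the price of counting any geometrically plausible triple.

## The synthetic-data generators

The package replaces MD trajectories with three seeded generators, each
built to have exactly the statistical structure one analysis stage assumes:

* `generate_gaussian_series()` draws i.i.d. Normal energy fluctuations
  (optionally AR(1) with chosen lag-one autocorrelation, to probe the IE
  estimator under correlated sampling — real interaction energies are
  autocorrelated on the ps scale, and the i.i.d. oracle is silent about
  that). The Gaussian choice is what makes an *exact* entropy oracle
  ($\sigma^2/2kT$) available.
* `generate_toy_complex()` builds a minimal polar "protein" (three atoms
  per residue: donor N, its H, acceptor O, residues 12 Å apart) plus a
  three-atom ligand, with each residue's designed hydrogen bond placed at
  2.8 Å / 165° when formed and 5.0 Å (or 90°) when broken — comfortably
  inside/outside the 3.5 Å / 120° criteria, so occupancy equals the
  schedule exactly. Gaussian jitter and cumulative rigid motion are
  applied on top, in that order, for B-factor and superposition tests.
* `generate_component_table()` draws snapshot-group component sets around
  fixed means with known SDs, emulating the
  20-groups-of-100-snapshots procedure used to attach standard deviations
  to published component tables; its defaults are the reported spread for
  a trypsin–benzamidine complex under an additive charge model
  (±6.94, ±3.03, ±6.09, ±2.12 kcal/mol for the electrostatic, van der
  Waals, solvation and entropy components).

What passing on these fixtures does **not** show: correctness on real
force fields (no bonded terms, no 1–4 scaling, no PME), robustness to
autocorrelated energies beyond the AR(1) probe, or agreement with any
particular PB solver or surface program. Trajectory-dependent published
values (mean RMSDs, occupancy percentages, component means) cannot be
recomputed without the original multi-hundred-ns simulations; the package
treats them strictly as fixed inputs to the bookkeeping layer, which the
acceptance checks reproduce to ±0.005 kcal/mol.

## Numerical and design choices, collected

* Sample SDs use the $n-1$ denominator throughout (`group_std()`,
  `block_sd()`); published tables rarely state the convention, and $n-1$
  is the standard choice at small group counts.
* Snapshot groups for the group-SD procedure are disjoint contiguous
  blocks; how published analyses positioned their groups is unstated, and
  contiguous blocks are the conservative choice under autocorrelation.
* Frame times are taken from the input file as-is; nothing assumes a
  uniform stride, because mixed-stride trajectory windows exist in
  practice.
* The trajectory interchange format is multi-model PDB (read through
  `bio3d`); coordinates there carry three decimals, so round-trips are
  exact only to 10⁻³ Å — the plain coordinate-table dialect round-trips to
  full precision and is what the generators use internally.
* The topology is a self-contained delimited table (charges, LJ, masses,
  groups) rather than a force-field file parser: the analyses need
  exactly those per-atom quantities and nothing else, and alternative
  charge sets (e.g. polarised protein-specific charges) are then just
  alternative tables.
* Degenerate inputs fail loudly with typed conditions: coincident
  interacting atoms, zero-frame trajectories, non-monotonic times,
  sub-3-atom superposition selections, an empty native hydrogen-bond set.

## Problem sizes

The test suite and the reproduction script run at deliberately desk-scale
sizes: 10⁶-frame series for the entropy oracle (where the closed form is
sharp), 10⁴ frames for B-factor recovery (Monte-Carlo error ≈ 1 %),
≤ 15-atom toy complexes for geometry, energy and surface checks (where
brute-force oracles are exact), and 20-group component tables for the
spread-recovery checks. These sizes were chosen so each check's tolerance
is dominated by its statistics, not by runtime convenience at larger n.

## Known limitations

* No polar solvation: $\Delta G_{pb}$ is an input, full stop.
* No entropy beyond IE: normal-mode values are inputs.
* The IE estimator's variance grows rapidly for $\sigma \gtrsim 2kT$;
  the warning and `block_sd()` surface this but do not fix it.
* Hydrogen-bond detection is geometric; protonation states and bonded
  topology are not consulted.
* SASA is solvent-accessible area only — no molecular (Connolly) surface,
  and no cavity/dispersion split of the nonpolar term.
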