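# iebind

End-point binding free energy analysis of protein–ligand complexes from
molecular dynamics snapshots, for computational chemists and structural
bioinformaticians who post-process solute-only trajectories rather than run
the simulations inside R.

The package assembles the MM/PBSA-style ledger

```
ΔG_bind = ΔG_gas + ΔG_sol
ΔG_gas  = ⟨E_int_pl⟩ − TΔS
ΔG_sol  = ΔG_pb + ΔG_np,     ΔG_np = γ·ΔSASA + β
```

and supplies three of the four ingredients itself:

* **⟨E_int_pl⟩** — per-frame Coulomb + Lennard-Jones protein–ligand
  interaction energies from a lightweight topology table (charges, σ/ε,
  group labels), with an exact per-residue decomposition
  (`compute_energy_series()`, `residue_decomposition()`);
* **−TΔS** — the interaction-entropy estimator
  `−TΔS = kT ln⟨exp(βΔE)⟩` computed from the energy fluctuations along the
  trajectory, in the log domain so large fluctuations cannot overflow, with
  running-convergence and block-SD diagnostics (`interaction_entropy()`);
* **ΔG_np** — Shrake–Rupley solvent-accessible surface area on a
  deterministic, rigid-motion-invariant quadrature grid, mapped through the
  linear law with γ = 0.00542 kcal/(mol Å²), β = 0.92 kcal/mol
  (`sasa()`, `delta_g_np()`).

Polar solvation (ΔG_pb, from a Poisson–Boltzmann solver) and normal-mode
entropies are accepted as external inputs. Aggregation supports both the
single-trajectory (rigid-body) and triple-trajectory schemes plus
snapshot-group standard deviations (`single_scheme()`, `triple_scheme()`,
`group_std()`), and trajectory stability diagnostics are included:
superposed backbone RMSD, B-factors, hydrogen-bond occupancy, and
fractional native hydrogen bonds. Seeded generators
(`generate_gaussian_series()`, `generate_toy_complex()`,
`generate_component_table()`) produce synthetic inputs with exactly the
statistical structure each stage assumes, so the whole pipeline is testable
without an MD engine.

## Worked example

Build a toy complex with three designed hydrogen bonds and a little thermal
jitter, then run the single-trajectory pipeline over it:

```r
library(iebind)

toy    <- generate_toy_complex(3, 50, jitter_sigma = 0.05, seed = 11)
series <- compute_energy_series(toy$topology, toy$trajectory)
series
#> <energy_series> 50 frames, <E> = -55.381 kcal/mol (ele -55.305, vdw -0.077)

ie <- interaction_entropy(series)
ie
#> <ie_result> N = 50, <E> = -55.3814 kcal/mol, -TdS = 0.1178 kcal/mol (T = 300 K)

np <- delta_g_np(toy$topology, toy$trajectory)
np$delta_g_np
#> [1] 0.9020347

single_scheme(series, g_pb_series = 12.0, g_np = np$delta_g_np, entropy = ie)
#> <fe_breakdown> scheme = single, entropy = IE
#>   e_ele              -55.3048 kcal/mol
#>   e_vdw               -0.0766 kcal/mol
#>   e_internal           0.0000 kcal/mol
#>   g_pb                12.0000 kcal/mol
#>   g_np                 0.9020 kcal/mol
#>   g_sol               12.9020 kcal/mol
#>   minus_t_delta_s      0.1178 kcal/mol
#>   g_gas              -55.2635 kcal/mol
#>   g_bind             -42.3615 kcal/mol
```

Reading the numbers: the net-positive toy ligand sits in a pocket of
net-negative polar residues, so the mean interaction energy is strongly
attractive (−55.4 kcal/mol, almost all electrostatic). Its fluctuations are
small relative to kT, so the interaction entropy penalty is tiny
(+0.12 kcal/mol) — on a real trajectory with several-kcal/mol fluctuations
this term grows to tens of kcal/mol and dominates the gap between entropy
methods. The external polar-solvation input (here a placeholder
12.0 kcal/mol) and the computed nonpolar term (+0.90 kcal/mol: only 3.3 Å²
of surface is buried in this open toy geometry, so the constant β
dominates) oppose binding, leaving ΔG_bind = −42.4 kcal/mol, the sum the
`fe_breakdown` identities guarantee to 10⁻⁹.

The stability layer on the same object:

```r
hbond_stats(toy$trajectory, toy$topology, toy$native_hbonds)$summary
#>          label mean_distance mean_angle occupancy
#> 1 TOY0 N-H...O      2.797530   165.0892         1
#> 2 TOY1 N-H...O      2.797622   163.2126         1
#> 3 TOY2 N-H...O      2.805713   163.3236         1

residue_decomposition(toy$topology, toy$trajectory)
#>   residue_index residue_name      e_ele         e_vdw    e_total
#> 1             0          TOY -32.472691 -7.592313e-02 -32.548614
#> 2             1          TOY -14.787015 -6.672747e-04 -14.787682
#> 3             2          TOY  -8.045051 -1.727106e-05  -8.045068
```

All three designed bonds stay formed under the 3.5 Å / 120° criteria
(occupancy 1), and the residue spectrum decays with distance from the
ligand while summing exactly to the mean total (−55.38 kcal/mol).

A thin command-line front end (`exec/iebind`) exposes the same pipeline as
subcommands (`simulate`, `energy`, `entropy`, `sasa`, `aggregate`,
`hbonds`, `rmsd`, `bfactor`, `decompose`); see `?iebind_cli`.

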