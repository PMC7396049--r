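# aquaflux

Water permeation analysis for channel-protein molecular dynamics
trajectories.

Aquaporins conduct water passively through a narrow pore whose energetics
set the permeation rate. Given an equilibrated MD trajectory, the standard
desk analysis is: project the water oxygens onto the channel axis, bin them
into slabs of width Δz, time-average the per-slab counts

&nbsp;&nbsp;&nbsp;&nbsp;N(z_i) = (1 / n_frames) Σ_j N(z_i, t_j),&nbsp;&nbsp;&nbsp;ρ(z_i) = N(z_i) / Δz,

and invert the density by the Boltzmann relation ρ(z) ∝ exp(−ΔG(z)/k_BT)
into a free-energy profile relative to a reference bin z_A:

&nbsp;&nbsp;&nbsp;&nbsp;ΔG(z_i) = k_B T · ln( ρ(z_A) / ρ(z_i) ),&nbsp;&nbsp;&nbsp;ΔG(z_A) = 0,

with a ±k_BT band per point (±2 k_BT on any difference of two points). The
maximum of ΔG inside the channel is the permeation barrier, which in
aquaporins sits at the selectivity filter (SF), the narrowest constriction
of the pore.

`aquaflux` implements this pipeline for anyone analysing channel
trajectories in R, together with the surrounding stages of a permeation
study:

* **trajectory I/O** — multi-MODEL PDB and multi-frame XYZ reading/writing,
  atom selections (`all`, `heavy`, `protein`, `sidechain`, `water_oxygen`);
* **water analysis** — the density profile above
  (`density_profile()`, radially gated by a counting cylinder) and
  single-file water-wire detection (`detect_single_file()`);
* **free energy** — `boltzmann_invert()`, `thermal_energy()`,
  `difference_error()`, `extract_barrier()`;
* **channel geometry** — a probe-sphere pore-radius profile with SF
  localization (`pore_radius_profile()`) and zoning of pore-lining residues
  into extracellular vestibule / NPA region / cytoplasmic side
  (`zone_lining_residues()`);
* **structure metrics** — Kabsch superposition, RMSD time series and
  sliding-window equilibration detection (`kabsch_superpose()`,
  `rmsd_series()`, `detect_equilibration()`);
* **synthetic data** — a seeded generator of water trajectories whose
  ground truth is known exactly (`channel_scenario()`,
  `sample_boltzmann_trajectory()`, `simulate_langevin_1d()`, plus geometry
  fixtures), so every stage is testable by parameter recovery;
* **pipeline** — `run_analysis()` / `run_synthetic()` orchestrate
  everything from a YAML/JSON config into a directory of CSV/JSON reports.

Results are tibbles with `tidy()`, `glance()` and `autoplot()` methods, so
they drop straight into dplyr/ggplot2 workflows.

## Worked example

Generate a 298 K scenario with a known 2.5 kcal/mol Gaussian barrier at the
selectivity filter, then recover it with the analysis pipeline:

```r
library(aquaflux)

sc <- channel_scenario(
  potential = potential_gaussians(height = 2.5, center = 0, sigma = 2),
  box_z = c(-40, 40), temperature = 298,
  n_waters = 5000, n_frames = 100, seed = 42)
traj <- sample_boltzmann_trajectory(sc)
traj
#> <trajectory: 5000 atoms, 100 frames, 99.0 ps>
#>   waters: 5000; elements: O

dens <- density_profile(traj, scenario_spec(sc), dz = 1, z_range = c(-40, 40))
glance(dens)
#> # A tibble: 1 × 6
#>   n_bins    dz n_frames   t_f    dt mean_total_waters
#>    <int> <dbl>    <int> <dbl> <dbl>             <dbl>
#> 1     80     1      100    99     1              5000

fep <- boltzmann_invert(dens, z_A = -30, temperature = 298)
extract_barrier(fep)
#> # A tibble: 1 × 6
#>   barrier_height barrier_z dG_sf  sf_z   z_A baseline
#>            <dbl>     <dbl> <dbl> <dbl> <dbl> <chr>
#> 1           2.47      -0.5    NA    NA -30.5 dG relative to reference bin z_A (…
```

The recovered barrier (2.47 kcal/mol at z ≈ 0) matches the imposed
2.5 kcal/mol to well within the ±k_BT = ±0.59 kcal/mol thermal band that
`thermal_energy(298)` attaches to every point of the profile;
`autoplot(fep)` draws the profile with that band.

The canonical single-file water wire — oxygens 2.8 Å apart along the axis —
holds exactly seven waters inside the −10 Å < z < 10 Å channel:

```r
wire <- build_single_file_fixture(spacing = 2.8, z_extent = c(-40, 40))
detect_single_file(wire, channel_spec(), hb_cutoff = 3.5)
#> # A tibble: 1 × 4
#>   frame  time n_file chain_z
#>   <int> <dbl>  <int> <list>
#> 1     0     0      7 <dbl [7]>
```

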