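---
title: "Water permeation energetics from channel trajectories: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water permeation energetics from channel trajectories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

## The model

`aquaflux` analyses water permeation through a channel protein whose pore
runs approximately along one axis. The channel is abstracted as a
`channel_spec()`: a unit axis vector and anchor point, an axial extent
`[z_lo, z_hi]` (default −10..10 Å, the span of an aquaporin's single-file
region), a counting-cylinder radius, and a declaration of which end faces
the extracellular medium.

Three physical quantities are computed from a trajectory:

1. **Water density.** For bins of width Δz tiling a chosen axial range,
   `density_profile()` counts the water oxygens per bin and frame, averages
   over frames, and divides by Δz. Two conventions are deliberate and
   documented rather than configurable facts of nature:
   * a water *is* its oxygen atom — the molecule's reference point is not
     otherwise defined;
   * a water only counts if it also lies within the counting cylinder
     (default radius 6 Å). Counting "per slab" with unbounded x, y would
     let the bulk reservoir, which spans the whole box cross-section,
     swamp the channel occupancy by orders of magnitude. The radius is a
     first-class parameter of `channel_spec()` because it defines what
     "the channel region" means for a given system.

2. **Free energy.** In an equilibrated isothermal ensemble the density is
   proportional to the Boltzmann weight, so
   `boltzmann_invert()` computes ΔG(z_i) = k_BT·ln(ρ(z_A)/ρ(z_i)) with
   k_B = 0.0019872041 kcal/(mol·K). The reference bin z_A gets exactly 0
   (assigned, not computed through `log`, so it is bitwise zero). Each
   point carries a ±k_BT band — the thermal fluctuation scale inherent to
   a finite equilibrium sample, about ±0.6 kcal/mol at 298 K — and any
   difference of two points carries ±2·k_BT (about ±1.2 kcal/mol), since
   two such measurements are subtracted. `extract_barrier()` reports the
   maximum unmasked ΔG inside the channel extent and its location; because
   the question "barrier at the selectivity filter" admits two readings,
   it can also report ΔG at a user-supplied SF position (e.g. the minimum
   of the pore-radius profile) alongside the channel-wide maximum.

3. **Geometry and equilibration.** `pore_radius_profile()` slices the
   channel and fits the largest probe sphere that touches no atom
   (center distance < probe + van der Waals radius);
   `zone_lining_residues()` classifies residues near the axis into
   extracellular vestibule, NPA region or cytoplasmic side;
   `rmsd_series()` + `detect_equilibration()` decide when the structure
   reached a conformational steady state.

## Defaults and why

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| channel extent | −10..10 | Å | span of the single-file region in aquaporins |
| counting radius | 6 | Å | wide enough to hold the pore and vestibule waters, narrow enough to exclude bulk |
| density Δz | 1 | Å | ≈ one third of a water–water spacing; bins stay well populated |
| temperature | 298 | K | standard laboratory conditions of the simulations analysed |
| hb_cutoff | 3.5 | Å | conventional O–O hydrogen-bond distance cutoff |
| pore Δz | 0.5 | Å | resolves the SF constriction without empty slices |
| max_probe | 10 | Å | caps the radius where the pore opens into bulk |
| contact_cutoff | 4.0 | Å | heavy-atom contact distance for "pore-lining" |
| npa_window | −5..5 | Å | mid-channel location of the paired NPA motifs |
| RMSD window / tolerance | 2000 ps / 0.5 Å | plateau rule, see below |

Water residues default to `{HOH, TIP3, WAT, SOL}` and are overridable; in
XYZ input (which has no residues) waters are the `O` records beyond a
declared protein-atom prefix. Van der Waals radii come from a fixed
Bondi-style table; unknown elements fall back to carbon's 1.70 Å.

## The synthetic generator

Real MD trajectories for this analysis are produced elsewhere; the package
ships a generator whose *ground truth is known exactly*, so that every
analysis stage can be validated by parameter recovery rather than by
eyeballing.

`sample_boltzmann_trajectory()` draws every water z-position i.i.d. from
the density ∝ exp(−U(z)/k_BT) by inverse-CDF sampling on a 0.01 Å grid
(piecewise-constant weight per cell, uniform placement within a cell), and
x, y uniformly in the counting cylinder. Because the draws come from the
exact stationary distribution, there is no burn-in or convergence question:
if density → inversion does not return U(z) − U(z_A), the analysis is
wrong, not the sampling. The suite checks this end to end — at 2×10⁶
samples (20 000 waters × 100 frames) over an 80 Å box, profiles binned at
1 Å recover imposed potentials with features wider than two bins and
heights up to ~5.5 kcal/mol within 0.3 kcal/mol RMS, and a 2.5 kcal/mol
Gaussian barrier at the SF is recovered within ±0.3 kcal/mol. Those sizes
run in seconds and are the ones used throughout the tests and the
acceptance script.

`simulate_langevin_1d()` is the temporally realistic alternative:
overdamped Euler–Maruyama steps dz = −U′(z)/γ·dt + √(2k_BT·dt/γ)·ξ with
reflecting walls, whose stationary law is the same Boltzmann weight but
whose frames are autocorrelated like a real trajectory. It validates
against the closed-form stationary variance k_BT/k of a harmonic well and
against the exact sampler's histogram.

Fixture builders supply geometric ground truth: an axial water wire at a
given O–O spacing (2.8 Å puts exactly seven members strictly inside
−10 < z < 10), a cylindrical pseudo-protein shell whose accessible radius
is known by construction, and rigid-body/noise perturbations for RMSD
(isotropic noise of sd σ gives a no-fit RMSD of σ√3).

What the generator does *not* emulate: water–water interactions and
hydrogen-bond network dynamics, the membrane, protein flexibility, and 3-D
coupling between radial position and the axial potential. Passing recovery
tests therefore demonstrate the *analysis* is correct, not that any real
channel's barrier is 2.5 kcal/mol; on real data the density estimate
additionally carries the autocorrelation and convergence error of the
simulation itself.

## Numerical choices

* **Empty bins are masked, never infinite.** ΔG is undefined where ρ = 0;
  such bins propagate as `NA` (and explicit sentinel rows in CSV/JSON).
  A `pseudocount` option exists for exploratory smoothing but is off by
  default because silent pseudo-counts bias barrier heights.
* **Reference choice.** `z_A` snaps to the nearest bin center and must be
  populated (a classed error otherwise). When unspecified, the populated
  bin nearest the cytoplasmic channel mouth is used — the permeation
  "start" at which profiles are conventionally zeroed. For barrier work,
  prefer an explicit bulk bin.
* **Pore recentering.** The probe center is optimized within each slice
  plane by hill-climbing in 0.1 Å steps from the nominal axis — a minimal
  stand-in for the Monte-Carlo center search of dedicated pore-profiling
  programs, adequate for near-cylindrical pores but not for strongly
  kinked ones. Slices with nothing within `max_probe + max(vdW)` of the
  axis point are masked. SF ties resolve to the smallest z.
* **Equilibration rule.** The onset is the earliest time from which every
  subsequent sliding window of length `window` has a value range ≤
  `tolerance`; the plateau band is the min/max after onset. The rule is
  monotone in the tolerance and has no fitted parameters. RMSD itself is
  the unweighted arithmetic form, with Kabsch superposition (proper
  rotation, reflections corrected) applied per frame when `fitted = TRUE`;
  `fitted = FALSE` is provided because restrained simulations fix the
  frame of reference and make fitting moot.
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state; identical config + seed reproduces
  every output byte for byte.
* **Degenerate inputs** get classed conditions (`aquaflux_format_error`,
  `aquaflux_config_error`, ...) rather than generic stops: empty PDBs,
  MODEL blocks of unequal size, XYZ header mismatches, superposition with
  fewer than three atoms, windows longer than the series, zero-density
  references, unstable Langevin steps.

## Design decisions that were genuinely open

* **Frame weighting.** The time average weights frames equally regardless
  of their timestamps — the definition is a plain average over frames, and
  a reader should not silently resample what the file contains. Frame
  spacing is recorded (`dt`, `t_f`) but never interpolated.
* **Chain tie-breaks.** When several maximal hydrogen-bonded runs tie in
  length, `detect_single_file()` prefers the run with the most members
  inside the channel, then the one nearest the channel midpoint — the
  in-channel wire is the object of interest, not a bulk cluster.
* **Orientation.** Which end of the axis is extracellular cannot be
  inferred from coordinates; it is declared in `channel_spec()` (default
  `+z`) and only affects zoning labels and the default reference side.
* **NPA-by-window.** The NPA region is zoned by an axial window rather
  than by residue identity, because mapping the motif onto sequence
  numbers requires a specific model's coordinates; callers who know their
  asparagine positions can narrow the window accordingly.

## Limitations

The pore profiler is a simplified probe-sphere method, not a replacement
for dedicated tools on tortuous channels. The free-energy profile is a
density inversion: it inherits every sampling deficiency of the input
trajectory and reports the thermal band ±k_BT, not a convergence estimate.
Water orientation (the dipole flip at the NPA motifs) is out of scope, as
is building the simulations themselves (topology, solvation, force
fields).
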