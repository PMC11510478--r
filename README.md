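# bartraj

Geometry analysis of BAR-domain membrane-bending trajectories in R.

BAR domains are crescent-shaped dimeric protein modules that bind lipid
membranes through a positively charged concave surface and bend them.
Whether they act as rigid scaffolds or bend membranes through internal
flexibility — the swinging of the Helix-2 "arm" segments about a central
kink — is examined with a handful of trajectory-level measurements, all of
which this package implements:

* **Membrane curvature** — per-frame least-squares circle fitting (Kåsa
  initialisation, geometric orthogonal-residual refinement) of the lipid
  phosphorus atoms inside a 160 × 10 Å² patch beneath the dimer, reported
  as κ in nm⁻¹ with R[nm] = 1/κ, plus trailing-window statistics.
* **Kink detection and arm/core segmentation** — sliding paired helix
  windows with exact local-normal axes; segmentation of Helix 2 into core
  (ARG92–VAL114) and arm (VAL114–SER157) segments.
* **Angle/span series** — per-frame α (arm–arm), β (core–core), γ
  (Helix2–Helix2) axis angles and the dimer span d (SER157A–SER157B),
  with Pearson correlation tables; RMSD and RMSF.
* **Interactions** — Shrake–Rupley SASA, the pairwise interaction area
  `(SASA_A + SASA_B − SASA_AB)/2`, and geometric hydrogen-bond counting
  (3.5 Å / 30°) grouped by charged-residue cluster.
* **Centripetal lipid displacement** — mean horizontal (z-ignored)
  distance from tracked lipid phosphorus atoms to the concave-surface
  centre (mean GLY69A/GLY69B Cα position).
* **Synthetic generators** — a bending phosphorus lattice and a kinked,
  arm-swinging pseudo-dimer with closed-form ground truth (including a
  planted Pearson(α, d) correlation), used as the oracle for every
  estimator.

Readers/writers cover PDB (single and multi-model), GRO (single frame and
series) and a bit-exact plain coordinate-table CSV. An end-to-end pipeline
(`run_pipeline()`) orchestrates align → curvature → geometry → hydrogen
bonds → displacement → interaction area from one config, writes per-frame
CSVs plus a JSON report, and a thin command-line front end lives at
`inst/cli/bartraj` (subcommands `simulate`, `curvature`, `geometry`,
`sasa`, `hbonds`, `displacement`, `run`, `report`).

## Worked example

Generate a 50-frame synthetic bundle — a membrane bending from R = 2000 Å
to 500 Å under 0.5 Å noise, with a swinging dimer above it — and run the
full pipeline:

```r
library(bartraj)

mem <- generate_membrane_trajectory(
  membrane_spec(radius_series = seq(2000, 500, length.out = 50),
                noise_sd = 0.5, seed = 1))
dim <- generate_dimer_trajectory(
  dimer_spec(z_offset = 15, seed = 1),
  motion_spec(n_frames = 50, amplitude = 5,
              correlation_alpha_d = 0.65, seed = 1))
bundle <- bind_trajectories(dim$trajectory, mem$trajectory)
bundle
#> trajectory: 958 atoms, 50 frames (t = 0..4900 ps)
#>   chains: A B M

report <- run_pipeline(run_config(), traj = bundle)
report$values$curvature$window_mean_kappa_nm
#> [1] 0.01376529
report$values$geometry$correlations
#>       x    y         r
#> 1 alpha    d 0.5561255
#> 2  beta    d 0.3877917
#> 3 gamma    d 0.5356195
#> 4 alpha beta 0.3288569
```

The curvature window mean (0.0138 nm⁻¹) is the average signed curvature
over the final third of frames, where the generator's radius sweeps
roughly 1000 → 500 Å (true κ 0.010–0.020 nm⁻¹); the α–d Pearson
coefficient of 0.56 at 50 frames scatters around the planted 0.65 target
(an OU swing with a 10-frame relaxation time carries only a handful of
independent samples at this length — the correlation tightens to ±0.1 at
3000 frames). The displacement series shrinks as the membrane bends,
because arc-length-preserving bending contracts the lattice horizontally.

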