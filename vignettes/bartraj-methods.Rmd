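---
title: "Methods: membrane curvature, arm/core geometry and interactions in bartraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane curvature, arm/core geometry and interactions in bartraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bartraj)
```

## The problem

BAR domains are crescent-shaped dimeric protein modules that bind lipid
membranes through a positively charged concave surface and bend them. A
long-standing question is whether the dimer acts as a rigid scaffold that
imprints its own curvature, or whether internal flexibility — in
particular the swinging of the "arm" halves of Helix 2 about a central
kink — drives bending by squeezing lipids toward the dimer centre.
`bartraj` implements the trajectory-level measurements with which that
question is examined: membrane curvature under the dimer, arm/core
segmentation and the inter-chain angle/span statistics, protein–lipid
hydrogen bonding, buried interaction area, and the centripetal horizontal
displacement of lipids. Because production MD trajectories of such systems
are rarely deposited, the package pairs every estimator with a synthetic
generator that emits the same kind of geometry with closed-form ground
truth, so each estimator's accuracy is measurable rather than assumed.

## Coordinate model and units

A `trajectory` is an atom table plus an `n_atoms x 3 x n_frames` array of
Cartesian coordinates. The internal length unit is the ångström, matching
the PDB's native unit; GRO input (nm) is scaled by 10 on read. Curvature is
reported in nm^-1 at the reporting layer only, via `kappa[nm^-1] =
10 / R[Å]`, and the fitting-circle radius in nm is defined as the exact
reciprocal `R[nm] = 1 / kappa[nm^-1]`. Chain + residue-number addressing is
1-based and residue ranges are inclusive at both ends, e.g. `GLY69A` is
chain A, residue 69.

The canonical interchange format for frames is a plain CSV
(`frame,time_ps,atom_index,x,y,z`) written with 17 significant digits, so a
write/read round trip is bit-exact; PDB and GRO are supported at their
native precisions (0.001 Å and 0.01 Å respectively).

## Membrane curvature

Frames are first aligned: the best-fit plane of the membrane phosphorus
atoms is rotated to have normal +z (with the protein on the +z side), the
phosphorus centroid is moved to the origin, and the dimer's principal axis
is rotated into x. Within each aligned frame the phosphorus atoms inside a
rectangle of `length_x x width_y` (default 160 x 10 Å², long side along x,
centred on the dimer footprint centroid or an absolute origin for the
no-protein control) are projected to the x–z plane and a circle is fitted.
The 10 Å strip is treated as thin and collapsed by projection rather than
binned; a strip this narrow contributes less than the positional noise to
the in-plane spread.

The fit has two stages. The Kåsa algebraic fit solves the linearised circle
equation `x² + z² + Dx + Ez + F = 0` by least squares — closed-form and
deterministic, and exact on noiseless circular data. It is, however,
well known to shrink the radius under positional noise, and on shallow
arcs the effect is large: on the synthetic recovery grid the raw algebraic
curvature of a 1000 Å-radius membrane under 1 Å noise comes out more than
50 % high. `curvature_series()` therefore refines the Kåsa solution by a
geometric (orthogonal-residual) Levenberg-style iteration by default; the
refinement is unbiased to well under 2 % across radii 250–1000 Å and noise
0–1 Å. `fit_circle(refine = FALSE)` exposes the raw algebraic fit.

Conventions chosen for degenerate and signed cases:

* collinear input maps to `R = Inf`, curvature 0 (flat-membrane
  convention), not an error, so the no-protein control runs cleanly;
* the per-frame sign is +1 when the fitted centre lies above the mean z of
  the patch points — the membrane bulging toward the protein side — and
  −1 otherwise;
* frames whose patch holds fewer than 3 atoms are flagged infeasible,
  excluded from the window statistics, and counted.

Window statistics default to the trailing third of frames, mirroring the
common practice of averaging the final segment of a production run (e.g.
the final 100 ns of 300 ns); the fraction is configurable.

## Arm/core segmentation and kink detection

Helix 2 of each chain is split at the kink residue into a core segment
(default ARG92–VAL114) and an arm segment (VAL114–SER157); the kink residue
belongs to both ranges, exactly as the segment definitions overlap at 114.
Segment axes are the principal component of the segment's C-alpha
coordinates, oriented N→C. For segments of 20+ residues this axis is
accurate to well under 0.5° (checked on an ideal 44-residue helix), and it
remains defined for bent or irregular helices.

Kink detection slides two adjacent non-overlapping windows (default 6
residues) along the helix and measures the angle between their axes at
each junction. Principal-component axes are *not* usable at this window
length — the partial helical turn biases a 6-residue PCA axis by tens of
degrees — so window axes use the helix local-normal construction instead: for an ideal
helix the second difference `p_i = r_{i-1} + r_{i+1} - 2 r_i` is exactly
the inward radial vector, and the cross product of consecutive `p` vectors
is exactly the axis. Calls are local maxima of the bend angle above the
threshold (default 20°). Windows that straddle a rigid kink are not ideal
helices and can slightly overshoot the true bend, so each raw maximum is
re-centred on the junction whose two flanking windows are most
self-consistent (highest resultant of the summed unit cross products);
ties go to the larger bend, then the smaller residue number. On planted
kinks this recovers the pivot residue and the planted angle exactly.

The per-frame observables are: α, the angle between the two arm axes; β,
between the two core axes; γ, between the two whole-Helix-2 axes (union
range, ARG92–SER157 — the only defensible reading of a "Helix 2 axis"
given overlapping sub-segments); and the span d, the distance between the
two SER157 C-alpha atoms. Axis angles (not vertex angles) are used
throughout: an angle "between two segments" that are never co-terminal is
only well defined between their axes. All angles are folded to [0, 180]°.

Pearson correlations between the series use the standard product-moment
estimator; a constant series makes the coefficient undefined and is
reported as `NA` with a warning, never coerced to 0. When several
trajectories are analysed the default is to pool frames before
correlating, with a per-trajectory-then-average mode available and
labelled in the output.

RMSD uses optimal rigid-body superposition per frame against the
reference. RMSF superposes every frame onto the time-average structure,
recomputes the average from the fitted frames, iterates twice, and reports
the per-atom RMS deviation from the final mean — for isotropic per-axis
jitter of σ this converges to σ√3.

## SASA, interaction area and hydrogen bonds

SASA uses the Shrake–Rupley construction: each atom's sphere is expanded
by the probe radius (default 1.4 Å, a water-sized probe; Bondi van der
Waals radii), 960 quasi-uniform test points are placed on it via a
deterministic Fibonacci spiral, and a point is accessible when outside
every other expanded sphere. 960 points keep the two analytic oracles —
the isolated-sphere area `4π(r+probe)²` and the two-sphere spherical-cap
buried area `2π(r+probe)h` — within 1 % and 2 % respectively, at a few
milliseconds per small body; the count is configurable.

The interaction area between bodies A and B is
`(SASA_A + SASA_B − SASA_AB) / 2`, the per-partner buried surface on
complexation. It is symmetric by construction; small negative values from
point sampling are clamped to zero with a warning.

Hydrogen bonds are geometric: donor–acceptor distance ≤ 3.5 Å (inclusive)
and hydrogen–donor–acceptor angle ≤ 30°, the convention of the standard MD
tools, with both cutoffs configurable. Hydrogens are associated to donors
by residue identity and a 1.2 Å covalent distance; topologies without
hydrogens fall back to a distance-only mode that is labelled in the
output. Grouped counting attributes each bond to the charged-residue
cluster containing its donor; the shipped example configuration
(`inst/extdata/charged_groups.yaml`) defines the two clusters that are
explicitly enumerated for this construct (ARG19/LYS23 and
LYS47/ARG48/LYS132, per monomer), and further clusters are user-supplied
rather than guessed.

## The synthetic generators and what they emulate

The generators define the study conditions for every test and for the
acceptance script; their defaults are fixed once and not tuned.

**Membrane.** A lattice of pseudo-phosphorus atoms (default 43 x 12 at 8 Å
spacing, ≈ 336 x 88 Å² — the order of the simulated bilayer the analysis
targets) bends toward a per-frame cylindrical radius R(t) along x,
preserving arc length: flat position (x₀, y₀) maps to `x = R sin(x₀/R)`,
`z = R(1 − cos(x₀/R))`, which satisfies the circle equation
`z = R − sqrt(R² − x²)` exactly. Arc-length preservation means bending both
bulges the patch (toward +z, the protein side, so the curvature sign is +1
by construction) and contracts it horizontally — the centripetal
displacement signal. Isotropic Gaussian noise is added afterwards. A
radius smaller than the half patch extent is rejected (the patch would
wrap).

**Dimer.** Each chain is an ideal-helix C-alpha trace (rise 1.5 Å/residue,
twist 100°/residue, radius 2.3 Å, residues 19–239) along x, kinked at
residue 114 by a static 20° lift plus a per-frame swing θ(t); the part
N-terminal of the kink can rock independently. Chain B is the C2 rotation
of chain A about z — a two-fold symmetric dimer that preserves helix
chirality, which a literal mirror reflection would not. Ground truth is
computed from the same affine construction that emits the coordinates
(rotated ideal axis vectors and axis points), never from the estimators
under test.

**Arm dynamics.** The default swing is a discrete Ornstein–Uhlenbeck
process shared by the two arms, stationary sd 5° and relaxation time 10
frames — mean-reverting oscillation is the simplest process with the
right phenomenology for a tethered arm, without committing to any
particular dynamics. A planted Pearson(α, d) target is achieved by
construction, not post-hoc adjustment: the shared swing makes α and d
co-move through the arm kinematics, an independent OU "span breathing"
term (rigid ±x chain translation, which changes no angle) dilutes the
correlation, and its sd is computed in closed form from the derivative of
the anchor position with respect to the swing angle
(`sd_breathing = |∂d/∂θ| · sd_swing · sqrt(1/ρ² − 1)`). Because the
geometry couples α and d positively, only non-negative targets are
supported. An independent OU core-rocking channel (sd 2°) drives β without
touching α or d, providing the null channel against which near-zero β–d
correlations are checked. At 3000 frames the planted 0.65 target is
recovered within the OU-autocorrelation-widened sampling error (±0.1).

**What the generators do not emulate.** Lipid packing and chemistry,
force-field energetics, water and ions, periodic boundaries, thermal
undulations beyond isotropic noise, and real secondary-structure
irregularity. Passing tests therefore demonstrate that the estimators
recover known geometry under realistic noise — not that any biological
claim about a particular protein is reproduced. The headline numbers of
the motivating analyses (membrane curvature ≈ 0.03 nm⁻¹ under the dimer
versus ≈ 0.007 without it, α–d correlation 0.65, ≈ 40 charged-residue
hydrogen bonds) derive from hundreds of nanoseconds of undeposited
all-atom trajectories and are treated as qualitative reference only.

## Numerical choices and degenerate inputs

* Collinearity in the circle fit is declared when the second singular
  value of the centred points falls below 1e-9 of the first; such input
  returns the flat convention rather than an error.
* Alignment fails loudly on collinear membrane points (no plane) and
  resolves the dimer-axis sign deterministically (first selected atom on
  the +x side in frame 1, continuity with the previous frame afterwards).
* Patch membership is inclusive with a 1e-9 Å tolerance so lattice points
  sitting exactly on the rectangle boundary are kept.
* `pearson_cor` requires ≥ 3 paired finite observations and signals
  constant series as missing.
* The hydrogen-bond distance cutoff is inclusive (a bond at exactly
  3.5 Å counts).
* Problem sizes used by the test-suite and the acceptance script — 500
  frames per membrane recovery cell, 3000 frames for correlation
  recovery, 2000 frames for the RMSF closed form, 960 SASA points — were
  chosen so each check's sampling error sits well inside its tolerance.

## Known limitations

* The curvature model is one-dimensional (a circle in x–z); 2-D
  mean/Gaussian curvature fields and leaflet-resolved analysis are out of
  scope, as is periodic-boundary unwrapping (trajectories are assumed
  whole).
* Kink calling reproduces the windowed bend-angle idea, not any published
  tool's exact scoring.
* SASA is O(n²) per frame in plain R and intended for per-chain bodies at
  a few thousand atoms, not for solvated systems.
* Binary trajectory formats (XTC/DCD) are not read; convert to a
  coordinate table or multi-model PDB first.

## A worked example

```{r example}
set.seed(1)
mem <- generate_membrane_trajectory(
  membrane_spec(radius_series = seq(2000, 500, length.out = 50),
                noise_sd = 0.5, seed = 1))
dim <- generate_dimer_trajectory(
  dimer_spec(z_offset = 15, seed = 1),
  motion_spec(n_frames = 50, amplitude = 5,
              correlation_alpha_d = 0.65, seed = 1))
bundle <- bind_trajectories(dim$trajectory, mem$trajectory)

report <- run_pipeline(run_config(), traj = bundle)
report$values$curvature$window_mean_kappa_nm
report$values$geometry$correlations
```
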