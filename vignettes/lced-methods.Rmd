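---
title: "Methods: detecting and classifying extra densities in fibril maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and classifying extra densities in fibril maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcedscan)
```

## The problem and the model

Amyloid fibrils image as stacks of flat, misfolded protein molecules
("rungs") repeating along the fibril axis at a rise of about 4.8 Å with
a small twist per rung. Many deposited maps additionally show rod-like
density not accounted for by the protein model, running parallel to the
axis, repeating in register with the protein, and lying within
hydrogen-bonding distance of lysine side chains. `lcedscan` measures and
classifies such extra densities along five axes: occupancy strength,
axial repeat, cross-sectional morphology, chain duplexing, and the
chemical character and pose of the coordinating environment. The package
also validates atomic models (clash score, bond geometry, sugar pucker),
since candidate ligand models for the extra density are judged by the
same criteria.

Everything operates on two objects: a `density_map` (3D scalar grid,
voxel size, origin, and the deposited display contour level — the
"authors' level" at which the map was meant to be viewed) and an
`atomic_model` (typed atoms with coordinates). All distances are in
ångström; voxel `(1,1,1)` is centered at the map origin.

## Tunable parameters

All parameters live in `lced_config()` and are embedded in every report.
The ones that matter:

| parameter | default | meaning |
|---|---|---|
| `protein_radius` | 3.0 Å | erase zone radius around model atoms |
| `coordination_cutoffs` | 3.5, 4.8 Å | dual coordination distances, both reported |
| `ladder_n_levels`, `ladder_spread` | 5, 0.5 | contour ladder: display level ± 50%, 5 rungs |
| `repeat_window` | 3–7 Å | rise/repeat search window (brackets ~4.8 Å) |
| `min_axis_ratio` | 1.5 | principal-axis anisotropy below which a map is not a fibril |
| `min_rungs` | 3 | minimum axial extent of a reported region |
| `merge_radius` | 8 Å | stack-centroid distance merged into one region |
| `duplex_split_frac` | 0.5 | fraction of section maximum probed for chain splitting |
| `t_threshold` | 0.8 | three-fold rotational correlation threshold |
| `side_ratio` | 0.85 | terminal symmetry threshold separating Y from X |

The dual coordination cutoffs reflect two natural hydrogen-bonding
radii: a tight 3.5 Å contact distance and a permissive 4.8 Å outer
bound; both coordination sets are computed and retained, and the summary
defaults to the outer one.

## Procedure

**Helical frame.** The axis is the principal eigenvector of the
density-weighted covariance of above-level voxels; a cloud whose first
two eigenvalues differ by less than 1.5× is rejected as isotropic. The
rise is the dominant spectral peak of the axial density profile. We
deliberately estimate the period in the frequency domain (Hann-tapered
profile, fine frequency grid over the search window) rather than by
lagged autocorrelation: with only 10–20 repeats the autocorrelation peak
is biased by the profile envelope by over +0.1 Å, and sharp per-rung
beads alias against the voxel lattice; the spectral peak is unbiased to
within ~0.005 Å under the same conditions. A profile with no interior
peak holding a minimum share of the power (default 0.1) yields an
indeterminate repeat — this is what an axially featureless rod returns.
The twist comes from an exhaustive in-plane rotation search aligning
cross-sections of the two fibril ends, divided by the rung count between
them.

**Nanodissection.** A zone mask marks every voxel within
`protein_radius` of any model atom; those voxels are erased (set to the
map floor) in a copy of the grid. We erase fully rather than to "just
below the display level": a zone held at level − ε resurfaces as fake
density at every sub-display ladder level and corrupts both strength
grading and cross-sections. Connected components (26-neighbour
connectivity, so diagonal voxel contacts count as joined) of the
residual above the display level are then grouped in two stages: single
linkage at 3.5 Å merges components stacked at the same in-plane position
(a weak density resolved as per-rung beads becomes one region), then
average linkage on stack mass-centroids at `merge_radius` merges
adjacent stacks (the two chains of a bulky duplex become one region).
Two-stage merging is deliberate: pure single linkage percolates through
stray satellite voxels and fuses well-separated densities, while pure
average linkage is poisoned by small junk stacks. Regions shorter than
`min_rungs` rungs, or with density opposite fewer than 60% of their
spanned rungs, are dropped; regions touching the map face are flagged.
With several regions, protofilament letters a, b, … are assigned left to
right.

**Strength grading.** Against a contour ladder (display level ± 50%,
five levels): `s` if a single component spans the region's axial extent
at the display level; `m` if not, but a spanning component exists at two
consecutive ladder levels; `w` if neither, provided the density resolves
into bead-like per-rung units of substantially uniform size — density
opposite ≥ 80% of rungs and per-rung volume CV < 0.5 — and `none`
otherwise. Two operationalizations are worth flagging. First, "joined at
two consecutive levels" is read as any two adjacent ladder levels, the
only reading consistent with s ⊃ m ⊃ w ordering. Second, uniformity is
judged on per-rung total volumes rather than "exactly one unit per
rung": a weak Y-shaped density legitimately resolves its peg as a
separate beadlet beside the main bead, and a strict one-unit rule would
misgrade every such density as noise. With these rules the grade is
monotone in occupancy: raising a rod's amplitude at fixed noise never
lowers its grade.

**Cross-sections.** The region's voxel cloud (taken at the lowest ladder
level, restricted to components connected to the region and centred
within 6 Å of it) is cut into axial repeat units, phase-aligned so units
are centered on rungs rather than cut through them. Each unit is
projected by column maximum on its own voxel lattice — a max projection
preserves in-plane amplitude ratios regardless of how strongly the
density is modulated axially, where a mean projection compresses them —
then resampled bilinearly into a common de-twisted frame centered on the
unit's in-plane centroid, and the units are averaged. Aligning units on
their own centroids absorbs the small systematic drift that a ~1–2°
error in the estimated axis direction would otherwise smear across the
average. The averaged image is rescaled so its maximum equals the
region's maximum 3D density, which keeps ladder levels meaningful on the
section.

**Marker graph and morphology.** Nodes sit at local maxima of the
averaged section above 0.35× its maximum; two nodes join when the
density along the straight segment between them stays above the lower of
the first ladder level and 0.25× the section maximum, and joins passing
through a third node's territory are suppressed. Node values are disc
means (radius 1 Å), which are far more noise-stable than single pixels.
Degree-2 chain nodes form the backbone; a degree-1 node clearly weaker
than the strongest terminal is a side node — the peg, joined just once.
The classification cascade: (1) bulky duplex `b` when, at some fraction
of the section maximum, the section splits into exactly two dominant,
comparably sized, elongated components running parallel to each other
and across their separation; (2) three-fold `t` when the section
correlates above `t_threshold` with its own 120°/240° rotations (best
rotation center searched near the centroid); (3) a three-node chain with
asymmetric terminals is `y`, (4) with symmetric terminals `x` (reported
with its admissible Y attitudes: forward/backward Y, lambda, reverse
lambda); (5) a two-node chain is `v`; (6) otherwise `i`. Ties at
thresholds break toward the less specific code. Before the cascade a
persistence gate requires the mean unit-to-average correlation to reach
0.72: a repeating substructure persists across units, noise does not
(measured margins: genuine rods ≥ 0.80 even at 20% noise, pure noise
≤ 0.67), so noise sections classify `i` outright.

**Duplex direction.** For a bulky density, the two chains found by the
duplex split partition the cloud by perpendicular bisector. Each chain's
polarity is the axial phase offset (circular mean at the repeat
frequency) between its peg-side and hump-side terminal lobes — windows
anchored on the outermost substantial density of each side so the middle
blob's skirt does not dilute the phase. Matching polarities give a
parallel duplex, opposite ones antiparallel; a chain without a
distinguishable weak side (an axially symmetric chain) is indeterminate
and the call falls back to single chains with a warning.

**Environment and pose.** A residue coordinates the region when any of
its side-chain donor/acceptor atoms (per the shipped polarity taxonomy:
Lys/Arg/Trp donors; His, hydroxyls, amides mixed; Asp/Glu acceptors;
backbone atoms excluded) lies within the cutoff of the region's density
surface. Residue identity is the (name, number) pair, so a residue
repeated across the stacked chains of a fibril model counts once. The
environment code is `D` when every coordinating residue is donor-only,
else `M` (acceptor-only residues land in `M`; the taxonomy has no pure
acceptor class of its own), plus the count clamped at 6. Pose is defined
against the two closest coordinating residues, ordered by residue number
so the sign convention is stable: alignment is horizontal when the
section's major axis is within 45° of the inter-residue vector
(ties break vertical), and the flip is the sign of the hump-to-peg
vector projected on the inter-residue normal — or on the pair direction
itself when the rod lies along the pair, so that an upside-down
rebinding always reverses the flip.

**Model geometry.** Covalent bonds are inferred by distance
(`d < 0.55 (0.6 + r_i + r_j)`, which accepts bonds near 1.5 Å while
excluding furanose ring diagonals near 2.35 Å); clashes are nonbonded
heavy-atom pairs overlapping by ≥ 0.4 Å, scored per 1000 atoms.
Hydrogens are not placed — a zero score certifies a clash-free model at
the heavy-atom level, which is the robust direction of the
approximation. Sugar puckers use the standard pseudorotation relation on
the five endocyclic torsions (IUPAC sign convention, verified against an
independent torsion implementation), with the named class read from 36°
bins of the phase.

## The synthetic generator

`generate_fibril()` emulates the features the analysis assumes: protein
rungs (2D Gaussian blobs swept along the axis at 4.8 Å rise and −1°/rung
twist), rod-like extra densities with Y/X/V/bulky/three-fold
cross-sections, pseudo-lysines with NZ atoms at stated offsets from the
rod, i.i.d. Gaussian voxel noise, and a display level at which the
protein is axially continuous. Its defaults are the package's study
conditions: 20 rungs, 1 Å voxels, noise at 10% of the protein amplitude.
Design choices worth recording:

* The Y triplet is hump (0, +2.8; σ 1.1; amp 1.0), middle (0, 0; σ 0.8;
  amp 0.85), peg (0, −2.8; σ 0.7; amp 0.7, axially offset +1.2 Å). The
  2.8 Å spacing and these widths are chosen so the three blobs stay
  bimodal after 1 Å voxel sampling and resampling blur; at tighter
  spacing the hump and middle merge into a single maximum and no
  Y-graph can form at this sampling. X is the half-amplitude
  superposition of a Y and its mirrored pose; V drops the peg; the bulky
  code is two Y chains 6 Å apart (plus a faint bridging blob at low
  contour); three-fold is three arms at 120°.
* Blob amplitudes are normalized per code so the rod's 3D peak equals
  the occupancy fraction of the protein amplitude — superposed
  half-amplitude codes would otherwise realize less occupancy than
  specified.
* Strength scenarios are realized by axial amplitude modulation: strong
  (σ_z 1.6, occupancy 0.80) stays continuous at the display level
  between rungs; moderate (σ_z 1.3, 0.82) bridges rungs only at the two
  sub-display ladder levels; weak (σ_z 0.9, 0.55) never bridges and
  appears as uniform per-rung beads. The weak axial width is kept at
  0.9 Å because sharper beads alias against the 1 Å sampling comb and
  corrupt period estimates. These scenarios are calibrated against the
  package's own grading criteria — a deliberate circularity: the
  generator defines what s/m/w mean operationally.
* The pose flip flag turns the rod end-over-end (in-plane reflection
  plus reversal of the peg's axial offset); the duplex-antiparallel flag
  applies the same flip to the second chain only.
* The pseudo-atomic model covers one virtual rung beyond each end of the
  blob stack so the erase zone also covers the finite stack's axial
  tails — a real fibril continues past the reconstruction box, and a
  real deposited model covers every rung in it.
* Noise is i.i.d. Gaussian per voxel, the simplest model consistent with
  an averaged cryo-EM background. It reproduces none of the correlated,
  resolution-dependent structure of real reconstruction noise, no CTF
  or B-factor envelope, and no helical-reconstruction artefacts; passing
  recovery tests on these maps therefore demonstrates the internal
  consistency of the pipeline under its stated assumptions, not its
  performance on deposited maps, whose display levels, noise spectra and
  modelling conventions vary.

## Numerical choices and degenerate inputs

Component labelling is strict 26-connectivity (single-voxel breaks
break a component). Distances are measured atom to voxel center, with a
stated ± half-voxel tolerance; the erase boundary is inclusive. A map
without a deposited display level falls back to the level enclosing the
top 1% of voxels and is flagged. Maps without models, isotropic maps,
and maps without axial periodicity are unassessable, with the reason
recorded. An empty residual after erasing is an empty region list, not
an error. Repeat estimation refuses regions spanning fewer than five
candidate repeats; cross-sections need at least three units. Reported
analyses are deterministic functions of (map, model, config): rerunning
produces byte-identical JSON reports, and the run manifest embeds the
config hash.

## Problem sizes

Round-trip validation runs 30 noise-free cases (5 morphology codes × 3
strength scenarios × 2 poses) at 12 rungs, morphology noise-robustness
runs 50 seeds per code at 20% of the rod amplitude, and the headline
repeat-recovery condition uses 20 fibrils of 20 rungs at 10% noise.
These sizes put every estimate's sampling error well under the asserted
tolerances while keeping the whole suite runnable in a few minutes on
one CPU.

## Known limitations

* All classification thresholds were calibrated on the generator's
  geometry; deposited maps at coarser voxel sizes or lower resolution
  will need the config revisited, and the morphology taxonomy is only as
  expressive as the marker-graph features behind it.
* The strength taxonomy leaves genuinely ambiguous cases (e.g. a rod
  continuous at exactly one ladder level with non-uniform beads) graded
  `none`.
* Hydrogen-bond and clash analysis is heavy-atom only; donors without a
  resolvable antecedent pass the angle test unchecked.
* The twist estimate assumes a modest per-rung twist (search window
  ± 60° overall) and reports `NA` rather than guessing outside it.
* Map-level assessability automates what was originally an expert visual
  judgement; borderline maps will not reproduce a human call, and
  summaries over heterogeneous collections should be read accordingly.
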