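---
title: "Models and methods behind dendricomplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dendricomplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendricomplex)
```

This vignette explains the models the package implements, the defaults
it ships with and why, and the design choices made where more than one
reasonable definition exists. It states no empirical result that the
test suite does not itself compute.

## The dendrimer charge model

A dendrimer is represented as concentric amine layers indexed by depth
from the terminal surface: depth 0 is the layer of terminal primary
amines, deeper layers are the interior tertiary amines, halving in
count toward the 2-amine core. Generations follow the labelling used
for the commercial polymers this package targets: generation *g* has
$2^{g+2}$ terminal amines for both families, so G3 carries 32 and G4
carries 64. The model is a layer-count abstraction — it exists to
compute formal charges, not geometry.

At neutral pH the families protonate differently:

* **PAMAM** — only the terminal primary amines are protonated; the
  interior tertiary amines (pKa well below 7 inside the branches)
  stay neutral. Net charge = terminal count: +32 (G3), +64 (G4).
* **PPI** — the terminal primaries plus *alternating* interior layers
  are protonated, the pattern that emerges from Ising-type models of
  site–site electrostatic repulsion in PPI. "Alternating" does not by
  itself say which layers; the package protonates the layers at even
  depth from the terminal surface (0, 2, 4, …) because that is the
  unique alternation consistent with the published formal charges of
  +42 (G3 = 32+8+2) and +84 (G4 = 64+16+4), and it charges exactly
  two-thirds of all amines for G4 (84 of 126) and nearly so for G3
  (42 of 62). Only the layer occupancy is reproduced; the underlying
  statistical model is out of scope.

```{r charges}
sapply(3:4, function(g)
  c(PAMAM = net_charge(assign_protonation(build_topology("PAMAM", g))),
    PPI   = net_charge(assign_protonation(build_topology("PPI", g)))))
```

## Stoichiometry from two-regime titration curves

Titrating a cationic dendrimer with an anionic dye produces a response
curve with two regimes: while free binding sites remain, the response
(zeta potential, or the F564/F575 emission ratio) changes roughly
linearly with the molar ratio; past saturation it plateaus. The
saturation-breakpoint construction — fit a line to each regime,
intersect, and read the stoichiometry *n* off the intersection's molar
ratio — is what this assay family calls Job's method, and it is what
`job_stoichiometry()` implements. (The classical continuous-variation
Job plot is a different experiment; the two-segment/intersection
reading is the one that matches how these titrations are analysed.)

Implementation choices:

* Candidate breakpoints are every interior ratio plus the midpoints of
  adjacent ratios; each candidate splits the data at $x \le c$ and
  $x \ge c$ (the boundary point belongs to both segments). Including
  midpoints makes recovery exact for non-integer truths on noiseless
  data. Total SSE selects the winner, ties toward the smaller
  breakpoint; at least 3 points per segment are required.
* The estimate is invariant under affine rescaling of the response, so
  arbitrary fluorescence units need no normalization.
* Strictly linear data (segment slopes equal at the optimum, relative
  tolerance $10^{-8}$) is flagged degenerate rather than estimated.
  If the fitted intersection escapes the sampled ratio range (possible
  under heavy noise), the SSE-optimal breakpoint is reported with a
  fallback flag.
* `n` is reported both continuous and as a "1:n" label rounded
  half-up.

`zeta_saturation()` evaluates the post-breakpoint fitted line at the
mean of its own x-range — the "eventual zeta potential of the fully
saturated dendrimer". `singlet_oxygen_rate()` is a deliberately small
statistic: the OLS slope of probe fluorescence vs time, as percent of
the control slope.

The F564/F575 readout (`fluorescence_ratio()`) linearly interpolates
between sampled wavelengths; 564 nm and 575 nm are the free-dye and
bound-dye emission peaks of rose bengal, so the ratio falls as binding
red-shifts the band. `peak_wavelength()` refines the sampled maximum
with a 3-point parabola when the local grid is uniform and reports
plateau midpoints with a flag.

## Shape descriptors

`radius_of_gyration()` is the mass-weighted RMS distance from the
selection's center of mass. `inertia_descriptors()` diagonalizes the
mass-weighted inertia tensor per frame, sorts eigenvalues ascending
($I_x \le I_y \le I_z$, so aspect ratios lie in (0, 1]) and computes
the asphericity

$$\delta = 1 - 3\,\frac{\langle I_2 \rangle}{\langle I_1^2 \rangle},
\qquad I_1 = I_x + I_y + I_z,\quad
I_2 = I_xI_y + I_yI_z + I_xI_z,$$

with time averages taken over the analysed frames. Two points deserve
emphasis:

* δ is defined from **moments of inertia**, not gyration-tensor
  eigenvalues. The thin-rod limit is therefore 1/4
  ($I_x \to 0$, $I_y = I_z$), not 1, and the test oracles assert that
  limit in closed form. δ = 0 exactly for isotropic inertia, and
  δ ≥ 0 always (Cauchy–Schwarz over the eigenvalues).
* δ and the mean aspect ratios are ratios/means of time averages;
  the per-frame ratio series are also exposed so a spread can be
  reported. The reported SD is the frame-level sample SD over the
  analysis window — whether published SDs are over frames, replicas or
  both is rarely stated, so the convention is made explicit here.

`window_average()` implements the standard "equilibrated tail"
averaging (default: last 25% of frames, mirroring analysing the final
quarter of a production run) and concatenates replica tails into one
ensemble window. `rog_pdf()` is histogram-based so a constant series
still yields a normalized single-bin spike.

## Radial organization

`radial_density()` histograms selection-to-reference distances per
frame, averages over frames and divides by spherical-shell volumes.
The reference point is the per-frame center of mass of the designated
`core` group — published analyses rarely define the "central core"
atomistically, so the package makes it an explicit, reproducible
selection. Count conservation
($\sum_b \rho_b V_b = \langle N \rangle$) holds by construction and is
asserted to $10^{-6}$ relative in the tests.

For a finite, inhomogeneous system there is no unique RDF
normalization. `rdf()` divides the density by a supplied bulk density
when one is available (e.g. the known box concentration of water or
ions), else by the mean selection density over the largest sampled
sphere; the profile records which reference was used so curves remain
comparable across systems. Absolute peak heights therefore depend on
that metadata; orderings and shapes do not.
`internalization_fraction()` integrates the profile up to a radius
(typically the dendrimer RoG) to quantify encapsulated vs
surface-bound ligand; partial bins are linearly interpolated.

Distances are plain Euclidean. The analyses assume an intact molecule,
the normal state of a single solvated dendrimer; minimum-image handling
is out of scope for the descriptor layer, and box vectors read from GRO
files are carried as metadata only.

## Hydrogen bonds

Published hydrogen-bond counts rarely state their criteria; the package
defaults to the widely used geometric definition — donor–acceptor
distance ≤ 0.35 nm and hydrogen–donor–acceptor deviation angle ≤ 30° —
and carries the criteria in the result's attributes so every count is
interpretable. Donor/hydrogen pairing and acceptor typing are input
data (explicit index lists), not chemical perception; a hydrogen
farther than 0.2 nm from its donor is treated as a list error. Bonds
are classified from group labels (internal / with water / with the
photosensitizer), the classes are disjoint by construction, and the
summary uses the sample SD, recorded as such. The implementation is
validated against an exhaustive triple-loop search and
planted-geometry recovery; loosening either cutoff can only grow the
record set.

## Void volumes

`sasa_volume()` rasterizes probe-inflated atoms on a cubic grid
(default spacing 0.05 nm) and counts as enclosed every point inside an
inflated atom **or** unreachable from the box boundary through
probe-free space (6-neighbour flood fill). That boundary flood fill is
the load-bearing choice: pockets the probe cannot enter count as
enclosed at large probes, which is exactly what makes the probe sweep a
cavity detector.

`void_volume_estimate()` sweeps probes 0.3–1.0 nm, fits
$V_{sasa}^{1/3}$ linearly over probes ≥ 0.4 nm and evaluates the
deviation at 0.3 nm. "Deviation" is ambiguous between cube-root space
and volume space; the default converts the fitted cube root to a
volume at the evaluation probe and subtracts the measured volume there,
which yields nm³ directly and reproduces the hollow-shell oracle
(a sealed shell of interior radius $r$ returns $\tfrac43\pi r^3$ within
tolerance, where $r$ = shell radius − bead radius − evaluation probe).
The cube-root-space alternative is available behind
`deviation = "cuberoot"`. Negative estimates are clipped to zero with a
flag. `void_ratio()` removes photosensitizer atoms from each complex
snapshot before the sweep so the comparison measures structural effects
on the dendrimer, not the volume the dye occupies.

Van der Waals radii come from the Bondi table for real elements;
synthetic beads use explicit radii. Grid error is controlled by
convergence tests (halving the spacing moves a single-sphere volume by
under 2%); rotation invariance holds within grid error.

## Synthetic-data generators

The generators define the study conditions for the test suite; they
are geometric stand-ins with controllable statistics, not force
fields.

* `gen_titration()` — two-segment curve with truth *n* inside the
  ratio grid 1–50, defaults +40 mV initial and −30 mV plateau (the
  typical zeta range for these titrations), additive Gaussian noise,
  full truth in metadata.
* `gen_spectra_series()` — mixtures of a free (564 nm) and bound
  (575 nm) Gaussian band with a saturation-binding bound fraction and
  a mid-titration quench dip.
* `gen_dendrimer_ensemble()` — beads placed along the layer model's
  branching tree (segment 0.35 nm, roughly a propyl/amidoamine branch
  span), with a stiffness parameter setting frame-to-frame angular and
  breathing fluctuation: high stiffness emulates the rigid PPI family
  (narrow RoG distribution), low stiffness the floppy PAMAM family.
  All frames are rescaled once so the time-mean RoG hits the requested
  target (the published per-system means are natural targets).
* `gen_complex_ensemble()` — 10 ligand beads by default (the 1:10
  dendrimer:dye working ratio), placed at radii proportional to the
  per-frame RoG: factor 0.5 for encapsulated dye, 1.6 for
  surface-bound, with an optional compaction factor emulating
  cavity closure upon binding.
* `gen_reference_solids()` — analytic oracles: uniform ball
  (RoG = $\sqrt{3/5}R$), thin rod (δ = 1/4), isotropic cloud (δ ≈ 0),
  and a hollow bead shell with one engineered circular aperture
  (circumradius 0.56 nm with 0.2 nm beads) that admits a 0.3 nm probe
  but seals against 0.4 nm — the geometry that makes the void
  estimator's extrapolation testable against a closed form.
* `gen_hbond_system()` — frames with exactly *k* planted near-linear
  contacts inside the default criteria and all cross-pair distances far
  outside the cutoff.

What the bead model does **not** emulate: atomistic packing, solvent
structure, electrostatics, binding kinetics, and realistic absolute
aspect ratios — a few dozen beads in a correlated tree have noticeably
more sample anisotropy (δ of order 0.05) than a several-thousand-atom dendrimer
(δ of order 0.01–0.03). Passing tests therefore demonstrate that the
descriptors measure what they claim on structures of known geometry and
that orderings (rigid vs flexible, encapsulated vs surface, cavity
retention vs closure) are recovered; they do not certify agreement with
any particular simulated or measured system.

## Problem sizes and numerical settings

The suite is sized for quick, deterministic runs: Monte-Carlo oracles
use $10^5$ points where 1% closed-form agreement is asserted;
breakpoint recovery uses 200 seeded replicates at 2% noise; the
exhaustive hydrogen-bond oracle runs 200 frames of 100 atoms; void
sweeps validate at 0.05 nm spacing on the reference solids and use
0.06–0.08 nm for ensemble-level comparisons. Seeds are fixed
throughout; every generator records its seed and truth in metadata.

## Known limitations

* The charge model is formal (integer protonation per layer); it does
  not model pH titration curves or site-specific pKa shifts.
* RDF normalization for finite systems is a convention, recorded but
  not canonical; compare profiles only under the same reference mode.
* The void estimator's absolute values depend on grid spacing near the
  1–2% level and on the probe set; comparisons should hold both fixed.
* `run_pipeline()` covers the common single-ensemble workflows; its
  hydrogen-bond stage expects donor/acceptor lists in the
  configuration rather than inferring them.
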