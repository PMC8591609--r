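# dendricomplex

Analytics for the complexation of cationic dendrimers with anionic
photosensitizers. PAMAM and PPI dendrimers bind rose bengal (RB), a
dianionic xanthene dye used in photodynamic therapy, largely by
electrostatics; characterizing the resulting nanocarrier means answering
a few recurring quantitative questions:

- **How charged is the carrier?** At neutral pH a PAMAM dendrimer
  protonates its terminal primary amines only, while a PPI dendrimer
  protonates its terminal primaries plus alternating interior tertiary
  layers (two-thirds of all amines). `build_topology()`,
  `assign_protonation()` and `net_charge()` encode this layer model and
  give formal charges of +32 / +64 / +42 / +84 e for PAMAM G3/G4 and
  PPI G3/G4.
- **How many dye molecules saturate one dendrimer?** Titration curves
  (F564/F575 fluorescence ratio, or zeta potential vs molar ratio) show
  two regimes: a linear change while binding sites fill, then a plateau.
  `job_stoichiometry()` fits one line per regime over a breakpoint grid
  and intersects them; the intersection's molar ratio is the binding
  stoichiometry *n*.
- **What shape is the carrier?** `radius_of_gyration()` and
  `inertia_descriptors()` compute RoG, principal moments of inertia
  (Ix ≤ Iy ≤ Iz), aspect ratios Ix/Iy and Ix/Iz, and the asphericity
  δ = 1 − 3⟨I₂⟩/⟨I₁²⟩ (I₁ = Ix+Iy+Iz, I₂ = IxIy+IyIz+IxIz), which is 0
  for a sphere and 1/4 for a thin rod.
- **Where does the dye sit?** `radial_density()`, `rdf()` and
  `internalization_fraction()` profile any labelled species
  (dye, water, ions, amines) against distance from the dendrimer core.
- **Who hydrogen-bonds with whom?** `find_hbonds()` applies the
  geometric criterion (donor–acceptor ≤ 0.35 nm,
  hydrogen–donor–acceptor angle ≤ 30°) and classifies bonds as
  dendrimer-internal, with water, or with the dye.
- **How much internal cavity space is there?** `sasa_volume()` and
  `void_volume_estimate()` sweep surface-enclosed volumes across probe
  radii, fit V^(1/3) linearly for probes ≥ 0.4 nm, and read the void
  volume off the deviation at a 0.3 nm probe; `void_ratio()` compares a
  complex (dye removed per snapshot) with the neat dendrimer.

Seed-deterministic generators (`gen_titration()`, `gen_spectra_series()`,
`gen_dendrimer_ensemble()`, `gen_complex_ensemble()`,
`gen_reference_solids()`, `gen_hbond_system()`) produce titration curves
and dendrimer-like bead ensembles with known ground truth, so the whole
pipeline is testable without molecular-dynamics trajectories or
laboratory data. Ensembles read and write multi-frame PDB, GRO and XYZ.

## Worked example

```r
library(dendricomplex)

# formal charge of a PPI G4 dendrimer at neutral pH
topo <- assign_protonation(build_topology("PPI", 4))
net_charge(topo)
#> [1] 84

# a zeta titration with true stoichiometry 1:26, 1 mV noise
series <- gen_titration(n_true = 26, initial = 40, plateau = -30,
                        noise_sd = 1, seed = 42)
est <- job_stoichiometry(series)
est
#> stoichiometry_estimate (zeta_job): n = 26.059 (1:26)
#>   segments: slope -2.835 | 0.01505, SSE 60.56
zeta_saturation(series)
#> [1] -30.25888

# shape of a rigid, PPI-like bead model tuned to RoG 1.284 nm
ens <- gen_dendrimer_ensemble(build_topology("PPI", 3), target_rog = 1.284,
                              stiffness = 40, n_frames = 30, seed = 5)
inertia_descriptors(ens)
#> shape_summary over 30 frames
#>   RoG      1.2840 +/- 0.0103 nm
#>   Ix/Iy    0.460 +/- 0.008
#>   Ix/Iz    0.397 +/- 0.005
#>   delta    0.0588
```

The estimate `n = 26.059` recovers the generator's truth of 26 dye
molecules per dendrimer to within the noise; the plateau estimate
recovers the −30 mV saturation potential; the bead ensemble reproduces
the requested size with the narrow RoG spread (±0.8%) of a rigid,
PPI-like model and the mild finite-size asphericity (δ ≪ the thin-rod
limit of 0.25) of a compact branched blob.

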