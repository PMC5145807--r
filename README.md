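# poreannotate

Functional annotation of ion-channel structures as conductive or
non-conductive, based on the physics of hydrophobic gating.

A channel pore can be sterically wide enough for ions and still be
functionally closed: if a narrow (radius below roughly 4–5 Å),
apolar-lined stretch of the pore dewets — expels its water and sits in a
vapour-like state — it presents a large free-energy barrier to ion
permeation without ever occluding the pore. Pore dimensions alone
therefore under-determine the functional state of a structure.
`poreannotate` implements the three-level analysis hierarchy used to
resolve this for pentameric ligand-gated ion channels (the serotonin
5-HT3 receptor and the glycine receptor):

1. **Pore geometry** — HOLE-style pore-radius profiles `R(z)` along the
   channel axis. At each axial position the largest probe sphere not
   overlapping any atom, `max_c min_i(|c − x_i| − r_vdW,i)`, is found by
   Monte Carlo simulated annealing in the plane, polished by a
   deterministic local search. Sub-threshold constrictions become
   candidate gates annotated with lining residues and their hydrophobic
   fraction (Kyte–Doolittle).
2. **Pore hydration** — from a trajectory: per-water axial tracks,
   gate occupancy and dewetted fraction, completed permeation events
   (two-gate hysteresis counting), axial density `n(z)`, and its
   Boltzmann inversion `E(z) = −kT ln n(z) + kT ln C` with the constant
   `C` fixed by zero free energy in the bulk at the two pore ends.
   Ion hydration-shell numbers are also available.
3. **Free energetics and voltage** — WHAM reconstruction of 1-D
   potentials of mean force from umbrella-sampling windows
   (`P(z_b) = Σ_i n_i(z_b) / Σ_i N_i exp[(F_i − w_i(z_b))/kT]`,
   iterated to self-consistency), with bootstrap error bars and
   convergence diagnostics; and computational-electrophysiology
   post-analysis: slab charge densities, the transmembrane potential by
   double integration of the 1-D Poisson equation, compartment ion
   bookkeeping, and per-species ion-crossing counts.

The evidence is combined by `classify_state()` into a per-gate and
overall verdict — OPEN, CLOSED or INDETERMINATE — using configurable
thresholds (defaults: CLOSED at a water barrier ≥ 10 kJ/mol (~4 kT at
310 K) or a dewetted fraction ≥ 0.5; OPEN requires all barriers
≤ 5 kJ/mol (~2 kT) and a continuously wetted pore). A CLOSED call means
"non-conductive": closed and desensitized states are deliberately not
distinguished.

A `synthetic` module generates every fixture needed to exercise and
validate the stack without running molecular dynamics: model cylinder
and hourglass pores with known inscribed radii, Metropolis-sampled water
trajectories with stationary density `exp(−U(z)/kT)` on prescribed 1-D
potentials, umbrella-window datasets, and charged parallel slabs with an
analytic capacitor voltage.

## Worked example

Profile a synthetic hourglass pore (wall radius narrowing from 10 Å to
4 Å), sample waters over a 15 kJ/mol gate barrier, and annotate:

```r
library(poreannotate)

pore <- make_hourglass_pore(mouth_radius = 10, waist_radius = 4)
prof <- compute_profile(pore, axis = c(0, 0, 1), z_range = c(-12, 12),
                        step = 0.5, seed = 1, origin = c(0, 0, 0))
min_radius(prof)
#> $z
#> [1] 0
#> $radius
#> [1] 2.162483

cyl <- pore_cylinder(radius = 5, z_lo = -15, z_hi = 15)
traj <- sample_water_trajectory(potential_spec("gaussian_barrier", height = 15),
                                cyl, n_waters = 60, n_frames = 2000, seed = 2)
tracks <- water_axial_tracks(traj, "resname HOH", cyl)
fe <- boltzmann_invert(density_profile(tracks, 1.0), temperature = 310)
occ <- occupancy_and_dewetting(tracks, gate = c(-3, 3))

report <- classify_state(prof, atoms = pore,
                         water_barriers = barrier_height(fe, c(-3, 3)),
                         dewetted_fraction = occ$dewetted_fraction,
                         structure_id = "hourglass demo")
report
#> Functional annotation: hourglass demo
#>   overall verdict: CLOSED
#>   minimum pore radius: 2.16 A at z = 0.00 A
#>   gate 1: z [-6.00, 6.00] A, min radius 2.16 A, barrier 16.0 kJ/mol,
#>           dewetted 0.86 -> CLOSED
```

The 2.16 Å waist is the construction's closed form (4 Å wall minus the
1.85 Å carbon vdW radius); the recovered barrier matches the 15 kJ/mol
imposed on the sampler within sampling noise; and the gate slab is empty
in ~86% of frames — a dewetted, non-conductive pore.

On deposited structures the same workflow starts from
`read_structure("4PIR.pdb")` + `assign_vdw_radii()`, with the profile
origin set to the L9′ C-alpha ring
(`select_atoms(atoms, "resid 260 and name CA")`) so that z = 0 sits at
the putative gate.

## Command line

A thin wrapper, installed under the package's `exec/` directory, wires
the same functions into a pipeline:

```sh
pore-annotate synth --kind hourglass --out pore
pore-annotate profile --pdb pore.pdb --axis 0,0,1 --step 0.5 --seed 1 --out pore
pore-annotate hydrate --traj waters.pdb --radius 5 --zlo -15 --zhi 15 \
    --gate -3:3 --out waters
pore-annotate annotate --profile pore_profile.tsv \
    --hydration waters_hydration.json --out report.json
```

Subcommands: `profile`, `hydrate`, `pmf`, `voltage`, `annotate`,
`synth`; `--config file.yml` supplies defaults that explicit flags
override, and every source of randomness is controlled by `--seed`.

## Selection grammar

`select_atoms()` supports the keywords `name`, `resname`, `resid`
(values or `a:b` ranges), `chain` and `element`, each taking one or more
values, combined with `and`, `or`, `not` and parentheses, e.g.
`"resname HOH and name O"`, `"resid 260:270 and chain A"`,
`"not element H"`.

## Units

Lengths in Å, energies in kJ/mol, times in ns, temperatures in K,
charges in e, potentials in V. Force constants follow the MD convention
kJ mol⁻¹ nm⁻²; the nm²→Å² conversion is handled internally wherever a
bias is evaluated.
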