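---
title: "Annotating ion-channel pores: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ion-channel pores: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreannotate)
```

## The problem

Ion-channel structures keep arriving faster than their functional states
can be assigned. The pore of a pentameric ligand-gated ion channel
(pLGIC) such as the serotonin 5-HT3 receptor or the glycine receptor is
lined by five M2 helices; mid-membrane, a ring of leucines (the L9′
position) forms a constriction whose radius — typically 1.5–5 Å across
conformational states — does not by itself decide whether the channel
conducts. A hydrophobic constriction of radius below roughly 4–5 Å can
*dewet*: water leaves the segment, it sits in a vapour-like state, and
the resulting free-energy barrier blocks ion permeation even though the
pore is sterically open. `poreannotate` turns this physics into an
annotation pipeline: geometry first, then pore hydration, then explicit
free energetics and voltage response.

## Pore geometry

The pore-radius profile is the classic probe-sphere construction: at
axial position $z$ the radius is

$$R(z) = \max_{c \in \text{plane}} \; \min_i \left( \lVert c - x_i \rVert - r^{\mathrm{vdW}}_i \right),$$

the largest sphere centred in the plane normal to the pore axis that
touches no atom. The inner optimisation is exact and vectorised; the
outer one is Monte Carlo simulated annealing (default 30 geometric
temperature stages of 50 moves, proposal steps shrinking 1.0 → 0.1 Å),
followed by a Nelder–Mead polish with a tight tolerance. The polish
matters for two documented properties: the result is never below the
fixed-centre evaluation, and profiles are invariant under rigid
transforms of the structure to better than $10^{-6}$ Å. Two further
choices:

* **Overlap rejection.** Proposals with negative clearance (probe centre
  inside the solid wall region) are rejected outright. Without this, the
  annealing walker can tunnel through a one-atom-thick wall at high
  temperature and report the larger optimum *outside* the pore — a
  failure mode we observed on the hourglass fixture.
* **Marching continuity.** Each plane's optimised centre seeds the next
  plane, so the centre line follows the pore rather than restarting.

The axis defaults to the principal axis of the atom set (a pentamer's
five-fold symmetry makes this the pore axis); the $z = 0$ origin
defaults to the atom-set centroid and should be set to the C-alpha ring
of a reference residue (L9′) when comparing structures. vdW radii follow
a HOLE-style table (C 1.85, N 1.75, O 1.65, S 2.00, H 1.00, P 2.10 Å,
default 2.00 Å); the source method does not print its radius file, so
this table is an overridable package decision. Candidate gates are
contiguous runs with $R(z)$ below 4.5 Å; residues with a heavy atom
within 2.8 Å of the local pore surface count as lining (that cutoff is
likewise a package decision, documented rather than sourced).

## Hydration analysis

Water positions are reduced to axial tracks inside an analysis cylinder.
The dewetted fraction is the fraction of frames with *zero* waters in
the gate slab. Permeation events use two-gate hysteresis: a particle
must come from beyond one mouth and leave beyond the other; jitter
across a single boundary can never count. Both directions are logged;
the headline flux is the total bidirectional rate in ns⁻¹, since
published equilibrium flux values do not specify direction handling.
Time-reversing a trajectory provably swaps up/down counts.

The axial density $n(z)$ (expected waters per bin per frame, 1 Å bins by
default) is Boltzmann-inverted:

$$E(z) = -kT \ln n(z) + kT \ln C,$$

with $C$ the mean density over the outermost three occupied bins at each
pore end — the bulk reference where $E \equiv 0$. Bins never visited
would be $+\infty$; instead they get the finite lower bound obtained by
substituting one observation over the whole run, flagged in
`lower_bound_mask`, so fully dewetted pores serialise cleanly. The
default temperature is 310 K throughout ($kT = `r round(thermal_energy(310), 3)`$
kJ/mol, the "RT ≈ 2.6 kJ/mol" yardstick).

## Potentials of mean force

Umbrella windows carry a harmonic bias $w_i(z) = \tfrac{k}{2}(z-c_i)^2$
with $k$ in kJ mol⁻¹ nm⁻² and $z$ in Å; the nm² → Å² factor of 100 is
applied in exactly one internal function and guarded by a test on the
analytic window variance $\mathrm{Var}(z) = kT/(k/100)$ — the classic
silent-bug site. WHAM iterates

$$P(z_b) = \frac{\sum_i n_i(z_b)}{\sum_i N_i\, e^{(F_i - w_i(z_b))/kT}},
\qquad F_i = -kT \ln \sum_b P(z_b)\, e^{-w_i(z_b)/kT}$$

from $F_i = 0$ until $\max_i |\Delta F_i| < 10^{-6}\,kT$ (cap $10^5$
iterations; non-convergence is an error carrying the last residual).
Bins are 0.5 Å over the window-centre range plus 1 Å padding; bins with
no samples are masked, never interpolated. The PMF zero uses the same
bulk convention as the Boltzmann inversion — the level of the *mean*
probability over the outermost three occupied bins per end — which makes
WHAM on a single unbiased window agree with direct Boltzmann inversion
of its histogram to numerical precision, a property the test suite
asserts at $10^{-9}$ kJ/mol. "Tethering" of PMF profiles is interpreted
as exactly this bulk zero-shift. Errors come from resampling each
window's sample vector with replacement (window identity preserved) and
re-running WHAM; convergence is monitored by recomputing the central
barrier on cumulatively longer slices of every window.

## Transmembrane voltage

For double-bilayer (computational electrophysiology) systems the
per-frame charge density $\rho(z)$ is binned in slabs (e/Å³, box
cross-section for volume), and the potential follows from the 1-D
Poisson equation by cumulative trapezoidal double integration with
$\phi = \phi' = 0$ at the lower box edge, the `g_potential` convention;
$\varepsilon_r = 1$ by default since all charges are explicit. The
conversion to volts is a single centralised constant
($e \cdot 10^{10} / \varepsilon_0$ for e/Å³ integrated over Å²),
unit-tested against the parallel-plate capacitor
$\Delta V = \sigma d / \varepsilon_0$, which the integrator reproduces
to machine precision and with second-order grid convergence. Compartment
bookkeeping labels the region between the two membrane slabs α and the
periodically connected outside β; the ion-crossing counter reuses the
hysteresis event detector per membrane, where *zero* crossings is the
expected, reportable outcome for a closed pore. The ion-swap engine that
*creates* the imbalance during MD is out of scope; this module analyses
its outputs.

## The verdict

`classify_state()` applies, per gate:

* **CLOSED** if the water barrier ≥ 10 kJ/mol (≈ 4 kT) *or* the gate is
  dewetted ≥ 50% of frames, *or* — geometry alone — the minimum radius is
  below the 1.4 Å radius of a water molecule (steric occlusion);
* **OPEN** if all barriers ≤ 5 kJ/mol (≈ 2 kT) and the pore is
  continuously wetted (dewetted fraction ≤ 0.05; an unknown fraction is
  not held against an otherwise low barrier);
* **INDETERMINATE** otherwise, in particular for any sub-threshold
  constriction with no hydration evidence.

The overall verdict is the worst gate. The 10/5 kJ/mol defaults are a
calibration from published barrier values for closed (9–25 kJ/mol) and
open (≤ ~4 kJ/mol) pLGIC states — no numeric cutoff is printed in the
source literature — and are fully configurable and recorded in each
report. Two deliberate asymmetries: geometry can prove CLOSED only via
steric occlusion, never via narrowness alone (a 2 Å hydrophobic waist
may still wet — deciding otherwise would make the hydration levels of
the hierarchy pointless); and flux is reported as evidence but never
vetoes a barrier-based call, since the relationship between intermediate
barriers and residual flux is not quantified well enough to arbitrate.
CLOSED means non-conductive; closed versus desensitized is explicitly
not distinguishable by this approach. For the desensitized
glycine-receptor evidence set, the published "degree of dewetting" at
the intracellular P-2′ ring is encoded as a dewetted fraction of 0.5,
which is what makes that state map to CLOSED.

## Synthetic data: what it emulates and what it does not

Every analysis stage is validated against generators with known ground
truth:

* **Cylinder / hourglass pores** have closed-form inscribed radii
  (wall − vdW). Lattice spacing is validated against a documented bound
  (≤ 0.05 Å perturbation, estimated as $s^2/4R$); the hourglass waist is
  leucine-labelled so gate-lining logic can be exercised.
* **Water trajectories** are independent Metropolis walkers with
  stationary density $\propto e^{-U(z)/kT}$ (reflected at the cylinder
  bounds), with bounded per-frame displacements so particle identity and
  event detection are meaningful. Burn-in (default 500 sweeps) is
  discarded; an acceptance rate collapsing below 2% is an error, not a
  silent bias. Metropolis rather than Langevin dynamics is deliberate:
  the analyses under test depend only on stationary densities, not
  kinetics, so passing tests certify equilibrium statistics — *not*
  realistic water dynamics, correlated hydrogen-bond networks, or real
  flux magnitudes.
* **Umbrella datasets** sample $e^{-(U+w_i)/kT}$ per window at the
  standard protocol defaults (1 Å spacing, k = 1000 kJ mol⁻¹ nm⁻²,
  310 K).
* **Charged slabs** give the analytic capacitor ΔV.

All generators are pure functions of their seed.

## Problem sizes and reproducibility

The shipped validation uses problem sizes chosen so each property is
measured comfortably above its noise floor: 10⁶ in-pore observations for
Boltzmann-inversion recovery of 5/12/15 kJ/mol barriers (tolerance
0.5 kJ/mol), 21 windows × 3000 samples for WHAM recovery of a 15 kJ/mol
barrier (tolerance 1 kJ/mol), 10⁴ random walks for the exact
event-counter replay, and 0.02-Å exhaustive grid searches as the
profiler oracle (agreement within 0.05 Å). Every stochastic test and the
acceptance script are seeded; reports embed thresholds, seed and package
version in their provenance block.

## Known limitations

* The profiler assumes a single, roughly straight pore; curved or
  branched channels (MOLE-style pathfinding) are out of scope.
* Boltzmann inversion of equilibrium density estimates *water* barriers;
  ion barriers require the umbrella-sampling route, and conductance in
  pS or quantitative selectivity are not predicted.
* The radial in-pore criterion is a cylinder, not the true pore surface;
  for strongly non-cylindrical pores the analysis radius should be set
  from the computed profile.
* Annotation thresholds are calibrated on pLGIC evidence; other channel
  families may need recalibration, which the configuration supports.
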