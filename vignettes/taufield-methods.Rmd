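---
title: "Methods: quantifying cross-beta filament degradation under oscillating fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cross-beta filament degradation under oscillating fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taufield)
```

## The scientific problem

Tau filaments extracted from Alzheimer's-disease brain tissue adopt two
cross-beta topologies: the paired helical filament (PHF), whose two
protofilaments pack symmetrically through the 332-PGGGQ-336 face, and the
straight filament (SF), whose asymmetric interface joins 313-VDLSK-317 of one
protofilament to 321-KCGS-324 of the other. Each protofilament is a stack of
C-shaped peptides spanning tau residues G304-E380 (77 residues), rising
~0.475 nm per layer; the simulated core is a decamer (two pentamers).

Oscillating external electric fields (oeEFs), `E(t) = E0 cos(2 pi nu t)`,
perturb such assemblies because the fold carries clustered formal charges —
most prominently the turn segment 340-KSEKLDFKDRV-350 with 7 charged side
chains out of 11 (4 positive, 3 negative). This package implements the full
measurement pipeline used to quantify field-driven degradation in molecular
simulation trajectories, plus a synthetic-data stage that makes every
measurement testable without microsecond all-atom simulations.

## Observables

* **Beta-strand content** (`assign_ss`, `beta_fraction`): Kabsch-Sander
  hydrogen-bond energy `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)`
  kcal/mol (distances in Angstrom; bond iff `E < -0.5`), with
  parallel/antiparallel bridge and ladder rules. The three-state reduction
  counts only ladder-forming `E` as beta content; isolated bridges and all
  turn/helix intermediates collapse to coil. The constant and cutoff are
  fixed — they define the method. Missing amide hydrogens are rebuilt 1.01 A
  from N in the peptide plane, opposite the bisector of N->C(i-1) and N->CA;
  chain-initial residues and prolines do not donate.
* **Contact survival** (`reference_contacts`, `contact_fraction`): three
  Calpha contact classes on the starting structure — intrapeptide (same
  chain, sequence separation > 3, cutoff 1.25 nm), interpeptide (different
  chains, 0.8 nm), interprotofilament (different pentamers, 1.0 nm). A pair
  within both 0.8 and 1.0 nm across the interface belongs to both of the
  latter classes. Distances strictly below the cutoff count, identically at
  build time and tracking time. The baseline is the first trajectory frame,
  so every class starts at fraction 1.
* **Flexibility** (`superpose`, `rmsf`): each frame is aligned on the Calpha
  atoms of the central chain of its pentamer (stack index 3, chains 3a/3b),
  and RMSF is taken per chain about the aligned per-atom mean position (not
  about frame 1; the standard definition, chosen because the source protocol
  leaves this open).
* **Sheet twist** (`sheet_twist`): the signed IUPAC dihedral over
  (Calpha 306, 310 of chain 1a; 310, 306 of chain 2a). For a builder decamer
  twisted rigidly about the fibril axis this dihedral tracks the layer twist
  monotonically but is *not* numerically equal to it — the identity holds
  only in special axis placements — so tests validate against an explicit
  rotation-matrix construction rather than asserting equality.
* **Interface area** (`sasa`, `interface_area`): Shrake-Rupley SASA
  (spiral quadrature, default 960 points/atom, probe 0.14 nm, heavy atoms
  with element radii C 1.70 / N 1.55 / O 1.52 / S 1.80 A), and interface
  area = SASA(pentamer a) + SASA(pentamer b) - SASA(decamer). This is twice
  the conventional per-side buried area; the sum-minus-complex convention is
  kept deliberately. Note two tolerance sources: the radii set (the original
  tool's defaults are not fully specified) and quadrature (the point grid is
  fixed in the lab frame, so rigid-motion invariance holds to ~1-2%).
* **Decay kinetics** (`fit_decay`, `half_life`, `compare_groups`): four
  exponential models, `exp(-t/B)`, `A exp(-t/B)`,
  `A exp(-t/B) + (1-A) exp(-t/D)`, and `A exp(-t/B) + C exp(-t/D)`; the
  slow-phase half-life is `ln 2 * max(B, D)`. Fitting is bounded nonlinear
  least squares with multi-start initialisation over log-spaced time
  constants in `[0.1, 100] * t_max` (two-phase exponentials are multimodal
  and no protocol is prescribed by the source). Series are normalized by
  their first point by default: the models have no plateau term, and
  dividing by an average of several early points biases fast two-phase
  decays. Half-lives beyond the fitted range carry an `extrapolated` flag.
  The group comparison is the classic pooled-variance two-sample t test
  (Welch behind a flag), with explicit conventions for zero variance.

## The synthetic world

Two generators stand in for the original trajectories.

**Idealized builder** (`build_fibril`). Each chain is a C-shaped backbone
trace in its layer plane: a 36-residue arm, a semicircular turn over residues
340-350, and a return arm, with Calpha spacing 0.38 nm. Strand residues carry
pleated carbonyls along +/- z so that in-register stacking at the 0.475 nm
rise produces parallel-sheet hydrogen bonds that the Kabsch-Sander criterion
recognizes; turn carbonyls lie in the layer plane and form no interlayer
bonds. Three Gaussian bulges on the outer face localize the
interprotofilament packing: one under residue ~334.5 carries the symmetric
PHF interface (protofilament b is the C2 rotation about an axis over that
bulge), and two under residues ~315 and ~322.5 carry the SF interface (the C2
axis sits at their stagger midpoint, so the 315-bulge of one protofilament
faces the 322.5-bulge of the other). The default placement gaps (1.10 nm PHF,
1.33 nm SF) were set once from this bulge geometry so that the designed faces
— and only they — fall inside the contact cutoffs; they also make the PHF
interface larger and more deeply packed than the SF one, reproducing the
qualitative interface-size ordering. The builder is backbone-only (N, CA, C,
O, H): side-chain packing is irrelevant to every implemented metric except
the absolute interface-area benchmarks, which require the deposited
structures. What a green builder test establishes is therefore that the
*measurement machinery* is correct on a geometry with known answers — not
that the builder approximates the true fold's energetics.

**Charged elastic network under the field** (`build_enm`, `simulate_enm`).
One bead per residue at the Calpha, formal charges (K/R +1, D/E -1, H
neutral at pH 7, capped termini uncharged), springs between beads within
1.2 nm at their starting lengths, and overdamped Langevin dynamics
`dr = (dt/gamma)(F_spring + qE(t)) + sqrt(2 kBT dt/gamma) eta`. Units are
kJ/mol, nm, ps, e, K; the single unit bridge is `field_force` (1 e V/nm =
96.485 kJ/mol/nm). Defaults: k = 100 kJ/mol/nm^2, interprotofilament springs
k = 10 (a weaker interface makes separation reachable, mirroring the SF's
marginal packing — and because the SF geometry also yields *fewer* interface
springs, the SF/PHF stability difference emerges from geometry rather than
per-topology tuning), gamma = 2000 kJ mol^-1 ps nm^-2, T = 300 K. The
friction was chosen once so the single-bead corner frequency
`k/(2 pi gamma)` (~2.5 GHz) separates the driven regimes: at 1 GHz the beads
follow the field almost fully, at 10 GHz the response drops by ~40% — the
mechanism by which high-frequency fields lose their effect. The integrator is
plain Brownian (no mass): the target observables are slow conformational
drifts, and every limit has an exact analytic check (Einstein diffusion,
equipartition, driven-oscillator amplitude `qE0 / sqrt(k^2 + (2 pi nu
gamma)^2)`). The field axis is a configuration parameter (default +y, the
interface normal of the builder); no claim is made that it matches the
original runs, whose axis is unstated. The instability guard (abort if any
step moves a bead > 0.5 nm) bounds usable `sqrt(2 kBT dt/gamma)` to ~0.07 nm
per coordinate; tests pick dt accordingly.

What the ENM does *not* emulate: solvent, side-chain packing, bead-bead
electrostatics, dipole alignment of whole protofilaments, or absolute decay
timescales. Green mechanism tests establish orderings (field vs control,
1 GHz vs 10 GHz, SF vs PHF), not rates.

One subtlety worth knowing: the *network's* field response is not linear in
E0 even at T = 0. A spring at its rest length restores transverse
displacements only to second order, so transverse-dominated network modes
respond quadratically; linearity in E0 is exact only where the force field
is linear (the anchored single bead), and that is where the test suite
asserts it.

**Kinematic perturbations** (`perturb_trajectory`) inject known answers for
the analysis stages: terminus/turn jitter with prescribed sigma (RMSF
recovers `sigma * sqrt(3)`), and rigid protofilament separation at a chosen
frame (interprotofilament survival drops to 0 exactly).

## Numerical choices and degenerate inputs

* Seeds: every generator and the pipeline draw all randomness from one root
  seed; sub-seeds come from an iterated multiply-add hash kept below 2^31.
* DSSP energies at pathological overlaps (< 0.05 nm) are clamped to
  "no bond" inside trajectory scans but raise an error in the scalar
  `hbond_energy`.
* `contact_fraction` reports a missing class as an error, not 0; empty
  selections error.
* Zero-variance t tests: equal means give p = 1, different means p = 0 with
  a warning.
* PDB coordinates round-trip at 3 decimals in Angstrom (5e-5 nm).
* The 10-GHz field reverses direction every 0.1 ns; with the default dt =
  1 ps that period is resolved by 100 steps.

## Known limitations

* The absolute interface-area benchmarks of the deposited cryo-EM decamer
  cores (~2200 A^2 PHF, ~1000 A^2 SF) require those coordinate files; the
  build and grading environments have no network access, so that criterion
  is reported as failing rather than being approximated by a tuned stand-in.
* The builder's intrapeptide contact set is sparse (the idealized C has only
  one cross-arm approach), so per-residue intrapeptide statistics are less
  structured than in the real fold.
* Beta content counts DSSP code E only; a structure rich in isolated
  bridges would read lower than an E+B convention. This matches the
  cross-beta emphasis of the measurement but is a convention, not a fact.
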