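# taufield

Analysis toolkit for the structural degradation of tau amyloid filament
cores under oscillating external electric fields (oeEFs).

## Who this is for

Tau filaments from Alzheimer's-disease tissue come in two cross-beta
topologies — the paired helical filament (PHF, symmetric protofilament
interface at 332-PGGGQ-336) and the straight filament (SF, asymmetric
interface, 313-VDLSK-317 against 321-KCGS-324). Each is a decamer of two
pentameric protofilaments; each chain is the C-shaped tau core G304-E380
(77 residues) stacked in register with a ~4.75 Å rise. Because the fold
carries clustered charges (the turn 340-KSEKLDFKDRV-350 holds 7 charged side
chains), an oscillating field `E(t) = E0 cos(2πνt)` — characterized by its
strength (mV/nm) and frequency (GHz) — can enhance flexibility and, for the
weakly packed SF, separate the protofilaments.

`taufield` implements the measurement pipeline for simulation trajectories
of such systems:

* **Secondary structure** — Kabsch–Sander (DSSP) assignment from the
  hydrogen-bond energy `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
  kcal/mol (bond iff `E < −0.5`), reduced to {E, H, C}; β-content time
  series with multi-run mean ± SD bands.
* **Contacts** — three Cα contact classes (intrapeptide 1.25 nm at sequence
  separation > 3; interpeptide 0.8 nm; interprotofilament 1.0 nm) defined on
  the starting structure and tracked as survival fractions.
* **Flexibility** — Kabsch superposition onto the central chain of each
  pentamer (3a/3b) and per-chain, per-residue RMSF.
* **Geometry** — β-sheet twist dihedral (Cα 306/310 of chains 1a/2a),
  Shrake–Rupley SASA, and protofilament interface area by SASA subtraction.
* **Kinetics** — one- and two-phase exponential decay fits
  (`e^(−t/B)`, `Ae^(−t/B)`, `Ae^(−t/B)+(1−A)e^(−t/D)`, `Ae^(−t/B)+Ce^(−t/D)`),
  slow-phase half-life `ln2·max(B, D)`, and pooled two-sample t tests.
* **Synthetic data** — an idealized cross-β decamer builder (PHF-like and
  SF-like, DSSP-recognizable backbone) and a charged elastic-network
  Brownian simulator driven by the oscillating field, so the whole pipeline
  is testable at desk scale.

PDB (including multi-model trajectories) is the interchange format; lengths
are nm internally, areas are reported in Å².

## Worked example

```r
library(taufield)

phf <- build_fibril("phf")
map <- build_assembly_map(phf)
print(map)
#> assembly_map: 10 chains; 2 protofilament(s)
#>   labels: A=1a B=2a C=3a D=4a E=5a F=1b G=2b H=3b I=4b J=5b
#>   central: C, H

ss <- assign_ss(phf)
mean(ss$code == "E")
#> [1] 0.740          # beta content of the idealized starting decamer

contact_counts(reference_contacts(phf, map))
#>       intrapeptide       interpeptide interprotofilament
#>                110               1944                356

# protofilament packing: symmetric PHF buries more surface than the SF
interface_area(phf, map)$interface_area       # ~252 A^2 (idealized, backbone-only)

# drive the charged elastic network at 1 GHz, 200 mV/nm for 3 ns
sys  <- build_enm(phf, map)
traj <- simulate_enm(sys, field_spec(200, 1), dt = 1, n_steps = 3000,
                     stride = 30, seed = 1)
cf <- contact_fraction(traj, reference_contacts(phf, map))
tail(cf$fraction[cf$class == "interprotofilament"], 1)
#> [1] 0.76           # the same run on the SF-like build drops to ~0.5

# two-phase decay kinetics on synthetic beta-content traces
tr  <- generate_decay_traces(par = c(A = 0.6, B = 0.5, D = 5), sigma = 0.02,
                             n_runs = 10, seed = 1)
tab <- do.call(rbind, tr)
fit_decay(tab$time_ns, tab$beta_fraction, model = "m3")
#> decay_fit m3 : A=0.6015 B=0.5259 D=5.052 | RSS=0.4382 half-life=3.502
```

The fitted half-life 3.502 is `ln2 × D` with the slow constant recovered
within ~1% of the true value (5.0 → half-life 3.466).

The interprotofilament survival numbers quantify the headline mechanism: at
1 GHz the beads follow the field (single-bead corner frequency
`k/2πγ ≈ 2.5 GHz`), strain crosses the weak interface springs, and the
SF-like assembly — whose interface is smaller and more shallowly packed —
loses its interprotofilament contacts faster than the PHF-like one. At
10 GHz the response amplitude falls by ~40% and both assemblies behave like
the no-field control.

## Command line

```sh
Rscript inst/cli/taufield build --topology sf --out sf.pdb
Rscript inst/cli/taufield simulate --topology sf --E0 200 --freq 1 --seed 7 --out traj.pdb
Rscript inst/cli/taufield analyze --what contacts --traj traj.pdb --outdir out/
Rscript inst/cli/taufield run --outdir run1/ --seed 1    # full condition grid
```

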