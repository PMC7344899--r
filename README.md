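# cgmelt

Conformational restraints and membrane-binding melting analysis for
coarse-grained (CG) peptide simulations.

## The problem

Intrinsically disordered membrane-binding peptides — the N-terminal region
of α-synuclein is the motivating case — bind lipid bilayers through two very
different backbone states: an extended-disordered *tethered* state and an
amphipathic α-helical *locked* state. Standard CG force fields with a single
fixed secondary structure cannot compare the two. `cgmelt` provides the two
ingredients needed for such a comparison on a desk machine:

1. **Gaussian conformational restraints** on backbone bend angles θ and
   dihedrals φ that pin a one-bead-per-residue chain in either a helical
   (θ<sub>min</sub> = 96°, φ<sub>min</sub> = 60°) or an extended-disordered
   (θ<sub>min</sub> = 124°, φ<sub>min</sub> = 100°) state, with analytic
   Cartesian forces and export as tabulated bonded potentials for a standard
   MD engine.
2. **A membrane-binding "melting" analysis** built on residue–phosphate
   contacts: per-residue and global contact indices, melting curves over a
   temperature ladder (310–450 K in 10 K steps), logistic
   melting-temperature (T<sub>m</sub>) fits, the temperature-averaged global
   contact index (TAGCI) for deletion constructs, and three-segment
   convergence errors.

The package is aimed at simulators who want to prepare such restrained CG
systems, and analysts who want to turn multi-temperature binding
trajectories into melting curves and T<sub>m</sub> shifts.

## The model

The restraint on a bend angle θ<sub>ijk</sub> between three consecutive
backbone beads (and identically on a dihedral φ<sub>ijkl</sub>) is a
negative Gaussian well

    V(θ) = −K · exp( −(θ − θ_min)² / σ ),    F = −dV/dθ · dθ/dr

with σ = 14° (degree-squared-valued denominator as conventionally printed,
so the 1/e half-width is √σ ≈ 3.7°) and configurable depth K (default
50 kJ/mol). Dihedral wells carry periodic images at φ<sub>min</sub> ± 360°
so the energy is continuous across the atan2 boundary at ±180°. All angle
arithmetic is in degrees; the deg↔rad conversion sits explicitly in the
dθ/dr chain-rule factor.

A residue contacts the membrane in a frame when its backbone bead lies
within 1 nm (inclusive, minimum-image) of any lipid phosphate bead. The
*contact index* of a residue is its contact fraction over frames; the
*global contact index* (GCI) averages it over a residue window; GCI versus
temperature is the melting curve, and T<sub>m</sub> is the midpoint of a
4-parameter logistic fit `b + (a−b)/(1+exp((T−Tm)/s))`. The TAGCI averages
the 15-residue-window GCI over the 15-temperature ladder — one scalar per
construct.

A synthetic-campaign generator with known ground truth (two-state Markov
binding kinetics per residue, logistic temperature dependence, per-residue
affinity weights) drives end-to-end validation; the nine construct
sequences of the α-synuclein N-terminal panel (WT, six deletions, the
C-terminal control, F4A) ship as fixtures.

## Worked example

```r
library(cgmelt)

## restraints for a 30-residue helical chain: 28 bends + 27 dihedrals
set <- build_conformation_restraints(30, "helical")
nrow(set)                                  # 55
write_restraint_config(set, "restraints.cfg")
export_tabulated_potential(restraint_spec("bend", 96), 0.1, "table_bend.xvg")

## validate the well statistically against exp(-V/kT)
spec <- restraint_spec("bend", 96)
s <- metropolis_sample(spec, sampler_config(310, 1e5, 3, seed = 1,
                                            burn_in = 5000, thinning = 10))
ks_against_boltzmann(s, spec, 310)
#> [1] 0.0056

## synthetic multi-temperature campaign with known Tm = 380 K
params   <- binding_params(tm_true = 380, steepness = 10)
campaign <- generate_campaign(params, n_frames = 2000, seed = 1)
curve    <- melting_curve(campaign$contacts)
fit      <- fit_melting_temperature(curve)
fit
#> <melt_fit> Tm = 379.52 K (logistic, se 0.16 K)
#>   plateau 0.722 -> 0.002, steepness 9.82 K
tagci(campaign$contacts, "WT")
#> # A tibble: 1 x 4
#>   construct window_start window_len tagci
#> 1 WT                   1         15 0.462

autoplot(fit)             # melting curve with the fitted logistic
plot_residue_profile(campaign$contacts)
```

The fitted T<sub>m</sub> of 379.5 K recovers the generator's true 380 K to
within the sampling error of 2000 frames per temperature; the plateau 0.72
is the mean per-residue affinity weight of the default N-terminal-weighted
profile; the TAGCI 0.46 is the 15-residue-window GCI averaged over the
ladder.

Real trajectories enter through `load_labeled_frames()` (multi-frame GRO,
or PDB + DCD with Å→nm conversion) and the same pipeline:
`run_pipeline(tibble(temperature, path), out_dir)` writes tidy CSVs
(per-residue indices, melting curve, T<sub>m</sub> fit, TAGCI) plus a run
log. A thin command-line front end with subcommands `gen-restraints`,
`simulate-toy`, `synth`, `analyze`, `melt`, `tagci` and `run-all` lives at
`inst/cli/cgmelt.R`.

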