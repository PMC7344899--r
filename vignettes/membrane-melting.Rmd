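---
title: "Conformational restraints and membrane-binding melting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational restraints and membrane-binding melting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmelt)
```

## Scope and model

`cgmelt` implements two connected pieces of methodology for coarse-grained
(one backbone bead per residue) peptide–membrane simulations:

* Gaussian restraints on backbone internal coordinates that pin a chain in a
  helical or an extended-disordered conformation, with analytic Cartesian
  forces and tabulated-potential export;
* a contact-based "melting" analysis of multi-temperature binding
  trajectories: per-residue/global contact indices, melting curves,
  logistic melting-temperature (Tm) fits, the temperature-averaged global
  contact index (TAGCI), and segment-based convergence errors.

It deliberately does **not** implement a nonbonded force field, lipid
topologies, thermostats/barostats, or any engine integration beyond the
tabulated-potential files: production sampling belongs to a real MD engine;
this package prepares its bonded restraint inputs and analyses its output.

## The restraint potential

For three consecutive backbone beads $i,j,k$ the bend angle is
$\theta_{ijk} = \arccos(\hat u \cdot \hat v)$ with $u = r_i - r_j$,
$v = r_k - r_j$; for four beads the dihedral $\varphi_{ijkl}$ is the
four-quadrant `atan2` torsion with the cis (eclipsed) arrangement at 0°
and the sign fixed by the handedness of the two bond-plane normals about
the central bond (verified by a mirror-antisymmetry property test). The
restraint is a negative Gaussian well

$$V(x) = -K\, e^{-(x - x_\mathrm{min})^2/\sigma},\qquad
  \frac{dV}{dx} = \frac{2K (x - x_\mathrm{min})}{\sigma}\,
  e^{-(x-x_\mathrm{min})^2/\sigma},$$

summed over the center and, for dihedrals, two periodic images at
$x_\mathrm{min} \pm 360°$ so the energy is continuous across the ±180°
boundary (the residual jump is below $10^{-8}$ kJ/mol). Forms of this well
are sometimes printed with a positive exponent; that version is unbounded
below and cannot restrain anything, so the package implements the negative
exponent throughout — the only reading under which $V$ has its minimum
$-K$ at $x_\mathrm{min}$ and the force pulls toward it.

Cartesian forces follow the chain rule
$F = -\,dV/dx \cdot dx/dr$ with analytic angle gradients; the deg↔rad
conversion lives explicitly in $dx/dr$, and all user-facing angles,
centers and widths are in degrees.

### Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| $\theta_\mathrm{min}$ | deg | 96 (helical) / 124 (extended) | bend center |
| $\varphi_\mathrm{min}$ | deg | 60 (helical) / 100 (extended) | dihedral center |
| $\sigma$ | deg² (printed as 14°) | 14 | well-width constant; 1/e half-width $\sqrt\sigma \approx 3.7°$ |
| $K$ | kJ/mol | 50 | well depth per restraint |

Two conventions deserve a note. First, $\sigma$ divides a squared-degree
quantity but is conventionally quoted as "14°"; the package treats it as
the printed numeric value with $x$ in degrees and exposes it as a plain
scalar. Reported control calculations at $\sigma = 114°$ giving consistent
results suggest downstream observables are insensitive to this choice, so
we follow the printed denominator rather than guessing a $\sigma^2$ form.
Second, the production value of $K$ is not established in the literature
this implements; 50 kJ/mol is a typical CG bonded scale (deep enough that
well escapes are negligible at 310–450 K, $K/k_BT \approx 13$–19) and every
statistical test in the package is parameterised in $K$ so nothing depends
on the default.

A chain of $n$ residues receives $n-2$ bend and $n-3$ dihedral restraints
(`build_conformation_restraints()`); helical and extended sets differ only
in their centers. `export_tabulated_potential()` writes the
three-column (angle, $V$, $-dV/dx$) tables that mainstream engines accept
for tabulated bonded interactions, on $[0°,180°]$ for bends and
$[-180°,180°]$ for dihedrals.

## Validating the restraints statistically

Two toy samplers exist purely to certify the restraint implementation:

* **Internal-coordinate Metropolis** (`metropolis_sample()`): a scalar
  chain on $\theta$ or $\varphi$ with symmetric uniform proposals. Its
  stationary law is exactly $\propto e^{-V(x)/k_BT}$ on the coordinate's
  domain — no Jacobian, because the coordinate itself is the state — so the
  quadrature-normalized Boltzmann density (`boltzmann_density()`) is an
  exact oracle. Agreement is scored by the Kolmogorov–Smirnov distance;
  at $10^5$ samples (thinning 10) all mode/temperature combinations sit
  near 0.005, well under the 0.02 certification bound.
* **Overdamped Brownian dynamics** (`brownian_dynamics()`):
  $r \leftarrow r + \mu F \Delta t + \sqrt{2\mu k_B T \Delta t}\,\xi$ with
  restraint plus harmonic-bond forces ($b_0 = 0.35$ nm,
  $k_b = 1250$ kJ/mol/nm², CG backbone scale; mobility
  $\mu = 0.01$ nm²·(kJ/mol)⁻¹·ps⁻¹). Cartesian sampling induces a
  $\sin\theta$ measure on bend angles, so Brownian-dynamics averages are
  compared against the $\sin$-corrected quadrature expectation, keeping
  both oracles exact. With the default scales the first-order integrator is
  stable for $\Delta t \lesssim 5\times10^{-4}$ ps (set by
  $\mu\,k_\mathrm{eff}\,\Delta t < 1$ with the well curvature
  $2K/\sigma$ expressed per radian); the default configuration uses
  $10^{-4}$ ps, and force blow-ups abort with the offending step rather
  than propagating NaNs. $k_B = 0.0083145$ kJ/mol/K everywhere.

## Contact metrics

A residue is in membrane contact in a frame when the minimum-image distance
from its backbone bead to the nearest phosphate bead is **at most 1 nm**
(inclusive boundary — any convention works; inclusivity is fixed so tests
can be exact). "Cα" in atomistic descriptions of this metric maps to the
single backbone bead of a CG residue. Both leaflets' phosphates are
eligible partners. Boxes must be orthorhombic; triclinic cells are rejected
with a clear error rather than silently mis-wrapped.

From the binary residues × frames contact matrix:

* per-residue contact index = row mean;
* global contact index (GCI) = unweighted mean over a residue window
  (full sequence by default; the construct-comparison window is residues
  1–15);
* melting curve = GCI per temperature, rows always sorted by temperature;
* TAGCI = 15-residue-window GCI averaged with equal weights over the
  15-temperature ladder (equal weighting is the natural reading of
  "averaged across the temperatures");
* convergence error = population standard deviation of the GCI over three
  consecutive frame blocks, earlier blocks taking the remainder
  (10 frames → 4/3/3), a deterministic and testable split rule.

### Melting-temperature extraction

Published melting-curve comparisons report Tm shifts without fixing an
estimator, so the package adopts standard melting-curve practice: a
least-squares 4-parameter logistic
$\mathrm{gci}(T) = b + (a-b)/(1+e^{(T-T_m)/s})$ fitted by
Levenberg–Marquardt (`minpack.lm::nlsLM`), reporting the midpoint $T_m$,
the steepness $s$ and standard errors. A half-range crossing estimator
(`method = "midpoint"`) is exposed as well and used automatically if the
logistic fit fails to converge. Curves whose total decrease is below 0.2
raise a no-transition error instead of returning a meaningless midpoint.
Note the scaled-logistic structure of heterogeneous-affinity data (see
below) leaves the midpoint unbiased: scaling the plateau does not move
$T_m$.

## The synthetic campaign generator

`generate_campaign()` emulates the *statistical* structure of a
multi-temperature binding campaign, not its physics: each residue $r$ is an
independent two-state Markov chain in discrete frames whose stationary
bound probability is

$$p_r(T) = \frac{w_r}{1 + e^{(T - T_m^\mathrm{true})/s}},$$

with defaults $T_m^\mathrm{true} = 380$ K (the ladder midpoint),
$s = 10$ K (one ladder step), and an N-terminal-dominated weight profile
($w_r = 1$ for residues 1–7, then linearly down to 0.3) mimicking the
residue-resolved pattern of extended-state binding; set
`weights = rep(1, n)` for a uniform helical-like profile. The per-frame
on-rate default $k_\mathrm{on} = 0.05$ gives persistent bound/unbound runs
(lag-1 autocorrelation > 0.5), so segment-based convergence errors are
exercised on correlated data rather than i.i.d. frames. The off-rate is
derived from $k_\mathrm{on}$ and the target stationary probability (with
the pair rescaled when the derived rate would exceed one per frame, and
absorbing chains at $p = 0$ or $1$).

Rendering (`render_frames()`) places phosphates on a planar grid at
$z = 0$ and residues directly above grid nodes at truncated-Gaussian
heights (bound: mean 0.5 nm, unbound: 2.5 nm, jitter 0.1 nm, truncated so
bound < 1 nm < unbound); contact analysis of rendered frames therefore
reproduces the generated state matrix bit for bit, which is tested. A
jitter large enough to mix the two populations across the threshold is a
configuration error. Because rendering cannot change any analysed number,
the large recovery studies run on the state matrices directly
(`render = FALSE`, the default); the rendered path is covered by the
round-trip test and the file-format round trips.

Per-temperature RNG streams are derived deterministically from the single
campaign seed, so a campaign is exactly reproducible and distinct
temperatures are independent.

**What passing tests do and do not show.** The generator produces sigmoidal
melting, residue heterogeneity, temporal correlation and seed-stable
sampling noise — the features the analysis stack must handle. It has no
forces, no lipid dynamics, no conformational coupling between residues, no
drift or aging; recovery of $T_m$ to ±3 K here certifies the estimator
pipeline, not the force field or the sampling adequacy of any real
campaign.

## Numerical choices and degenerate inputs

* Collinear or coincident bead geometries raise classed errors
  (`cgmelt_degenerate_geometry`) rather than silently returning 0°/180°,
  which would produce NaN forces downstream.
* Dihedrals are reported in $(-180°, 180°]$; the $-180°$ edge maps to
  $+180°$.
* The tabulated-export self-consistency checks (column 3 vs the central
  difference of column 2, and linear re-interpolation of the table) are
  absolute $10^{-3}$ kJ/mol bounds whose truncation errors scale linearly
  with $K$; they are certified at $K = 5$ kJ/mol, and the table itself is
  exact to machine precision at any depth since both columns are analytic.
* The logistic fit is bounded ($a, b \in [0, 1.5]$, $s > 0$) and started
  from the half-range crossing; ties in the crossing bracket resolve to the
  bracket midpoint.
* Segment splitting gives remainders to earlier segments; the spread is the
  population (divide-by-$n$) standard deviation, matching the closed-form
  oracle $\sqrt{\mathrm{mean}((g - \bar g)^2)}$.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` certify: force/finite-difference
agreement on 1000 random poses (relative error $\le 10^{-5}$); KS < 0.02 at
$10^5$ Metropolis samples for both modes at 310 and 450 K; exact
brute-force equivalence of all contact metrics on random 30 × 1000
instances; Tm recovery within ±3 K and steepness within ±30% over 20
campaign seeds at 15 temperatures × 5000 frames; and recovery of a true
60 K Tm gap to within ±4 K — the desk-scale analogue of the
helical-versus-extended melting-temperature contrast. These sizes were
chosen as the smallest at which the statistical bounds are comfortably
non-marginal.

## Known limitations

* The restraints fix one conformational basin per run; conformational
  exchange between helical and extended states is outside the model.
* Only orthorhombic boxes; only GRO (nm) and PDB/DCD (Å) input dialects.
* The Brownian sampler is first-order and unthermostatted beyond its
  fluctuation–dissipation noise; it validates restraints, not kinetics.
* Contact analysis is binary per residue per frame; counts of phosphate
  neighbours, lipid-type resolution, insertion depth and curvature effects
  are out of scope.
* TAGCI assumes the construct is at least as long as the window (an error
  names the required length otherwise) and, by default, exactly the
  15-temperature ladder.
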