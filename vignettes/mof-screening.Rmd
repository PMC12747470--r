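---
title: "Hierarchical screening of MOFs for drug delivery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical screening of MOFs for drug delivery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mofscreen)
```

This vignette is the package's own account of the science it implements:
the models behind each screening stage, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, the
numerical choices, and the known limitations.

## The screening problem

A metal–organic framework is a crystalline solid of metal nodes bridged by
organic linkers. As a drug carrier it must (a) be built from
non-toxic components, (b) have pore openings wide enough for the drug to
enter, and (c) hold enough drug to be therapeutically useful. The package
encodes this as a hierarchical cascade — biocompatibility → porosity →
simulated loading → threshold — in which each stage only sees the
survivors of the previous one and every elimination is recorded with its
reason.

## Stage 1: biocompatibility of the building blocks

`split_building_blocks()` removes every atom classified as a metal
(alkali through actinide, packaged element table), takes connected
components of the remaining periodic bond graph, and unwraps each
component across cell boundaries into a finite molecule. Bonds are
perceived geometrically: atoms bond when their distance is at most the sum
of Cordero-type covalent radii plus a 0.45 Å tolerance, under the periodic
minimum image. Atoms that had coordinated a metal (O or N donors) are
capped with hydrogen by default, so carboxylate linkers are read back as
the carboxylic acids for which LD50 data are reported. A component that
reaches one of its own atoms at two different periodic images is an
infinite (rod-like) ligand; it is flagged `polymeric` and excluded from
classification with a warning rather than silently mis-featurized.
Components of six or fewer atoms are flagged `likely_solvent` but still
classified; every organic component counts.

**Metal verdicts** come from a packaged, user-replaceable CSV keyed by
element (the choice to score *elements* rather than salts or clusters is a
deliberate simplification; the note column records the representative-salt
LD50 behind each verdict). A metal absent from the table is an error — an
unknown metal must never pass silently. A whitelist argument admits
specific metals despite an adverse verdict; that is the route by which
well-tolerated Fe- and Zn-based carriers, whose in-vivo record is better
than their salt LD50 suggests, can re-enter a screen. The default
whitelist is empty.

**Linker toxicity** is a three-class problem. The UN GHS bins acute oral
toxicity by LD50 with inclusive upper bounds — (0,5] Cat 1, (5,50] Cat 2,
(50,300] Cat 3, (300,2000] Cat 4, (2000,5000] Cat 5, above that
unclassified — and the screening scheme groups these into *fatal*
(≤ 50 mg/kg, Cat 1–2), *toxic* ((50, 2000], Cat 3–4) and *safe*
(> 2000 mg/kg). The 50/2000 thresholds are package defaults, exposed in
configuration and echoed in every report; any sane grouping must call an
LD50 of 8300 mg/kg safe, and this one does. Boundary doses go to the more
toxic class, and prediction ties break toward toxicity — both choices are
conservative for a safety screen. A MOF is "highly biocompatible" only if
every metal passes *and* every unique linker is predicted safe (a
min-rule: one bad linker vetoes).

**Features** (`featurize_linker()`, version `fragments-v1`) are 47
substructure-pattern counts (element counts, bonded pairs, functional
groups, six-ring systems and ring substitutions), four Gasteiger
partial-charge statistics, and four shape descriptors (heavy atoms,
longest intramolecular distance, radius of gyration, cycle rank).
Substructure matching is VF2 subgraph isomorphism on element-colored
graphs and deliberately ignores bond orders: linkers recovered from
crystal structures carry only distance-perceived orders, and
connectivity-plus-element patterns are invariant to that choice. Charges
are assigned by Gasteiger–Marsili partial equalization of orbital
electronegativity, eight damped sweeps, with hybridization inferred from
bond orders (lengths, for crystal-derived fragments); the per-molecule
mean charge is computed as net charge over atom count exactly, because a
tree ensemble will happily split on 10^-17 floating-point noise.
Molecules without coordinates are embedded by classical MDS of graph
distances at 1.5 Å per bond — a fallback that preserves determinism, not
conformational realism.

**The classifier** is a 500-tree random-forest probability ensemble
(`ranger`), trained on a stratified 80/20 split with a fixed seed, chosen
over boosting for its robustness at this feature count and its
interpretability. The held-out report carries accuracy, per-class
precision/recall and the confusion matrix.

**Shapley explanations** use background-mean imputation: the value of a
coalition is the model evaluated with coalition features from the
instance and the rest at the background average, so the base value is the
model at the background mean and efficiency (base + Σφ = f(x)) holds
exactly — for the permutation estimator too, since per-permutation
contributions telescope. Exact enumeration runs up to 12 active features
(features equal to the background mean are inactive and get zero);
beyond that a seeded permutation sampler reports per-feature Monte-Carlo
standard errors, and exact enumeration above 30 features is refused. The
background set is caller-supplied; a subsample of the training features
(a hundred or two rows) is the recommended choice.

## Stage 2: pore geometry

All descriptors derive from a periodic distance grid: at each grid point,
the distance to the nearest atom's van der Waals surface (Bondi-type
radii, overridable), negative inside an atom. Defaults: 0.2 Å spacing for
reported descriptors, ~0.4–0.5 Å for library screening.

* **LCD** is twice the grid maximum, polished by a local Nelder–Mead
  maximization of the exact clearance function from the best grid point.
  The refinement removes the half-grid-diagonal discretization error, so
  LCD is near-exact at any spacing.
* **PLD** is found by incremental percolation: grid cells activate in
  decreasing clearance order and merge in a union-find that tracks
  periodic wrap offsets; the first merge that joins a component to its own
  periodic image (a mismatch in accumulated offsets) fixes the threshold
  t, and PLD = 2t. Percolation along *any* single lattice direction
  suffices — 1D channel systems count. PLD resolution is the grid spacing
  (bottleneck saddles off the grid cost up to a grid diagonal).
* **The pore-size distribution** is the histogram of
  largest-covering-sphere diameters over void points, computed by
  descending-radius ball marking with a subsumption skip (a center already
  covered by a sphere at least as large as its own is not re-expanded).
  The skip makes the transform exact on convex channels and cavities —
  the fixtures and the two-channel stand-in — and a close approximation
  in general. Peaks are local histogram maxima above a 2% weight floor,
  reported largest-first.
* **Accessible pore volume** is Monte-Carlo probe insertion: the fraction
  of uniform points with clearance ≥ probe radius, times cell volume over
  cell mass (cm³/g), with a binomial standard error. In accessible mode
  (default) only points whose grid component percolates at the probe
  radius count, excluding isolated pockets a guest could never reach.

The porosity gate is drug-specific: a framework passes for a drug iff
PLD ≥ that drug's minimal projection diameter (inclusive) and it has
accessible volume. The minimal diameter of a rigid guest is approximated
as the middle eigen-extent of its site cloud plus the largest site σ —
the width of the narrowest slab the molecule can slip through, up to the
rigid-bead idealization.

## Stage 3: GCMC loading

Uptake is simulated in the grand canonical ensemble: rigid guests, rigid
framework, fixed temperature and fugacity. The framework is replicated to
a supercell whose perpendicular widths are at least twice the 12.8 Å
cutoff so the minimum-image convention is valid. Moves are insertion /
deletion / translation / rotation at probabilities (0.25, 0.25, 0.40,
0.10) — insertion and deletion equal by detailed balance — with the
standard fugacity-form acceptance rules and uniform-quaternion
orientations. βfV is dimensionless with f in Pa, V in Å³ and
k_B = 1.380649·10⁷ Pa·Å³/K. The maximum translation is tuned toward 40%
acceptance during equilibration and frozen for production, preserving
detailed balance where averages are taken. Production guest counts are
block-averaged (10 blocks) for the standard error; a run in which no
insertion ever succeeds returns a zero-loading record flagged
`inaccessible` instead of an exception. All randomness flows through R's
RNG, so a seed fixes the trajectory bit-for-bit.

Energies are 12-6 Lennard-Jones in Kelvin with Lorentz–Berthelot mixing,
truncated (optionally shifted) at 12.8 Å, with generic UFF-style
parameters for framework elements in a packaged editable table.
Electrostatics default off (a damped-shifted-force option exists):
packing-driven uptake ranking is dominated by the repulsive/dispersive
terms, and Ewald summation is out of scope. "Loading capacity" is
operationalized as uptake at a single high-fugacity operating point,
default 10⁵ Pa at 298 K, converted as mg/g = 1000·⟨N⟩·M_guest/M_box and
wt.% = 100·m_drug/(m_drug + m_framework), so 1 g/g is exactly 50 wt.%.
An optional accessibility mask pre-rejects insertions outside the
percolating void component (default on in the pipeline), so closed
pockets do not inflate capacities.

The simulation core is validated against analytic oracles rather than
reference data: the empty box reproduces ⟨N⟩ = βfV with Poisson number
fluctuations; Widom insertion gives K_H = β·⟨e^(−βΔU)⟩ and GCMC uptake at
low fugacity matches K_H·f·V; a lattice-gas mode with M independent sites
matches its closed-form isotherm M·x/(1+x), x = z·e^(−βε), across
activities; and the incrementally updated energy is checked against full
recomputation (relative drift below 10⁻⁶ over long runs).

## Stage 4: threshold and reporting

The loading threshold is 1000 mg/g (1 g drug per g framework, 50 wt.%),
inclusive, and a framework passes overall only when it passes for *every*
requested drug (a config switch selects the any-drug reading).
`loading_volume_regression()` fits loading against accessible pore volume
above the PLD knee, the regime where capacity is volume-limited. Reports
are exported as deterministic CSV + JSON with one terminal state and
reason per structure.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions for every test in the package:

* `make_cubic_framework()` (one atom per cell corner) has closed forms
  LCD = √3·a − 2r and PLD = √2·a − 2r; `make_dilation_series()` scales it
  so that accessible volume strictly increases at fixed topology, the
  family on which loading-vs-volume scaling is demonstrated.
* `make_channel_framework()` builds straight 1D channels of prescribed
  free diameter through a tight atom-grid wall; `make_pcn222_like()` uses
  it with 36 and 17 Å channels as a *synthetic geometric stand-in* for
  the PCN-222 channel system (licensed crystal structures cannot be
  shipped). It reproduces the channel metrics — not the crystal
  chemistry, topology or atom types.
* `make_toxicity_dataset()` (defaults: n = 2000, priors 0.25/0.35/0.40,
  log10-LD50 noise σ = 0.35, seed 7) assembles molecules from a
  benzene/pyridine fragment grammar in which each decoration carries a
  multiplicative LD50 effect (nitro is the planted potent toxicophore at
  10^-2.3, aromatic amine 10^-0.7, halides mildly negative, hydroxyl /
  carboxyl / methyl mildly positive). Expected log-LD50 is an exact
  function of composition, so the Bayes-optimal rule and its accuracy on
  the realized sample are returned with the data (≈ 0.95–0.97 under the
  defaults). Tests accept a held-out accuracy within [B − 0.07, B + 0.02]
  of the realized Bayes accuracy B; the +0.02 is a finite-validation-set
  allowance fixed at design time. The grammar spans the package's own
  pattern list, *not* the chemical diversity of real linker libraries —
  a classifier passing here demonstrates correct learning machinery, not
  real-world toxicology performance.
* `make_screening_library()` produces the six-structure end-to-end
  fixture (two toxic-metal, two dense, two porous-safe frameworks around
  an embedded terephthalate-style linker) with a ground-truth manifest of
  expected terminal stages: 6 → 4 → 2.

Every generator is a pure function of its arguments and seed.

## Numerical choices and degenerate inputs

Fractional coordinates always wrap to [0,1); symmetry images closer than
0.1 Å merge (typical CIF precision); sites with occupancy below 1 are
rejected — disorder modeling is out of scope. Empty (zero-site) boxes are
legal in GCMC and volume routines (they are the ideal-gas oracle) but
massless boxes report NA loadings; geometry descriptors require at least
one site. GCMC requires orthogonal cells; the spec of every packaged
fixture is orthorhombic, and skewed cells are rejected with a clear
message rather than simulated incorrectly. Test and acceptance problem
sizes (grids near 0.2–0.45 Å, 10³–10⁴ GCMC cycles, n = 2000 training
records) were chosen as the smallest sizes at which the analytic oracles
resolve their targets comfortably.

## Known limitations

* Guests are rigid coarse beads with the right masses and size ordering;
  conformational flexibility (paclitaxel especially) is ignored, and
  cross-drug mg/g comparisons inherit the arbitrariness of the coarse
  well depths. Rankings across frameworks for a fixed guest are the
  meaningful output.
* No electrostatic Ewald summation, no framework flexibility, no solvent,
  no mixture co-adsorption; capacities are vacuum single-component
  numbers and will overestimate wet-lab loadings.
* Canonical linker signatures use iterated neighborhood refinement;
  theoretical blind spots (distinct strongly regular graphs) do not arise
  for chemical fragments at these sizes.
* The covering-sphere PSD uses a subsumption-skip approximation away from
  convex void shapes.
* Line-notation (SMILES) input is not parsed; molecules enter as explicit
  atom/bond tables or through the fragment grammar.
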