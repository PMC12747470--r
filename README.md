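# mofscreen

Hierarchical virtual screening of metal–organic frameworks (MOFs) as
drug-delivery carriers, for computational chemists and materials scientists
who want to rank candidate frameworks before any synthesis. The package
implements the full desk-side cascade:

1. **Biocompatibility of the building blocks.** A MOF is deconstructed into
   its metal centers and organic linkers. Metals are looked up in a curated
   toxicity table (Zr-class metals pass; Cd, Ni and the like fail; Fe/Zn can
   be admitted through an explicit whitelist). Linkers are classified
   *fatal* / *toxic* / *safe* from acute oral-rat LD50 structure–activity
   data: the three classes group the UN GHS acute-toxicity categories at
   LD50 ≤ 50, (50, 2000], and > 2000 mg/kg. The classifier is a random-forest
   ensemble over substructure-fragment counts, Gasteiger partial-charge
   statistics and shape descriptors, and every prediction can be explained
   with Shapley values (exact coalition enumeration up to 12 active features,
   seeded permutation sampling beyond).
2. **Porosity.** On a periodic distance grid the package computes the
   largest cavity diameter LCD = 2·max<sub>r</sub> d(r), the pore-limiting
   diameter PLD (largest probe that percolates to its own periodic image,
   by union-find percolation over grid levels), the pore-size distribution,
   and the guest-accessible pore volume (Monte-Carlo probe insertion,
   optionally restricted to the percolating component). A framework passes
   for a drug iff PLD ≥ the drug's minimal projection diameter.
3. **Loading capacity.** Grand canonical Monte Carlo of rigid coarse guest
   models in the rigid framework at fixed (μ,V,T), with the standard
   fugacity-form acceptance rules — insertion
   min{1, βfV/(N+1)·e^(−βΔU)}, deletion min{1, N/(βfV)·e^(−βΔU)} — a
   Lennard-Jones force field with Lorentz–Berthelot mixing, and conversion
   of ⟨N⟩ to mg drug per g framework and wt.% (1000 mg/g ⇔ 50 wt.%).
4. **Threshold ranking.** Candidates must load at least 1 g drug per g MOF
   (inclusive), for every requested drug by default.

Because licensed structure databases cannot be redistributed, the package
ships first-class synthetic-data generators: corner-lattice frameworks with
closed-form LCD/PLD, dense blocks, channel frameworks with prescribed free
diameters (including a synthetic PCN-222-like two-channel stand-in at 3.6
and 1.7 nm), a lattice-gas system with an exact isotherm as a GCMC oracle,
coarse guest models with the formula masses of gemcitabine (263.2 g/mol),
SN-38 (392.4 g/mol) and paclitaxel (853.9 g/mol), and an LD50 dataset
generator with planted fragment→toxicity rules whose Bayes-optimal accuracy
is computable alongside the sample.

## Worked example

```r
library(mofscreen)

# train the linker toxicity classifier on the synthetic LD50 benchmark
ds  <- make_toxicity_dataset(n = 2000, seed = 7)
mod <- train_toxicity_classifier(ds, seed = 7)
mod
#> toxicity_model (fragments-v1): 500 trees, trained on 2000 records
#>   held-out accuracy: 0.975 (n = 402)

# a trimesic-acid-like linker (benzene + 3 COOH) comes out "safe",
# matching its reported oral-rat LD50 of 8300 mg/kg
btc <- build_linker("benzene", c("carboxyl", "carboxyl", "carboxyl"))
predict_toxicity(mod, btc)$probabilities
#>      fatal toxic  safe
#> [1,]     0 0.034 0.966

# screen the six-structure synthetic library against all three drugs
lib    <- make_screening_library()
drugs  <- make_guest_models()[c("gemcitabine_like", "sn38_like", "paclitaxel_like")]
report <- screen_library(lib$structures, drugs, mod,
                         screen_config(cycles = 1200, equilibration = 300,
                                       spacing = 0.45))
report
#> screening_report:
#>   survivors: input 6 -> biocompat 4 -> porosity 2 -> threshold 0
#>   lib_cd_porous      biocompat  biocompatibility: metal Cd is not_biocompatible
#>   lib_ni_porous      biocompat  biocompatibility: metal Ni is not_biocompatible
#>   lib_zr_dense1      porosity   porosity: PLD 0.50 A below every drug's minimal diameter
#>   lib_zr_dense2      porosity   porosity: PLD 0.68 A below every drug's minimal diameter
#>   lib_zr_porous1     loading    threshold: loading below 1000 mg/g for drug(s) ...
#>   lib_zr_porous2     loading    threshold: loading below 1000 mg/g for drug(s) ...
```

The cascade narrows 6 → 4 → 2 exactly as the library's ground-truth
manifest prescribes: the Cd/Ni frameworks fail on their metal, the dense
Zr frameworks fail the porosity gate, and the two porous Zr frameworks
reach the GCMC loading stage (at the default 10⁵ Pa operating point their
simulated capacities sit below the 1 g/g bar, so they are ranked but not
passed). `export_report()` writes the full audit trail as CSV + JSON.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mofscreen` (subcommands `decompose`, `pores`, `gcmc`, `synth`,
`screen`).

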