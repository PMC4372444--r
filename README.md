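# memnmr

Ensemble modeling and thermodynamic analysis of flexible, membrane-associated
peptides from sparse magic-angle-spinning solid-state NMR data.

## The problem

Short lipidated peptide hormones such as acyl-ghrelin are highly flexible at
the membrane surface: no single conformer explains the data, circular
dichroism and solution NMR disagree about their helicity, and the solid-state
NMR observables that *are* measurable — isotropic chemical shifts for a
subset of residues, C–H dipolar order parameters, and ¹H spin-diffusion
buildup from the lipid into the peptide — are sparse. `memnmr` implements
the full analysis chain for this situation:

1. **Chemical-shift data handling** — per-residue/per-atom shift tables,
   restraint selection, and the Cα/Cβ secondary-shift index
   (Δδ꜀ₐ − Δδ꜀ᵦ; > +1 ppm helical, < −1 ppm sheet-like).
2. **Conformer pools** — ideal-geometry backbone construction from φ/ψ/ω
   torsions, multi-model PDB I/O, and three pool filters: membrane polar-slab
   depth of an anchor Cα, minimum receptor distance, and an energy
   percentile over the reference pool.
3. **Monte Carlo ensemble selection** — searches the filtered pool for an
   ensemble of 10–30 models whose *ensemble-averaged* predicted shifts
   minimize the RMSD to experiment,

   RMSD = sqrt( mean_r [ (⟨δ_pred(r)⟩ − δ_exp(r)) / s_r ]² ),  s_r = 4 for
   carbons, 1 for protons,

   with add/swap/remove moves, greedy or Metropolis acceptance, and a fully
   seeded, reproducible trace.
4. **PPII-aware secondary structure** — relabels DSSP coil (`-`) as
   polyproline II (`P`) when φ = −75 ± 29°, ψ = 145 ± 29° for at least two
   sequential residues, plus per-position ensemble composition.
5. **Spin diffusion** — the 1D lattice model
   dM_i/dt = −2Ω M_i + Ω M_{i+1} + Ω M_{i−1} with a clamped lipid reservoir,
   T1 correction, normalization at 900 ms, and integer step-distance
   fitting; C–H order parameters S = coupling/22.8 kHz.
6. **Binding thermodynamics** — % bound from supernatant/pellet
   fluorescence, effective-lipid correction (× 0.45), hyperbolic-isotherm
   K_D fitting, ΔG⁰ = RT ln(K_D/55.5 M), a mole-fraction partition model,
   Henderson–Hasselbalch net charge, and additive binding-energy budgets.
7. **Synthetic data** — seeded generators replacing the external folding and
   shift-prediction tools, so every stage is testable offline.

## Worked example

```r
library(memnmr)

# a 500-model synthetic pool, 70 % helix-rich / 30 % coil
rec  <- pool_recipe(500, class_mix = c(helix = 0.7, ppii = 0, coil = 0.3),
                    seed = 2024)
pool <- gen_pool(rec)

# "experimental" shifts = average over 20 helix-rich models + 0.1 ppm noise
classes <- vapply(pool$models, `[[`, "", "ss_class")
truth   <- pool$models[classes == "helix"][1:20]
tb  <- gen_experimental_shifts(truth, pool$sequence, noise_sd = 0.1, seed = 11)
rs  <- select_restraints(tb, c("CO", "CA", "CB", "HA"))
rs
#> <restraint_set> 111 restraints (83 carbon, 28 proton)

ens <- select_ensemble(pool, rs,
                       selection_config(min_size = 10, max_size = 30,
                                        cycles = 20000, seed = 5))
ens
#> <ensemble> 26 members, CS-RMSD 0.0277 ppm (initial 0.0853)
mean(ens$member_ids %in% which(classes == "helix"))
#> [1] 1
```

The selector recovers a pure helix-rich ensemble (fraction 1.0) and drives
the scaled shift RMSD from 0.085 ppm (random start) to 0.028 ppm, the noise
floor of the generated "experiment".

Thermodynamics from the printed assay numbers:

```r
delta_g_from_kd(520e-6)                          # K_D = 520 uM, 310.15 K
#> [1] -29.85505                                 # kJ/mol
net_charge(GHRELIN_SEQUENCE, charge_config(pH = 6))
#> [1] 5.79753                                   # elementary charges
binding_energy_total(c(-13.4, -12))              # hydrophobic + electrostatic
#> [1] -25.4                                     # kJ/mol
```

Chemical-shift index of the packaged measured table (sheet-like torsions at
the N-terminus, helical tendency around residues 8–12):

```r
tab <- read_shift_table(system.file("extdata", "ghrelin_shifts.csv",
                                    package = "memnmr"))
head(chemical_shift_index(tab, read_random_coil_reference()), 4)
#>   residue_number residue_name csi_ppm label
#> 1              2          SER    -1.4 sheet
#> 2              3          SER    -4.2 sheet
#> 3              4          PHE     0.7  none
#> 4              5          LEU    -1.5 sheet
```

## Command line

A thin CLI wraps the main entry points (see `inst/cli/memnmr`):

```sh
memnmr charge --sequence GSSFLSPEHQRVQQRKESKKPPAKLQPR --ph 6
memnmr binding-fit --data assay.csv
memnmr csi --table shifts.csv
memnmr spindiff-fit --curve ser3.csv --omega 25 --nmax 12
memnmr run --config run.yaml
```

See `vignettes/memnmr-methods.Rmd` for the model assumptions, parameter
choices, and known limitations.
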