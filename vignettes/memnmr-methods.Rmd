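---
title: "Methods and design notes for memnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for memnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memnmr)
```

# Scope and model

`memnmr` analyzes flexible, membrane-associated peptides for which only
sparse solid-state NMR observables exist. The central modeling assumption
is *ensemble averaging*: a highly mobile peptide interconverts between
conformers faster than the chemical-shift timescale, so the measured
isotropic shift of each atom is the population-weighted mean over the
conformational ensemble, not the shift of any single structure. The
package therefore never tries to fit one conformer; it searches a large
pool of candidate backbones for a small sub-ensemble whose *averaged*
predicted shifts reproduce experiment.

The upstream tools that would produce such a pool in a production study
(a fragment-assembly folding engine with an implicit membrane score, and
a trained chemical-shift predictor) are deliberately out of scope.  They
are replaced by seeded generators (`pool_recipe()`, `gen_pool()`,
`toy_shift_model()`) so that every downstream algorithm can be tested
offline with known ground truth.

# The selection objective

For restraint set $R$ (atoms CO, Cα, Cβ, Hα of the measured residues,
excluding the N-terminal glycine whose shifts are perturbed by the free
amine), the objective is

$$\mathrm{RMSD}(E)=\sqrt{\frac{1}{|R|}\sum_{r\in R}
\left(\frac{\bar\delta_E(r)-\delta_{\exp}(r)}{s_r}\right)^2},\qquad
s_r=\begin{cases}4 & r\ \text{carbon}\\ 1 & r\ \text{proton}\end{cases}$$

where $\bar\delta_E(r)$ is the arithmetic mean of the member predictions.
Dividing carbons by 4 stops their ~10× larger ppm magnitudes from
dominating the pooled residual vector; the scaling is applied to the
residuals (both sides), not as a weight, so the reported RMSD remains in
ppm.  Uncertainties from the shift table are carried through the data
model but never enter the objective — the RMSD is unweighted.

## Monte Carlo moves and acceptance

Each cycle proposes one move chosen uniformly among the currently legal
ones: *add* a uniformly chosen non-member (if below the maximum size and
the pool is not exhausted), *swap* one uniformly chosen member against
one uniformly chosen non-member, or *remove* a uniformly chosen member
(if above the minimum size).  The published description of this class of
algorithm states the moves and the cycle count but not the acceptance
criterion.  The default here is **greedy** (accept iff the objective does
not worsen): it is the minimal reading of the flowchart, makes the trace
monotone, and makes the selector testable against exhaustive enumeration.
A **Metropolis** mode at fixed temperature is exposed for users who
suspect the original used stochastic acceptance (a cycle count of
5×10⁶ hints at it); in both modes the *best-seen* ensemble is returned,
so the Metropolis mode is safe by construction.  The reported RMSD is
recomputed from scratch on the returned member set, eliminating
incremental-update drift (tested to 10⁻¹⁰ ppm).

The implementation keeps per-restraint running sums, so a cycle costs
O(|R|); the 5×10⁶-cycle production default runs in minutes, while tests
and the acceptance script use 10⁴–10⁵ cycles, which suffice for the pool
sizes they examine.

# Pool filters

Three pure predicates, commuting as set operations:

* **Membrane slab** — keeps models whose anchor-residue Cα satisfies
  `slab_zmin ≤ |z| ≤ slab_zmax`.  The defaults (12–18 Å from the bilayer
  center) are this package's own choice: the source protocol invokes
  "the polar region" of an implicit membrane without printing numbers, so
  we adopt the conventional hydrophobic half-thickness (~12–15 Å) plus an
  interfacial shell, and make both bounds configurable.  Because the
  original bounds are unrecoverable, the printed survivor counts of the
  original study (3,692 → 355) are not reproduction targets.
* **Receptor distance** — keeps models whose minimum backbone-to-receptor
  atom distance is ≥ 5 Å.  The receptor is a spatial proxy only.
* **Energy percentile** — cutoff at the `ceiling(f·N)`-th lowest energy
  of a *reference* pool (by default the pool itself; passing the original
  unfiltered pool reproduces a percentile-over-all-models protocol).
  Ties at the cutoff are included, so the fraction is a lower bound.

# PPII overlay

Hydrogen-bond-based secondary-structure assignment reports polyproline II
helix as coil, because PPII lacks regular intra-chain hydrogen bonds.
The overlay relabels a coil residue as `P` iff φ ∈ [−104, −46]°,
ψ ∈ [116, 174]° (closed windows; they avoid ±180°, so no wrapping issues)
and at least one sequence neighbor also satisfies all conditions — i.e.
runs of `P` have length ≥ 2.  The alternative "strict pair" reading
(both of a specific adjacent pair qualify) yields identical results, and
the duplicated condition numbering in the source description is read as
four conditions.  Only `-` is ever rewritten; bend/turn (`S`/`T`)
residues are *not* eligible, following the stated rule literally.  DSSP
itself is not re-implemented: assignments come from `.dssp` files
(`read_dssp()`) or, for backbone-only synthetic models, from a documented
torsion-region fallback (`assign_ss_torsion()`).

# Spin diffusion

The 1D lattice model moves magnetization between neighboring spins at
rate Ω; interior sites obey
$\dot M_i = -2\Omega M_i + \Omega M_{i+1} + \Omega M_{i-1}$ and chain
ends $\dot M = \Omega(M_{nb} - M)$.  Two conventions deserve comment:

* **Rate from D and a.** The printed relation "Ω = D/a" is dimensionally
  inconsistent (nm²/s ÷ nm is a velocity).  When Ω is derived from a
  diffusion coefficient, the package uses the standard lattice relation
  Ω = D/a², *flags* the discrepancy in the spec's provenance string, and
  otherwise treats Ω as a direct user input.  Note that D = 0.001 nm²/s
  with a = 2 Å gives Ω = 0.025 s⁻¹, far too slow for buildup within
  900 ms; a units slip (nm²/ms) in the source is plausible but is not
  silently assumed.
* **Source mode.** The lipid proton reservoir dwarfs the peptide's, so
  the default clamps the source site at unit magnetization
  (`clamped_reservoir`).  An `initial_pulse` mode without clamping is
  provided; it conserves total magnetization (tested to 10⁻⁹) and
  supports conservation-law checks.

The solver is a symmetric eigendecomposition (exact matrix exponential);
an explicit fixed-step RK4 integrator under the diffusion stability bound
Δt ≤ 1/(4Ω) cross-validates it.  RK4 was chosen over forward Euler
because Euler's O(Δt) global error cannot reach the 10⁻⁶ cross-validation
tolerance at the stated step size.

T1 correction divides by exp(−t/T1) (the standard longitudinal-decay
correction; the source does not print a formula), then the curve is
normalized to 1 at the longest mixing time (900 ms).  Step-distance
fitting simulates sites 1..n_max on a chain with n_max + 2 free sites
(insulating the far boundary), normalizes each candidate trace the same
way, and returns the SSE-minimizing integer distance, ties toward
smaller n.  The acquisition-side T2 filter (6 ms) has no counterpart in
the model and is not simulated.

# Binding thermodynamics

* **Isotherm.** The source text cites only the %-bound definition as its
  "equation (1)", not a binding model; the package fits the standard
  single-site hyperbola $f(L)=B_{max}L/(K_D+L)$ with $B_{max}\in(0,1]$
  free, consistent with the observed >90 % saturation.  Start values come
  from a Hanes linearization ($L/f$ vs $L$), which makes the bounded
  port-algorithm fit robust; "false convergence" reports on noiseless
  data (objective already at machine zero) are accepted.
* **Standard state.** ΔG⁰ = RT ln(K_D/55.5 M) at T = 310.15 K.  This
  mole-fraction convention at the incubation temperature (37 °C, even
  though centrifugation was at 4 °C) exactly reproduces the printed
  −29.9 kJ/mol from K_D = 520 µM, which is why it was fixed as the
  default.
* **Effective lipid.** Total lipid × 0.45: ~90 % of lipid pellets and
  only the outer leaflet (50 %) is peptide-accessible.
* **Net charge.** Henderson–Hasselbalch sums with a conventional
  intrinsic pKa set (Arg 12.5, Lys 10.5, His 6.5, Glu 4.25, Asp 3.65,
  Tyr 10.1, Cys 8.3, termini 9.0/3.6), chosen because it reproduces the
  printed +5.8 at pH 6 for the ghrelin sequence; fully overridable.
* **Partition model.** $K_x=\exp(-\Delta G/RT)$,
  $f=K_xX_L/(1+K_xX_L)$ with $X_L=L_{eff}/(L_{eff}+55.5\,\mathrm{M})$.
  The source's "~8 %" (from −13.4 kJ/mol) and "~90 %" (from −25 kJ/mol)
  bound fractions are *not* reproducible under any single standard
  partition convention at the stated lipid concentrations; this package
  fixes one convention, documents it, and does not treat those two
  figures as targets.  The −12 kJ/mol electrostatic term is a literature
  constant (pentalysine on slightly anionic membranes), consumed as an
  input, never computed — Gouy–Chapman modeling is out of scope.

# Synthetic data: what it emulates, and what a green test means

The generators emulate *structure*, not physics:

* Pools draw per-model torsion classes (helix −57/−47, PPII −75/145,
  coil broad) with 10° Gaussian jitter, ideal-geometry backbones, a
  uniform anchor-depth draw over 0–30 Å, and class-dependent Gaussian
  energies (helix −20, PPII −15, coil −10, σ = 5) under which
  helix-rich models score best — emulating a scorer that rewards
  compact hydrogen-bonded structure.  These defaults are this package's
  realistic-world choice where the sources state none, and they are not
  tuned against test outcomes.
* The toy shift predictor is linear: random-coil base (a Wishart-style
  1995 table shipped with provenance label, user-overridable — the
  original study never names its reference set) + class offset
  (helix Cα +2.5, Cβ −0.5 ppm, standard secondary-shift magnitudes) +
  Gaussian noise.  Linearity makes the selection optimum analytically
  known; it has none of the sequence- or geometry-sensitivity of a real
  predictor.

A green recovery test therefore establishes that the *algorithms* are
correct (the selector finds planted ensembles, the isotherm fitter
recovers planted constants, the step fitter recovers planted distances)
— not that the pipeline would reproduce any particular published
ensemble, which depended on an unpublished 10,000-model pool and
predictor.  The headline production results (22 models, 0.4 ppm,
PPII at 21–23/26–27) are consequently checked as *properties*, never as
numbers.

# Numerical choices

* Backbone builder: NeRF chain extension with ideal bond lengths
  (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å) and standard angles; ω
  defaults to 180° with no cis-proline handling (synthetic pools only).
  Torsion re-measurement recovers inputs to < 10⁻³ °.
* Energy-percentile ties included (≤ cutoff); membrane slab symmetric in
  |z| across both leaflets.
* Isotherm identifiability guard: ≥ 4 distinct concentrations required.
* Shift CSV round trips are written at full decimal precision.
* All stochastic code paths take explicit seeds; two runs with the same
  seed are byte-identical.

# Known limitations

* No side chains, hydrogen bonds, or real DSSP — the torsion-only
  fallback is cruder than DSSP near element boundaries.
* The toy shift model applies one class offset per model, uniformly over
  residues; real peptides mix secondary structure within a chain.
* The lattice model is 1D with a single Ω for lipid, interface and
  peptide; real spin diffusion is 3D and rate-heterogeneous.
* The multi-model PDB reader handles only the package's own
  backbone-only files, not general PDB.
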