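---
title: "Models and methods behind cyclomimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyclomimic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cyclomimic)
```

`cyclomimic` implements the computational arc of a loop-mimetic design
study: graft a protein surface-loop epitope onto a short linker, cyclise it
head to tail, sample its conformations, determine its structure from NOE
data, and quantify how well the result mimics the source loop. This
vignette explains each model, the parameters that matter, and the design
choices made where the problem left them open. The worked design used
throughout is the TNFR-1 loop epitope `HYWSENLFQ` plus a Pro–Gly linker —
an 11-mer macrocycle.

## The molecular representation

Residues use a reduced template: backbone `N`, `CA`, `C`, `O`; a `CB` for
every non-glycine residue; one side-chain centroid pseudo-atom `SC` for
residues with heavy atoms beyond CB (at a per-residue CB–SC distance, e.g.
1.43 Å for Ser, 3.9 Å for Arg); and three protons — the amide `HN` (absent
on proline), `HA`, and a single β pseudo-proton `HB` (absent on glycine).

The choice is deliberate: the NOE machinery in this package only ever
restrains HN, HA and HB, so atoms finer than a β centroid add cost without
information. The price is that side-chain packing is coarse; the package is
about backbone folds, and backbone comparisons (N, CA, C) are unaffected.
Restraints to `HB` receive a +1.0 Å upper-bound pseudo-atom allowance, the
standard compensation for replacing a proton group by its centroid.

Ideal geometry (bond lengths; 109.47° at sp³ centres, 120° at sp² centres)
is frozen into every topology from the force-field parameter object, so the
builder, the potential and the internal-coordinate (NeRF) chain
construction are exactly self-consistent: an extended build scores
essentially zero bond, angle, torsion and chirality energy. Chirality
improper targets are measured off the ideal template itself rather than
hard-coded, which guarantees the same consistency for any parameter
override. Handedness is a fixed convention of the template (CB at −120°
about the N–CA axis); NOE data cannot distinguish mirror images, so the
convention, not the data, pins the enantiomer.

## The potential

The energy is a transparent geometric model, authored for this package (it
deliberately replaces molecular-mechanics force fields so that every term
is auditable; absolute values are not comparable to AMBER-class energies):

| term | form | default constant |
|---|---|---|
| bond | $k_b(r-r_0)^2$ | 1000 kJ mol⁻¹ Å⁻² |
| angle | $k_a(\theta-\theta_0)^2$ | 150 kJ mol⁻¹ rad⁻² |
| rotor (φ, ψ, χ) | $k_t(1+\cos 3\phi)$ | 2 kJ/mol |
| repulsion | $k_r(r_{min}-r)^2,\ r<r_{min}$ | 200 kJ mol⁻¹ Å⁻²; radii 1.45 Å heavy / 1.0 Å H |
| ω planarity | $k(1-\cos(\omega-\omega_0))$ | 80 kJ/mol; ω₀ = 180° (trans) or 0° (cis) |
| chirality impropers | $k(1-\cos(\phi-\phi_0))$ | 80 kJ/mol |
| ring closure | closure bond + its angle/ω terms | bond constant |
| NOE restraints | flat-bottom, harmonic walls | k ramped 2 → 50 kJ mol⁻¹ Å⁻² |
| compaction | $k_{rg}(R_g-R_{g0})^2,\ R_g>R_{g0}$ | off (generator only) |

Non-bonded pairs exclude 1-2 and 1-3 neighbours. There is no attraction,
electrostatics or solvation: the potential's job is to keep geometry ideal,
chirality and ω configurations fixed, sterics honest and the ring closed,
while NOE restraints (or nothing) decide the fold. The proline
configuration requested in the design (trans by default, per the usual
small Cβ–Cγ shift difference criterion implemented in
`classify_proline()`: Δδ ≤ 6 ppm trans, ≥ 8 ppm cis) is enforced by the ω
target of the X–Pro bond throughout every stage, never only at the end.

Analytic gradients back an L-BFGS minimiser (`stats::optim`) iterated to an
RMS-gradient tolerance, default 0.01 kJ mol⁻¹ Å⁻¹ over all 3N coordinates;
the gradient is property-tested against central finite differences.

## Conformational search and Boltzmann analysis

`monte_carlo_search()` is basin hopping: every atom is displaced by an
independent uniform vector of norm ≤ `max_displacement` (default 3 Å), the
structure is minimised, and the move is accepted by the Metropolis rule on
*minimised* energies at the search temperature (default 500 K, 5000
steps). Reading a "Monte-Carlo conformational search with per-step
minimisation" as basin hopping is the standard interpretation when no
explicit acceptance rule is given, and it makes the search's output a set
of distinct local minima — exactly what downstream docking or Boltzmann
analysis wants. `boltzmann_weights()` shifts energies by the ensemble
minimum before exponentiating (pure overflow hygiene; every ratio is
unchanged) and reports ratios relative to the highest-energy conformer,
with R = 8.314×10⁻³ kJ mol⁻¹ K⁻¹ so that kJ/mol energies and kelvin
temperatures are dimensionally consistent.

On a tetraglycine cycle the search is cross-checked against
`grid_torsion_scan()`, an exhaustive 30° enumeration of all build torsions
with sound triangle-inequality pruning of branches that cannot close the
ring, followed by minimisation of the best grid points. The tests assert
the search reaches the grid minimum to within 1 kJ/mol (it may go lower:
the grid is resolution-limited).

## NOE calibration and restrained annealing

Calibration is the inverse-sixth-power law
$r_{ij} = r_{ref}(\alpha_{ref}/\alpha_{ij})^{1/6}$ against a reference pair
of known distance. Bounds are flat-bottom at ±0.5 Å (no bounds scheme being
dictated by the data, this is conventional NMR practice), the lower bound
clamped to the 1.8 Å hard-sphere contact where possible.

Annealing runs in torsion space: single-torsion pivot moves (φ, ψ and
non-proline χ; ω never moves) with Metropolis acceptance, cooling
geometrically from 3500 K to 100 K (60,000 steps by default; the package's
tests use 10,000-step schedules, the problem size at which the recovery
experiments below are run). Pivot moves on a macrocycle necessarily break
the ring open transiently; the closure bond and its angle/planarity terms
act as the restoring penalty, and every accepted structure is finally
Cartesian-minimised. Move amplitude scales with √(T/T₀) from 120° down to
8°, so the hot phase hops between folds and the cold phase anneals within
one. The NOE force constant ramps linearly 2 → 50 kJ mol⁻¹ Å⁻² during
cooling — weak restraints guide early, strong restraints discipline late —
and a final refinement stage re-minimises with the constant escalated ×4
(up to five rounds) until every restraint sits inside its flat bottom, the
usual high-constant final stage of NMR refinement. Reported energies are
always evaluated at the schedule's end constant.

`violation_report()` counts a restraint satisfied when its violation is
below 0.01 Å: gradient refinement approaches a flat bottom asymptotically,
so an exact-zero test would never report full satisfaction; 0.01 Å is at
the minimiser's convergence scale and fifty-fold below the bound
half-width. The maximum violation is always reported exactly.

## Ensemble analysis

Superposition is closed-form Kabsch (SVD with the determinant correction),
tested against a brute-force rotation search: a 10° global ZYZ Euler grid
followed by exhaustive 1° local refinement, using the identity that for a
fixed rotation the optimal translation aligns centroids. "Backbone" means
N, CA, C — carbonyl O excluded, the common main-chain convention when a
source does not define one. Cyclic-to-reference residue mapping is by
position (epitope-first designs align the grafted epitope onto its source
loop); re-registration of the cycle is deliberately not attempted.
Clustering is average-linkage on the pairwise backbone-RMSD matrix with a
2.0 Å default cutoff — both unstated in typical experimental reports, so
chosen here as the common defaults and left configurable. Clusters sort by
size, ties by lowest member energy.

## Bioassay analysis

`normalize_inhibition()` maps the negative control (full reporter response
to TNFα) to exactly 0% inhibition and the 100% anchor to exactly 100%,
preferring the neutralising-antibody positive control and falling back to
the vehicle blank — the two-anchor reading of a normalised reporter assay.
Fits are per-well (replicate scatter informs the standard errors), by
Levenberg–Marquardt on the 4PL with the IC50 parameterised on the log
scale, bottom/top bounded in [−20, 120]% and the Hill slope free in sign so
agonist-shaped data fails loudly rather than fitting spuriously. The
`extrapolated` flag marks an IC50 outside the tested dose range. Degenerate
inputs (flat responses, fewer than four distinct doses) are explicit
errors.

## What the synthetic generators emulate — and what they do not

`simulate_noesy()` is the exact forward model of the calibration equation:
volume = c·r⁻⁶ (c = 10⁶ a.u.·Å⁶) for every proton pair within a 5.0 Å
observability cutoff, multiplicative log-normal noise (σ = 0.1 ≈ 10% volume
noise in the noisy experiments), reference pair = the closest intra-residue
HA–HB contact with its noise-free volume. It does **not** emulate spin
diffusion, peak overlap, integration error correlations or incomplete
assignment — so passing recovery tests show the pipeline inverts its own
physics faithfully, not that real NOESY spectra are this kind. An optional
`subsample` fraction thins the peak list toward experimentally realistic
sparsity (a few dozen restraints on an 11-mer).

`make_ground_truth()` produces the truth by *unrestrained* annealing from a
random build with a weak flat-bottom radius-of-gyration term switched on
(k = 5 kJ mol⁻¹ Å⁻² above R₉₀ = 0.40·n Å, n residues): the bare potential
has no attractive term, and without compaction a macrocycle truth would be
an open ring whose sequential-only NOE pattern underdetermines the fold.
The compaction term exists only inside the generator; the final truth is
re-minimised under the standard potential, and recovery runs never see it.

`simulate_assay()` inverts the inhibition normalisation: absorbances
between anchors 1.0 and 0.1, additive Gaussian noise expressed in percent
of the dynamic range (i.e. percentage points on the inhibition scale),
Hill slope 1 by default (simple 1:1 inhibition), doses log-spaced over
3.16–1000 µM. Note a statistical fact the tests document: with 5-point
noise, 8 doses in duplicate and all four parameters free, the Fisher
information of this design bounds the achievable median relative IC50
error near 15% — IC50 recovery to a few percent needs lower noise, more
replication or a constrained fit, whatever the estimator.

## Problem sizes and numerical choices

The test suite and the acceptance script run: recovery experiments on the
11-mer with 10 annealing runs of 10,000 steps each (noise-free, plus five
independent truths at σ = 0.1); a 30° grid scan of the tetraglycine cycle
(12⁶ torsion grid, pruned, top 300 minimised) against a 2000-step search;
50 random 5-point Kabsch trials against the rotation-grid oracle; and 100
simulated plates for the IC50 study. Every stochastic stage takes an
explicit integer seed and replays bitwise; ensembles record the per-member
seeds they were built from.

Degenerate inputs are rejected loudly throughout: non-standard residue
codes name the offending character, restraints naming unknown atoms fail
before any computation, collinear point sets refuse superposition, and a
ring closure that cannot be refined below 0.3 Å of ideal reports its
residual gap.

## Limitations

* The potential is geometric; energies rank conformers of the same
  molecule under the same restraints and nothing more.
* Side chains are centroids: no χ-rotamer analysis, no aromatic ring
  geometry, no hydrogen-bond term.
* NOE calibration ignores spin diffusion; distances from strongly coupled
  spin systems would be systematically short in real data.
* The mimicry mapping is positional; designs whose epitope is not a prefix
  of the macrocycle need an explicit residue mapping.
* Docking is out of scope: externally produced poses enter only as PDB
  coordinate sets for the mimicry ranking.
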