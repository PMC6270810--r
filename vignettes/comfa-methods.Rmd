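---
title: "Grid-based 3D-QSAR with comfar: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based 3D-QSAR with comfar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comfar)
```

## The method

Comparative Molecular Field Analysis (CoMFA) correlates biological
activity with the steric and electrostatic environment that a series of
aligned molecules presents to a probe atom moved over a rectangular
lattice. The pipeline implemented here is the classical one:

1. **Conformer preparation.** Each molecule is energy-minimized, passed
   through a simulated-annealing step (hot phase, then cooling), minimized
   again, and superimposed onto a template scaffold by least-squares atom
   fitting.
2. **Field generation.** At every lattice point, the interaction energy of
   an sp3-carbon probe (Lennard-Jones 6-12) and of a +1 point-charge probe
   (Coulomb with distance-dependent dielectric) with each molecule is
   evaluated, truncated, and assembled into a molecules x (2 x points)
   descriptor block.
3. **Regression.** Activities (pKi) are regressed on the descriptor block
   by partial least squares (PLS); the number of latent components is
   chosen by leave-one-out (LOO) cross-validation.
4. **Interpretation.** The fitted model is summarized as q2/r2/SEE/F
   statistics, steric/electrostatic percentage contributions, and
   StDev*Coeff contour maps exportable as OpenDX volumes.

External predictive power is reported as the predictive r-squared over a
held-out test set,

$$ r^2_{pred} = \frac{SD - PRESS}{SD}, $$

where $PRESS = \sum_i (x_i - y_i)^2$ over test molecules (actual $x_i$,
predicted $y_i$) and $SD = \sum_i (x_i - \bar{x})^2$ with $\bar{x}$ the
mean *training-set* activity. `predictive_stats()` computes all three.

## The packaged affinity tables

`load_affinity_table()` ships a transcription of a published cannabinoid
CB1/CB2 binding data set for 92 aminoalkylindole ligands: 49 CB1 records
(36 train / 13 test) and 80 CB2 records (60 train / 20 test), each with
Ki (nM), actual pKi, model-predicted pKi, residual and split flag.
`validate_tables()` recomputes every derived quantity and checks it
against the printed values; the packaged transcription reproduces
PRESS/SD/r2_pred of 5.46/15.22/0.641 (CB1) and 2.56/10.16/0.748 (CB2) at
printed precision.

One subtlety is worth documenting. The printed Ki column is rounded to at
most one decimal while the printed pKi was clearly computed from the
*unrounded* Ki: for example a pKi of 9.187 sits next to Ki "0.7" nM,
implying Ki 0.65 before rounding. The pKi-consistency invariant therefore
allows, per row, the half-ulp of the printed Ki propagated to the log
scale (floored at 0.005 for the pKi column's own rounding). Four CB2 rows
(ids 39, 41, 58, 66) need this allowance; all other 125 rows agree to
better than 0.005.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| grid spacing | 2.0 | A | lattice resolution |
| grid margin | 4.0 | A | clearance beyond the union bounding box |
| probe radius / epsilon | 1.70 / 0.107 | A, kcal/mol | sp3-carbon probe |
| probe charge | +1 | e | electrostatic probe |
| energy cap | 30 | kcal/mol | steric truncation; marks excluded points |
| column filter | 2.0 | kcal/mol | minimum column standard deviation |
| Coulomb constant | 332.0 | kcal A/(mol e^2) | with dielectric D = d |
| PEOE damping / iterations | 0.5 / 6 | -- | charge equilibration |
| annealing | 700 K -> 200 K, 1000 + 1000 moves | | torsional Metropolis |
| minimization | 1000 cycles, 0.005 kcal/(mol A) | | L-BFGS convergence |
| LOO degrees of freedom | n - N - 1 | | SEP/SEE convention |
| contour levels | 80th / 20th percentile | | favored / disfavored |

All of these are exposed as configuration objects (`probe_spec()`,
`anneal_config()`, `minimize_config()`, `charge_config()`,
`pipeline_config()`), so sensitivity to any of them can be explored. At
points where a molecule's steric energy reaches the cap the electrostatic
value is unreliable; it is replaced by the column mean over non-excluded
molecules, the conventional treatment. Block scaling weights each field
block by the inverse of its overall standard deviation over retained
entries ("inverse_stdev", the CoMFA-standard choice); `"none"` is also
provided because published percentage contributions can depend on the
block-scaling variant in ways that a text rarely pins down.

## Design choices in the energy model

The force field is deliberately minimal: Lennard-Jones 6-12 plus Coulomb
(1/d^2, distance-dependent dielectric) over all pairs except 1-2 and 1-3
neighbors, and a 3-fold torsional potential on rotatable bonds. Two
choices deserve justification:

* **Harmonic bond/angle restraints.** Cartesian minimization with purely
  nonbonded terms would let 1-4 attractions collapse a molecule, so the
  energy includes harmonic restraints toward the reference bond lengths
  and angles captured from the input coordinates. The restraints are
  exactly zero at the input geometry; they keep covalent geometry intact
  while clashes relax.
* **Torsional Metropolis annealing.** The heating/cooling protocol is
  implemented as Metropolis sampling over single random torsion moves
  (uniform in +-30 degrees) with the same temperature endpoints as a
  short molecular-dynamics anneal, hot phase followed by a linear cooling
  ramp. Torsion-only moves leave bond lengths and angles untouched, make
  the procedure exactly reproducible per seed, and preserve the
  scientific role of the stage: relaxing conformers before alignment.

Scaffold correspondence for the atom fit is supplied explicitly as an
index map (`read_scaffold_map()`), not inferred by substructure search:
this removes both a heavy dependency and a source of silent ambiguity.

## PLS, component selection, and statistics

`fit_pls()` is a NIPALS PLS1: sequential extraction of latent components
with X-deflation, mean-centering, and no per-column autoscaling (field
columns keep their energy units). Predictions through the latent path and
through the collapsed coefficient vector agree to numerical precision,
and at full rank the predictions coincide with ordinary least squares --
both are enforced by tests against independent oracles.

Cross-validation is plain LOO refitting; with fewer than a hundred
molecules this costs nothing, and an accelerated sample-distance variant
would produce the same statistic by construction. `scan_components()`
computes (N, SEP, q2) for N = 1..15 in a single LOO pass (the models are
nested) and applies a selection rule: maximize q2 (default), first N
within a tolerance of the maximum, or an explicit override. The override
exists because published models are sometimes chosen by criteria the text
does not state; reproducing such a model requires pinning N explicitly.
Applied to the published CB1 scan, the argmax rule selects N = 2, the
published choice; the published CB2 scan is monotone past its chosen
N = 10, which no simple rule reproduces -- that model needs the override.

Degrees of freedom for SEP and SEE are n - N - 1.

## The synthetic-data generator

Published structure tables are often figures, not machine-readable data;
the generator provides aligned molecule sets with a *known* sparse linear
field-to-activity ground truth so that every downstream stage can be
validated end to end. Its defaults emulate the study design behind the
packaged tables: 92 molecules, a shared rigid bicyclic (indole-like)
scaffold of 9 heavy atoms with three substitution regions, activities
spanning 4 log units, and Gaussian activity noise of 0.2 log units.

Substituents are *pseudo-groups*: chains of 1-6 atoms with element-typed
radii, well depths and partial charges, attached along fixed region
vectors. This is intentional -- the generator's job is statistical
structure, not pharmacology, and parameter bundles make field effects
exactly controllable. Activities are a weighted sum of each molecule's
field values at a few "hotspot" lattice columns, rescaled so the
noiseless span equals the target, plus noise.

Hotspot columns are chosen greedily by descending variance subject to
pairwise correlation below 0.5. Adjacent lattice columns are nearly
collinear; collinear causal columns with opposing weights would make the
ground truth unidentifiable *for any regression method*, so
decorrelation is an identifiability requirement of the design, not a
convenience. For the same reason, "parameter recovery" is stated in its
identifiable forms: the fitted coefficients *at the causal columns*
track the true weights, and model-implied activities track the true
noiseless activities; the full dense-versus-sparse coefficient
correlation is not a meaningful target on a collinear lattice.

What passing synthetic tests does and does not show: they demonstrate
that the field computation, PLS machinery, cross-validation, and contour
bookkeeping are correct and that the pipeline recovers a linear
field-activity relationship under realistic noise. They do not show that
real aminoalkylindole affinities are linear in field values, nor do they
reproduce the published q2/r2 for the real series, whose 3D structures
are not machine-readable.

## Numerical choices and degenerate inputs

* Steric energies are clamped at +30 kcal/mol; pair Lennard-Jones terms
  inside the intramolecular energy are clamped at 1e4 kcal/mol with a
  warning for overlapping atoms (d < 1e-6 A).
* Columns with standard deviation below the filter (default 2.0
  kcal/mol) are masked before regression; a configuration that masks
  every column is an error suggesting a smaller filter, not a silent
  empty model.
* NIPALS stops with an informative error when the requested component
  count exceeds the achievable rank; zero-variance responses are
  rejected.
* `predictive_stats()` flags SD = 0 explicitly (r2_pred is NA with a
  warning), never silently zero.
* Atom fitting requires at least three non-collinear mapped atoms and
  only ever applies proper rotations; a mirrored pose keeps a nonzero
  RMSD rather than being silently reflected.
* All stochastic steps (annealing, generation, splitting) consume an
  explicit seed and restore the caller's RNG state.

## Problem sizes used by the test suite

The suite validates statistical properties at the scale the method is
designed for: single runs use the full 92-molecule design; repeated-seed
properties (cross-validated q2 under noise, hotspot localization) use 100
generated sets each; brute-force oracle comparisons use small instances
(for example 12 x 20 LOO, 5-10-atom energy toys) where exhaustive
recomputation is exact. A complete run takes a few minutes on one core.

## Known limitations

* Chemistry is simplified: no aromaticity perception beyond input bond
  orders, no protonation-state handling, no hydrogen-bond or hydrophobic
  fields, and the Hueckel pi component of the charge model is
  approximated by uniform spreading of conjugated-system formal charge
  (switchable off).
* The Tripos-style van der Waals table is a per-element transcription;
  force-field atom-type granularity (and the exact parameter version a
  given commercial package used) is out of reach and the table is
  swappable configuration.
* Region interpretation of contour maps (`region_report()`) is a
  numerical surrogate for visual contour analysis; exact published
  contour levels behind rendered figures are unrecoverable.
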