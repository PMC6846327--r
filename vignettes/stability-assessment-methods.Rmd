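---
title: "Structure-based stability assessment of missense variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based stability assessment of missense variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MissenseStability)
```

## The problem and the approach

Missense variants in disease genes are hard to classify: unlike truncating
variants, the effect of a single amino-acid substitution depends entirely on
its structural context. For compact, well-crystallised proteins such as
menin (the *MEN1* tumor suppressor, 610-residue isoform), an empirical
force field can predict the change in folding free energy, ΔΔG (kcal/mol,
positive = destabilising), that a substitution causes in a given structure.
Averaged over an ensemble of crystal structures, this quantity separates
known-pathogenic from population (putatively benign) variants well enough
that a ΔΔG threshold is a useful line of evidence for classification.

This package implements that analysis as a reusable pipeline:

1. **variants** — ingest a variant table, assign groups from database
   membership (HGMD DM class vs gnomAD/SGCD population presence), collapse
   nucleotide-level records to protein substitutions, and renumber
   between the 615- and 610-residue isoforms.
2. **structures** — parse and write PDB files, strip nonnative (tag)
   residues, compute residue coverage across the ensemble, and superpose
   chains (Kabsch) for RMSD reporting.
3. **stability** — aggregate per-structure ΔΔG observations per variant
   (mean and SD across all chains resolving the position), apply threshold
   calls, and compute interface shifts ΔΔΔG between complexed and
   isolated chains.
4. **sasa** — Shrake–Rupley solvent-accessible surface area, normalised to
   relative solvent accessibility (RSA) on the Tien theoretical scale,
   with burial at RSA < 0.2 and interface occlusion ΔRSA.
5. **stats** — confusion metrics, ROC/AUC, the combined ΔΔG + REVEL rule,
   two-sample t tests and group summaries.
6. **synthetic_data** — a seeded generator of cohorts and toy structures
   so that every stage runs and is testable offline.
7. **pipeline** — `runAssess()` / `runInterface()` orchestration plus a
   thin command-line wrapper (`inst/scripts/stabpipe.R`).

The ΔΔG predictions themselves come from an external force-field tool
(e.g. FoldX RepairPDB + BuildModel); the package deliberately treats that
step as a backend behind two adapters — a generic TSV layout
(`parseDdgTsv()`) and the tool's tabular "Dif" output
(`parseFoldxDif()`) — plus the synthetic backend. Re-implementing the
force field is out of scope.

## Aggregation and classification

Each unique substitution `(position, ref, alt)` is summarised by the
arithmetic mean (optionally median) and SD of its per-structure ΔΔG
observations; `n_structures` records the evidence base, which in the menin
ensemble ranges from 1 to 31 chains. Variants resolved in no structure
cannot be assessed and are reported separately.

Destabilisation calls use a **strict** inequality, ΔΔG > threshold, with
3 kcal/mol as the conventional "strongly destabilising" line and
4 kcal/mol as a conservative alternative. Published descriptions of such
thresholds mix ">" and "≥"; we fixed strict ">" (configurable), and exact
boundary hits are surfaced via a message so the choice is never silent.
The approximately ±0.8 kcal/mol uncertainty of force-field ΔΔG estimates
is carried through reports as an annotation; it is *not* propagated into
the SD, because per-structure observations are not independent draws of
that error.

The combined rule with the REVEL meta-predictor calls a variant when
ΔΔG > threshold **and** REVEL ≥ 0.7 by default. Whether the published
combination was conjunctive or disjunctive is not stated; we default to
"and" because that is the direction in which the combination increases
positive predictive value, and provide `mode = "or"` for sensitivity
analyses. Variants lacking a REVEL score fall back to the ΔΔG-only call
with a warning rather than dropping out.

## Solvent accessibility

The reference analysis obtained per-residue accessibility from DSSP. This
package instead implements Shrake–Rupley sampling: each atom's
solvent-expanded sphere (van der Waals radius + 1.4 Å water probe) is
covered with a deterministic golden-spiral point set (960 points per atom
by default), and a point is exposed iff it lies outside every other
atom's expanded sphere. The area is the exposed fraction times
4π(r + probe)². We chose an implemented, oracle-verifiable algorithm over
wrapping an external binary because the downstream analysis consumes RSA
only at a coarse 0.2 threshold, and Shrake–Rupley admits closed-form
checks (isolated spheres, two-sphere cap geometry) that the test suite
enforces to within 1%. Numerical notes:

* The quadrature grid is fixed in space, so the estimator is exactly
  invariant under translation and invariant to quadrature error (< 1%
  at 960 points) under rotation. `shrakeRupley(..., orientation = R)`
  co-rotates the grid, making the estimator rigid-motion *equivariant*;
  the invariance test uses this to demand 1e-6 relative agreement.
* Occluders are tested nearest-first, which resolves most points early.
* Hydrogens are ignored by default (crystal structures generally lack
  them); element radii are C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å,
  overridable.
* Missing side-chain atoms simply contribute nothing; the residue's area
  is computed from the atoms present.

RSA is computed by averaging absolute ASA across the representative
structures resolving a position *first*, then dividing by the Tien
theoretical maximum for the residue type (that order follows the sentence
order of the method being reproduced; the alternative — normalise per
structure, then average — differs only when the residue type differs
across structures, which a consistent numbering excludes). The Tien
values are not printed in the source analysis; they are transcribed from
the cited scale into `maxAsaTien()`. RSA can exceed 1 against a
theoretical maximum and is reported uncapped. Burial is RSA < 0.2,
strictly.

## Superposition

`kabschSuperpose()` computes the least-squares proper rotation via SVD of
the 3×3 covariance matrix, flipping the sign of the smallest singular
direction when needed to avoid reflections. Degeneracy (coincident or
collinear points, second singular value below 1e-8 of the first) is an
error rather than a silent garbage fit. The test suite checks the result
against an independent multi-stage grid search over Euler angles (to
1e-3 Å) and against `bio3d::rot.lsq`.

## Evaluation layer

`confusionCounts()` treats "pathogenic" as the positive class and scores
strictly above the threshold as positive calls; metrics with zero
denominators are reported as `NA` rather than 0 or 1. `rocCurve()` sweeps
all distinct score values, groups ties into diagonal segments, and
integrates by the trapezoidal rule, which makes the AUC exactly the
Mann–Whitney pair-concordance probability with ties counted ½ — the test
suite enforces exact agreement with pair enumeration on random fixtures.
Higher scores must mean "more pathogenic"; inverse scorers (e.g. SIFT)
must be negated by the caller.

Group comparisons default to Student's pooled-variance t test to match
the labelling of the analysis being reproduced, with Welch available —
and advisable, given group SDs as different as 4.25 vs 1.46 kcal/mol.
Quartiles use the linear-interpolation convention (R type 7), documented
here because the source never states one. When both groups are constant,
p = 1 for equal means (and 0 otherwise) by convention.

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure of the real menin
cohort so the pipeline can run and be tested with no downloads:

* two groups of 161 variants each; latent true ΔΔG ~ N(5.06, 4.25²) for
  pathogenic and N(1.13, 1.46²) kcal/mol for benign variants;
* each structure chain resolving a variant contributes an observation
  latent + N(0, 0.8²), the 0.8 matching the nominal force-field error;
* 95% of variants are resolved in all 31 chains and the remainder in a
  single chain, mirroring the real ensemble's coverage proportions;
* pathogenic RSA is drawn from Beta(2, 8) with probability 0.863 (else
  uniform), benign RSA uniformly — a burial-skewed mixture, not a claim
  about real packing;
* REVEL-like scores are a logistic transform of the standardised latent
  ΔΔG plus N(0, 0.15) noise clipped to [0, 1] — purely a fixture model;
* everything flows from one seed; identical seeds give byte-identical
  tables.

What the generator does **not** emulate: the visibly non-Gaussian shape
of real ΔΔG distributions (only the first two moments are matched),
spatial clustering of variants on the structure, multiallelic sites
(positions are distinct by default), linkage between burial and ΔΔG
beyond group membership, and any force-field systematic error. Passing
tests on synthetic cohorts therefore demonstrate correctness of the
*pipeline arithmetic and its statistical behaviour under the stated
model*, not fidelity to real menin data. Quantities that require the real
ensemble — per-variant ΔΔG values, the published AUCs (0.833/0.864), the
86.3% buried fraction, the 0.65 Å ensemble RMSD — are intentionally not
reproduced at desk scale; the pipeline accepts real inputs when a user
supplies them.

`generateToyStructure()` builds ideal α-helices (1.5 Å rise, 100° twist,
2.3 Å radius) with one pseudo side-chain sphere per residue; the
two-chain variant places the second helix 7 Å away with side chains
facing the first, guaranteeing interface occlusion for ΔRSA/ΔΔΔG
fixtures by construction.

## Problem sizes and determinism

The test suite runs cohorts of 322 variants (about 9,500 ΔΔG records),
SASA on structures of up to ~60 atoms at 960–7,680 quadrature points, and
closed-form/large-n checks at up to 2×10⁵ latent draws with single-chain
coverage; these sizes give standard errors comfortably inside the
asserted bounds while keeping the whole suite in the low minutes. All
stochastic tests fix their seeds. The acceptance script averages the
generator's group means over 200 replicates of the default 161+161
cohort, deriving per-replicate seeds from its `--seed` argument.

## Known limitations

* PDB parsing accepts the fixed-width subset that crystal-structure files
  use (first model, highest-occupancy altloc, no insertion-code positions
  in coverage maps); mmCIF is out of scope.
* The Shrake–Rupley estimator's rotational invariance is exact only with
  a co-rotated grid (see above); absolute areas differ from DSSP by small
  algorithm-level amounts, which the RSA < 0.2 threshold absorbs.
* Isoform renumbering assumes the five inserted residues occupy positions
  149–153 of the long isoform (inserted after residue 148); the start is
  configurable because annotations could place the block one residue
  differently.
* The evaluation layer assumes exactly two evaluated classes; "uncertain"
  and "novel" variants are assessed but never enter metrics.
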