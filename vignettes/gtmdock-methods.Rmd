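---
title: "Mapping docking conformational space with gtmdock: models and methods"
author: "gtmdock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping docking conformational space with gtmdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gtmdock)
```

This vignette explains what `gtmdock` computes, the assumptions behind
each step, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical conventions that a
user re-implementing or auditing the pipeline needs to know.

## 1. Site preparation and key atoms

All structures are assumed pre-aligned in one common site frame; the
package never superposes coordinates.  RMSD between poses of one ligand
is therefore plain index-matched heavy-atom RMSD, with no
graph-automorphism symmetry correction (a known limitation for
symmetric ligands: their RMSD can be overestimated).

Key atoms — the anchors of the contact fingerprint — are selected in
two steps on the *ligand-free* site:

1. keep site atoms within 4.0 Å (closed cutoff, `<=`) of any atom of
   any overlaid ligand;
2. among those, keep atoms exposing strictly more than 5% of their
   surface to solvent.

Per-atom solvent accessibility is computed with the Shrake–Rupley
method on a deterministic Fibonacci lattice (960 points by default;
probe radius 1.4 Å, the standard water probe).  The exposed fraction
divides the accessible area by the area of the probe-expanded sphere,
so it equals the accessible solid-angle fraction and is comparable
across atom radii.  Whether the 5% threshold should be strict and which
denominator convention applies are genuinely open choices; both are
arguments (`min_exposed_fraction`, and the fraction is defined by the
probe-expanded sphere) so either convention can be reproduced.  Van der
Waals radii are the Bondi set with 1.2 Å for hydrogen — a standard,
reproducible choice where no specific set is mandated.  H-bond roles
use a deliberately simple, testable rule: a donor flag on every H
bonded to N/O/S, an acceptor flag on any O or N with formal charge ≤ 0
except N carrying an H.  Partial charges are taken from the input Mol2;
for PDB input (which has none) a Gasteiger-type assignment is applied
through OpenBabel and recorded in the site's provenance.

## 2. Contact fingerprints

For a pose, every (key atom *i*, ligand atom *j*) pair gets a fuzzy
association score `s = 1/(1 + exp(k (d − d0)))`.  The direct-band
cutoff is `d0 = rvdW(i) + rvdW(j) + 0.5 Å`; the long-range band adds a
water radius (1.4 Å) and *includes* the direct contacts — its channels
are computed over the full long-range scores, not the increment.
Hydrogens participate as ligand contact atoms (donor counting requires
it).  The five channels per band are score sums weighted by 1, the
donor flag, the acceptor flag, the signed partial charge, and the
absolute partial charge.  Slot order is key-atom major, then band, then
channel, so a 156-key-atom site gives a 1560-long vector.

The sigmoid steepness defaults to 5 Å⁻¹: the score is ≈ 0.92 at
0.5 Å inside the cutoff and ≈ 0.08 at 0.5 Å outside, i.e. the
transition band matches the 0.5 Å tolerance scale.  Only the inflexion
point is dictated by the contact definition; the slope is a free
parameter and is exposed in the configuration.  Whether the charge
channels should be score-weighted or hard-gated is ambiguous in the
contact-fingerprint literature; this package weights by the score,
consistently with the other channels.

## 3. Circular fragments and Hybrid vectors

Ligand 2-D structure enters through counted circular fragments: for
every heavy atom and every sphere radius (bond depth) in the scheme's
range, the canonical string of the rooted environment is emitted and
counts are aggregated per string.  Canonical names are built by
recursively expanding neighbors (never back along the incoming edge),
sorting the child strings, and always parenthesising expanded nodes so
that the radius is encoded in the name; bond orders prefix the child
(`=`, `#`, `~` for double/triple/other; single is bare).  Atom labels
are the element, the element plus a formal-charge flag, or a
pharmacophore class.  This is the Morgan-environment family of
descriptors; invariance under atom renumbering is property-tested.  The
default search grid spans sphere ranges 1–1, 1–2, 2–2, 1–3 crossed with
the three label modes (12 schemes); the scheme class that historically
wins for hybrid maps (circular, spheres 1–2, element+charge) is the
default.

A Hybrid vector is the raw concatenation of the CF block and the
fragment counts over a vocabulary frozen on the training ligands;
out-of-vocabulary fragments of new ligands are dropped with a logged
count.  No inter-block scaling is applied at concatenation — mixed-unit
blocks can instead be handled by the map-level column standardisation
option (`scale` in `gtm_config()`, default off, because CF channels
share units and scaling is a modelling choice best made explicitly).

## 4. The GTM core

The map is a K-node square latent grid in [−1,1]², pushed through an
RBF manifold `y(x; W) = Φ(x) W` into descriptor space, each node
carrying an isotropic Gaussian with shared precision (the model's noise
precision — distinct from the Boltzmann β of Section 7).  The basis
has M Gaussian RBFs on a regular sub-grid (width = width-factor ×
center spacing, the convention in which grid-based GTM width parameters
are usually quoted), plus two linear columns and a bias.  The linear
columns are a deliberate design choice: they make affine planes exactly
representable, which turns "the manifold can capture a linear subspace
exactly" into a sharp, testable statement (`gtm_reconstruction_error()`
measures the residual of data off the affine span of the node images —
that span is preserved by every M-step because the weight solution is a
linear combination of data rows).

Initialization is deterministic: W maps the latent grid onto the first
two principal components (sign convention: largest-magnitude loading
positive), and the initial noise variance is the larger of the third-PC
variance and the squared half inter-node image spacing.  EM then
alternates responsibilities (softmax of `−β/2 ‖y_k − t_n‖²`, rows
summing to 1) with the penalized weight update
`(ΦᵀGΦ + (λ/β) I) W = Φᵀ R T` (no decay on the bias row) and the
closed-form β update.  With λ > 0 the quantity EM provably increases
is the *penalized* objective (log-likelihood minus `λ/2 ‖W‖²` over the
decayed rows); the model records both traces, converges on the
penalized one (relative change < 1e−5 by default), and the raw
likelihood trace is monotone whenever λ = 0.  Degenerate cases are
handled without NaNs: the noise precision is capped at 1e12 on exactly
noiseless data, and a singular M-step system falls back to a ridge
solve with a warning.

The defaults of `gtm_config()` (29×29 nodes, 144 RBFs, width 1.8,
λ = 6.61) echo a published contact-fingerprint map parameterisation by
name; since the conventions those numbers plug into (what the width
multiplies, whether λ is scaled by the noise precision) vary between
implementations, they are honored as named defaults, not as a claim
that this implementation reproduces that map.

## 5. Landscapes, Q² and map selection

A regression landscape assigns each node the responsibility-weighted
mean of a property over the coloring items; a node is "defined" when
its density exceeds ε = 1e−6·N/K (a pure guard against 0/0 — landscape
plots show "white spots" where density vanishes, but no specific
threshold is canonical).  Prediction for a projected item is its
responsibility-weighted mean over *defined* nodes, renormalised; the
summed responsibility on defined nodes is the coverage, an
applicability-domain weight, and predictions with coverage below 0.1
are returned undefined.  Classification landscapes store per-class
cumulated responsibilities; the class with maximal density wins a node
(ties to the lower class index, flagged), and the fuzzy value is the
weighted mean of the numeric labels, always inside the label range.

Q² = 1 − SSE/SST on left-out items, with SST about the *training* mean
(the test-mean convention exists too; training-mean is used because the
prediction must not peek at the test fold).  Cross-validation is
3-fold × 3 repeats, stratified by property quartile (RMSD distributions
are skewed; stratification stabilises the fold Q²).  By default the
manifold stays fixed and only the coloring is refit per fold — the CV
then measures landscape transferability on one map; a full-refit mode
exists behind a flag.  Undefined predictions are imputed with the
training mean and counted.  Map fitness pools the per-repeat Q² values
of all properties: mean minus one SD.

Hyperparameter selection is an elitist genetic search over a discrete
space (grid sides, width factor, λ, and a `data_set` gene).  One gene
indexes the candidate descriptor matrices, which covers both frame-set
choice and fragment-scheme choice: each candidate matrix is one
frame-set × scheme combination, which keeps the optimizer agnostic of
how the matrices were built.  GA defaults — population 20, tournament
3, mutation 0.2, crossover 0.5, ≤ 200 evaluations — are conventional
small-budget settings; the search is deterministic under its seed and
the budget counts fitness evaluations (cached genomes are free).

## 6. Docking-specific analyses

**IRI(p)** projects two runs on one map and accumulates the density of
nodes where the dominant run holds more than p of the population
(default p = 0.85); nodes with zero density are excluded, and the index
is the dominated density over the total density.  It is 0 for an exact
copy, 1 for disjoint node sets, monotone non-increasing in p, and
ill-defined for p ≤ 0.5 (rejected).

**Q/R/M/F.**  An explorer ligand's RMSD landscape predicts the RMSD of
test poses (observed values capped at 6.0 Å, like the coloring —
discriminating "badly docked" from "quasi-undocked" above 6 Å is
neither relevant nor hard, since the latter have near-empty
fingerprints).  Three criteria: determination coefficient
r² = 1 − SSE/SST (the prediction-quality form, consistent with the Q²
convention — not squared Pearson), balanced accuracy of the native-like
call at the fixed 2 Å threshold (strict `<`, applied identically to
predictions and observations), and ROC AUC of prioritising observed
native-likes by ascending predicted RMSD.  Verdicts are evaluated in
order: Q if all three exceed 0.75, else R if AUC exceeds 0.8, else F if
none exceeds 0.6, else M.  A single-class test set gets an r²-only
verdict, flagged.  ROC AUC itself is delegated to pROC with midrank tie
handling; an exhaustive pairwise oracle cross-checks it in the tests.

**AR vectors.**  A compound's docked ensemble is summarised by the
Boltzmann-weighted average of its pose responsibilities; energies are
shifted by their minimum before exponentiation (mathematically
identical, overflow-safe), β = 0 gives the plain average, β = ∞ the
most stable pose's row.  The β grid default {0, 0.1, 0.3, 1, 3}
(kcal/mol)⁻¹ brackets the region where Boltzmann weighting of
evolutionary-sampling ensembles has been discussed.  pK landscapes are
colored from the color compounds' AR vectors exactly like regression
landscapes; test compounds with zero coverage are excluded from the ROC
(not imputed — out-of-domain compounds should not silently rank) and
counted.  The color/test split is a seeded random half-split stratified
by class.  Scenario TvO ranks potent actives against everything else;
AvD ranks all actives against decoys (decoy pK fixed at 3 by
convention).

**Pose-pool bookkeeping.**  The energy window keeps poses with excess
energy ≤ 50 kcal/mol over the pool minimum (boundary kept).  The
diverse subset is greedy: accept the energetically best remaining pose,
discard everything within the dissimilarity threshold of an accepted
pose, stop at 200; energy ties break lexicographically by conformer id
for determinism.  The default pose dissimilarity is the coordinate-RMS
distance; a CF-based distance can be passed instead and is the
descriptor-aware choice when a schema exists.  The energy convergence
criterion is met when at least five runs exist and the runs ranked 2–5
by their minima all lie within 1 kcal/mol of the best; a driver repeats
a simulation callback up to 20 times until it holds.

## 7. The synthetic generators

The generators exist so that every pipeline stage runs on data with
known ground truth:

* `make_toy_site()` builds a spherical shell of typed atoms (radius
  ≈ 5 Å, ≈ 80 atoms with a far rim outside the expansion range) around
  a small rigid ligand, with a designated carbonyl-O / amide-H hot-spot
  pair facing complementary ligand atoms at 1.9 Å — so hot-spot contact
  baselines can be exercised literally.
* `make_pose_ensemble()` displaces the native pose rigidly: a
  translation of magnitude t has RMSD exactly t, so the generator
  controls the RMSD distribution exactly (native-like band 0.2–1.9 Å
  with the requested frequency, non-native 2.1–8 Å).  Energies follow
  the funnel `E = E₀ + a·RMSD + N(0, σ²)` with E₀ = −50 kcal/mol,
  a = 2 kcal/mol/Å, σ = 1 — the minimal model that makes
  energy-vs-RMSD ranking comparisons meaningful and tunable.
* `make_paired_runs()` samples two runs around well-separated modes
  (displacements of 3 Å, jitter 0.5 Å) sharing a controlled fraction of
  modes: overlap 1 means statistically identical runs, 0 disjoint.
* `make_screening_set()` builds 100 potent (pK 7.2–9.0), 91 weak
  (pK 4.7–5.5) and 101 decoy (pK 3) compounds; the fraction of a
  compound's poses placed in the hot-spot-contacting mode rises with
  its pK at a strength set by `effect_size` (0 decouples them, giving a
  null benchmark with AUC ≈ 0.5).  Per-compound energy offsets
  (SD 2 kcal/mol) make the docking-score baseline informative but
  noisy, as a scoring function would be.

What the generators deliberately do **not** emulate: force-field
energetics, ligand flexibility (poses are rigid displacements),
receptor chemistry beyond typed spheres, and ligand structural
diversity (screening compounds share a scaffold and differ in their
pose distributions).  Passing tests therefore demonstrate the
*machinery* — descriptor geometry, EM correctness, landscape
statistics, index arithmetic, ranking behavior — not performance on
real docking data, which depends on external docking software.

Problem sizes used by the test suite and the acceptance script were
chosen to make each statistical check stable at desk scale: 500 poses
per run for the reproducibility sweep (per-node populations of ~20 on a
49-node map keep one-run dominance from arising by chance), 2000
samples for noise-precision recovery (the estimator lands well within
20%), 292 compounds × 8 poses on a 100-node map for screening.

## 8. Numerical conventions and edge cases

* Responsibilities are computed with log-sum-exp; rows sum to 1 within
  1e−9 and total mass is conserved to 1e−6.
* Overlapping identical atoms in SASA bury each other (fraction 0, no
  NaN).
* The CF of a pose 50 Å from the site is numerically empty (< 1e−6
  everywhere) — quasi-undocked poses are representable, not errors.
* All generator randomness flows from one master seed through named
  substreams (`derive_seed`), so multi-stage runs are reproducible and
  sub-seeds stay within R's 32-bit integer range.
* CSV outputs print 12 significant digits (byte-identical reruns);
  node tables print 17 (bit-exact read-back of finite values).  Mol2
  charges round-trip at the format's 4-decimal printed precision.
* Q² is unbounded below and reported as-is; fuzzy class values are
  provably inside the label range; the Q/R/M/F label function is total.

## 9. Known limitations

* No symmetry-corrected RMSD.
* Contact channels are distance-based only; no angular H-bond terms.
* The evolutionary map selector searches a discrete grid, not a
  continuous space.
* The published hyperparameter values for contact-fingerprint and
  hybrid maps are honored as named defaults only (Section 4).
* Fragment canonicalisation uses recursively sorted environment
  strings, not canonical SMILES; names are stable and
  permutation-invariant but not interchangeable with SMILES-based
  vocabularies.
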