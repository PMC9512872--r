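---
title: "Shape-guided fragment growing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-guided fragment growing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growlite)
```

## The problem

Fragment growing starts from a ligand core whose binding pose is known
(typically from a crystal structure) and asks which fragments, attached to a
marked open valence of that core by one new single bond, fit the adjacent
sub-pocket. Because the core is trusted, the search is over fragment identity
and the geometry of the new attachment only — a far smaller space than full
docking, which is what makes library-scale screening feasible. growlite
implements this workflow end to end: shape-based pose generation from a
fixed core, pharmacophore search-point constraints, water-replacement
queries, restrained gradient refinement, ensemble screening, and the
evaluation statistics used to validate such methods.

## The shape descriptor

The geometric heart is a pocket/fragment-symmetric ray descriptor. From the
core's attachment atom, `D` unit directions are laid out on a deterministic
Fibonacci sphere. For the pocket, each ray is cast until it first hits the
van der Waals surface of a receptor heavy atom (waters removed first),
capped at `max_range`; for a posed fragment, each ray measures the distance
to the *last* exit from the fragment's heavy-atom vdW volume (0 if the ray
never enters it). Because both objects are reduced to the same `D`-vector of
lengths, comparison is a vector operation:

* filled volume proxy: `filled = sum_d min(frag_d, pocket_d)`
* clash: `clash = sum_d max(0, frag_d - pocket_d - tau)`
* combined score: `filled - w_clash * clash + w_contact * contacts`,

where `contacts` counts fragment/receptor heavy-atom pairs at close-contact
range. Clash is tolerated up to `tau` per ray: pose generation is
deliberately permissive, leaving small collisions for the optimizer to
resolve; this matters when a transferred ligand fits a non-native site
imperfectly.

The descriptor is geometric only — it carries no electrostatic information,
which is exactly why typed search points exist as a separate constraint
channel.

Defaults (all in `growlite_config()`): `n_rays = 128`, `max_range = 10` A,
`tau = 0.75` A, `w_clash = 3`, `w_contact = 0.3`, close contacts counted in
3.2–4.0 A. The ray count trades angular resolution against cost; 128 rays
resolve sub-pockets at the ~1 A scale of the test cavities. The published
ray-volume-matrix family of descriptors groups rays into origin/level
matrices; here a single-origin direction set is used, isolated behind the
config so a multi-origin variant could replace it.

## Pose enumeration

`enumerate_attachments()` forms the new bond at the sum of covalent radii,
aligns the fragment's own open-valence direction anti-parallel to the
growth vector (giving an idealized tetrahedral/trigonal junction), and spins
the torsion about the new bond in 30-degree steps. Fragments carrying a
single conformer additionally get ring-free internal torsions sampled at
120 degrees; multi-conformer fragments (built once per library with
`fragment_conformers()`, capped at 25) are enumerated per conformer.
Near-duplicates are merged by a symmetry-aware RMSD (greedy element-wise
nearest matching, threshold 0.1 A), which is what collapses the 3-fold
redundancy of a rotating methyl. Enumeration is capped at 600 poses per
fragment with a logged truncation. Poses in hard steric clash — any
fragment/receptor heavy-atom pair whose vdW overlap exceeds 60% — are
discarded before scoring, reusing the water-replacement overlap rule for
internal consistency.

Where a library fragment has several open valences the lowest-index one is
used (configurable); the published behavior for this case is not documented,
so the choice is logged rather than guessed.

## Search points

A search point is a typed constraint — donor, acceptor or hydrophobic — with
a position and a tolerance radius (default 2 A). A surviving pose must
satisfy *all* points: each point needs a compatible ligand feature (donor
atom, acceptor atom, hydrophobic atom or fully-hydrophobic ring centroid)
within its tolerance. `detect_interactions()` generates points from a posed
ligand: donors at N/O bearing hydrogens with a receptor N/O at 2.5–3.5 A and
a D-H...A angle of at least 120 degrees; acceptors mirrored; hydrophobic
points at centroids of fully hydrophobic rings and at terminal hydrophobic
groups with receptor C/S at 3.5–4.5 A. Points always sit on the ligand side
of the interaction. The hydrogen-bond windows are package defaults: the
interaction-geometry criteria they stand in for are defined in external
tabulations that are not reproduced numerically here, so the thresholds live
in config and the gap is documented.

Receptor protonation is not assigned (no protonation engine is in scope), so
receptor N/O act as both donor and acceptor candidates and the angle test
applies only where an explicit hydrogen exists. This is a deliberate
protonation-agnostic simplification; it makes point generation slightly
permissive on the receptor side.

## Water replacement

A crystallographic water counts as replaced when its maximum vdW overlap
with a ligand heavy atom exceeds 60%, with overlap defined as the linear
penetration fraction `max(0, (r1 + r2 - d)/(r1 + r2)) * 100` (an
intersection-volume alternative sits behind `overlap_metric` for sensitivity
checks). Each replaced water proposes donor, acceptor *and* dummy
hydrophobic points at its oxygen — the dummy hydrophobic point covers purely
steric displacement. Only proposals confirmed within 2 A by a same-type
point generated from the ligand itself are kept, and the replaced waters are
then removed from the site for growing.

## Restrained optimization

`optimize_pose()` refines a pose under a simplified empirical interaction
model with four terms: quadratic clash repulsion beyond vdW contact, a
Gaussian hydrogen-bond well (ideal 2.9 A, width 0.4 A) gated by an angular
switch, a Gaussian hydrophobic well (ideal 3.9 A, width 0.6 A), and a
flat-bottom quadratic restraint on core atoms that engages only past 0.5 A
displacement (force constant 10 score-units/A^2, applied per atom; a
centroid variant would be the natural alternative and is noted as such).
Receptor atoms are rigid; only ligand atoms move.

Three numerical choices deserve explanation:

* **Polar contact shrinkage.** The N/O vdW contact distance (3.07 A) exceeds
  the ideal hydrogen-bond separation (2.9 A), so with raw radii the clash
  term would penalize every ideal hydrogen bond. As in common empirical
  scoring functions, the contact distance for N/O–N/O pairs is reduced by
  `polar_shrink = 0.4` A so hbond partners reach their minimum unpenalized.
* **Angular switch.** The hydrogen-bond well is scaled by
  `max(0, (-cos(theta) - 0.5)/0.5)` with `theta` the D-H...A angle: 1 at a
  linear geometry, fading continuously to 0 at 120 degrees and below. A
  continuous ramp (rather than a hard gate at the cutoff) keeps the analytic
  gradient well-defined along the whole approach.
* **Limited step length.** The optimizer is plain steepest descent with the
  per-iteration displacement of every atom capped at 0.1 A and step-halving
  (up to 10 times) on any energy increase, so accepted energies are
  non-increasing by construction. It stops when the energy change falls
  below 1e-4 or after 500 iterations. First-order-only optimization is a
  feature here: with no bonded terms in the model, stability comes from
  small steps and a finite budget, and the procedure stays deterministic.

The restraint threshold (0.5 A flat bottom) and the restrained-core,
limited-step contract are the anchored behaviors; the well depths and widths
are package parameters chosen so that documented contracts hold — in
particular, under the synthetic pocket fields the 95th percentile of core
RMSD after optimization stays at or below 0.6 A (flat bottom plus a small
elastic excursion). Deeper attractive wells would drag cores further;
anyone re-parameterizing the model should re-check that contract.
Gradients are analytic and verified against central finite differences.

## Ensemble screening

`grow_ensemble()` screens a library against 2–5 pre-aligned conformations of
one binding site and keeps, per fragment, the single best-scoring pose
across members — so a fragment clashing in three of four conformations is
scored from the fourth. Ties go to the lexicographically smallest frame id
for determinism. Scores are *not* normalized across members before taking
the best (whether the published tool does so is unstated; raw best is the
simpler contract and is property-tested as exact equality with the
per-member maxima). Alignment itself is out of scope: members come
pre-aligned, e.g. from an external binding-site retrieval tool.

## Evaluation machinery

* **Cross-growing cases.** `build_case()` accepts two aligned complexes if
  their ligands differ by exactly one connected substituent on one acyclic
  single bond, found by cutting each candidate bond of the larger ligand and
  testing element- and bond-order-colored graph isomorphism of the core side
  against the smaller ligand (exact search, limited to 40 heavy atoms). The
  core is posed from the growing structure; the reference ligand is held out
  of every growing input.
* **Fragment RMSD** is heavy-atom, in place (no superposition — both poses
  live in one aligned frame by construction), and minimized over graph
  automorphisms so that symmetric fragments are not spuriously penalized.
* **Success statistics** use the conventional 2 A threshold and the normal
  approximation to the binomial for 95% intervals:
  `1.96 * sqrt(p(1-p)/n)`. This arithmetic reproduces published interval
  half-widths exactly from their printed (rate, n) pairs.
* **Interaction maintenance** regenerates search points from a grown pose
  and counts, per type, input points matched within 2 A by a same-type
  point (greedy one-to-one matching).
* **Enrichment** is rank-statistic AUC with mid-ranks for ties; confidence
  intervals come from 1000 stratified bootstrap resamples (actives and
  inactives resampled separately; percentile 2.5/97.5; seeded — the count
  and interval style are package choices, as the published procedure states
  only that bootstrap resampling was used). The molecular-weight baseline
  scores by descending weight. Rule-of-Three property records (MW, donors,
  acceptors, logP estimate, rotatable bonds, TPSA) drive greedy
  nearest-neighbor decoy matching in z-scored property space; the logP and
  TPSA values are deliberately crude atom-count heuristics — sufficient to
  rank and match synthetic fragments, not to predict partitioning.

## The fixture generator

Every test input is generated by code. `make_pocket()` builds closed atom
shells (spherical, two-lobe, channel) with optional polar wall atoms and
waters; `plant_case()` builds a two-lobe cavity whose sub-pocket lies along
a seeded attachment torsion of a planted fragment, yielding a cross-growing
case whose answer is known exactly and recoverable by exhaustive
enumeration; `make_enrichment_set()` builds labelled libraries whose actives
fit the sub-pocket and whose decoys are property-matched branched fragments.
A seeded random rotation de-axes every scene. Two-lobe shells keep wall
atoms within 0.3 A of the intersection seam so the lobes join without a gap
ring.

These fixtures are geometric, not chemical: walls are bare carbon shells,
fragments are idealized zigzag chains, there is no protein context,
electrostatics, solvation or conformational strain. Passing tests therefore
demonstrate that the geometry, scoring, constraint and statistical machinery
behave exactly as specified — they say nothing about recovery rates on real
protein–ligand data, which require curated crystallographic test sets. In
the same spirit, the generator's defaults are the study conditions of the
test suite (cavity radius 4.5 A, lobe radius 3.0 A at 3.5 A, wall spacing
1.2 A, noise 0) and are not tuned per test. In the synthetic screening
library the decoys are heavier than the actives, so the descending-weight
baseline scores near 0 there; that baseline is informative on
property-matched real libraries, and is reported for completeness.

Problem sizes used by the test suite and the acceptance script — 12–128
rays, 20 oracle fixtures, 25 planted cases, 10 optimization cases, libraries
of 55 — were chosen as the smallest sizes at which each property is
meaningfully exercised.

## Known limitations

* Bond-order perception, protonation and tautomers are out of scope; inputs
  are taken at face value.
* The energy model has no bonded, torsional or electrostatic terms; it
  refines rigid-plus-torsion poses locally and is not a general minimizer.
* Ring perception uses a fundamental cycle basis — adequate for
  fragment-sized molecules, not for fused polycyclic cage systems.
* The common-substructure search is exact and intentionally capped at 40
  heavy atoms.
* Atom indices are 1-based throughout, following R convention.
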