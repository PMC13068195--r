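---
title: "Grid free-energy fragment screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid free-energy fragment screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, and the choices made where the method
leaves the design open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## From occupancy to grid free energies

The screening engine starts from per-voxel occupancy counts of small solute
probes sampled around a protein at a known bulk concentration (about
0.25 M per probe; the probes — benzene, propane, formamide, methanol,
dimethyl ether, imidazole, acetate, methylammonium — are representative of
six generic functional-group classes: aromatic, aliphatic, hydrogen-bond
donor and acceptor, positive, negative). `to_gfe()` converts counts to grid
free energies by the Boltzmann inversion

$$\mathrm{GFE}(v) \;=\; -RT \,\log\frac{\rho_\text{local}(v)}{\rho_\text{bulk}},$$

where the local density is `counts / (n_samples × voxel volume)` converted
to mol/L with Avogadro's number. The method assumes the occupancy is an
equilibrium sample; systematic sampling error in the input propagates
directly into the maps. Two numerical guards are not part of the published
description and are therefore explicit, configurable parameters:

* **Temperature** (default 298.15 K) — sets RT ≈ 0.5925 kcal/mol.
* **Clamp `cap`** (default ±3 kcal/mol) — bounds every map value; voxels
  never visited receive `+cap` rather than +∞. The clamp matches common
  FragMap practice and keeps pose refinement finite everywhere. Raising the
  cap never changes values strictly inside the old range (tested).

Voxels are 1 Å cubes by default, addressed by half-open intervals with the
grid origin at the center of the first voxel, so every point belongs to at
most one voxel. `gfe_at()` evaluates maps at arbitrary points by trilinear
interpolation over voxel centers; a nearest-voxel mode exists because the
original workflow does not state which lookup it uses, and the oracle tests
exploit the nearest mode's exactness. Points outside the grid contribute
0 kcal/mol (bulk reference). Exclusion maps are geometric: a voxel is
excluded when its center lies within (atom radius + probe) of any protein
heavy atom, with an element-based radii table. The published workflow's
exclusion definition is not given; the geometric construction is this
package's documented choice.

## LGFE scoring and Monte-Carlo pose refinement

A ligand is scored by the **ligand grid free energy**: each heavy atom is
assigned one map class by a fixed priority walk
(positive > negative > donor > acceptor > aromatic > aliphatic, unmatched
atoms "none"), and LGFE is the sum of the class-matched map values at the
atom coordinates. Classification runs on perceived SYBYL atom types plus
the bond graph and formal charges; donor capacity is attributed to the
heavy atom (polar hydrogens are implicit).

Pose refinement follows the published two-stage protocol, implemented in a
compiled kernel with a pure-R mirror that consumes the RNG stream in the
identical order (the two engines are compared draw-for-draw in the tests):

* stage 1 — 100 Metropolis steps at the start temperature with move limits
  0.5 Å translation, 15° rotation, 180° dihedral;
* stage 2 — 1,000 simulated-annealing steps with limits 0.25 Å / 9° / 9°
  and the temperature decreasing **linearly to 0 K** (the method
  description leaves the annealing schedule and start temperature open; the
  linear schedule and 298.15 K are this package's documented defaults);
* each step applies one move type chosen uniformly at random with magnitude
  uniform in (0, max] — the move scheduling is likewise unstated in the
  original and fixed here;
* poses placing any heavy atom in an excluded voxel, or whose centroid
  leaves the site sphere, are rejected outright (hard rejection, not a soft
  penalty);
* the total energy is LGFE plus a reduced intramolecular term.

**Reduced intramolecular energy.** The original workflow scores ligand
strain with a full molecular-mechanics energy using a distance-dependent
dielectric ε(r) = 4r. A complete force field is out of scope here; the
package's energy keeps the stated dielectric treatment — Coulomb
`332.06·qᵢqⱼ/(4r²)` over heavy-atom pairs separated by at least three
bonds — plus a generic Lennard-Jones term with per-element parameters and a
threefold torsional barrier (0.2 kcal/mol) on rotatable bonds. All oracle
tests use rigid ligands, for which this term is a constant (zero for the
star-topology planted binders), so the docking oracles are insensitive to
the simplification. Scores for flexible real ligands should be read as
qualitative.

**Run control.** `dock_ligand()` executes independent refinement runs with
derived seeds; after the 50-run minimum it stops when the two lowest
run-best LGFE values agree within 0.5 kcal/mol, else continues to 250 runs,
and repeats the whole procedure five times. The protocol fixes the
50/250/0.5/5 numbers but not the convergence semantics; "two lowest run
minima within the tolerance" is this package's deterministic, testable
reading, documented rather than asserted as the original.

## Hotspots and binding sites

`dock_fragment()` seeds one docking per non-excluded lattice point (stride
3 Å by default) across the whole grid, confining each search to a sphere of
the stride radius so returned poses tile the volume. Poses are clustered
greedily (best LGFE first, absorb everything within 3 Å), merged across
fragment types the same way, and binding sites are the connected components
of hotspots within 8 Å containing at least two hotspots. Stride, clustering
radius and adjacency distance are unstated in the original and are
configurable, logged defaults here. Greedy best-first clustering was chosen
because it is deterministic and admits a brute-force oracle, which the test
suite runs on every small input. The default fragment set is ten mono- and
bicyclic rings common in drugs (benzene, pyridine, pyrimidine, imidazole,
furan, thiophene, piperidine, piperazine, naphthalene, indole),
user-replaceable. The original site selection also applied manual judgment
on top of the adjacency rule; only the rule is automated.

## Pharmacophore hypotheses and screening

Features are extracted per class from voxels at or below a GFE threshold
(default −0.5 kcal/mol) inside the site, single-linkage-clustered within a
merge radius (default 2 Å); each cluster becomes a feature at its
|GFE|-weighted centroid with the weighted RMS spread as radius and the
summed GFE as score. Hypotheses are all 3- and 4-subsets with pairwise
spans ≤ 15 Å, ranked by combined score. Threshold, merge radius and span
are unstated in the original; the defaults are logged.

Matching superposes ligand feature points (aromatic ring centroids,
donor/acceptor heavy atoms, charged-group centroids, aliphatic-cluster
centroids) onto hypothesis features over every injective type-respecting
assignment, using the Kabsch least-squares rotation, and keeps the minimum
RMSD. A compound hits when that RMSD is **strictly** below 1.2 Å (the
threshold is stated as a strict inequality, and the boundary tests pin that
behavior at 1.19 versus 1.21 Å). "Correct number and type of functional groups" is
read as: the ligand must supply at least the hypothesis's count of points
of each required type; surplus points are allowed. Per hypothesis at most
10,000 hits are kept — the truncation orders by RMSD ascending, a rule the
original does not state — and pooled hits are deduplicated by compound,
keeping each compound's best record. One known geometric subtlety: adjacent
fused-ring centroids (~2.1 Å apart) always merge into a single extracted
map feature at realistic well widths, so planted sites use one aromatic
well per ring system.

## Triage

The cascade order is fixed: weight window (200–550 Da, boundaries pass) →
Lipinski rule of five (violations of MW > 500, logP > 5, HBD > 5, HBA > 10;
pass means ≤ 1 violation, strict mode available) → 4DBA → PAINS. Each
discarded compound is attributed to its first failing filter; verdicts are
order-independent, only attribution depends on the order. The 4DBA scalar
is implemented as the normalized Euclidean norm
`sqrt((MW/500)² + (logP/5)² + (HBD/5)² + (HBA/10)²)` with retention at
≤ 2.0 — no exact 4DBA formula was available to this implementation, so this
definition is the package's documented stand-in, with
the property that a compound at every rule-of-five boundary scores exactly
2. The PAINS set shipped in `inst/extdata` is a ten-alert representative
subset of the published families, user-replaceable; tests assert behavior
on designed structures, not coverage of the full published list.

Morgan fingerprints are ECFP4 (radius 2) from OpenBabel, folded to 2048
bits; clustering is Butina leader clustering with "cutoff = 0.45"
interpreted as a **Tanimoto distance** cutoff (the common convention; the
original does not say distance or similarity). Lead selection keeps the
most negative LGFE per cluster (ties by id), optionally pre-truncates to
the top 1,000 per source database, and returns the top 100 per site.

## Quantitative endpoints

* `tumor_volume()` implements `V = L·S²/2` (mm), erroring when the axes are
  swapped.
* `fold_change()` implements `E = 2^−ΔΔCt` with ΔCt = Ct(target) − Ct(18S).
* `fit_ic50()` fits the four-parameter logistic
  `R = Rmin + (Rmax − Rmin)/(1 + (c/IC50)^h)` by Levenberg–Marquardt with
  the bottom constrained ≥ 0; vehicle (c = 0) wells anchor Rmax. Flat or
  rising responses are flagged as errors, never silently fitted. Intervals
  come from a seeded residual bootstrap.
* `fit_kd()` fits the 1:1 isotherm `f = c/(c + Kd)`; `f(Kd) = 0.5` by
  construction; seeded case bootstrap for spread.
* `auc_trapezoid()` is the linear trapezoid over the sampled span with
  interpolation at the 24 h endpoint, plus Cmax and Tmax.
* `conservation()` aligns with Needleman–Wunsch (BLOSUM62, gap open 10,
  extend 0.5, via Biostrings) and reports identity and similarity over a
  reference residue window, similarity counting pairs with strictly
  positive substitution scores; columns where the reference carries a gap
  inside the window stay in the denominator. These alignment choices are
  documented because the source states only the percentages; identity is
  robust to them, similarity less so. The bundled FASTA carries the
  N-terminal bHLH-PAS regions of the two human HIF-alpha paralogs.
* `aggregate_cr()` pools complete-response counts and prints percentages at
  the study's precision (integers at ≥ 10 %, one decimal below).

## What the synthetic generators emulate — and what they do not

`make_pocket()` plants isotropic Gaussian GFE wells (depth, width) on a
flat background, converts to expected counts by inverse Boltzmann at the
study conditions (0.25 M bulk, 1 Å voxels, 298.15 K) and draws Poisson
counts. Gaussian wells are the simplest shape with an analytic optimum;
real FragMaps have anisotropic, multi-modal basins, correlated classes, and
protein-shaped exclusion. At the generator's default sampling depth
(`n_samples = 1e5`, i.e. about 15 expected counts per background voxel) the
background GFE noise is roughly 0.15 kcal/mol (1σ) and a −2 kcal/mol well
is recovered to well under 0.1 kcal/mol, the round-trip tolerance the tests
assert.

`make_planted_binder()` returns a star-bonded rigid pseudo-molecule whose
typed atoms sit exactly at the planted features: no rotatable bonds, no
nonbonded pairs, hence identically zero intramolecular energy and an
analytic optimal LGFE equal to the sum of well depths. It is a docking
oracle, not chemistry.

`make_library()` draws from a frozen, structure-verified pool
(`inst/extdata/library_blocks.csv`): 537 analog-series decoys over 19
scaffolds, each decorated with 2–6-heavy-atom substituents; 12 planted
weight-window failures; 5 rule-of-five failures (long alkanes with exactly
two violations while staying inside the weight window); 6 planted PAINS
matches, each inside the weight window so the cascade attributes it to the
PAINS stage; and 10 rigid halogenated amino-naphthalenol actives. The pool
was verified at design time so that every within-series compound pair has
Tanimoto distance ≤ 0.45 and every cross-series pair > 0.45 — this makes
the designed cluster labels exact expectations for Butina clustering of
*any* seeded subsample, which is what the triage acceptance test asserts.
What the library does not emulate: real-library property distributions,
tautomers/protomers, stereochemistry, or scaffold diversity beyond the
designed series.

`make_screen_fixture()` assembles the end-to-end study: a seeded
500-compound library (10 actives, 12 + 5 + 6 planted failures, decoys for
the rest), 3D conformers via OpenBabel embedding, and a 21³ Å pocket whose
wells sit at the pharmacophore feature geometry of the first active (one
aromatic well of −1.2 kcal/mol at the fused-ring center, −2.5 kcal/mol
wells at the two donor points). The actives share a rigid scaffold, so all
of them match the planted site; flexible decoys mostly lack the two-donor
geometry. These depths and the composition were fixed when the fixture was
designed and are the study conditions of the acceptance screen. Passing
this screen shows the pipeline's stages compose correctly and that planted
signal dominates designed noise — not that the method enriches actives in
any real chemical library.

## Problem sizes, seeds, and reproducibility

The test suite and `scripts/acceptance.R` use these scales, chosen as
comfortable desk-scale study sizes: Metropolis calibration at 10⁵ trials;
planted-binder docking over 20 seeds with the published per-run protocol
and the 50–250-run convergence loop (one repeat per seed — the five-repeat
default multiplies cost without changing the oracle's question); estimator
sweeps over 100-fold parameter ranges noiselessly and 200 seeded repeats at
5 % noise; the hit-cap check on 12,000 constructed matches; the end-to-end
screen on 500 compounds with a reduced ranking protocol (8–25 runs, two
repeats). Every stochastic step runs R's RNG under an explicit seed.

Two reproducibility boundaries are inherent to the toolchain: OpenBabel's
3D embedding is not bit-stable across runs (pipelines needing frozen
conformers should serialize the embedded library to SDF once and reuse the
file — `run_screen()` treats the conformers it is given as the
deterministic input), and Butina clustering of a *new* conformer-free
fingerprint set is deterministic given the SMILES, so all determinism
guarantees are stated at the SMILES/SDF level.

## Known limitations

* The intramolecular energy is a reduced surrogate (no full force field,
  no 1–4 scaling, generic LJ/torsion parameters); flexible-ligand strain is
  qualitative.
* Atom typing is rule-based over SYBYL types; exotic functional groups fall
  to "none" and contribute nothing to LGFE.
* The 4DBA definition and the PAINS subset are documented stand-ins, not
  reproductions of the cited references.
* Site selection automates only the adjacency rule; the original also used
  expert judgment.
* Sequence "similarity" depends on the alignment tool's definition; this
  package documents its own (BLOSUM62 > 0) rather than asserting the
  original's.
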