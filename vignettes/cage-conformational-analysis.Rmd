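---
title: "Conformational analysis of Pd2L4 lantern metallacages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational analysis of Pd2L4 lantern metallacages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagedyn)
```

## The system and the model

Lantern-shaped [Pd₂L₄]⁴⁺ metallacages consist of two square-planar Pd(II)
centres bridged by four banana-shaped bitopic ligands, each coordinating one
pyridyl nitrogen to each Pd. The two analogs treated here differ only in the
central ring of the ligand: a benzene ring presenting an inward C–H
(*endo*-C, ligand C₂₀H₁₂N₂) or a pyridine ring presenting an inward nitrogen
lone pair (*endo*-N, ligand C₁₉H₁₁N₃). Despite their rigid-looking
architecture these cages are dynamic: in solution they interconvert between
a symmetric **closed** form, a **semiopen** form in which one pair of
adjacent ligands π-stacks, and a ring-shaped **open** form in which two
pairs stack and the cavity collapses.

`cagedyn` quantifies that dynamics from simulation output. The observable
is the inter-ligand angle θ: for each pair of adjacent ligands, the acute
angle between the best-fit planes of their central aromatic rings. Adjacency
is defined by the cyclic azimuthal order of the central-ring centroids about
the Pd–Pd axis, giving four pairs and hence four angles per frame. Closed
cages sit near θ ≈ 90° on all pairs; a stacking pair pulls its angle down to
≈ 60–70° (semiopen) or ≈ 40–50° (open).

### Classification thresholds

The three literature ranges (40–50°, 60–70°, ≈90°) leave gaps, so the
classifier needs explicit cutoffs. We place them midway between the ranges:

| parameter      | default | units | meaning                              |
|----------------|---------|-------|--------------------------------------|
| `open_max`     | 55      | deg   | θ_min ≤ 55 → open                    |
| `semiopen_max` | 80      | deg   | 55 < θ_min ≤ 80 → semiopen; else closed |

Both are exposed in `state_thresholds()` and in the workflow config because
they are conventions, not measured quantities. The intervals `[0, 55]`,
`(55, 80]`, `(80, 90]` partition `[0, 90]`, so classification is total and
exclusive. The default per-frame statistic is the *minimum* pair angle:
a single stacking event is what defines the semiopen/open states, and the
stacking pair is always the extreme one. An alternative pair-count rule
(open requires at least two pairs at or below `open_max`, matching the
two-stacked-pair geometry of the open form) is selectable via
`classify_states(rule = "pair_count")`; on the idealized fixtures both rules
agree because the generator realizes low angles in pairs.

### Symmetry grouping and charge averaging

Force-field preparation assigns one partial charge per class of
symmetry-equivalent atoms. `equivalence_classes()` computes those classes on
the molecular graph by colour refinement: atoms start coloured by element,
and each round recolours every atom by its previous colour plus the sorted
multiset of neighbour colours, until the partition stops refining. Ties are
broken canonically (classes are ordered by element and refinement
signature), never by input order, so the partition is invariant under atom
permutation. The grouping convention is a **single ligand, hydrogens
included, metal excluded** — all four ligands are equivalent in the cage,
and hydrogens form their own classes. Under this convention the endo-C
ligand yields 19 classes and endo-N yields 18 (the endo C–H pair of classes
collapses to a lone N). Colour refinement can in principle be coarser than
true automorphism orbits on pathological graphs; on these ligands (and on
every test graph, where we compare against a brute-force orbit enumeration)
the two coincide.

`average_charges()` replaces each atom's charge by its class mean. This is
an orthogonal projection, so it is idempotent and conserves total charge to
machine precision — the +4 cage charge is untouched by symmetrization.
`compare_charge_models()` reports per-class means across models, cross-model
ranges, and each model's polarization (min–max spread of class means), the
statistic under which Mulliken charges typically stand out.

### Populations

Residence-time populations are frame fractions of the state labels after an
optional burn-in (default 0 — equilibration is the caller's decision and is
recorded, never silently applied). Replicas are pooled with frame-count
weights. `angle_density()` provides the continuous view; with histogram bins
aligned to the thresholds (the default 1° bins align with 55 and 80),
`integrate_density()` is *exactly* the label count — an identity the test
suite asserts at 1e-12.

Boltzmann populations of energy-labelled ensembles use
`w_i = exp(−(E_i − E_min)/k_B T)` with k_B = 0.0019872041 kcal mol⁻¹ K⁻¹ and
T defaulting to 298.15 K (room temperature; the choice is exposed because
scan-derived reference populations depend on it). Centring at E_min before
exponentiation is analytically a no-op but prevents underflow for
quantum-chemical total energies of order −10⁵ kcal/mol.

### Scan surfaces and conformer gaps

Relaxed-scan energy grids over the endo–endo distances (d1, d2) are read
from CSV; a surface is "rectangular" when the (d1, d2) pairs form a full
Cartesian product. Minima on rectangular grids use strict 8-neighbour
(Moore) comparison — 4-connectivity would split diagonal valleys on coarse
scans into spurious minima. Connected plateaus of exactly equal energy whose
entire border is higher count as a single minimum, represented by their
lexicographically smallest (d1, d2); for generic (noisy) surfaces this
reduces to the strict rule. Ragged point sets fall back to an 8-nearest-
neighbour graph. Conformer gaps are energies of labelled minima relative to
the state of the lowest minimum, so the most stable state has gap 0 by
construction and gaps are invariant under global energy shifts.

### Cross-method energetics

`relative_energies()` subtracts, within each method, the minimum energy
over *all* of that method's frames (per-method global reference). The
rationale: in cross-method comparisons all methods show near-zero relative
energies for their most stable (closed) frames, which implies a shared
per-method minimum rather than per-state references; a `per_state` reference
is available for sensitivity checks. Box statistics follow the Tukey
convention — linear-interpolation quartiles (type-7), whiskers at the most
extreme points within 1.5×IQR of the quartiles, points beyond them listed as
outliers. Method agreement against a reference reports per-state absolute
median differences of E_rel and Spearman rank correlations over shared frame
ids; empty cells and undefined correlations are reported as missing, never
as zeros.

## The synthetic generators

The generators exist so every analysis stage can be exercised, and its
statistical claims tested, without MD or quantum-chemistry engines.

**Idealized cages.** `gen_ideal_cage()` builds a chemically sensible
geometry from textbook parameters (aromatic C–C 1.39 Å, C≡C 1.20 Å,
C(ar)–C(sp) 1.43 Å, C–H 1.09 Å, Pd–N 2.02 Å): planar ligands at base
azimuths 0/90/180/270° about the Pd–Pd axis, each rotated about the vertical
axis through its own two coordinating nitrogens so that the four
adjacent-pair plane angles hit the requested targets. Because those
rotations keep every ligand plane vertical, the signed deviations from 90°
must cancel around the 4-cycle: patterns like `c(65, 90, 90, 90)` are
geometrically infeasible in this construction and raise an error, while
`c(t, t, 90, 90)` realizes any minimum angle `t` via two stacking pairs —
consistent with the physical open geometry, in which stacking also comes in
pairs. The construction is exact: the closed pattern reproduces 90.000° on
all four pairs, and `theta_series()` recovers arbitrary feasible targets to
well under 1°.

**Trajectories.** `gen_trajectory()` is a deliberate kinetic surrogate, not
an MD emulator: a 3-state Markov chain over (closed, semiopen, open) with
Gaussian in-state noise on θ_min (truncated to (0, 90]). The default chain
is `P = 0.9 I + 0.1 𝟙π'` with stationary π = (0.70, 0.20, 0.10) —
closed-dominant switching with moderate persistence, qualitatively matching
cage MD — and in-state means 88/65/45° with σ = 2°. With these defaults the
classifier recovers the generating labels at ≥ 99% accuracy, which is a
statement about the fixture's noise level, *not* about real trajectories:
real MD has autocorrelated, non-Gaussian angle fluctuations, transition
paths that dwell near thresholds, and solvent-dependent kinetics, none of
which the surrogate reproduces. What the passing tests do establish is that
counting, pooling, density integration and classification are implemented
correctly on series whose ground truth is known. Geometry frames are built
on request (`geometry = TRUE`); label/angle-only generation keeps large-n
statistical tests cheap (the suite uses 10⁵ frames for the stationary
recovery check, with the standard error adjusted for the chain's
autocorrelation, and 2×10³ frames when full geometries are needed).

**Surfaces.** `gen_surface()` sums negative Gaussians on a grid (default
15×15 = 225 points over 3.5–10.5 Å). The default three wells sit at the
closed/semiopen/open basin positions with depths 10/7.24/5.15 kcal/mol, so
the recovered gap table is (0, 2.76, 4.85) kcal/mol. When wells are
separated by more than three widths the analytic minima coincide with the
well centres; closer spacings are flagged in the surface metadata.

**Charges.** `gen_charges()` adds Gaussian noise (default σ = 0.02 e) to
per-class means and spreads the residual uniformly so the net charge is hit
exactly. Recovery of class means by `average_charges()` is then guaranteed
within ~3σ/√(class size), which the tests assert.

All generators restore the caller's RNG state and are byte-deterministic
under a fixed seed.

## Numerical conventions and degenerate inputs

* Plane fitting is by SVD of centred ring coordinates; the normal is the
  least-variance direction. Normal signs are arbitrary, so all angles use
  the acute convention (|cos| before acos). Nearly collinear rings (second
  singular value below 1e-8 of the first) raise a geometry error.
* Bond perception: distance ≤ 1.15 × (r_cov(i)+r_cov(j)) with Cordero
  radii; the same rule covers Pd–N coordination (cutoff 2.42 Å). 1.15
  accepts aromatic, alkyne and dative contacts and rejects van-der-Waals
  range contacts.
* Ring perception uses fundamental cycles of a spanning tree, which equals
  the smallest set of smallest rings here because the ligands contain only
  isolated six-membered rings.
* Counterions (PF₆⁻ etc.) and solvent must be removed before topology
  detection; `select_atoms()` filters by element allow-list or PDB residue
  names. How a given MD package strips solvent is outside the package's
  knowledge, so the selection is explicit rather than automatic.
* Atom indices are 1-based everywhere, including reports (stated in the
  report header).
* Threshold boundary values belong to the lower state (θ_min = 55 is open);
  histogram bins are right-closed so the density–count identity holds at
  the boundaries.
* Classification of an empty angle set, burn-in consuming a whole replica,
  non-stochastic transition matrices, duplicate (d1, d2) scan points, and
  (frame, method) duplicates in energy tables are all hard errors with
  typed conditions (`cagedyn_config_error`, `cagedyn_data_error`), which
  the CLI maps to exit codes 2 and 3.

## Known limitations

* Colour refinement equals automorphism orbits on these molecular graphs
  but is not guaranteed to on regular graphs generally; if the package is
  pointed at exotic topologies the class counts should be cross-checked.
* The θ-based classifier ignores stacking offsets and centroid distances;
  genuinely distorted frames near a threshold are assigned by angle alone.
* The Markov/Gaussian trajectory surrogate carries no kinetic information
  transferable to real systems (see above).
* Scan surfaces are treated as given data: no geometry optimization,
  interpolation, or transition-state analysis is attempted.
* The cage builder idealizes ligands as rigid planar units; it is intended
  for generating test geometries with known angle patterns, not for
  modelling strain or counterion effects.
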