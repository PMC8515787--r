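---
title: "Methods: invariant featurization and decision-tree analysis of reactive trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invariant featurization and decision-tree analysis of reactive trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reactree` post-processes collections of molecular-dynamics trajectories
labeled reactive or unreactive and asks which geometric features of an early
frame predict the label. This vignette documents the model and the design
decisions behind each stage, in enough detail to judge what the package's
tests do and do not establish.

## The collective variable

For proton transfer from a carboxylic acid to a water cluster the package
ships a deliberately discontinuous order parameter `s(r)`:

* Let `r_min` be the smallest distance between any acid oxygen and any
  *reactive* hydrogen (every hydrogen except the acid's C-bound one). While
  `r_min < 1.4` Å the acid is considered protonated and `s = r_min`.
* Otherwise every reactive hydrogen is assigned to its nearest oxygen, water
  oxygens holding exactly three hydrogens are marked as hydronium-like, and
  `s` is the minimum distance between an acid oxygen and a hydrogen of such
  an oxygen. A change in the identity of the triply coordinated oxygen makes
  `s` jump — the jump is the geometric signature of a separated,
  Zundel-like product.

State A is `s < 1.05` Å (1.07 Å is appropriate for the six-water cluster;
the bound is a plain config field), state B is `s > 3.0` Å; both bounds are
strict. Two situations the state definitions leave open are resolved as
follows and logged rather than hidden:

* **No hydronium although `r_min ≥ 1.4` Å.** `s` falls back to `r_min`.
  This keeps the series defined and continuous instead of failing mid-path;
  the alternative of returning `NA` would propagate into segmentation and
  window selection for no benefit.
* **Several simultaneously triply coordinated oxygens.** The global minimum
  over all of them is taken — consistent with `s` being a minimum throughout.
* **Assignment ties.** A hydrogen exactly equidistant to two oxygens goes to
  the lower atom index; deterministic, and measure-zero for real data.

`segment_trajectory()` applies the textbook excursion rule to a long
unlabeled trajectory: a segment that leaves A and next touches A again is
unreactive, one that reaches B first is reactive; one boundary frame inside
each terminal state is kept, and leading/trailing incomplete excursions are
discarded. Only A-sourced excursions are emitted by default (`from_state =
"B"` gives the symmetric analysis).

## The index-invariant representation

The atom–atom distance matrix is already translation- and
rotation-invariant; atom-index invariance is obtained by sorting. Rows are
grouped per element and, within each group, ordered by distance to a
reference atom; each row's columns are grouped and ordered the same way but
by distance to that row's atom. The column index is therefore *per-row*
("primed"): `H5'` names a different physical atom in each row.

Design points worth making explicit:

* **Reference atom.** An element rule is accepted only when it matches
  exactly one atom (the carbon of formic acid in the shipped system);
  otherwise an explicit index is required. No automatic disambiguation is
  attempted — a silently arbitrary reference would make labels
  irreproducible across runs.
* **Element-group order.** The reference element first, remaining elements
  by descending atomic number (C, O, H here). The order is recorded in the
  returned object; labels are only meaningful relative to it.
* **Self-distances are kept.** Every row contains its own zero entry (rank 0
  of its own element group), so the flattened vector has length exactly
  M² — 529 features for the 23-atom six-water cluster, 289 for the
  four-water one. Constant-zero columns are harmless to a decision tree and
  keeping them makes the layout predictable.
* **Ties.** Exact distance ties are broken by original atom index (stable
  sort). Tied geometries (e.g. perfectly symmetric waters) make the
  representation formally non-unique; the invariance guarantees below hold
  *absent exact ties*, and the synthetic geometries are built asymmetric on
  purpose.
* **Unsorting and back-mapping.** All permutations are recorded, so
  `unsort()` reconstructs the symmetric matrix (in sorted-atom order)
  exactly, with no arithmetic. `backmap_coordinates()` is classical
  multidimensional scaling: double-center the squared distances, take the
  three leading eigenpairs, scale eigenvectors by the square roots of the
  eigenvalues. Eigenvalues are compared against a relative tolerance of
  1e-9 of the largest: more than three significantly positive ones means
  the input is not 3D-embeddable (warning, best rank-3 approximation);
  negatives beyond tolerance are clamped with a warning. The reconstruction
  is defined up to rigid motion *and reflection* — chirality is not
  recoverable from distances alone.

## Window selection and the dataset

Frames within one trajectory are heavily correlated, and so are
consecutively generated trajectories. The selection window limits both:
`frames_per_path` frames (default 1) are drawn uniformly without replacement
from the frames with `lower < s < upper` (defaults 1.1 and 1.25 Å — just
above state A, so the classifier sees pre-transition configurations). The
window location, width and per-path count are the three hyper-parameters of
the method; widening the window or taking more frames per path buys samples
at the price of correlation. Paths with fewer in-window frames contribute
what they have; paths with none contribute nothing (logged). Dataset rows
are ordered by `generation_order`, the sampling-time ordinal, because the
error model below blocks over that order.

## Tree, main path, and first-split reliability

The classifier is a binary decision tree, Shannon-entropy criterion, maximum
depth 3, no pruning (`cp = 0`, `minsplit = 2`, `minbucket = 1`), fit by
`rpart` and exported into a plain node structure: split feature label,
threshold (midpoint between adjacent sorted values), and the (unreactive,
reactive) counts entering each node. The left child always holds
`feature < threshold`. Depth 3 keeps the output human-readable — the tool's
purpose is interpretation, not prediction accuracy.

The *main decision path* ends at the leaf maximizing `n_r²/(n_r+n_u)`
(reactive count weighted by reactive fraction); ties go to the shallower
leaf, then to preorder position. The leaf's `n_r/(n_r+n_u)` is reported as
the reactive probability under the path's conditions.

Because the features are strongly correlated, the root split itself is the
fragile quantity. Its reliability is estimated with a forest of depth-1
stumps: each stump is fit on a bootstrap sample with the entropy criterion
restricted to a random feature subset, and since a stump has one split, the
forest's normalized impurity importance reduces to the frequency each
feature wins the first split. Choices made here:

* **Stumps are implemented directly** (bootstrap, subset, exhaustive
  midpoint entropy scan) rather than through a general forest package: the
  available implementations use the Gini criterion and cannot be restricted
  to entropy, and the depth-1 special case is what makes "importance =
  first-split frequency" exact. An independent Gini forest restricted to
  two terminal nodes is used in the test suite as a cross-check on planted
  data.
* **`mtry` defaults to F/3**, not the common `sqrt(F)`. Every distance
  appears twice in the matrix (entry and mirrored entry) and neighboring
  entries are near-duplicates; under small subsets the win frequency of the
  true first split is diluted across its proxies and the ranking drowns in
  forest noise. A third of the features keeps subsampling (so the estimate
  still explores alternatives) while giving the dominant feature a stable
  margin. `n_trees` defaults to 1000.
* **Equal-gain ties** go to the lowest flattened feature index — again
  deterministic; the mirrored twin of a winning feature therefore never
  outranks it.

For the error bars, rows are cut into `n_blocks = 10` contiguous,
near-equal blocks in generation order (25 rows and 10 blocks give sizes
3,3,3,3,3,2,2,2,2,2), row order is randomized within each block, and one
stump forest per block yields a per-feature importance series whose standard
deviation is σ. The block shuffle and the block forests share seeds across
blocks (common random numbers), so σ measures block-to-block *data*
variation rather than the estimator's own sampling noise — and ten copied
identical blocks give exactly σ = 0. The mean importance comes from one
forest on the full dataset.

Finally, `prob_most_important()` models each feature's importance as an
independent Gaussian with that mean and σ and estimates by Monte-Carlo
argmax (default 1e5 draws) the probability that each feature draws the
largest value. The Gaussian-argmax reading is the simplest mechanism
consistent with "compare the probability distributions"; its two-feature
case has the closed form Φ(Δμ/(σ√2)), which the tests check to 0.01. With
all σ = 0 the probability degenerates onto the maximum mean (ties split
uniformly). σ is floored at zero; independence between features is an
approximation — block importances are in truth negatively coupled through
normalization, so the reported probabilities are best read as rankings with
honest uncertainty, not calibrated posteriors.

## The synthetic generator

`template_cluster(n)` builds an idealized planar formic acid (C=O 1.22 Å,
C–O 1.34 Å, O–H 0.97 Å, C–H 1.09 Å) with `n` rigid waters (O–H 0.96 Å,
H–O–H 104.5°) on a ring, radii staggered by 0.18 Å (the outermost pushed a
further 0.6 Å out) and orientations twisted per water so that no exact
distance ties exist and all intermolecular pairs exceed 1.5 Å.

`generate_paths()` scripts kinematic trajectories on top of it:

* every path starts in state A and stretches the acid proton along its bond
  through the selection window (s = 1.12, 1.18, 1.23 Å) to 1.31 Å;
* unreactive paths retrace back to 0.97 Å;
* reactive paths put the proton 0.98 Å from the nearest water oxygen
  (creating the triply coordinated oxygen, s ≈ 1.8 Å) and then relocate it
  to a water on the far side of the cluster, so the hydronium identity
  changes and s jumps above 3 Å in one step;
* all atoms get per-frame Gaussian jitter (default σ = 0.02 Å) and each
  path a random rigid rotation and translation.

The recoverable ground truth is planted independently of the proton script:
the outermost water's oxygen is placed on a sphere centred on the carbon
with radius `planted_threshold − planted_delta` (reactive) or `+
planted_delta` (unreactive; defaults 4.54 ± 0.25 Å), with randomized
angular position and molecular orientation. The carbon–outer-oxygen
distance is therefore exactly class-separated while the water's distances
to everything else are smeared by the angular randomness; in the invariant
matrix that distance is the entry `C0-O<k>'` (k = n+1), whose flattened
position precedes its mirrored twin, so both the tree and the stump forest
identify it deterministically up to feature subsampling. Reactive labels
are interleaved evenly over generation order (count = `round(frac_reactive
· n_paths)`, exact), so contiguous blocks contain both classes.

Defaults describe the conditions the validation suite runs under: the
four-water cluster (17 atoms, 289 features — the smaller published system),
200 paths, reactive fraction 0.5.

What the generator does *not* emulate: real dynamics (no momenta, no
energies, no barrier), realistic hydrogen-bond geometry, thermal
fluctuations of the water ring beyond isotropic jitter, or correlated
path-sampling moves. Passing the planted-recovery tests therefore shows the
*pipeline* is sound — featurization, selection, tree, error model — not
that any particular chemical conclusion transfers to ab initio data.

## Problem sizes and runtime choices in the suite

The test suite runs the planted-recovery check on 100 generator seeds with
200 paths each (tree fit only, ≈1 min total) and one full blocked-forest
analysis (1000 stumps × 11 forests, ≈1 min); invariance checks use 100
rigid transforms and 100 permutations of the 23-atom cluster; back-mapping
is checked on random point sets of 10–50 atoms. These sizes were chosen to
keep the full suite in the low minutes while leaving the statistical checks
meaningful.

## Known limitations

* The feature count scales as M²; beyond a few hundred atoms both memory
  and stump scans become the bottleneck. Restricting featurization to a
  subsystem of interest is the practical route (at the price of
  reintroducing a selection bias).
* Exact distance ties make the representation non-unique; symmetric
  idealized geometries should be perturbed before featurization.
* The tree is fit on in-window frames only; inequalities it reports are
  conditions *at the window*, not along the whole transition path.
* Trees are not transferable between systems — atom counts change the
  feature layout — and thresholds are data-scale quantities in Å.
* Velocities present in input files are stored but never featurized; on the
  systems this package targets they added no signal, and a velocity-aware
  feature set would need its own invariant construction.
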