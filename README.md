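# reactree

Data-driven identification of the geometric features that distinguish
reactive from unreactive molecular-dynamics trajectories.

## The problem

Rare-event simulations (transition-interface path sampling, or a long plain
MD trajectory cut into excursions) produce collections of *reactive* paths —
trajectories that leave an initial state A and reach a product state B — and
*unreactive* paths that fall back into A. The mechanistic question is: *what
does a frame have to look like, early on, for its trajectory to end up
reactive?* Answering it by hand means guessing collective variables, which
injects chemical intuition and hypothesis bias.

`reactree` answers it with a supervised classifier whose inputs are free of
coordinate-frame and atom-labeling artifacts:

1. **Index-invariant distance matrix.** Each frame's atom–atom distance
   matrix is made invariant to translation, rotation and atom input order:
   rows are grouped per element and sorted by distance to a reference atom,
   and each row's columns are grouped and sorted by distance to that row's
   atom. Entries are labeled `O2-H5'` — the distance from the third-closest
   oxygen to the reference to that oxygen's sixth-closest hydrogen (ranks are
   0-based; the prime marks the secondary, per-row index). The matrix is
   flattened row-major into an M² feature vector (529 features for a 23-atom
   system). The sorting is recorded, so every feature can be *unsorted* back
   to a physical atom pair, and a bare distance matrix can be back-mapped to
   3D coordinates by classical multidimensional scaling.
2. **Selection window.** To limit inter-sample correlation, a small number of
   frames per trajectory (default one) is drawn from a narrow
   order-parameter window near state A (default 1.1 < s < 1.25 Å) — before
   the transition happens.
3. **Decision tree.** A depth-3 tree with the Shannon-entropy criterion is
   fit to the labeled feature vectors. The *main decision path* is the
   root-to-leaf path whose leaf maximizes n_r·n_r/(n_r+n_u), the number of
   reactive samples weighted by the reactive fraction; its leaf probability
   n_r/(n_r+n_u) estimates how likely a path satisfying the inequalities is
   to be reactive.
4. **First-split reliability.** With strongly correlated features, slightly
   different data can flip the root split. A random forest of depth-1 stumps
   makes the forest importance equal the first-split frequency; the samples
   are cut into 10 generation-ordered blocks to get a per-feature σ, and a
   Gaussian Monte-Carlo argmax turns (mean, σ) into the probability that
   each feature truly is the most important first split.
5. **Back-mapping.** The split features of the main path are resolved to
   their physical atom pairs and marked with dummy `X` atoms in an XYZ file
   for direct visualization (VMD and friends).

The shipped order parameter targets proton transfer from formic acid to a
small water cluster: s(r) is the minimum acid-O/reactive-H distance while the
acid is protonated (< 1.4 Å), and otherwise the minimum distance between an
acid oxygen and any hydrogen of a triply coordinated (hydronium-like) water
oxygen — a deliberately discontinuous collective variable whose jump marks
the hydronium identity change. State A is s < 1.05 Å, state B is s > 3.0 Å.

A synthetic-trajectory generator (`fixture_spec()`, `generate_paths()`)
produces labeled formic-acid/water paths with a *planted* geometric
signature, so the whole pipeline can be validated end to end with known
ground truth and no simulation data.

## Worked example

```r
library(reactree)

# 200 synthetic paths of HCOOH + 4 H2O with a planted signature
dir <- tempfile()
recs <- generate_paths(fixture_spec(n_paths = 200, seed = 1), dir = dir)

cfg  <- cluster_colvar_config(4)             # acid O = atoms 2,3; reactive H
sel  <- window_select(recs, cfg, selection_window(seed = 1))
data <- build_dataset(sel)                   # 200 frames x 289 features

tree <- fit_tree(data)                       # depth-3 entropy tree
main_decision_path(tree)
#> <decision_path>
#>   C0-O5' < 4.54  (100 unreactive, 100 reactive)
#>   leaf: (0 unreactive, 100 reactive), score = 100.000, p_reactive = 100.0%

est <- blocked_importance(data, seed = 1)
est <- prob_most_important(est, seed = 1)
print(est)
#> <importance_estimate> top features:
#>   C0-O5'     mean = 0.3160  sigma = 0.0027  p_first = 1.000
#>   C0-H9'     mean = 0.2170  sigma = 0.0186  p_first = 0.000
#>   O0-O3'     mean = 0.1730  sigma = 0.0120  p_first = 0.000
#>   ...
```

The tree's root split recovers the planted feature `C0-O5'` — the distance
from the reference carbon to its sixth-closest oxygen (the outermost water)
— with the threshold 4.54 Å sitting between the two classes, and the blocked
forest assigns that feature probability ≈ 1 of being the true first split.
The same calls work on real trajectories: write a manifest CSV
(`path_id,xyz_file,label,generation_order`) next to your XYZ files and start
from `load_path_collection()`, or use `segment_trajectory()` to label a
single long trajectory.

A command-line front end covering every stage
(`synth`/`cv`/`features`/`tree`/`importance`/`backmap`/`analyze`) is
installed at `system.file("scripts", "reactree.R", package = "reactree")`;
`analyze` runs the whole pipeline from one YAML config and writes the DOT
tree, the importance TSV, the main-path report and the dummy-atom XYZ.

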