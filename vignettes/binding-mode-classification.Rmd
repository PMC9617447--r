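---
title: "Classifying binding modes with interaction graphs and one-class SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying binding modes with interaction graphs and one-class SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igocsvm)
```

## The model

`igocsvm` learns what the binding mode of a reference agonist *looks like*
from a conformational ensemble of one agonist–receptor complex (typically
MD frames), and then decides whether a docking pose presents the same mode.
Because only one class of examples exists — frames of the reference
complex — the problem is novelty detection, not two-class discrimination.

The pipeline is:

interactions → IPA triplets → complete interaction graph → shortest-path
fingerprint → kernel → ν-one-class SVM → signed pose score → molecule
decision.

### Assumptions

* The ensemble's frames are pre-aligned to a common receptor frame of
  reference (membrane-protein trajectories usually are); the binding-site
  RMSD used for clustering therefore has no superposition step.
* Protonation and tautomer states are taken as given in the MOL2 files; no
  pKa logic is applied.
* Interactions conserved across the ensemble are the functionally relevant
  ones. This is the core modelling assumption: the one-class boundary
  tightens around the conserved pattern, and poses lacking it fall outside.

## Interaction detection

Seven types are detected between annotated protein and ligand structures:
hydrogen bonds split by direction (`HBA`: protein acceptor, `HBD`: protein
donor), ionic contacts split by protein charge sign (`ION_PPLUS`,
`ION_PMINUS`), aromatic stacking (`ARO`, face-to-face and edge-to-face
pooled), hydrophobic contacts (`HYD`) and metal chelation (`MET`). Each
detection emits three pseudo-atoms: ligand point, protein point, midpoint.

The upstream program this re-implements does not publish its thresholds, so
the defaults in `geometry_config()` are conventional structural-chemistry
values; every one is a user-visible parameter, and the tests construct
geometry relative to the configuration rather than assuming specific
numbers:

| parameter | default | meaning |
|---|---|---|
| `hb_dist_max` | 3.5 Å | donor–acceptor heavy-atom distance |
| `hb_angle_min` | 120° | donor–H–acceptor angle (best hydrogen; distance-only with a warning when no explicit H) |
| `ionic_dist_max` | 4.0 Å | cation–anion distance |
| `aro_dist_max` | 4.0 Å | ring-centroid distance; the reference pipeline widens it to 5.0 Å |
| `aro_ftf_angle_max` | 30° | max inter-normal angle, face-to-face |
| `aro_etf_angle_min` | 60° | min inter-normal angle, edge-to-face |
| `hydrophobic_dist_max` | 4.5 Å | C/S–C/S contact distance |
| `metal_dist_max` | 2.8 Å | metal–chelator distance |

Two hydrophobic definitions exist: `hyd` accepts every C/S heavy-atom pair
in range; `newhyd` additionally requires both atoms to sit in a hydrophobic
bonded environment, operationalised as *no bonded heavy neighbour that is
N, O or charged*. This is an approximation of an unpublished rule; by
construction every `newhyd` contact is also a `hyd` contact, which the
tests assert as an invariant. A geometry satisfying both the ionic and the
hydrogen-bond criteria is emitted as both interactions — the upstream
behaviour is unknown, and keeping both preserves information in the graph.

The donor/acceptor/charge rule table is frozen in
`inst/extdata/sybyl_feature_rules.tsv` so tests can pin it; it is likewise
a documented approximation of unpublished atom-typing rules.

## The interaction graph and its kernel

All IPAs of a frame form one complete graph; node labels are the 21
(type × role) combinations. Edge weights are Euclidean distances rounded to
the nearest Å. Three numerical choices matter:

* **Ties round half up** (2.5 Å → 3 Å). The rounding convention of the
  reference implementation is unknown; ours is fixed and test-pinned.
* **Weights are stored as deci-Å integers** (rounded Å × 10), making every
  later shortest-path sum exact integer arithmetic — no float-binning
  ambiguity when path lengths become fingerprint keys.
* **Overlapping IPAs** (rounded distance 0, i.e. < 0.5 Å apart) get weight
  1 deci-Å = 0.1 Å, keeping the edge present. Because 0.1 edges and
  rounding can break the triangle inequality, shortest paths are computed
  properly (Dijkstra per source) instead of assuming direct edges are
  shortest; a Floyd–Warshall brute force serves as the independent test
  oracle.

A fingerprint counts one feature per unordered node pair:
`(label_a ≤ label_b, shortest-path length)`, with label order
canonicalised by a fixed total order over the 21 labels. Self-pairs are
excluded (an *n*-node graph yields exactly *n(n−1)/2* counts); whether the
reference implementation counts distance-0 self-pairs is unknown, and the
exclusion is test-pinned. Similarity is the dot product over shared
features (`nn`) or the cosine (`normalized`). The "temporary vocabulary
extension" of the kernel falls out naturally: a query feature unseen in
training contributes to the query's own norm (lowering cosine similarity)
but can never contribute to a dot product, so `nn` scores are invariant
under vocabulary extension — both directions are asserted as properties.

The Polar variant simply removes `HYD` triplets before graph construction;
aromatic and metal interactions are retained.

## Training the one-class SVM

The ν-OCSVM dual, `min ½αᵀKα` subject to `0 ≤ α_i ≤ 1/(νn)`, `Σα_i = 1`,
is solved by SMO over maximal-violating pairs on the precomputed Gram
matrix (no pre-installed R package provides a precomputed-kernel one-class
SVM, and the solver is small). At the optimum the ν-property holds: the
training-outlier fraction is ≤ ν and the support-vector fraction ≥ ν; the
test suite checks both across seeds and ν values at tolerance 1e−3. The
offset ρ is taken as the *minimum* gradient over margin support vectors: at
the exact optimum all margin gradients coincide, and the minimum keeps
boundary points (which are margin SVs) on the inlier side of f = 0 despite
solver-tolerance noise. Consistently, a score of exactly 0 is classified as
an inlier.

ν itself comes from the profile of average similarity to the K nearest
neighbours, K = max(1, round(0.03 · N)), self excluded:

* **QMS2**: sort the profile ascending, find the first knee with the
  kneedle construction (min–max normalise both axes, difference curve
  d = y − x, first local maximum of d whose threshold
  `d_max − S/(n−1)` is undercut before the next local maximum), discard
  the instances ranked strictly below the knee, train with ν = 0.01. With
  no knee (constant/linear profile) all instances are retained. Only the
  low-similarity end is trimmed — whether the original heuristic also trims
  the high end is unclear from its description, and the conservative
  reading was kept. The sensitivity S defaults to 1 and is exposed, since
  the original was tuned manually.
* **MAD**: ν = fraction of instances with |s − median| > 3 × MAD. The MAD
  is raw (no 1.4826 consistency factor), the inequality strict — so a
  zero-MAD profile (most values identical) counts only true deviants — and
  ν is clamped to ≥ 1/N when the rule yields 0, since ν = 0 is outside the
  OCSVM domain.

Models using the non-normalized kernel are trained with QMS2 only,
mirroring the reference protocol (`method = "nn"`). The KNN profile is
computed with the model's own kernel mode; the alternative (always cosine)
is defensible but using one kernel end-to-end is more coherent.

## Screening and evaluation

A molecule is agonist-classified iff **any** of its poses — all
stereoisomers, and in ensemble mode all representative receptor
structures — scores ≥ 0. This union rule makes ensemble recall
monotonically ≥ any single-structure recall (a test invariant).
Precision, recall and F1 use the standard definitions with agonist as the
positive class and antagonist/inactive pooled as negatives; 0/0 cases
resolve to 0, and report tables round half-up to 2 decimals.

The IFP baseline sets one bit per (binding-site residue × interaction
type), compares by Tanimoto, and the threshold sweep evaluates midpoints of
consecutive sorted unique scores plus the select-all baseline, returning
the lowest F1-maximising threshold. Per-trajectory average IFPs display a
bit only when present in ≥ 10 % of frames or in the crystallographic
reference — a reporting mask, never a filter.

## Representative conformations

The binding site is defined as protein heavy atoms strictly closer than
4.5 Å to any ligand heavy atom in at least 10 % of frames (both constants
exposed); a shared definition unions the residues of several
system-specific definitions. Pairwise RMSD uses the plain
`sqrt(Σ(X_i − Y_i)²/N)` without superposition, faithful to the stated
formula (an optional pre-alignment would change the semantics and is
deliberately absent). Clustering offers average-linkage hierarchical and
PAM k-medoids; PAM's BUILD+SWAP is deterministic, so the `seed` argument
exists only for interface stability. Medoids are always recomputed as the
exhaustive within-cluster row-sum minimiser. The number of clusters is
chosen by majority vote of silhouette (max), Dunn (max) and Davies–Bouldin
(min), ties toward smaller k — how the three indices were originally
combined is unstated, and majority vote with a parsimony tie-break is this
package's documented choice. Degenerate all-zero distance matrices produce
a warning and an arbitrary split rather than an error.

## The synthetic world

`default_template()` states a fixed, ADRB2-flavoured binding mode: ionic +
hydrogen-bond anchors to "Asp113" (conservation p = 1), hydrogen bonds to
"Asn312" (p = 0.9) and "Ser207" (p = 0.8), three hydrophobic contacts
(p = 0.6–0.8) and one aromatic stacking (p = 0.5), spanning ~10 Å. The
residue names are readable identifiers only. `simulate_trajectory()` draws
each interaction per frame with its p, jitters endpoints with isotropic
Gaussian noise (default σ = 0.5 Å), recomputes midpoints, and adds
Poisson-many spurious interactions (default rate 0.5/frame) within 8 Å of
the template centroid so that pollution lands at the same graph scale.
Decoys are type-swapped (permuted interaction types), displaced
(protein-side anchors translated ≥ 3 Å, default 5 Å) or subset poses
(anchors with p ≥ 0.8 dropped, at most half kept). Everything is seeded and
byte-reproducible.

What the generator emulates: conservation structure, positional noise,
spurious contacts, and the inlier/decoy contrast. What it does **not**
emulate: real chemistry (no force field, no correlated motions, no
water-mediated contacts), realistic docking-pose error modes, or class
imbalance of real libraries. A green end-to-end test therefore establishes
that the machinery recovers a planted conserved pattern under stated noise
— not that the method reproduces the original screening performance, which
would require the original trajectories and docking poses.

## Known limitations

* The atom-typing table and geometric thresholds approximate unpublished
  rules; absolute interaction counts on real complexes will differ from the
  reference implementation even where the downstream machinery is faithful.
* Halogen bonds and water-mediated interactions are not detected.
* The MOL2 reader covers the machine-generated dialect used in this
  workflow (MOLECULE/ATOM/BOND), not the full TRIPOS specification.
* SMO on a dense Gram matrix is O(N²) memory; ensembles of ~10⁴ frames are
  the practical ceiling.
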