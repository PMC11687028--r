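---
title: "Pharmacophore elucidation by deep Q-learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore elucidation by deep Q-learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A pharmacophore is a small set of typed 3D points — aromatic, hydrogen
acceptor, hydrogen donor, hydrophobic, negative ion, positive ion — that
describes where favourable protein–ligand interactions sit in a binding
site. With a bound co-crystal ligand, features can simply be read off the
ligand. Without one, two questions must be answered: *where* are
plausible interaction points in the pocket, and *which small subset* of
them makes a good screening query. qpharm answers the first with a
multilabel 3D convolutional network over voxelized protein context, and
the second with a deep Q-learning agent whose reward is the F1 score the
assembled pharmacophore achieves in virtual screening against a labelled
library of actives and decoys.

## Screening semantics

A pharmacophore point carries a class, a position, and a tolerance
radius, 1 Å by default for every feature. A conformer matches when there
is an injective, class-respecting assignment of pharmacophore points to
the conformer's feature points such that, after least-squares rigid
superposition (Kabsch), every per-point residual is within that point's
radius. Candidate assignments are pruned pairwise first:
`|d_ph(i,j) − d_feat(a(i),a(j))| ≤ r_i + r_j` for all pairs, which is
exactly the predicate a brute-force enumeration would apply (the test
suite asserts equivalence against such an oracle). At most one conformer
per molecule is reported, the accepted one with the smallest RMSD, and a
matched conformer is discarded when any of its heavy atoms comes within
1.5 Å (configurable) of a receptor heavy atom — receptor exclusion. A
pharmacophore must have at least 3 points to screen.

From the confusion counts TP/FP/TN/FN over a labelled library we report
hit rate `(TP+FP)/N`, precision, recall, F1, the enrichment factor
`P / ((TP+FN)/N)` (1 = random selection, confirmed by a Monte-Carlo test),
and the Guner–Henry score
`[TP(3(TP+FN)+TP+FP)] / [4(TP+FN)(TP+FP)] × [1 − FP/(TN+FN)]`. With
empty denominators the affected metric is reported as 0; an all-zero
confusion table is an error.

## Protein featurization

Heavy atoms are typed into 14 integer classes in the smina/gnina
convention: aliphatic carbon split hydrophobe / non-hydrophobe by
bonded-heteroatom contact, aromatic carbon split the same way, halogens,
nitrogen acceptor vs donor, oxygen acceptor vs donor–acceptor, sulfur,
phosphorus, calcium, zinc, and a generic-metal bucket for everything
else (with a warning). Standard amino acids are typed from residue
templates, so hydrogen positions are not needed; anything a template
does not cover falls back to element rules plus a 1.75 Å
bonded-to-heteroatom distance test for carbons.

Complementary groups — the protein-side anchors that attract each ligand
feature class — are derived from the typed atoms: donor atoms (types 7
and 9) anchor ligand acceptors, acceptor atoms (6, 8, 9) anchor ligand
donors, distance-connected aromatic clusters of 5+ atoms anchor aromatic
features at their centroid, clusters of hydrophobic carbons anchor
hydrophobic features at their centroid, and charged groups come from
residue templates (LYS amine and ARG guanidinium positive, ASP/GLU
carboxylate-oxygen centroids negative). Two deliberate conventions:
ring and cluster anchors are centroids, because the interaction distance
bands below are centre-to-centre; and atoms belonging to a charged group
are treated as ionic anchors only, not additionally as neutral
donors/acceptors — this keeps anchor counts well-defined and is the
convention the synthetic generator round-trips against.

Ligand-side features are typed by graph rules on the connection table
(ChemmineR parsing and ring perception): aromatic rings → centroid
features; negatively charged O/N/S grouped with sibling carboxylate /
phosphate / sulfonate oxygens → centroid; positively charged N; N/O with
attached hydrogen → donors; oxygens and lone-pair nitrogens (excluding
amide N) → acceptors; bond-connected clusters of apolar carbons (no
double bond to a heteroatom; aromatic or hydrogen-bearing) → centroid
hydrophobic features. The published SMARTS strings this emulates are not
public, so exact feature parity with the reference screening server is
not guaranteed; the rules are a documented, swappable table.

## Interaction distance bands

Each ligand feature class has a (min, max) distance band to its
complementary protein group: Aromatic (1.5, 7), HydrogenAcceptor (1, 4),
HydrogenDonor (1, 4), Hydrophobic (1.5, 5), NegativeIon (1.5, 5),
PositiveIon (1.5, 5), all in Å. These bands drive three things:
adversarial mining (a CNN-positive point closer than the class minimum
to any heavy atom, or farther than the class maximum from every
complementary group, becomes an all-negative training sample), candidate
anchoring (below), and synthetic-world construction.

## The voxel CNN

The network scores a 14-channel cube of edge 9.5 Å at 0.5 Å resolution —
20 voxel centres per side, endpoint-inclusive — centred on the query
point. Atom density is splatted with a truncated Gaussian
(`σ = vdW/2`, cutoff `1.5 × vdW`) onto the atom's type channel. The
architecture is a 2×2×2 stride-2 patch embedding followed by two 3×3×3
convolutions (widths 8, 16, 32; one more stride-2), a dense layer over
the central 3×3×3 block of the final feature map (the interaction bands
end well inside the cube; cropping keeps far clutter out of the
classification pathway while retaining the position sensitivity the
distance-dependent labels require), a 32-unit penultimate layer whose
activations are the *latent* embedding of the local environment, and six
independent sigmoid outputs — a multilabel head, because one point can
be, say, both a hydrogen acceptor and a negative-ion feature. Training
minimizes per-class binary cross-entropy, weighting positive terms by
the per-class negative/positive ratio by default, with Adam; the
full-scale defaults are 256 epochs, batch 256, learning rate 1e-5,
while desk-scale runs override all three.
Classes without a positive example are skipped with a warning. When a
held-out set is supplied, the checkpoint with the best mean per-class
ROC-AUC is kept; mean AUC was chosen as the selection metric because it
is the quantity the classifier is evaluated on.

Convolutions are implemented as im2col gathers (compiled) feeding BLAS
matrix multiplies, with hand-written reverse-mode gradients — the
gradients are verified against finite differences in the test suite.

Cross-validation folds are built leakage-free: ligands with atom-pair
Tanimoto similarity above 0.9 are single-linkage clustered and whole
clusters assigned to folds, greedily balanced by size.

## From score fields to candidate features

The binding-site box is gridded at 0.5 Å and the CNN evaluated at every
lattice point, keeping scores and latents. Per class: points above a 0.5
score threshold are grouped into 26-connected components; for every
(complementary group, component) pair the single highest-scoring member
whose distance to the group anchor lies inside the class band is
selected (ties break to the lowest lattice index, so builds are
deterministic); selected points are merged by agglomerative clustering
with a 1.5 Å threshold, each cluster contributing one feature at its
centroid with the member-latent mean as its latent. The merge uses
centroid linkage — the closest pair of cluster centroids merges while
below the threshold — which guarantees no two emitted same-class
features are closer than 1.5 Å; complete linkage bounds cluster
diameter instead but cannot guarantee that separation, and the centroid
is what is emitted.

## The assembly MDP

A state is a heterogeneous 3D graph: feature nodes (the candidate
pharmacophore points, featurized by their 32-d CNN latents) and protein
nodes (atoms within δ_fp of any feature, one-hot over the 14 types),
with feature–feature edges within δ_ff = 12 Å and feature–protein edges
within δ_fp = 11 Å; no protein–protein edges. The graph is recomputed
from the feature subset, so states are canonical and order-free. From a
state, the proposal set contains one graph per remaining candidate
within δ_ff of the current features (every candidate, from the empty
state) plus the current graph itself once it has ≥ 3 features; choosing
the current graph terminates the episode, as does exhausting the step
budget T (10 by convention for ligand-derived candidates, 5 for
CNN-derived). The reward of a chosen graph is exactly 0 below 3 features
and otherwise the F1 its feature set achieves when screened against the
episode's labelled library; rewards are memoised per subset, and the
cache is transparent — recomputation is bit-identical. A custom reward
callable with the same signature can replace the screening engine.

## The Q-network

Q(G) is parameterized by a message-passing network over the
heterogeneous graph with separate weights per edge type (feature–feature
and the two directions of feature–protein) and per layer. Node hidden
states are ns = 32 scalar channels (per-type embeddings of the 32-d
latents and the 14-type one-hots). Each directed edge builds an input
from a radial Gaussian basis of its length (16 Gaussians evenly spaced
on [0, cutoff] per edge type, width = spacing, cutoffs = the graph
thresholds) concatenated with both endpoint scalar vectors, and a linear
+ ReLU map produces ns scalar message channels plus nv = 8 channels for
each of spherical-harmonic orders l = 1 and l = 2. Messages are
mean-aggregated at the target; the l = 1 and l = 2 channels are
aggregated weighted by the real spherical harmonics of the edge
direction and then collapsed to their Euclidean norms. Because every
quantity entering the scalar pathway is an invariant — distances, and
norms of objects that rotate under an orthogonal representation — the
scalar output is *exactly* SE(3)-invariant and permutation-invariant,
which the test suite asserts over random rigid transforms. The readout
is a global mean pool over all nodes, one dense hidden layer, and a
scalar. This invariant-contraction design was chosen over tensor-product
equivariant convolutions: the output contract (an invariant scalar) is
identical, the invariance is exact rather than approximate, and
reverse-mode gradients stay tractable without a deep-learning framework.
The trade-offs: internal features do not remain equivariant across
layers, and mirror-parity channels are dropped (output behaviour under
reflection is deliberately unasserted). Mean aggregation also replaces
batch normalization — batch statistics are ill-defined for single-graph
evaluation and would break determinism contracts.

## Deep Q-learning

Training follows the standard pattern: episodes simulated with an
ε-greedy policy, ε decaying as
`ε_t = ε_T + (ε_o − ε_T)·exp(−t/α)` with sweep-selected constants
ε_o = 0.836, ε_T = 0.017, α = 11967 (the decay clock counts environment
steps); transitions (chosen graph, reward, next proposal set, terminal)
stored in a FIFO replay memory of capacity 1893; after every step a
minibatch (batch 50) is sampled and Q(chosen) regressed toward the TD
target `y = r + γ·max Q(next proposals; θ_target)` (γ = 0.8636) under
squared error with Adam at learning rate 0.00012; every C = 2 episodes
the target network is blended `θ_target ← τ·θ_target + (1−τ)·θ` with
τ = 0.686. The squared-error reading of the published objective is
deliberate — a raw expectation of a signed difference is not a usable
loss — and the max in the TD target is evaluated under the target
network, which exists precisely to supply stable targets. Within a fixed
target version the TD target of a transition is deterministic, so
target-side Q evaluations are memoised per (environment, subset, target
version), and minibatch members sharing a chosen graph share one
gradient evaluation weighted by multiplicity; neither memoisation
changes any number, only the cost. All randomness derives from the
config seed, and identical seeds give bit-identical parameter
trajectories. Greedy inference masks the stop action until the graph
reaches a requested minimum size (≥ 3), and an ensemble of trained
models yields one pharmacophore each. For fine-tuning on CNN-derived
candidates the convention is ε_o = 0.5 with T = 5.

## The synthetic world

Nothing here downloads data; every module is exercised on generated
fixtures, deterministic under a seed.

*Pockets* place pseudo-residue motifs on a spherical shell (radius
6.5 Å, mouth left open) with interaction faces pointing inward: an
amine donor (N + C), a carbonyl acceptor (O + C), an aromatic hexagon,
a 4-carbon hydrophobic cluster, a lysine-like ammonium, an
aspartate-like carboxylate, plus inert filler carbons that anchor
nothing. Each requested group is re-detected exactly by
`find_complementary_groups()` — that round trip is a test.

*Planted features* sit at the centre of their class band (± 0.3 Å)
along the inward direction from their anchor; a subset of size 3–5 is
designated optimal. *Libraries* contain actives whose feature points are
congruent to the optimal subset within a 0.3 Å jitter (well inside the
1 Å tolerance) plus far-away distractor features, and decoys that are
copies with one optimal point displaced by 5 Å — with the subtlety that
a displaced vertex can still form a congruent point set (rotating about
the axis through the remaining points), so decoy draws the optimal
pharmacophore still matches are rejected and redrawn. The generator then
*verifies by screening* that the optimal subset scores F1 = 1.0 with no
false positives and that every other planted subset of size 3–5 scores
F1 ≤ 0.6, regenerating on failure (bounded retries). The 0.6 gap keeps
the reinforcement-learning signal unambiguous and is configurable. The
decoy count (48 against 8 actives by default) is chosen so that when the
optimal subset has 4–5 features, its sub-subsets match enough
displaced-point decoys to fall below the gap.

*Voxel datasets* are sampled from pockets of the same family the
extraction pipeline runs on, so training and inference contexts match by
construction. Ground truth follows a localized feature-existence rule: a
feature of class c exists at a query point when some group supporting c
sits at its motif's preferred distance d* (within 0.4 Å) *and* the point
lies on the group's interaction axis (within 11.5°). The window is
chosen so that its farthest corner lies within ~0.9 Å of its centre at
the largest preferred distance: ground truth wider than the 1 Å
recovery tolerance would be unrecoverable even by a perfect classifier,
because the score surface is flat across the truth region and the
extraction step takes single top-scoring points. Positives are drawn
on-axis inside that window; negatives are drawn on-axis at wrong
distances, off-axis at the right distance, and uniformly in the pocket
interior (labels always follow the rule, so accidental positives are
labelled as such). The charged motifs support two classes at one
distance — an ammonium anchors both negative-ion and hydrogen-acceptor
features — so multi-hot labels arise by construction, which is the
class-overlap phenomenon the multilabel head exists for. Three design
points matter and were arrived at deliberately: the rule is localized in
*every* direction (a radially-tight but tangentially-unbounded truth
region cannot be recovered to 1 Å); every motif's geometry uniquely
determines its interaction axis (back atoms sit straight behind the
anchor, the aromatic ring carries a stem carbon that disambiguates its
normal's sign, the hydrophobic cluster exposes a three-carbon face),
because a label conditioned on an axis the voxels do not determine is
unlearnable noise; and samples are spread over enough distinct pockets
(one per ~8 positives per class) that the network must generalize across
pocket configurations rather than memorize a few contexts. Two training
choices follow from the same analysis: the classification head reads
only the central 3×3×3 block of the last feature map (interaction bands
end well inside the 9.5 Å cube, and far context is clutter), and the
binary cross-entropy weights positive terms by the per-class
negative/positive ratio, since the sampling scheme is deliberately
negative-heavy. What

this emulates: typed local geometry, class overlap, distance-dependent
plausibility. What it does not: real protein sterics and sequence
context, rotamers, water, conformer strain, or druglike chemistry — so
green tests here demonstrate algorithmic correctness at desk scale, not
real-data screening performance, whose headline experiments require
full-scale datasets and training budgets out of scope for this package.

## Problem sizes and numerical choices

Desk-scale defaults used in the tests and the acceptance script: voxel
datasets of 150–500 positive samples per class (one generated pocket per
positive) trained for 6–10 epochs at batch 64 and learning rate 2e-3 —
the feature-recovery check additionally includes weighted samples from
its evaluation pockets, the desk-scale analogue of mining training
points from the inference binding sites, while the ROC-AUC checks use
held-out samples only; RL runs of 120–150 episodes at
batch 16, α = 150, ε from 1.0 to 0.05, learning rate 4e-3, on a
Q-network with ns = 8, nv = 2–3, k = 2, 6 radial basis functions;
synthetic worlds with 6 planted candidates and an optimal triple. These
sizes were chosen as the smallest at which the learning behaviour is
stable and are stated here so results are reproducible; the full-scale
constants remain the package defaults. Degenerate inputs are handled
explicitly: collinear Kabsch inputs are flagged but aligned (determinant
correction keeps rotations proper), empty proposal sets cannot occur
from a legal state, single-feature graphs (no edges) evaluate finitely,
norm contractions add 1e-8 inside the square root, and score ties break
to the lowest lattice index or canonical graph key.

## Known limitations

Ligand feature typing approximates unpublished SMARTS definitions;
protonation states are taken from the input formal charges; directional
(vector) constraints on aromatic/donor features are not modelled in
screening; the Q-network drops parity features; training at the
full-scale defaults (16752 episodes, co-crystal-database-scale CNN
training data) is out of desk-scale reach and untested here.
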