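---
title: "Multi-view morphology analysis with cellmorph: models and methods"
author: "cellmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view morphology analysis with cellmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models implemented in `cellmorph`, the
assumptions behind them, the tunable parameters with their defaults and
units, the numerical conventions of the rendering and training code, and
what the synthetic-data generators do and do not emulate. Everything
quantitative that the package claims about itself is computed by its test
suite or by `scripts/acceptance.R`; this document explains *why* the code
is the way it is.

## 1. The multi-view representation

Neurons reconstructed from volume EM are sparse, elongated objects: a
process 50 nm thin can traverse the whole volume. Dense 3D CNNs on such
data waste almost all of their input on empty voxels, while a single
whole-cell projection sacrifices the nanometer detail that distinguishes,
say, a spiny dendrite from a smooth axon. The multi-view representation
keeps both scale and detail by probing the cell at many *rendering
locations* and analyzing small, high-resolution 2D projections around each
one.

**Location sampling** (`sampleRenderingLocations`). The mesh's vertex
density is evaluated in a grid of 2 × 2 × 2 µm³ voxels. For every occupied
voxel, the location is the mean of the mesh vertices within 1 µm of the
voxel center. Dense surface regions therefore yield *one* location per
grid voxel rather than one per vertex — the sampler is deliberately
insensitive to local mesh density (tested as the "oversampling resistance"
property). Two conventions are ours: the grid is anchored at the global
coordinate origin (so the SVs of one cell sample consistently), and an
occupied voxel whose center is more than 1 µm from every vertex falls back
to the mean of its own vertices, guaranteeing one location per occupied
voxel.

**Local frames** (`localFrame`). At each location, PCA on a deterministic
subset (every 8th vertex, fraction 0.125) of the vertices near the
location gives the view axes, ordered by decreasing variance; views are
rendered orthogonal to the first and second principal components, and
rotated copies are obtained by rotating about the first component by φ
(90° for classification 2-views, 50° for the triplet pairs). Sign
conventions are not identifiable from PCA, so each axis is flipped to make
its largest-magnitude entry positive and the third axis is recomputed as
the cross product, making every frame right-handed and reproducible. When
the local covariance is rank deficient or isotropic (relative eigenvalue
spread below 2 %), the frame is flagged degenerate and global axes are
used — axes fit by noise would make renderings irreproducible.

**Rendering** (`renderViews`, `renderFaceIds`). The rasterizer is a plain
orthographic z-buffer over a clip box of 8 × 4 × 4 µm³ (8 × 4 × 8 µm³ for
embedding training) at 256 × 128 pixels (31.25 nm pixel pitch); a pixel is
covered when its center lies inside the projected triangle, and the
nearest fragment wins (ties to the lower face index). Depth is stored as
unsigned 8-bit: background 0, near clip 255, far clip 1, linear in
between, rounded half-up. The encoding is our choice — only "8-bit depth
maps" is fixed by the approach — and was picked so 0 unambiguously means
background and larger always means nearer. The same camera renders the
organelle channels (mitochondria MI, synaptic junctions SJ, vesicle clouds
VC) and the face-identity map used for surface segmentation, which
guarantees pixel-exact correspondence between the channels (tested: a
pixel has a face id iff its depth is nonzero). The whole pipeline is
deterministic: the acceptance tests require *bit-identical* images under
rigid transformation of scene and frame, and per-pixel agreement with a
brute-force ray caster.

**2D masking** (`maskUnconnected2D`). For fragment-level (glia)
classification, background structures that happen to fall into the clip
box are removed by keeping only the 8-connected foreground component
containing the central pixel. 8-connectivity is our convention.

## 2. Organelle mapping and meshing

Candidate organelle objects are assigned to a cell by their relative voxel
overlap: MI and VC require overlap > 0.5, SJ — which straddles the
membrane between two partners — requires overlap within [0.2, 0.8] read as
a closed interval; objects below the class minimum size (SJ 498, VC 1584,
MI 2786 voxels) are ignored. The overlap denominator is the *object's*
voxel count: only under that normalization does an upper bound for SJ make
sense (a junction shared between two cells overlaps each with roughly
half its voxels).

Meshes for mapped objects are extracted from the binary mask via a signed
Euclidean distance field (positive inside, anisotropic voxel size
respected), Gaussian-smoothed with σ = 1 voxel, with the zero level set
triangulated by marching tetrahedra (6 tetrahedra per cube, linear edge
interpolation, triangles oriented outward along the field gradient).
Tetrahedral decomposition produces closed, consistently oriented surfaces
without case tables; the enclosed volume of a 10³-voxel cube is correct to
well within the 15 % smoothing tolerance asserted in the tests. Objects so
small that smoothing removes all interior field fall back to the
unsmoothed field so that even a single voxel yields a closed mesh.

## 3. The CMN model family

All classifiers share one convolutional family: seven valid-mode
convolution layers, each followed by ReLU and non-overlapping max pooling,
then fully connected layers of 50 and 30 units and an n-class softmax.
The input is a stack of multi-view images of shape
(batch, channels, z = views, 256, 128) with a z kernel size of 1
everywhere, i.e. all views share every filter; internally the engine folds
the z axis into the batch during convolution and concatenates the view
features at the flatten step. The reference glia configuration is

```
conv L1 (13, 1×5×5, pool 1×2×2)   conv L5 (29, 1×2×2, pool 1×2×2)
conv L2 (17, 1×5×5, pool 1×2×2)   conv L6 (30, 1×1×1, pool 1×2×2)
conv L3 (21, 1×4×4, pool 1×2×2)   conv L7 (31, 1×1×1, pool 1×1×1)
conv L4 (25, 1×4×4, pool 1×2×2)   fc 50, fc 30, fc n + softmax
```

With two output classes and one input channel this yields exactly 35,770
trainable parameters (the acceptance target; `countParameters` sums
weights and biases layer by layer). Odd feature-map sizes are floored by
the pooling, and a kernel that no longer fits its input raises an error
naming the layer. Pixel values are divided by 255 before entering the
network; dropout sits on the fully connected hidden layers for classifiers
(rate 0.1; where dropout lives is not fixed by the architecture
description, so we chose the common convention), and ReLU follows every
hidden layer. Default optimization is Adam (lr 1e-4, β = 0.9/0.99, weight
decay 5e-4 on weights only, batch 20) with the order of a sample's two
views inverted with probability 0.5 — a multi-view analogue of flipping.
Compartment training weights the loss (dendrite 2, axon 1, soma 1); the
cell-type setting uses dropout 0.08 and exponential learning-rate decay
0.98 per 1000 steps; N-view batches are class-balanced.

The engine itself (`nn-core.R`) is a compact im2col-based CPU
implementation — convolution as a matrix product, cached gather/scatter
indices, exact backpropagation (verified against numerical gradients to
1e-6 in the tests), Adam and momentum/plain SGD.

## 4. Neuron2vec triplet embeddings

Single views are embedded into d_z dimensions (10 by default) by triplet
training: the reference view and its rotated twin at the same location
(φ = 50°) form the similar pair; the dissimilar view comes from a
different cell. With neighborhood size N_r > 1, the similar view may also
come from one of the N_r − 1 nearest rendering locations of the same cell,
which smooths the latent space across adjacent locations. The loss is

L = α + λ₂ if α > 0, else λ₂, with α = r₊ − r₋ + λ₁,

where r± are Euclidean distances from the reference embedding to the
similar/dissimilar embedding, λ₁ = 0.2 is the margin, and λ₂ — the mean
norm of the three embeddings — keeps the latent vectors small.

Two practical findings from the scaled-down experiments are worth
recording. First, this objective is fragile under Adam on small corpora:
the λ₂ shrink gradient has constant per-coordinate magnitude and is
coherent across every sample, so Adam's per-coordinate normalization
preserves it while the incoherent margin repulsion averages out, and the
embedding collapses to the origin (a local optimum: the zero embedding has
loss λ₁). Plain SGD without momentum preserves the 3:1 magnitude advantage
of the repulsion term and trains stably; `trainTriplet` therefore accepts
`optimizer = "sgd"` and the packaged experiments use it (momentum itself
re-amplifies the coherent component and re-collapses the embedding).
Second, the benefit of N_r > 1 — smoother, more compartment-coherent
latents, visible as a higher kNN F1 — only materializes after the
embedding has had time to organize; early in training the extra
pull-together of genuinely different views hurts. The packaged experiment
uses 1000 SGD steps (lr 0.05, batch 8 triplets, no weight decay) at which
point N_r = 3 scores at or above N_r = 1, matching the direction reported
for the full-scale setting.

Embeddings feed a uniform-weight kNN classifier (k = 5, ties to the lowest
class code) and the PCA RGB visualization: the first three principal
components of the location embeddings, min-max scaled per channel, colored
onto the mesh by nearest location.

## 5. Glia classification and top-down splitting

A supervoxel is called glia when the mean of its multi-view glia
probabilities exceeds θ *and* at least 70 % of the views vote glia
(argmax). The two rules are only non-redundant when the first uses the
mean probability and the second counts argmax votes, which is how we read
them; θ is chosen by maximizing F1 on validation data over a 0.01 grid
(`tuneTheta`).

Splitting a labeled SSV graph proceeds in the fixed order: (1) connected
components induced by the glia labels; (2) glia components with
bounding-box diagonal ≥ 8.0 µm (computed over the mesh vertices of the
component's SVs — vertices are always available in this toolkit, and the
boundary 8.0 goes to removal) are moved to the glia side; (3) remaining
small glia components are relabeled neuron, bridging isolated
misclassifications; (4) neuron components of the reduced graph with BBD
< 8 µm are demoted to the glia side; (5) the final connected components of
each side become individual SSVs. The implementation is verified against
an independently coded, step-literal oracle on exhaustive enumerations of
small labeled graphs (all connected graphs with ≤ 4 nodes under every
label/size assignment; all 21 non-isomorphic 5-node shapes under every
assignment together with a tested node-relabeling equivariance, which
extends the agreement to every labeled 5-node graph) plus 1000 fuzzed
random graphs; its output always partitions the input node set.

Glia cells are assembled around soma seeds on a location graph (edges to
the ≤ 15 nearest locations within 10 µm, weighted by Euclidean distance);
each SV joins the soma with the smallest Dijkstra distance from any of its
locations, and unreachable SVs are reported rather than force-assigned
(arbors can enter the volume from outside). Split evaluation reports
per-class precision/recall/F1 both per SV and volume-weighted, plus the
number of newly introduced neuron splits relative to the ground-truth
neuron components.

## 6. Skeleton features

Skeleton parts are merged by repeatedly connecting the globally closest
pair of nodes of different components; degree-2 nodes are removed when the
summed length of their edges is below 50 nm, or when the unit-edge dot
product exceeds 0.8 while the summed length stays below 500 nm (branch and
end nodes are never removed). Node radii are the median distance to the
ten nearest mesh vertices.

The 23-feature descriptor collects, over all nodes within a context (4 or
8 µm maximal traversed path length, Dijkstra over edge lengths, source
included): mean and population s.d. of node diameters (2 × radius); a
10-bin diameter histogram; the mean node degree; the node density inside
the axis-aligned cube of edge 2 × context (per µm³); and per organelle
class the count, mean size and s.d. of size of organelles assigned to
traversed nodes. Three conventions are ours because no others are
recorded: histogram bin edges fixed at 0–2000 nm in 200 nm steps with the
last bin open (fixed edges keep train and test feature spaces identical),
the density normalized by the cube volume, and each organelle assigned to
the skeleton node nearest its voxel centroid. The random-forest baseline
(`rfcBaseline`, via the randomForest package) predicts by argmax class
probability; label smoothing uses a sliding majority vote within 12.5 µm
traversal windows (ties keep the original label), and unclassified
locations inherit the label of the closest classified location (Voronoi
partitioning, ties to the lowest class code).

## 7. Surface segmentation

Per-vertex ground truth is produced by Voronoi propagation of annotated
skeleton nodes followed by smoothing: each vertex takes the majority label
of the 40 vertices found by breadth-first search on the vertex graph
(edges between vertices closer than 120 nm). The pixel model is a
VGG-style fully convolutional encoder–decoder (same-padded 3 × 3
convolutions, 2 × 2 pooling, nearest upsampling, 1 × 1 class head) trained
with the Lovász-Softmax loss (cross-entropy available as a fallback for
tiny corpora), Adam (lr 4e-3, exponential decay 0.99), and x/y flips with
probability 0.5.

Predictions return to the mesh through the face-ID maps: every
non-background pixel contributes one vote for its label to each of the
three vertices of the face it shows (the simplest pixel→vertex rule
consistent with face-ID granularity), vertices take their majority label,
and uncovered vertices are filled by kNN from the labeled ones (k = 20,
mirroring the synapse-evaluation k; the fill k is otherwise
unconstrained). Because the synthetic generators build spines, necks and
shafts as separate sub-meshes, every face is uniformly labeled, and the
acceptance round trip demands *error-free* recovery on all covered
vertices when ground-truth label images are used. Face coverage — the
fraction of faces visible in at least one view — is monotone in the view
set and saturates with more perspectives per location; synapse contacts
are called spinous when the k = 20 nearest labeled vertices vote head or
neck, shaft for shaft, and flagged ambiguous otherwise (a "head only"
scoring mode restricts the positive class to spine heads).

## 8. Synthetic data: what it emulates and what it does not

The generators exist so the entire pipeline is exercisable without an EM
volume. `makeNeuron` builds a spherical soma (default radius 5 µm) with
alternating dendrite and axon branches (default 4 branches of 8–15 µm;
tube radii 350–600 nm, axons scaled by 0.45 with bouton swellings at
0.3/µm); dendrites carry spines (neck 80 nm radius and 600 nm length, head
250 nm) at 1.5/µm — a density in the range reported for spiny striatal
dendrites. Organelles are ellipsoids: mitochondria inside the lumen,
vesicle clouds in boutons, synaptic junctions straddling the membrane at
spine heads and boutons so the SJ overlap fraction lands near 0.5 and the
[0.2, 0.8] mapping window is actually exercised. The mesh is cut into ~5 µm
supervoxel segments along the skeleton — deliberately of the same order as
the 8 µm BBD threshold so the splitting heuristic faces nontrivial
decisions. `makeGliaFragment` builds undulating two-sided sheets
(8 × 8 µm², 200 nm thick, 1 µm undulation) with thin filopodia —
sheet-like, in contrast to everything tubular. All generators are pure
functions of their configuration (one seeded stream per bundle, sub-draws
in documented order; byte-identical outputs per seed, tested).

What the generators do **not** emulate: EM texture and staining artifacts,
reconstruction errors other than the planted merger, realistic branching
statistics, myelin, organelle ultrastructure, or contact sites between
many cells. Passing the packaged learning checks therefore shows that the
models, losses, rendering and bookkeeping are implemented correctly and
can learn genuinely separable morphology — it does not certify the
dataset-scale scores attainable on real tissue, which depend on data the
package does not ship.

## 9. Scaled problem sizes and numerical choices

The packaged experiments run on reduced conditions chosen once: 64 × 32
pixel views (the multi-view approach is explicitly robust to resolution
reduction), a reduced member of the CMN family (filters 8/12/16, one
hidden FC layer of 32), corpora of 4–6 synthetic cells per task, 400
training steps for the supervised tasks (Adam, lr 1e-3, class-balanced
batches) and 1000 SGD steps for the triplet runs. Rendering-location
labels for the compartment task come from the radius-adjusted nearest
skeleton node (distance minus node radius, so the single soma node claims
the whole soma surface), and locations within 2 µm of a differently
labeled node surface are excluded as boundary-ambiguous — the synthetic
analogue of annotating only clear compartments.

Other conventions worth knowing: all internal coordinates are nanometers,
with µm only at reporting boundaries and thresholds; SV graphs are
undirected with deduplicated edges and isolated SVs count as singleton
SSVs; voxelization anchors its grid at whole-voxel coordinates so
whole-voxel translations leave counts unchanged; the population s.d. of a
singleton is 0; majority votes break ties toward the original label
(smoothing), the highest summed softmax then lowest class index (N-view
voting), or the lowest class code (kNN). The LabeledVolume container is a
single-file format with a plain-text header and gzip-compressed 32-bit
payload — self-describing and dependency-free.

## 10. Known limitations

* The NN engine is CPU-only and single-threaded beyond BLAS; it is meant
  for the packaged problem sizes, not for 350k-iteration training runs.
* The rasterizer draws triangles with pixel-center coverage and no
  anti-aliasing; sub-pixel structures (a 50 nm process at a 125 nm pixel
  pitch) can drop out, exactly as they would in any point-sampled
  renderer.
* Triplet training on small corpora is sensitive to the optimizer (see
  §4); the packaged protocol is validated for the shipped corpus sizes.
* `voxelize` assumes a closed (or near-closed) surface; meshes with
  internal double walls are handled by parity counting only when the walls
  coincide exactly.
* The skeleton tools assume skeletons are given (e.g. TEASAR-style inputs
  via SWC); the package does not skeletonize volumes.
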