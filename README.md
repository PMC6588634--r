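# cellmorph

Multi-view cellular morphology networks (CMNs) for volume-EM neuron
reconstructions, in R.

Automated reconstruction of brain tissue from volume electron microscopy
produces cells as triangle meshes, supervoxel (SV) adjacency graphs and
skeletons. Interpreting those reconstructions — which fragments are glia,
where a merge error joined an astrocyte to a neurite, which parts of a cell
are axon, dendrite or soma, which cell type a reconstruction is, where the
dendritic spines sit — is a morphology-analysis problem. `cellmorph`
implements the multi-view approach to that problem: a cell is probed
homogeneously at many rendering locations; at each location a local
PCA-aligned frame is computed and 2D orthographic depth maps of size
256 × 128 (8-bit; optionally with mitochondrion/synaptic-junction/
vesicle-cloud channels) are rendered; convolutional networks then classify
single views, multi-view sets or N-view collections, or embed views into a
latent space by unsupervised triplet-loss training (Neuron2vec).

The package is aimed at connectomics researchers and methods developers. It
contains:

* **Geometry core** — S4 classes `TriangleMesh`, `Skeleton`,
  `SupervoxelGraph`, `LabeledVolume`; PLY/OBJ/SWC/edge-list/GraphML I/O;
  bounding-box diagonals (BBD) and connected components.
* **Synthetic data** — seeded generators for branched, spiny neuron meshes,
  undulating glia sheets, organelle voxel sets, SV decompositions and
  planted neuron–glia merge errors, so every stage runs without an EM
  volume.
* **View sampling and rendering** — the 2 µm density-grid location sampler
  and a deterministic software rasterizer (orthographic, z-buffered, exact
  per-pixel semantics, face-ID color buffering for 2D→3D back-mapping).
* **CMN models** — a compact CPU neural-network engine; the reference
  architecture family (the two-class, one-channel glia model has exactly
  35,770 trainable parameters); the triplet loss
  `L = α + λ₂` for `α = r₊ − r₋ + λ₁ > 0`, else `λ₂`, with `λ₁ = 0.2` and
  `λ₂` the mean embedding norm; N-view assembly and majority voting;
  kNN-on-embedding classification; PCA RGB mesh coloring.
* **Glia pipeline** — per-SV classification (mean view probability > θ and
  ≥ 70 % glia votes) and the top-down splitting heuristic: glia components
  with BBD ≥ 8 µm are removed, small glia components are bridged, small
  leftover neuron components are demoted, and the resulting connected
  components become individual neuron/glia SSVs.
* **Skeleton tools** — merging, degree-2 sparsification (λ = 50 nm /
  dot > 0.8 with λ = 500 nm), radius estimation from the 10 nearest mesh
  vertices, the 23-feature node descriptor with a random-forest baseline,
  12.5 µm sliding majority votes and Voronoi label propagation.
* **Surface segmentation** — 40-vertex BFS label smoothing on the 120 nm
  vertex graph, per-pixel semantic segmentation of views, face-ID
  back-mapping with per-vertex majority votes, kNN filling, face-coverage
  statistics and spinous-vs-shaft synapse calls (k = 20).

## Worked example

```r
library(cellmorph)

## a synthetic neuron with a planted astrocyte merger
cfg    <- synthesisConfig(seed = 3, voxelSize = c(40, 40, 40))
neuron <- makeNeuron(cfg)
glia   <- makeGliaFragment(cfg)
merged <- plantMergeError(neuron, glia, nBridges = 2)
merged
#> GroundTruthBundle: 3872 vertices, 123 skeleton nodes, 14 SVs, 30 organelles

## rendering locations and one multi-view fingerprint
L  <- sampleRenderingLocations(neuron@mesh)
nrow(L)
#> [1] 150
fr <- localFrame(neuron@mesh, L[3, ])
vs <- renderViews(organelleScene(neuron), fr,
                  renderConfig(resolution = c(64, 32)))
vs
#> ViewSet: 64 x 32 px, 2 perspective(s), channels: cell, mi, sj, vc

## the reference glia architecture
countParameters(buildCmn(cmnArchitecture("glia"), nClasses = 2, nChannels = 1))
#> [1] 35770

## splitting the planted merger with ground-truth SV labels
res <- splitSsv(merged@svGraph)
lengths(list(neuron = res$neuron, glia = res$glia))
#> neuron   glia
#>      1      1
```

The split returns one neuron SSV and one glia SSV: the planted bridge is
cut because the glia side forms a connected component with a bounding-box
diagonal above 8 µm, while an isolated mislabeled SV would have been
bridged instead of splitting the neuron.

`runPipeline(runConfig(seed = 1))` chains the stages end to end on a small
synthetic preset — synthesis, rendering, CMN training, SV classification,
splitting, scoring — and writes `metrics.json`; rerunning with the same
seed reproduces the file byte for byte.

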