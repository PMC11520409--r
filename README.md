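# SliceOT

Spatial transcriptomics (ST) assays measure gene expression at spatially
barcoded spots while retaining each spot's position in the tissue section.
Integrating several sections — adjacent slices of one sample, replicates, or
a developmental series — requires removing per-slice batch effects *without*
erasing genuine structural differences between sections, and, unlike
single-cell batch correction, there is no known correspondence between the
spots of different slices. SliceOT is for analysts who need all three
products of such an integration at once:

1. a **probabilistic spot-to-spot alignment** between slices,
2. a **common low-dimensional embedding** of all spots, and
3. a **rigid 2D/3D coordinate registration** of the sections.

## Model

Each slice contributes a spot × gene matrix of normalized expression and 2D
spot coordinates. Per slice, an undirected spatial neighbor network connects
spots closer than a radius *r* (adjacency `A`, `A_ij = 1 ⇔ ‖s_i − s_j‖ < r`).
A graph attention autoencoder embeds the concatenated slices over the
block-diagonal union of these graphs:

    h_i^(k) = σ( Σ_{j ∈ S_i} att_ij^(k) · W_k h_j^(k−1) ),
    e_ij^(k) = σ( v_s·(W_k h_i^(k−1)) + v_r·(W_k h_j^(k−1)) ),
    att^(k)  = softmax over the neighbor set S_i of e^(k),

with the decoder fully tied to the encoder (Ŵ_k = W_kᵀ, âtt^(k) =
(att^(k))ᵀ), so the latent code `z` is regularized by a reconstruction loss
`L_recon = Σ_i ‖h_i − ĥ_i‖²` without doubling the parameter count.

Between two slices the transport cost is the latent Euclidean distance
`C_ij = ‖z_xi − z_yj‖`, and the coupling is the unbalanced entropic optimal
transport plan

    T* = argmin_{T ≥ 0} ⟨C, T⟩ − ε H(T) + ρ₁ KL(T1 ‖ a) + ρ₂ KL(Tᵀ1 ‖ b),

solved by proximal Sinkhorn scaling iterations
(`α = (a / Gβ)^{ρ₁/(ρ₁+ε)}`, `β = (b / Gᵀα)^{ρ₂/(ρ₂+ε)}`). The KL marginal
penalties let only part of the mass move: with `ρ₁ = ∞, ρ₂ = 0.01` (the
partial-alignment regime) rows are transported exactly while columns may
starve, which is what tolerates partially overlapping sections. Autoencoder
and plan are optimized alternately under the combined objective

    L_total = (1 − γ) L_recon + γ Σ_ij C_ij T*_ij ,   γ = 0.2,

with the plan held fixed between refreshes (its gradient flows only through
the cost). Finally, the plan's weights feed a weighted SVD Procrustes (ICP)
solve that returns the rotation/translation mapping one section onto
another, and multiple sections are stacked in 3D against a chosen reference
template. Hard matchings (`π(i) = argmax_j T_ij`), alignment accuracy,
label-transfer ARI, batch mixing entropy and silhouette scores are provided
for evaluation, and a synthetic-slice generator plants ground truth for
every one of these capabilities.

## Worked example

```r
library(SliceOT)

cfg <- syntheticConfig(gridShape = c(10, 10), rotationDeg = 30, seed = 42)
sim <- simLayeredPair(cfg)          # two slices, 4 tissue bands, batch
sim$sliceX                          # effect + noise, planted 30° rotation
#> STSlice 'sliceX': 100 spots x 60 genes
#>   assays: logcounts
#>   labels: 4 levels
#>   coords: x in [1, 10], y in [1, 10]

buildSpatialGraph(sim$sliceX)       # default radius targets ~6 neighbors
#> SpatialGraph: 100 spots, 342 edges, radius 1.414 (mean degree 6.84)

res <- trainPair(sim$sliceX, sim$sliceY,
                 config = trainConfig(epochs = 300, warmupEpochs = 100,
                                      hiddenDims = c(64, 30), seed = 0))
transportPlan(res)
#> TransportPlan 100 x 100: mass 0.9224, epsilon 0.05, rho1 1, rho2 1
#>   6 outer iterations, converged: TRUE

m <- maxProbMatching(transportPlan(res))
metricsReport(res, spotLabels(sim$sliceX), spotLabels(sim$sliceY))
#>  alignmentAccuracy ltari batchEntropy  batchASW celltypeASW nMatched
#>                  1     1    0.0458744 0.2001766   0.6348537      100

weightedProcrustes(spatialCoords(sim$sliceX), spatialCoords(sim$sliceY),
                   transportPlan(res))
#> RigidTransform: angle 30.2828 deg, t = (0.1516, -0.207), det 1
```

Every matched spot pair lands in the same tissue band (accuracy and
label-transfer ARI of 1), and the plan-weighted Procrustes solve recovers
the planted 30° rotation to a third of a degree. Batch mixing in the
embedding keeps improving with longer training than this quick
demonstration runs (see the vignette for the trade-off).

A command-line interface wrapping the same functions ships in
`inst/scripts/sliceot`:

```sh
sliceot simulate   --grid 20 --seed 0 --out sim/
sliceot align-pair --x sim/sliceX.h5ad --y sim/sliceY.h5ad --out run/
sliceot align-pair --x left.h5ad --y right.h5ad --partial --out run2/
sliceot stack      --inputs a.h5ad,b.h5ad --plans run/plan.csv \
                   --reference b --out stack/
```

Slices are accepted as AnnData `.h5ad` (dense or CSR `X`, coordinates in
`obsm/spatial`), MatrixMarket MTX + TSV coordinates, or dense CSV, and
results are written back as h5ad/CSV/TSV.

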