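# coalternet

Morphometric coalteration ("coatrophy") network analysis for
coordinate-based meta-analysis of voxel-based morphometry (VBM) findings.

Neurodegenerative and psychiatric disorders do not atrophy the brain at
random: gray-matter decreases reported across independent VBM studies tend
to co-occur in specific sets of regions. `coalternet` implements a
meta-analytic pipeline that turns a collection of reported alteration peaks
("foci", one set per experiment) into an undirected network whose nodes are
consistently altered brain loci and whose edges mark statistically
significant co-occurrence of alteration across experiments. It is aimed at
neuroimaging researchers running coordinate-based meta-analyses who want to
go beyond "where is the atrophy" to "which alterations travel together".

## The method

1. **ALE mapping.** Each experiment's foci are smoothed with an isotropic
   3-D Gaussian kernel, p(d) = (σ³(2π)^{3/2})⁻¹ e^{−d²/2σ²} with
   σ = FWHM/√(8 ln 2) (default FWHM 10 mm), converted to per-voxel
   probabilities and combined per experiment by voxel-wise maximum into a
   modeled alteration (MA) map. The ALE map is the probabilistic union
   across experiments, ALE = 1 − ∏ᵢ(1 − MAᵢ), thresholded at voxel-level
   FWE p < 0.05 against a simulated max-statistic null (foci redrawn
   uniformly over the brain mask).
2. **Node creation.** The thresholded map is intersected with a labeled
   atlas: regions with ≥ 20 suprathreshold voxels count as altered; local
   maxima above the 90th percentile of the suprathreshold value
   distribution, at least 10 mm apart, become atlas-labeled nodes
   (numbered rostrocaudally within each region).
3. **Coalteration.** A binary experiments × nodes matrix records which
   experiments altered which nodes. For each node pair, the four joint
   state probabilities θ₁…θ₄ (both, a-only, b-only, neither) give
   Patel's κ:

   κ = (θ₁ − E) / (D(θ₁ᵐᵃˣ − E) + (1 − D)(E − θ₁ᵐⁱⁿ)),

   with E = (θ₁+θ₂)(θ₁+θ₃), θ₁ᵐᵃˣ = min(θ₁+θ₂, θ₁+θ₃),
   θ₁ᵐⁱⁿ = max(0, 2θ₁+θ₂+θ₃−1), D = 1{θ₁ ≥ E}; κ ∈ [−1, 1]. Edge
   significance is assessed by Monte-Carlo sampling of the posterior
   Dirichlet(1+n₁, …, 1+n₄); a pair is connected when
   P(κ > 0 | data) ≥ 0.99.
4. **Topology.** Node degree (pathoconnectivity hubs), edge betweenness
   (fractional or integral tie handling), k-core decomposition (the
   maximal non-empty core is the "core subnetwork"), inter- vs
   intrahemispheric edge counts, and region-level node merging.

A fully synthetic generator (toy cuboid atlas + multinomial alteration
model with planted pairwise couplings) provides ground-truth data for
validation; its planted couplings have closed-form population κ.

## Worked example

```r
library(coalternet)

spec  <- defaultGenerativeSpec(seed = 0)   # 60 experiments, 10 regions,
                                           # 4 planted couplings
atlas <- makeToyAtlas(spec, defaultGrid(4))
sim   <- simulateDataset(spec, atlas)
cfg   <- coalternetConfig(voxel_size = 4, null_iterations = 200)
res   <- runPipeline(sim$experiments, atlas, cfg, seed = 1)

res$network
#> CoalterationNetwork: 10 nodes, 4 significant edges (of 45 pairs tested)
networkEdges(res$network)
#>          node_a       node_b     kappa posterior_prob
#> 1 Occipital_R_1   Limbic_R_1 0.6543779              1
#> 2   Frontal_L_1 Parietal_L_1 0.7836538              1
#> 3 Occipital_L_1  Frontal_R_1 0.5333333              1
#> 4  Temporal_L_1 Temporal_R_1 0.9250000              1
sim$truth$planted
#>     region_a    region_b population_kappa
#> 1 Temporal_L  Temporal_R              0.9
#> 2  Frontal_L  Parietal_L              0.8
#> 3   Limbic_R Occipital_R              0.7
#> 4  Frontal_R Occipital_L              0.6
```

All four planted couplings are recovered with no spurious edge, and each
κ̂ sits close to its population value (0.93 vs 0.9, 0.78 vs 0.8, 0.65 vs
0.7, 0.53 vs 0.6) — the residual gap is the sampling error of estimating a
2×2 joint distribution from 60 experiments. `res$topology` carries the
degree, betweenness and k-core report, and `writeOutputs()` (or passing
`outDir =` to `runPipeline()`) serializes nodes.tsv, matrix.tsv,
edges.tsv, network.graphml, the NIfTI ALE map and a JSON run manifest.

A thin command-line front end lives at `inst/cli/coalternet.R`
(`run`, `simulate`, `ale`, `network` subcommands).

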