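---
title: "Building morphometric coalteration networks with coalternet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building morphometric coalteration networks with coalternet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`coalternet` treats a coordinate-based VBM meta-analysis dataset as a list
of *experiments*, each reporting a handful of stereotaxic peak coordinates
(foci, in Talairach mm) where gray matter was found decreased in patients
relative to controls. The pipeline makes three modeling moves.

**Spatial uncertainty → ALE.** A reported coordinate is an uncertain
estimate of the true alteration locus. Each focus is therefore replaced by
an isotropic 3-D Gaussian, $p(d) = (\sigma^3 (2\pi)^{3/2})^{-1}
e^{-d^2/2\sigma^2}$ with $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$. The
density is converted to a per-voxel probability by multiplying by the
voxel volume, which keeps modeled-alteration (MA) values in $[0,1]$ as the
union formula requires; within an experiment, overlapping kernels are
combined by voxel-wise **maximum**, so duplicated or tightly clustered
foci are not double counted. Across experiments the ALE map is the
probabilistic union $1 - \prod_i (1 - \mathrm{MA}_i)$: the probability
that at least one experiment's true locus lies in the voxel, assuming
experiments independent. Significance is assessed against a simulated
null in which every experiment keeps its foci count but the foci are
placed uniformly over the brain mask; recording the per-iteration maximum
ALE value yields voxel-level family-wise-error control (a cluster-size
null, given a cluster-forming threshold, is also available). The
assumptions to keep in mind: isotropic, experiment-independent spatial
uncertainty, and a spatially uniform null.

**Thresholded map → nodes.** The suprathreshold map is intersected with an
integer-labeled atlas. Three thresholds shape the node set, all of them
redundancy filters rather than significance tests (every suprathreshold
voxel is already FWE-significant): a region is *altered* when it contains
at least 20 suprathreshold voxels; local maxima (26-connectivity; flat
plateaus contribute their centroid voxel) are kept when they exceed the
90th percentile of the suprathreshold value distribution; and a greedy
minimum inter-peak distance of 10 mm — the mean spatial-uncertainty scale
of reported coordinates — prunes near-duplicate peaks in descending-value
order. Survivors become nodes named `<Region>_<k>`, numbered
anterior-to-posterior within each region.

**Nodes → network.** A binary $N \times M$ coalteration matrix marks which
experiments altered which nodes. For a node pair, the empirical joint
probabilities $\theta_1..\theta_4$ of the four alteration states feed
Patel's $\kappa$, the excess of joint alteration over the independence
expectation $E = (\theta_1+\theta_2)(\theta_1+\theta_3)$, normalized by
the distance to the Fréchet bound on the side indicated by
$D = 1\{\theta_1 \ge E\}$, so $\kappa \in [-1, 1]$ with the endpoints
attained exactly at perfect co-occurrence and perfect complementarity.
Uncertainty is handled by a conjugate Monte-Carlo test: the posterior of
the 4-cell multinomial under a flat Dirichlet prior is sampled, and the
pair is connected when $P(\kappa > e \mid \mathrm{data}) \ge 1 - p$ with
$e = 0$, $p = 0.01$. The resulting graph is undirected and unweighted for
all topological computations ($\kappa$ annotates edges but is never a
path weight).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fwhm_mm` | 10 | mm | mean reported spatial-location uncertainty is ≈10 mm; subject-count-dependent widths are out of scope |
| `voxel_size` | 2 | mm | conventional ALE analysis grid; the full Talairach box at 2 mm is 71×87×70 voxels |
| `truncation_factor` | 3 | ×FWHM | kernel truncation radius; ≤10⁻⁶ absolute error vs dense evaluation (≤10⁻¹² at 5) |
| `alpha` | 0.05 | — | voxel-level FWE rate, max-statistic null, conservative "higher" quantile |
| `null_iterations` | 1000 | — | null sample size; the threshold is an order statistic, so ≥1000 keeps its own noise small |
| `min_region_voxels` | 20 | voxels | excludes rarely altered regions from the node set |
| `peak_percentile` | 90 | % | keeps only high-consensus peaks; basis is the suprathreshold *voxel* value distribution (`peak_percentile_basis = "peaks"` switches to peak values) |
| `min_interpeak_mm` | 10 | mm | inclusive at exactly 10 mm, since equality is within the uncertainty that motivates the rule |
| `assign_radius_mm` | 10 | mm | focus-to-node assignment radius for the coalteration matrix (`assign_rule = "region"` uses atlas membership instead) |
| `e_threshold`, `p_threshold` | 0, 0.01 | — | edge test: P(κ > e) ≥ 1 − p |
| `mc_samples` | 10⁴ | — | Dirichlet draws per pair; <10³ is rejected as an unstable tail estimate |
| `alpha0` | 1 | — | flat Dirichlet prior, the minimal-assumption choice |

## Design choices where the design was open

Several steps admit more than one defensible reading; the package picks
one, records it in the run manifest, and exposes the alternative where it
is cheap.

* **Kernel normalization.** $p(d)$ is a density with unit integral over
  $\mathbb{R}^3$, not a probability. We multiply by the voxel volume
  ("probability that the focus lies in this voxel"), the standard ALE
  reading, which bounds MA values by the kernel peak times voxel volume.
* **Percentile basis.** "90th percentile of the value distribution" could
  mean peak values or voxel values. Peaks are few once maps are
  thresholded, so their empirical percentile is unstable; the default uses
  the suprathreshold voxel distribution.
* **Order of region rule and distance filter.** The default applies the
  20-voxel region rule *after* the inter-peak distance filter, so a strong
  peak in a failing region still suppresses nearby peaks — the
  conservative order (`region_rule_first = TRUE` switches).
* **Focus-to-node assignment.** How an experiment's foci set the 1s of
  its matrix row is the least constrained step of the method. The default
  marks a node when a focus falls within 10 mm of its peak — the same
  spatial-uncertainty constant used for the inter-peak distance — and one
  focus may mark several nearby nodes; atlas-region membership is the
  alternative rule.
* **D in the κ denominator.** Defined as $1\{\theta_1 \ge E\}$, the
  convention that makes the normalization reach the correct Fréchet bound
  on each side and guarantees $\kappa \in [-1,1]$.
* **Point estimate per edge.** Reported κ uses the maximum-likelihood
  $\hat\theta = n/N$, not the posterior mean, so printed values match the
  closed-form examples; the Monte-Carlo test supplies the uncertainty.
* **Multiple comparisons across pairs.** The default is the method's
  fixed per-edge p < 0.01; `buildNetwork(bonferroni = TRUE)` adds a
  corrected flag without changing the default decisions.
* **Betweenness ties.** Equal-length shortest paths split contributions
  fractionally by default; an integral mode (every tied path counts 1) is
  available since a verbal "number of shortest routes" definition admits
  both.
* **Degenerate columns.** Nodes altered in all or no experiments make κ
  undefined (zero-width normalization); such pairs are excluded with a
  logged reason rather than erroring the run.

## What the synthetic generator emulates — and what it does not

`defaultGenerativeSpec()` defines the package's reference conditions: 60
experiments over 10 disjoint cuboid "regions" (5 mirrored left/right
pairs) with marginal alteration probability 0.5, and 4 planted pairwise
couplings with population κ of 0.9, 0.8, 0.7 and 0.6 (excess joint
probability κ/4 at these marginals), a mix of inter- and intrahemispheric
pairs. Couplings are restricted to a matching (each region in at most one
pair), which lets every planted pair be sampled *exactly* from its 4-cell
multinomial — no copula approximation — while uncoupled regions stay
independent Bernoulli. An altered region contributes 2–4 foci scattered
isotropically (sd 4 mm ≈ the σ of a 10 mm-FWHM kernel, so ALE peaks land
near region centers), truncated to the region cuboid; 0–3 noise foci per
experiment are placed uniformly over the labeled voxels, emulating the
scattered low-consensus findings that the 20-voxel rule should remove.

The generator is deliberately idealized: cuboid regions on a regular
grid, equal marginal probabilities, pairwise-only dependence, isotropic
scatter, and noise confined to the mask. Real VBM data have irregular
anatomy, heterogeneous study sizes and smoothing kernels, higher-order
co-alteration structure, and reporting biases. Passing the recovery tests
therefore shows that the estimator chain is correct under its own
generative model — not that real-data networks are free of those
confounds.

## Numerical choices and degenerate inputs

Foci are snapped to the nearest voxel centre before kernel placement;
out-of-grid foci are dropped with a warning (an all-outside experiment is
an error). Empirical quantiles use "higher" (ceiling order statistic)
interpolation for the FWE threshold — conservative — and thresholding
keeps voxels *at* the threshold. Peak ties are broken by voxel linear
index so the greedy distance filter is independent of input order; flat
plateaus contribute one peak at the centroid-nearest member. Maxima use
26-connectivity, null cluster formation 6-connectivity. Dirichlet draws
with degenerate marginals (measure zero under a flat prior, possible only
by floating-point underflow) are rejected, redrawn and counted. Empty
networks, edgeless graphs, background-only atlases and all-zero matrix
rows are all valid inputs with defined outputs.

Problem sizes used by the shipped validation suite (chosen as the
smallest sizes at which each property is sharply testable): ALE oracle
equivalence on a 4 mm grid with 10-focus fixtures; FWE calibration on a
13³ voxel 6 mm grid with 1999 null iterations and 500 fresh datasets;
edge-significance calibration over 2000 independent pairs at N = 57 with
10⁴ draws each; end-to-end recovery at the default generator conditions
with a 200-iteration null; graph-metric oracles on 100 random graphs of
up to 12 nodes (exhaustive k-core up to 9).

## Known limitations

* No MNI↔Talairach transform: all coordinates are treated as Talairach
  mm, and a non-Talairach header only warns. No image resampling: atlas
  and analysis grid must already agree.
* Kernel width is fixed and global; subject-count-dependent widths are
  not implemented.
* The edge test is per-pair; network-wide error control is reported only
  as an optional Bonferroni flag.
* Patel's directional τ (asymmetric ascendancy) is not implemented; the
  networks are undirected by construction.
* κ is a co-occurrence measure across experiments; edges are not evidence
  of causal or temporal spread.
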