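# ratmind

Structural similarity networks for the rat cortex from voxel-level MRI
features, with weighted-topology analysis, distance-preserving null
inference, external validation, and longitudinal / case-control modelling.

## What problem this solves

Cortical network analysis in rodents has mostly relied on tract tracing or
post-mortem measurements; ratmind brings the MIND (Morphometric Inverse
Divergence) similarity-network approach to in vivo rat MRI. Each of the
cortical regions in a scan is represented by the distribution of its
voxels' magnetization transfer ratio (MTR = (PD − MT)/PD, a myelin- and
neuropil-sensitive contrast), and the edge weight between regions *i* and
*j* is

    w = 1 / (1 + KL_sym)

where `KL_sym` is the symmetrized Kullback–Leibler divergence between the
two regions' fitted Gaussian MTR distributions, so `w ∈ (0, 1]` and
identical regions get `w = 1`. To keep the estimate independent of region
size, KL is estimated by drawing the same number of points (5,000 by
default) from each fitted distribution and applying a k-nearest-neighbour
divergence estimator (k = 3); the closed-form Gaussian KL is available as
`estimator = "analytic"`.

On top of network construction the package provides:

* **Topology** — nodal strength `s`, hubs (top-10 strength), and the
  weighted rich-club coefficient `Φ = W_club / W_max` (hub–hub weight over
  the equally many strongest edges anywhere), with inference against
  nulls that reshuffle edge weights within three spatial-distance bins.
* **Validation** — edge-weight vs centroid distance, Jaccard similarity of
  ordinal tract-tracing profiles, cortical-type intraclass enrichment,
  transcriptomic-profile alignment, and atlas crosswalk aggregation
  (median over subdivision pairs).
* **Inference** — developmental (PND 20–35) and aging (PND 63–230) slopes
  from mixed models (`normalized measure ~ age + TBV + (1|subject)`, edge
  models add `(1|ROI edge)`), case-control group effects with
  subject-level permutation z-scores, their coupling, and
  Kruskal–Wallis/Dunn comparisons of strength distributions.
* **Synthetic cohorts** — a generator with planted similarity structure,
  epoch slopes, group offsets and subject intercepts, so every stage is
  testable without MRI data (there are none bundled).

It is aimed at researchers analysing rodent structural MRI who want
similarity networks with tested, reproducible statistics, and at
methodologists who need a planted-truth sandbox for similarity-network
inference.

## Worked example

```r
library(ratmind)

regions <- generate_parcellation(n_regions = 20, n_systems = 4, seed = 1)
truth   <- generative_truth(regions)
scan    <- generate_scan(truth, age = 63, seed = 1)   # tibble: Label, MTR

net <- build_mind_network(scan, estimator = "analytic")
net
#> <mind_network> 20 nodes, 190 edges (analytic estimator)
#>   edge weights: min 0.351, median 0.786, max 0.998

strengths <- nodal_strength(net)
hubs <- top_hubs(strengths, k = 5)
rich_club(net, hubs)
#> <rich_club> phi = 0.919 (5 hubs, 20 ordered hub pairs)

dists <- edge_distances(as_parcellation(regions))
distance_weight_correlation(net, dists)
#> # A tibble: 1 × 5
#>   pearson_r  pearson_p spearman_rho spearman_p n_edges
#> 1    -0.321 0.00000641       -0.316 0.00000911     190
```

The rich-club phi of 0.919 says the five strongest nodes' mutual edges
carry 92% of the weight that the network's ten strongest edges carry — a
strongly interconnected core. The negative distance–weight correlation
(−0.32 here) is the expected signature of spatially coupled cortical
similarity: the generator plants a spatial gradient in regional MTR means,
so nearby regions have more similar distributions. Against 1,000
distance-preserving nulls this particular 20-region toy network's core is
not beyond chance (`permutation_z_p` gives p ≈ 0.07), which is the correct
reading: its hubs arise from the distance structure the nulls preserve.

Networks tidy into edge tables (`tidy(net)`), summarize with
`glance(net)`, and plot with `autoplot(net)`. The end-to-end pipeline is
`mind_config()` → `run_simulate()` → `run_networks()` → `run_analysis()`,
which writes per-scan networks, medians, and a CSV/JSON report bundle with
full seed provenance.

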