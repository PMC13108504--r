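---
title: "Estimating and analysing rat cortical MIND networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and analysing rat cortical MIND networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratmind)
```

## The model

ratmind estimates structural similarity networks for the rat cortex from
voxel-level magnetization transfer ratio (MTR) data, using the MIND
(Morphometric Inverse Divergence) construction. Each cortical region is
represented by the distribution of its voxels' MTR values, summarized by a
Gaussian fit (sample mean $\mu_r$, sample SD $\sigma_r$). The similarity
between regions $i$ and $j$ is

$$ w_{ij} \;=\; \frac{1}{1 + \mathrm{KL}_{sym}(i, j)}, \qquad
   \mathrm{KL}_{sym} = \tfrac12\left[\mathrm{KL}(P_i \| P_j) +
   \mathrm{KL}(P_j \| P_i)\right], $$

so $w \in (0, 1]$ with $w = 1$ for identical feature distributions. MTR is
computed per voxel as $(PD - MT)/PD$ from receiver-gain-scaled proton
density and magnetization transfer scans; voxels with $PD \le 0$ are
flagged missing. The network for one scan is the symmetric region-by-region
matrix of $w$, with unit diagonal; a cohort's *normative* network is the
element-wise median across scans.

Because the printed transform $w = 1/(1+\mathrm{KL})$ does not specify a
direction and every downstream analysis requires symmetric weights, the two
directed divergences are averaged *before* the transform. (Averaging the
two transformed weights instead changes third-decimal digits at most; the
choice is recorded here as a package decision.)

### The two estimators and region-size balancing

KL divergence between two regions could be computed directly from the
fitted Gaussians (the closed form
$\log(\sigma_q/\sigma_p) + (\sigma_p^2 + (\mu_p-\mu_q)^2)/2\sigma_q^2 -
1/2$), and `estimator = "analytic"` does exactly that. The default
`estimator = "resampled"` instead draws the *same number* of points
(`n_resamples = 5000`) from each fitted Gaussian and estimates KL
nonparametrically with a k-nearest-neighbour density estimator ($k = 3$),
which removes the sensitivity of sample-based divergence estimation to
unequal region sizes: a region with 100 voxels and one with 10,000
contribute identically after resampling. Negative k-NN estimates are
truncated to zero so $w \le 1$ always holds. Per-edge random seeds are
derived from the scan seed and the sorted region pair, so results do not
depend on the order in which edges are evaluated.

The analytic form is kept both as a fast path and as the independent oracle
the test suite checks the resampling estimator against. Two numerical
properties of the k-NN estimator are worth knowing:

* With equal region SDs its bias is small (within ~0.1 nats even at a
  2-SD mean separation, and far smaller in the regime a real cortex
  occupies).
* When the two distributions differ in *scale* by a factor around 2, the
  wide-distribution direction $\mathrm{KL}(q\|p)$ is systematically
  underestimated: sample tails of the wide distribution fall in regions
  containing no neighbours from the narrow one, and no feasible resample
  count repairs this (the bias shrinks only logarithmically; we measured
  $-0.45$ nats at $\Delta\mu/\sigma = 2$, $\sigma$-ratio 2, $n = 5000$ and
  $-0.29$ at $n = 50{,}000$, identically across two independent
  implementations). This is an inherent property of nonparametric k-NN
  divergence estimation, not of this implementation. In weight units the
  effect is modest (|Δw| ≈ 0.06 at the worst edge of a typical synthetic
  scan, mean ≈ 0.014), and it cancels almost entirely in rank-based and
  comparative analyses because the bias is monotone in the true
  divergence.

Defaults: `min_voxels = 20` (regions below it are dropped and listed in
the network metadata), `sigma_floor` = $10^{-6}$ of the scan's global MTR
SD (prevents infinite divergences from degenerate regions). Both are
package choices; the method's description is silent on them.

## Topology and distance-preserving nulls

Nodal strength is the sum of a region's incident edge weights; *hubs* are
the `k = 10` strongest nodes (ties broken by label so the set is
deterministic). The weighted rich-club coefficient is

$$ \Phi = \frac{W_{club}}{W_{max}}, $$

the total weight over the $k(k-1)/2$ unordered hub–hub pairs divided by the
sum of the equally many strongest edge weights anywhere in the network.
Both the unordered count and the doubled, ordered count (90 for ten hubs)
are reported; the ratio is identical under either convention.

Inference uses distance-preserving nulls: unique edges are ranked by
Euclidean centroid distance, split into three evenly sized bins (proximal,
intermediate, distal; remainder edges go to the proximal bins; ties break
on the label pair), and weights are reshuffled only within bins. Every null
conserves each bin's weight multiset exactly, hence the distance–weight
relationship up to bin coarseness. Permutation summaries follow
$z = (\mathrm{obs} - \bar{x}_{null})/s_{null}$ and the add-one convention
$p = (1 + \#\{null \ge obs\})/(1 + n_{null})$, whose floor with 10,000
nulls is $1.0\times10^{-4}$; a p-value of exactly zero is never reported.

Two methodological caveats discovered while calibrating the procedure:

* Hub sets must be re-derived within each null network. Importing the
  observed hubs into the nulls leaves the data-dependent hub-selection step
  unmatched and inflates the type-I rate several-fold even under an exactly
  exchangeable null.
* The three-bin null conditions on distance only at bin granularity. If
  weights decay *continuously* with distance, the most proximal pairs
  within the proximal bin (which is where mutual hub neighbours
  concentrate) are genuinely stronger than their bin-mates, and the test
  rejects far above nominal rate even with symmetric hub selection. The
  calibration suite therefore simulates its null with weights constant
  within each distance bin plus independent noise — the exchangeability
  class the test actually conditions on. Users should read small rich-club
  p-values against strongly distance-decaying networks with this
  limitation in mind (or increase `n_bins`).

## External validation

Four reference comparisons are implemented, all over unique edges of
shared regions:

* **Distance**: Pearson correlation of weight with centroid distance
  (Spearman reported alongside as a sensitivity output).
* **Tract tracing**: ordinal connection matrices are converted to
  profile similarities with a Jaccard index — for pair $(i,j)$, over all
  third regions $k$: matches are positions with identical *and* nonzero
  ordinal weight, the union counts positions where either region connects,
  and $J = 0$ on an empty union. Whether both-zero positions should count
  as matches is genuinely ambiguous; both-nonzero is the default and
  `count_zero_matches = TRUE` gives the alternative. Strictly monotone
  level transforms (e.g. $\log_{10}$) cannot change equality or nonzero
  patterns, so they are no-ops under this reading. Alignment with MIND
  weights is a Spearman correlation tested against the distance-preserving
  null ensemble.
* **Cortical types**: regions carry one type label (archicortical
  allocortex; agranular or dysgranular mesocortex; paleocortical and
  eulaminate regions are excluded as too few). The intraclass-edge curve
  thresholds the network at densities 1%–10% (the printed "0%–10%" has no
  edges at 0%) and reports the percentage of top edges joining same-class
  regions; class-pair weight differences (allo-allo vs allo-meso vs
  meso-meso) use rank-based Wilcoxon tests — the method's description
  does not name its test, and the weight distributions are skewed — with
  Benjamini–Hochberg adjustment.
* **Expression**: regional gene-expression profiles are converted to a
  pairwise correlation matrix and aligned with MIND weights as for tract
  tracing.

Atlas crosswalks map regions into a reference space; when several
subdivisions form one reference region, the reference-space edge weight is
the median over all subdivision pairs, and subdivision pairs inside one
reference region never contribute to off-diagonal entries.

## Longitudinal and case-control models

Two epochs are modelled: development (PND 20–35, inclusive) and aging
(PND 63–230); the PND 35–63 gap belongs to neither. Responses ("normalized
strength/weight") are z-scored across the observations entering each fit —
the source description never defines its normalization, and z-scoring makes
t statistics comparable across units. Models, fit by REML via lme4:

* node level: `normalized strength ~ age + TBV + (1 | subject)`;
* system-pair edge level: ROI edges between the two systems are pooled and
  `(1 | ROI edge)` added;
* case-control (adult timepoint): `normalized value ~ group + sex + age +
  TBV`, plus `(1 | ROI edge)` at edge level.

The age/group coefficient's $t = \hat\beta/\mathrm{SE}$ is the standardized
effect (degrees of freedom for mixed models are deliberately not chased);
conventional flags are $|t| > 2$ for nodes and $|t| > 3.3$ for edges, both
parameters. Singular or non-converged mixed fits fall back to OLS with a
logged flag — with a single global subject intercept in the generator this
is common and harmless, because a shift applied to *all* regional means
cancels exactly in KL-based similarity (similarity networks are invariant
to global intensity shifts; the same applies to the TBV term). Group
inference permutes labels at the *subject* level (1,000 permutations by
default), refits, and flags $|z| > 1.96$; permuted label vectors that are
collinear with the covariates (e.g. an exact sex match, probability
$\approx 2/\binom{12}{6}$ per draw in a balanced 12-animal design) have no
identifiable group effect and are excluded from the null. The
stress–development coupling correlates edge-level case-control effects
with developmental t statistics and permutes the edge assignment (10,000
permutations by default). Strength distributions across timepoints are
compared with a Kruskal–Wallis omnibus on per-region medians and Dunn's
tie-corrected pairwise z tests (implemented in-package; no installed
package provides them) with BH adjustment.

## The synthetic cohort generator

No MRI data accompany the method, so every stage is exercised against a
generator with planted ground truth. It emulates: Gaussian per-region MTR
distributions (matching the estimator's fitting assumption); spatial
clustering of systems and a smooth spatial gradient of regional means, so
proximity and similarity are coupled as in real cortex; per-system
developmental (PND 20–35) and aging (PND 63–290) slopes with a plateau
between; a per-system offset for stressed animals applied from PND 63 (the
case-control age); subject random intercepts; and a TBV coefficient.
Reference assets (ordinal tract matrix, type table, expression profiles,
crosswalk) are derived from the same planted similarity so alignment tests
have a known positive truth at zero noise.

Default magnitudes are package choices stated once and not revisited:
grand mean MTR 0.5, spatial gradient 0.015 per unit, system offsets SD
0.03, regional noise SD 0.01, voxel SDs uniform on 0.04–0.08, voxel counts
log-uniform on 100–2,000 (minimum 10), subject intercept SD 0.01. MTR
values are *not* clipped to $[0,1)$: clipping would distort the Gaussian
model the estimator assumes. A single cohort seed derives per-scan seeds by
hashing subject and timepoint, so any scan regenerates independently.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: registration and segmentation error, within-region
spatial autocorrelation and non-Gaussian voxel distributions, motion and
coil-gain artefacts, litter structure, and hemispheric asymmetries.

Recovery tests need a known *direction* of effect on strength, which a
planted slope alone does not give (a region moving toward the rest of the
cortex gains similarity; one moving away loses it). The recovery fixtures
therefore pin the targeted system's means as a tight cluster displaced from
the pack — below it and converging for the development epoch, level and
diverging for aging, shifted away under stress — sized so the induced
weight changes (~0.1–0.3) clear the per-scan estimation noise
($\sigma/\sqrt{n_{vox}} \approx 0.003$ at 500 voxels) by an order of
magnitude. These magnitudes were fixed by this power reasoning before the
tests were run.

## Problem sizes

The test suite and the acceptance script use: 53 regions / 15 systems for
structural checks; 20 regions, 4 systems, 12 subjects, 4 timepoints and
500 voxels per region for cohort-level recovery (50 cohorts per rate);
10,000 nulls for the permutation floor, 199 per network for calibration
(400 networks); 200 group permutations and 500 coupling permutations in
rate estimates. Full-scale defaults (10,000 nulls, 1,000 and 10,000
permutations) remain the package defaults in `mind_config()`.

## Worked example

```{r example, fig.width = 5, fig.height = 4}
regions <- generate_parcellation(n_regions = 20, n_systems = 4, seed = 1)
truth <- generative_truth(regions)
scan <- generate_scan(truth, age = 63, seed = 1)
net <- build_mind_network(scan, estimator = "analytic")
net

strengths <- nodal_strength(net)
hubs <- top_hubs(strengths, k = 5)
rich_club(net, hubs)

dists <- edge_distances(as_parcellation(regions))
distance_weight_correlation(net, dists)
autoplot(net, parcellation = as_parcellation(regions))
```

## Known limitations

* Single-feature (MTR) networks only; multivariate MIND is out of scope.
* The k-NN KL estimator underestimates large divergences between
  distributions of very different spread (see above); absolute weights for
  such pairs are biased upward, ranks essentially unaffected.
* Three-bin nulls preserve distance structure only at bin granularity.
* Left/right homologues are whatever the parcellation lists; no stance is
  taken on hemispheric merging, and hemisphere is metadata only.
* Litter effects are not modelled, matching the source models.
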