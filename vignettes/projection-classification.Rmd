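---
title: "Classifying neurons by brain-wide axonal projection patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying neurons by brain-wide axonal projection patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonclass)
```

## The problem

Whole-brain single-neuron reconstructions make it possible to ask whether
the neurons projecting out of a source region fall into discrete
*projection types* — statistically distinct patterns of anatomical
targeting — or whether their axons merely vary randomly within the
constraints of the region's overall connectivity. `axonclass` implements
a complete pipeline for this question: each neuron is reduced to a
k-dimensional vector of axonal point counts over the k target parcels of
a reference atlas, a single-class null hypothesis is built by
randomizing the count matrix, and hierarchical splits are accepted only
where a variance test rejects that null. Accepted classes are then
characterized by their abundance in the source population, the
topography of their somata, and the cable distances their axons travel.

## The classification model

**Distance.** The dissimilarity between neurons $i$ and $j$ is the angle
between their count vectors,
$\theta_{ij} = \arccos\left(\frac{x_i \cdot x_j}{\lVert x_i\rVert\,\lVert x_j\rVert}\right)$,
reported in degrees. Angles are scale-invariant: a neuron with twice the
axonal cable but the same regional allocation is at distance zero from
its half-sized twin, so classes are defined by *where* axons go, not how
much axon there is.

**Null model.** Under the single-class hypothesis, the projection
pattern continuum is represented by matrices with the same per-neuron
axonal sizes (row sums) and the same regional targeting (column sums)
as the data, but no further structure. `swap_randomize()` samples this
null by a long chain of unit moves: two neurons and two regions are
drawn uniformly and one count is moved between them in a way that
preserves both margins; moves that would drive a cell negative are
rejected and do not count. The chain's proposal kernel is symmetric, so
its stationary distribution is uniform over the connected set of
margin-preserving count matrices. The default chain length is 10 times
the total count of the matrix, which at the problem sizes used here
(tens of neurons, thousands of points) mixes the matrix thoroughly; it
is exposed as `n_swaps` because no single value suits every matrix
scale.

**The gate.** The observed pairwise angle distribution is compared with
the angle distribution of a randomized matrix using the one-tailed
Levene test in its *absolute* variant: a one-way F statistic on absolute
deviations from each group's mean, with the one-tailed p-value equal to
half the two-tailed p-value when the observed variance exceeds the null
variance. When it does not, the p-value is reported as not applicable
and the group is accepted as a class — the alternative hypothesis
(distinct classes produce an over-dispersed mixture of within- and
between-class distances) is one-sided by construction.

**Recursion.** Starting from all neurons, each candidate group with at
least `min_testable` members (default 4; below that there are too few
pairwise angles to test a variance) is gated. If the gate rejects, the
group's average-linkage (UPGMA) dendrogram — built from the same angle
distances — is cut at its root into two subtrees, and each is gated in
turn, with the null rebuilt from the subgroup's *own* submatrix
restricted to the regions it actually targets. Groups that fail to
reject, or that are too small to test, are the output classes, labelled
by a letter in decreasing order of size followed by the class size
(`A38`, `B27`, ...). The dendrogram is recomputed per node rather than
reusing subtrees of the global tree; on nested data the two coincide,
and recomputation keeps every decision a function of the data actually
under test.

## Calibration: what the gate does and does not control

Two properties of the gate deserve emphasis; both are measured by the
test suite and the acceptance script rather than assumed.

*On homogeneous multinomial data the gate is strongly conservative.* If
every neuron draws its counts from one shared profile, the observed
angle variance is far *below* that of the swap null: the uniform
distribution over margin-preserving tables is much more dispersed than
multinomial sampling around a common profile. The false-split rate is
then essentially zero — the method will not invent classes in data
whose only variation is counting noise.

*Under its exact null the gate is mildly anti-conservative.* When the
data themselves are drawn from the continuum (`generate_null_matrix()`:
a multinomial seed matrix mixed by a long burn-in of margin-preserving
swaps), the measured root-level false-split rate at $\alpha = 0.05$ is
about 0.11 at 50 neurons and 12 regions. The cause is pseudo-replication:
the $n(n-1)/2$ pairwise angles entering the Levene statistic are treated
as independent observations although only $n$ neurons exist, so the
test's degrees of freedom overstate the information available and small
variance excesses are declared significant. Users who need strict
type-I control at the nominal level should interpret borderline
root-level rejections (one-tailed p close to $\alpha$) with caution;
planted-structure recovery, by contrast, is unaffected — between-class
variance exceeds the null by orders of magnitude at realistic effect
sizes, and the recursion recovers 2, 3 and 5 planted classes with
adjusted Rand index 1.0 in essentially every replicate at the default
effect size.

## Synthetic data: what it emulates

`generate_matrix()` plants class structure with block profiles
(`synthetic_profiles()`): each class concentrates `within_mass`
(default 0.8) of its probability mass on its own block of regions with a
1/rank decay, the remainder on a shared background, emulating the
empirical picture of a few dominant targets per class plus weak side
branches. Per-neuron totals are log-normal (default median 1000 points,
`sdlog` 0.5), the order of magnitude of axonal point counts in
whole-brain reconstructions. Within a class, counts are multinomial by
default (`concentration = Inf`): under this framework's own null,
within-class variation beyond counting noise *is* residual class
structure, so the default single-class data carry none; finite
`concentration` adds Dirichlet over-dispersion for users who want to
emulate biological within-class variability.

`generate_morphologies()` grows one straight branch per targeted region
along a fixed spherical-lattice direction, placing the planted number of
axonal points so that the per-neuron median path distance equals the
configured class/region offset exactly at zero noise. Somata are drawn
from class-specific isotropic Gaussian clouds; layers are assigned by
thresholding one soma coordinate. These toys deliberately omit realistic
axonal geometry — tortuosity, branching angles, shared trunks — so
passing tests demonstrate the correctness of the measurement and test
machinery, not robustness to reconstruction artifacts such as
registration error or truncated arbors, which no synthetic fixture here
models.

## Abundance deconvolution

Single-neuron sampling is not proportional sampling of the source
population, so class abundances are estimated by matching class
projection patterns against regional anterograde tracing strengths. With
$A$ the regions-by-classes weight matrix and $b$ the per-region tracing
weights (mean projection volume times mean projection density,
normalized to sum one), `nnls_solve()` finds $x \ge 0$ minimizing
$\lVert Ax - b\rVert$ by the Lawson–Hanson active-set algorithm, and the
squared residual norm is reported as the proxy for the fit's
uncertainty. $A$ is *bi-normalized* first (`binormalize()`): rows
normalized to one (removing the axonal-length scale of each region),
rescaled by $k/m$ so the grand total equals the number of classes, then
columns normalized to one (removing class-size scale). The regions
entering the problem are the intersection of the count matrix's parcels
and the regional table's regions; hemisphere-split columns are pooled
first because tracing strengths are not hemisphere-resolved. Reported
fractions are $x$ renormalized to sum one. The per-region tracing
weight multiplies the two per-region *averages* (volume and density)
rather than averaging per-experiment products; with per-experiment data
unavailable in the regional summary table, this is the only computable
form, and both conventions coincide when experiments are homogeneous.

## Soma topography

Class territories are compared as convex hulls of soma positions.
Outliers are removed in a single pass: with full-set hull volume $V$
over $n$ points, a point is an outlier iff deleting it changes the
volume by more than $V/n$; all flagged points are removed together, and
if fewer than four points would remain the original set is kept (a 3D
hull needs four points). A sequential variant (re-computing the hull
after each removal) is available via `sequential = TRUE`. The overlap
between two class hulls is computed exactly: the intersection of two
convex polytopes is itself convex, its vertices lie on triples of facet
planes, so the implementation enumerates those triples, keeps the
points satisfying every halfspace, and integrates the volume facet by
facet. The reported statistic is intersection over union, in $[0,1]$;
empty or lower-dimensional intersections are reported as ratio 0 with a
flag rather than as an error, since fully segregated classes are a
meaningful outcome. The exact volumes are cross-checked against
Monte-Carlo estimates in the test suite.

## Path-distance statistics

Path distance is cable length: the sum of Euclidean segment lengths
along the unique tree path from the soma to an axonal point; it is
always at least the straight-line distance. The unit of observation for
all tests is the *per-neuron median* path distance to a target region —
neurons, not axonal points, are the independent replicates; pooling
points would pseudo-replicate, since one neuron contributes many highly
correlated points. Divergence analyses compare targets within one class
(ipsilateral and contralateral territories are distinct targets and are
never compared with each other, as contralateral paths are
systematically longer); convergence analyses compare classes at one
target. Both use the two-sample rank-sum (Mann–Whitney) test — exact
when the combined sample is at most 20 and tie-free, normal
approximation with tie correction otherwise — with Benjamini–Hochberg
FDR at 0.05 across the family of pairwise comparisons within one
analysis. The unpaired rank-sum test is used deliberately: divergence
and convergence samples are not generally paired (different neurons
reach different target subsets), so a signed-rank formulation would
discard or mis-pair observations.

## Numerical choices

* Angles are computed in degrees and clamped to $[0, 180]$ against
  floating-point overshoot of the cosine.
* The Levene gate returns `stop` with a diagnostic when all absolute
  deviations are identical (the statistic is undefined).
* UPGMA ties are resolved by the deterministic merge order of
  `stats::hclust`; classification is fully reproducible given a seed,
  which drives all swap chains through one RNG stream.
* Hull computations use a relative tolerance of $10^{-9}$ of the
  coordinate scale; points coplanar with a facet are treated as visible
  during incremental construction so that inputs in non-general
  position (lattices, boxes, polytope vertex sets) are handled without
  coordinate perturbation.
* A count matrix whose support admits no legal swap (all mass in one
  column) cannot be randomized; the chain stops at a proposal cap with
  a warning rather than spinning forever.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
desk scale: calibration uses 200 replicates of 50 neurons by 12 regions,
recovery uses 50 replicates each of 2/3/5 planted classes with 15
neurons per class, geometry uses $10^6$ Monte-Carlo points, and the
NNLS oracle enumeration covers 100 problems with up to 4 classes. These
sizes were chosen to estimate each rate to within a few percent while
keeping a full run in the order of a minute.

## Known limitations

* The variance gate's mild anti-conservatism under its exact null
  (above) is inherent to testing dependent pairwise distances; a
  permutation-calibrated version would remove it at substantial cost
  and is out of scope.
* Axonal "points" are reconstruction nodes; node density can vary
  between tracing pipelines, which the count representation inherits.
  No volumetric normalization by region size is applied.
* The hull overlap is exact for the polytopes defined by the retained
  somata but says nothing about density overlap within the hulls.
* The abundance model assumes regional tracing strength is a
  class-weighted mixture of the single-neuron patterns; systematic
  tracer biases violate that assumption and are not modelled.
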