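---
title: "Measuring inter- and intra-forest variability in insect herbivory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter- and intra-forest variability in insect herbivory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The measurement model

`herbnet` analyses insect herbivory recorded the way paleobotanists score
fossil leaf assemblages: each censused leaf carries zero or more *damage
types* (DTs) -- morphologically distinct feeding patterns -- each with an
*occurrence* (presence/absence on the leaf) and an *abundance* (number of
incidents). DTs belong to one of seven *functional feeding groups* (FFGs):
hole, margin, skeletonization, surface, piercing-and-sucking, gall, and
mine; a catalog additionally classes each DT as generalized or specialized.
Sampling is hierarchical: forests contain depositional environments (swamp,
tributary, dynamic river, upland), each environment is sampled by replicate
quarries of roughly 400 leaves.

Undamaged leaves are data. Every frequency in the package is a
per-leaf-censused proportion, so censuses must record undamaged leaves as
rows with an empty DT field. Incident counts on duplicate (leaf, DT) rows
sum.

## Herbivory metrics

* **Damage frequency** for a selector (total, a spec class, or an FFG) is
  the fraction of leaves bearing at least one matching DT; a leaf counts
  once however many incidents it carries.
* **Rarefied DT diversity** standardizes richness to `n_std = 300` leaves
  (quarries with fewer leaves are removed by `filter_quarries()`, which
  reports the exclusions). We use the analytic sample-based form
  `E[S] = sum_d [1 - C(N - m_d, n)/C(N, n)]`, the exact mean over all
  size-`n` leaf subsets. A resampling standardization has the same
  expectation but is stochastic; a Monte Carlo mode is retained purely as a
  cross-check (`method = "montecarlo"`). Binomial coefficients are computed
  in log space so censuses of thousands of leaves are safe.
* **Plant diversity** is Shannon's H (natural log) of leaf shares per
  taxon, with Pielou's J = H/log(S); J is reported as `NA` for a single
  taxon rather than an arbitrary value.
* **Logit transforms** of FFG frequencies use the natural log. Boundary
  frequencies (0 or 1) are replaced by the empirical-logit adjustment
  `p' = (p (n - 1) + 0.5)/n`, flagged on the result; this keeps quarries
  with no (or ubiquitous) damage of some FFG usable in downstream linear
  models without an ad hoc constant.

Natural logarithms are used throughout (Shannon entropies, logits, H2').

## Probabilistic co-occurrence

Whether two DTs share leaves more or less often than chance is assessed at
the leaf level with the exact hypergeometric model: conditioning on the
occurrence counts `N1`, `N2` among `N` leaves, the number of jointly
occupied leaves is hypergeometric, and the pair is classified positive
(`P(J >= j_obs) < alpha`), negative (`P(J <= j_obs) < alpha`), or random.
Both tails include the observed value, so `p_lt + p_gt >= 1`. The sampling
unit is always the leaf within one forest; no quarry-level variant is
offered, because mixing units changes the meaning of "co-occurrence". Pairs
with expected co-occurrence `N1 N2 / N < 1` are excluded by default (the
usual convention for this model -- such pairs cannot be informative), and
singleton DTs can be dropped. The reported effect size,
`(j_obs - expected)/N`, is our documented choice for the strength scale of
co-occurrence heat maps. A DT present on every leaf admits no variation and
is forced to "random" with a diagnostic note.

## Bipartite plant-DT networks

Each quarry yields a weighted bipartite network: plants x DTs with summed
incident counts as weights. To standardize sampling effort, quarries are
bootstrapped to 300 leaves drawn *without replacement*, 500 times by
default; degenerate replicates (fewer than two plants or two DTs after
resampling) are skipped and counted, never zero-filled. Metrics:

* **Connectance**: realized fraction of possible links.
* **Nestedness** is binary NODF (0-100). The interpretive orientation we
  need -- higher values meaning more overlapping, generalized interaction
  structure -- matches NODF; matrix-temperature nestedness runs in the
  opposite direction, which is why the choice is pinned down explicitly. A
  weighted variant is available behind a flag.
* **Partner diversity (plants)**: mean Shannon entropy of each plant's
  interaction weights.
* **Robustness (DTs)**: area under the curve of surviving DT fraction as
  plants are removed in random order (a DT survives while any host
  remains). All `P!` removal orders are enumerated exactly for `P <= 6`
  plants; otherwise 100 random orders are averaged. The complete network on
  `P` plants has robustness `1 - 1/(2P)` exactly, a useful calibration
  point.
* **H2'**: the standardized two-dimensional interaction entropy,
  `(H2max - H2)/(H2max - H2min)`, where `H2max` is the maximum entropy
  attainable under the observed marginals (an integer rounding of the
  independence expectation `r_i c_j / m`, with unit deficits redistributed
  to the cells with the largest fractional parts) and `H2min` the minimum
  (a greedy fill that repeatedly routes `min(remaining row, remaining
  column)` weight to the currently heaviest row-column pairing). Both
  fills are heuristics -- the standard approach for this index -- so the
  result is clipped to [0, 1] and the two bounds are validated against
  exhaustive enumeration of all marginal-preserving integer matrices on
  small cases in the test suite. H2' is 0 when interactions are as mixed as
  the marginals allow and 1 when completely specialized; when
  `H2max = H2min` the index is undefined and returned as `NA` with a
  reason.

DT **degree** (number of host plants per quarry) is the node-level
generalization measure; absent DTs score zero.

## Ordination and group tests

Quarry-level composition tables come in two modes: FFG (fraction of leaves
bearing each FFG; rows need not sum to one since a leaf can carry several
FFGs) and plant (leaf shares; rows sum to one). Dissimilarity is
Bray-Curtis -- the standard choice for composition data in this ecosystem
of methods; the ordination method itself is rank-based, so any monotone
distance gives the same stress. NMDS minimizes Kruskal stress-1 with
monotone regression (via `vegan::metaMDS`, 20 random restarts by default).
ANOSIM is implemented in the package because the permutation null is
enumerated *exactly* whenever the number of distinct label arrangements is
at most 10,000 (random permutations with the +1 correction otherwise);
ranks use average ties. Forests with disjoint plant pools are never
co-ordinated: the pipeline partitions forests into components connected by
shared species and ordinates each component separately.

Rosner's generalized ESD test screens quarry-level metric values for
outliers (exposed as an explicit, logged option -- which metrics to screen
is an analysis decision, not a package default), and Tukey-Kramer
comparisons on quarry values test cross-forest differences in means,
including for bootstrap network metrics, where the comparison is run on
per-quarry bootstrap means.

## The synthetic census generator

Because the package must be exercisable without field data, it ships a
generative model of the study design: 3 forests, 28 quarries, 400 leaves
per quarry (11,200 leaves). Composition is hierarchical Dirichlet: each
environment draws its plant composition from
`Dirichlet(env_shift x forest weights)` and each quarry redraws tightly
around its environment (`quarry_concentration = 150`), which produces the
within-environment clustering that ANOSIM later detects. The
cool-temperate forest `TF1` gets the smallest plant pool, the tropical
pool shares no species with the two (overlapping) temperate pools, and
`TF1`'s environments are given weak environmental filtering
(`env_shift = 40`) -- a species-poor temperate community looks similar
across its depositional settings, and this also stabilizes the realized
abundance of the outbreak's preferred host across quarries. Each DT owns a
fixed pseudo-random host subset per forest (`ceiling(host_breadth x
pool)`); host sets are drawn once, not per leaf, because specialists must
be *consistently* specialized for degree and H2' structure to emerge.
Occurrence is Bernoulli per permitted leaf; incident counts are
zero-truncated Poisson, keeping the occurrence/abundance distinction of
the recording protocol without occurrence-with-zero-count contradictions.
Piercing-and-sucking occurrence is discounted by 0.5 for preservation
bias.

One deliberate simulation-design choice: occurrence uniforms and incident
counts are drawn for *every permitted leaf*, whether or not the DT occurs,
so RNG consumption is independent of the probabilities. Two configurations
differing only in their outbreak block therefore share all randomness
except the outbreak's incremental occurrences (common random numbers),
which makes paired outbreak/control comparisons sharp.

### The outbreak scenario

The outbreak emulates a defoliating caterpillar irruption: a surface DT
(`DT33`; young instars skeletonize leaf surfaces) plus two hole DTs
(mature instars chew holes) have their occurrence multiplied 25-fold on a
single preferred host (`temp_sp04`, a mid-dominance taxon) -- effectively
saturating it -- and by 1.05 on other hosts, with probabilities clipped at
1. The outbreak surface DT is rare at background levels (p = 0.04) but
leaves many feeding patches per occupied leaf (zero-truncated Poisson mean
8), concentrating interaction *weight* rather than newly damaged leaves.
Because the baseline census already damages about three quarters of all
leaves, the outbreak's signature appears in the H2' preference index
(outbreak minus control roughly +0.035 at these defaults) while total
damage frequency moves by only ~3 percentage points -- an outbreak visible
to network metrics but invisible to the classical frequency metric, which
is precisely the phenomenon the experiment is designed to probe. The true
intensity of real outbreaks is unknown; the multipliers are free
configuration parameters, not estimates.

What the generator does *not* emulate: mechanistic insect population
dynamics, leaf transport and taphonomy (beyond the piercing-and-sucking
discount), within-taxon leaf-quality variation, and temporal structure.
Passing tests on synthetic data therefore demonstrate that the estimators
recover known structure under the model's assumptions, not that real
censuses satisfy those assumptions.

## Numerical and degenerate-input policy

* Rarefaction requires `N >= n_std` and directs the caller to
  `filter_quarries()` otherwise.
* Single-taxon views flag Pielou's J as `NA`; 1 x k incidence matrices
  flag NODF and H2' as `NA` with reasons, rather than returning
  misleading zeros.
* Ties everywhere use deterministic first-index tie-breaks (greedy fills)
  or average ranks (ANOSIM).
* All stochastic stages take explicit seeds; the pipeline expands one
  top-level seed through a counter scheme so disabling a stage never
  shifts another stage's stream, and every output records the seeds used.

## Problem sizes

The shipped defaults follow the study design (bootstrap 300 leaves x 500
replicates per quarry). The package's own test suite and experiments use
smaller, stated sizes chosen for desk-scale runs: the outbreak experiment
runs 20 paired seeds at the full 28-quarry design with 100 bootstrap
replicates per quarry, and calibration checks use a few hundred
simulations each. These sizes are design choices recorded here so results
are reproducible exactly as configured.
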