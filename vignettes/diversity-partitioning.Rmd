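---
title: "Formation-scale diversity partitioning: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formation-scale diversity partitioning: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formdiv)
library(dplyr)
```

## The model

A geological formation is treated as a fossil metacommunity: a regional
pool of species sampled by many fossil collections, each collection a local
community sample. Diversity is partitioned multiplicatively:

* **alpha** = mean species richness per collection,
* **gamma** = pooled species richness of the formation,
* **Whittaker's beta** = gamma / alpha,
* **Simpson's metric** = the multiple-site Simpson dissimilarity

$$\beta_{SIM} \;=\; \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
  {\Big(\sum_i S_i - S_T\Big) + \sum_{i<j}\min(b_{ij},b_{ji})},$$

where $S_i$ is the richness of collection $i$, $S_T$ the pooled richness
and $b_{ij}$ the number of species in collection $i$ absent from $j$.
Fossil collections are frequently *nested* — poorer samples of the same
fauna — and richness-difference dissimilarity would read that sampling
artifact as beta diversity. The Simpson family counts only turnover: a
perfectly nested chain of collections scores 0 even though Whittaker's
beta exceeds 1. The term "Simpson's metric" is conventional in this
literature and has nothing to do with Simpson's diversity index.

Two analytic limits pin the implementation: identical collections give
exactly 0 and pairwise-disjoint collections give exactly 1. Both are
asserted in the tests, together with an exhaustive two-site reduction
(every non-degenerate pair of subsets of 6 species) and equivalence with a
brute-force set-difference oracle on random matrices.

## Vetting rules and their order

Occurrence records pass five ordered filters: (0) records with missing or
unparseable midage; (1) unclear genus identification (qualifier on the
genus token: `aff.`, `cf.`, `ex gr.`, `?`, quotation marks — configurable
predicate, since database qualifier conventions vary); (2) records without
a formation assignment; (3) a user-supplied exclusion list, the auditable
stand-in for manual revision of questionable ages; (4) collections left
with fewer than two distinct species; (5) formations left with fewer than
26 collections ("more than 25"). Every step logs records removed, and the
ledger must sum back to the input count.

The formation-size threshold is applied *after* single-taxon collections
are removed. The alternative order would admit formations whose effective
collection count is below the subsampling size; applying it last guarantees
every admitted formation supports a 20-of-N draw.

Species identity is the whitespace-normalized, case-folded binomial string;
no synonymization is attempted. The shipped geological timescale has 11
Phanerozoic periods (Cambrian base 541 Ma; the Neogene extended to 0 Ma,
since no separate Quaternary bin is used). Period intervals are half-open,
`[older, younger)`, so an age exactly on a boundary belongs to the younger
period — a pure tie-break convention, chosen for determinism. The
environment term → category mapping (7 categories) ships as an editable
table; it is best-effort over PBDB vocabulary and user-overridable, because
no canonical mapping exists.

## Subsampling

Sampling intensity varies enormously between formations, and all four
metrics respond to it. Each formation is therefore reduced to the mean of
500 random 20-collection subsamples (without replacement). Species columns
unobserved in a draw are dropped before computing gamma and beta: the
metrics must describe the subsampled matrix, not the parent. The trial mean
of alpha is an unbiased estimator of the formation's mean collection
richness (a uniform row subset preserves the mean of row sums), which the
tests verify at 10,000 trials; gamma and beta are rarefaction-style
quantities whose values are only comparable *at the common subsampling
level*, which is the point.

Each formation draws from its own RNG stream derived from the master seed
and the formation *name*, so results are independent of processing order,
stable under adding or removing other formations, and embarrassingly
parallel without changing values.

## Trajectory fits

Alpha–gamma trajectories are fit linearly; beta–gamma trajectories
logarithmically ($y = a + b\,\ln x$), reflecting that beta is bounded and
levels off while alpha is practically unbounded. `compare_fits()` exposes
the AIC comparison between the two shapes so the model choice is
reproducible on any dataset rather than asserted. Loess overviews use span
0.75 and degree 2 — common defaults, configurable, since no canonical
smoothing level exists for these data — with pointwise bands of ±1.96 local
standard errors; parametric fits carry exact lm confidence bands. All fits
are order-invariant and agree with closed-form normal equations to 1e-10 on
fixtures.

A period's trajectory is labelled from its logarithmic beta–gamma slope:
**low-beta-first** when the slope is positive and exceeds the randomization
null by more than 1.96 null SDs (beta rises with gamma before levelling
off), **high-beta-first** when the slope's own 95% CI covers zero (beta
started high and stays flat), **indeterminate** otherwise. Both thresholds
are configuration, not constants.

## The randomization null

Is a period's beta–gamma coupling stronger than expected for *any* random
set of formations of that size? The null draws 20 formations (without
replacement per trial, independently across trials) from the pooled
estimate table, fits the logarithmic slope, and repeats 200 times; a
period's observed slope is scored as
$z = (b_{period} - \bar b_{null}) / \mathrm{sd}(b_{null})$.

Because beta can only respond to gamma while gamma is low, the comparison
is restricted to formations with at most 100 subsampled species. The
restriction is applied to **both** the null pool and the period fits: an
unrestricted null mixed with restricted period fits would compare slopes
estimated over different gamma ranges. The alternative (unrestricted null
pool) remains available as `restrict_null = FALSE`.

Calibration is a test: with period labels assigned at random over a
homogeneous synthetic pool (5 pseudo-periods × 20 formations, 300 label
draws), the empirical rate of |z| > 1.96 must lie within the binomial band
0.025–0.075 around the nominal 5%.

## Confounder screening and sensitivity

Spearman rank correlations (average ranks for ties; two-sided p from the
large-sample t approximation, adequate at n in the tens to hundreds) screen
every metadata factor — references, collections, environments, duration,
higher-taxon count — against every diversity estimate. No multiple-testing
correction is applied: the grid is descriptive, and its consumers care
about effect sizes (rho), not significance stars.

The **monographic effect** — taxon-specific publications splitting one
fauna into several database "collections", inflating beta and deflating
alpha — is probed by discarding formations with more than 10 contributing
references and re-running everything downstream. Because of name-keyed RNG
streams, filtering commutes exactly with estimation, which the tests
assert.

Geographic spread per formation: `maxGCD` and `medianGCD` are the maximum
and median over all pairwise great-circle distances (haversine, radius
6371 km, via geosphere). The spread MAD is defined here as the median
great-circle distance from each collection to the coordinate-wise median
point — a distance-based median absolute deviation chosen to be
unit-coherent (km) with the GCD metrics; a degrees-space MAD would not be.
The higher-taxon count resolves genera against a configurable
genus→class table over the five target classes (Trilobita, Brachiopoda,
Echinodermata, Gastropoda, Bivalvia).

## The synthetic generator

The generator emulates exactly the structure the analysis assumes, nothing
more: a species pool with uniformly assigned home habitats; collections
assigned one habitat each; patchy incidence (a matching species enters a
collection with probability `occupancy`, default 0.15); habitat fidelity
suppressing out-of-habitat occurrences; and time averaging mixing
noncontemporaneous communities into each assemblage.

**Time averaging acts by eroding effective fidelity.** A species outside a
collection's habitat occurs with probability
`occupancy * (1 - habitat_fidelity * (1 - time_averaging))`. We model
mixing at the species level — every assemblage partially mixed — rather
than flipping whole collections to "fully mixed" with some probability.
The all-or-nothing variant produces a *non-monotone* response of the
multiple-site Simpson metric to the mixing rate: at intermediate rates,
mixed collections nearly contain the faithful ones, creating nestedness
(which the turnover-only metric ignores) while suppressing turnover, so
measured beta dips and then rises again toward full mixing. Partial mixing
per assemblage is also taphonomically the more realistic reading — time
averaging affects every bed to some degree — and it makes the intended
directions hold monotonically by construction: alpha can only rise and
beta can only fall as `time_averaging` grows, with full mixing exactly
equivalent to zero fidelity. The tests verify both directions with paired
seeds (common random numbers couple the draws across levels).

Default study conditions, fixed once: formations of 26–60 collections
(just above the vetting threshold up to a well-sampled unit), species
pools of 30–150 (so roughly a quarter of formations exceed the gamma = 100
restriction), 1–4 habitats weighted toward 2–3 (formations usually span
more than one habitat), fidelity 0.3–0.9, occupancy 0.08–0.25, time
averaging 0–0.5, 2–15 references with clustering 0.2–0.8 tying references
to habitats (the monographic mechanism), collection coordinates scattered
1.5° around a formation centroid. The `low_beta_first` sampler makes
fidelity rise with pool size up to ~100 species and flatten above —
the canonical coupled trajectory — for end-to-end tests of the classifier.

What the generator does **not** emulate, hence what passing tests cannot
show about real data: no abundance structure (incidence only), no
birth–death or dispersal dynamics, no taxonomic noise or synonymy, no
spatial autocorrelation of composition within habitats, no secular trends
in preservation, and habitats of equal size and detectability. The
generator validates the *statistical machinery*, not the paleobiology of
any particular dataset.

## Numerical and degenerate-input choices

* Single-taxon collections regenerated by the simulator: after 50 redraws a
  collection is topped up with occupancy-weighted forced picks so
  generation terminates; the tiny bias toward the 2-species floor is
  irrelevant at default occupancies.
* Metric layer rejects empty collections loudly rather than silently
  (they cannot occur post-vetting; reaching one is a contract violation).
* `multisite_simpson` returns 0 (not 0/0) for identical or perfectly
  nested collections, matching the analytic limit.
* A single-trial null distribution reports `sd = NA` and z-scoring refuses
  it explicitly.
* Child seeds: FNV-1a-style 32-bit string hash of the stream name added to
  the master seed modulo 2^31 — exact in double arithmetic, portable, and
  order-free.
* Boundary ages, thresholds: strictly-greater-than-25 collections,
  strictly-greater-than-10 references, gamma ≤ 100 — all `>=`/`<=`
  semantics documented at the function level and covered by edge tests.

## Problem sizes used by the test suite

The suite exercises the default operating points (20-collection
subsamples, 500 trials, 20-formation null draws, 200 null trials) but
validates stochastic claims at sizes chosen for tight Monte-Carlo error at
reasonable cost: calibration of subsampled alpha at 10,000 trials;
standard-error scaling over trials {50, 200, 800} × 25 replicates;
null-model calibration over 300 label draws of a 100-formation pool;
fidelity recovery over a 10-level sweep × 20 replicates; determinism on a
30-formation dataset at 150 trials. All seeds are fixed in the tests.

## Known limitations

* The environment mapping and the genus-uncertainty predicate are
  best-effort conventions; real downloads may need overrides.
* The multiple-site Simpson metric saturates near 1 for many patchy
  collections; comparisons are most informative at the common subsampling
  level, not across levels.
* The null model conditions on the pooled estimate table; it answers "is
  this period's coupling unusual among these formations", not "among all
  conceivable formations".
* `coord_mad` is one of several defensible readings of a coordinate MAD;
  it is configurable by computing your own from the occurrence table.
* With `time_averaging` and `habitat_fidelity` acting through their
  product, the two parameters are not separately identifiable from a
  single formation's incidence matrix — by design, they describe mechanism,
  not independently recoverable quantities.
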