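# formdiv

Diversity partitioning of fossil metacommunities at the scale of geological
formations.

Marine geological formations preserve pools of species that could plausibly
interact at local-to-regional scale, so each formation can be treated as a
metacommunity and its species diversity can be split into three components:

- **alpha** — the mean species richness of its fossil collections,
- **beta** — the compositional differentiation among those collections,
- **gamma** — the total species richness of the formation.

`formdiv` is for paleoecologists who want to run that partition on
Paleobiology Database (PBDB) style occurrence downloads, reproducibly and at
scale: it vets the raw occurrence table, equalizes sampling effort by
subsampling collections, computes the diversity components per formation,
fits alpha–gamma and beta–gamma trajectories per geological period, and
tests the strength of beta–gamma coupling against a randomization null
model. A synthetic metacommunity generator with known alpha/beta/gamma
structure ships with the package, so the whole pipeline can be exercised and
validated without any database access.

## The statistics at the core

For a binary collections × species incidence matrix with site richnesses
S_i, pooled richness S_T, and b_ij the number of species present in site i
but absent from site j:

- Whittaker's beta: `beta_W = gamma / mean(alpha)`.
- Multiple-site Simpson dissimilarity ("Simpson's metric" — a dissimilarity
  of the Simpson/Baselga family, *not* Simpson's diversity index):

  ```
  beta_SIM = sum_{i<j} min(b_ij, b_ji) /
             ( [sum_i S_i - S_T] + sum_{i<j} min(b_ij, b_ji) )
  ```

  It isolates spatial turnover and ignores richness-difference (nestedness)
  structure: 0 when all collections are compositionally identical or nested,
  1 when no two collections share a species. For two sites it reduces to
  `min(b, c) / (a + min(b, c))`.

Each formation's components are estimated by drawing 20 collections without
replacement, recomputing all metrics on the subsampled matrix, and averaging
over 500 such trials (both counts configurable). Only formations with more
than 25 vetted collections enter the analysis. Per-period beta–gamma
coupling is the slope of the logarithmic fit `beta_SIM = a + b ln(gamma)`,
scored as a z-value against the slope distribution of random 20-formation
draws from the pooled data (200 trials), with the comparison restricted to
formations of at most 100 subsampled species, the range over which beta can
still respond to gamma.

## Worked example

```r
library(formdiv)
library(dplyr)

ds <- simulate_dataset(tibble(period = c("Ordovician", "Permian"),
                              n_formations = c(10L, 10L)), seed = 42)
vetted <- vet(ds$occurrences)
est <- run_all_formations(vetted, n_trials = 500, seed = 42)
est |> select(formation, Period, CollpF, AlphaForm, BetaSimForm, GammaForm) |> head(4)
#> # A tibble: 4 × 6
#>   formation        Period     CollpF AlphaForm BetaSimForm GammaForm
#>   <chr>            <chr>       <int>     <dbl>       <dbl>     <dbl>
#> 1 Ordovician Fm 01 Ordovician     32      7.53       0.937      79.9
#> 2 Ordovician Fm 02 Ordovician     59     20.7        0.910     132.
#> 3 Ordovician Fm 03 Ordovician     53      9.67       0.943     109.
#> 4 Ordovician Fm 04 Ordovician     41      5.98       0.896      32.4
```

`AlphaForm`, `BetaSimForm` and `GammaForm` are the trial means of mean
collection richness, multiple-site Simpson dissimilarity, and subsampled
total richness. `Ordovician Fm 01` is a patchy formation: on average each
20-collection subsample saw ~80 species but a single collection only ~7.5,
and the collections are strongly differentiated (Simpson's metric 0.94).

```r
res <- coupling_test(est, gamma_max = 100, draw_size = 8, n_trials = 200, seed = 42)
glance(res$null)
#> # A tibble: 1 × 4
#>   mean_slope sd_slope n_trials draw_size
#>        <dbl>    <dbl>    <int>     <int>
#> 1    0.00686   0.0116      200         8
res$periods
#> # A tibble: 1 × 5
#>   Period     n_formations  slope     z verdict
#>   <chr>             <int>  <dbl> <dbl> <chr>
#> 1 Ordovician            6 0.0263  1.68 uncoupled
spearman_rho(est$AlphaForm, est$GammaForm)
#> # A tibble: 1 × 3
#>     rho      p_value     n
#>   <dbl>        <dbl> <int>
#> 1 0.911 0.0000000234     20
```

The Ordovician beta–gamma slope (0.026 per log-species) sits 1.68 null SDs
above the pooled-draw expectation — suggestive of a "low-beta-first"
accumulation but not beyond the 1.96 threshold for this small example —
while alpha and gamma are tightly rank-correlated (rho = 0.91), the
signature of diversity growth carried by local species packing. (The
Permian is skipped here: after the gamma ≤ 100 restriction only 4 of its
formations remain, below the fitting minimum.)

`autoplot(abg_plot_data(est, grouping = "period"))` renders the
alpha–beta–gamma panels (alpha red, beta blue, 95% bands); `run_pipeline()`
wires all stages together behind one config with one master seed, and
`inst/scripts/formdiv.R` exposes the same stages as shell subcommands
(`simulate`, `vet`, `partition`, `nullmodel`, `report`, `all`).

## Not in scope

No live PBDB/fossilworks client, no taxonomic synonym resolution, no
abundance-based dissimilarities, and no beta diversity *among* formations —
the unit of analysis is always the single formation.
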