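# flocknet

Social network analysis of mixed-species bird flocks, from
gambit-of-the-group field observations to inference about community
structure.

Winter flocks of Carolina chickadees (CACH) and tufted titmice (TUTI) are
recorded as flock scans: each observation lists the colour-banded birds
seen together in one flock. Under the gambit of the group, co-membership is
association. flocknet turns a season of such observations into a weighted
social network and asks the questions behavioural ecologists ask of it —
who associates with whom, whether the population divides into communities,
whether conspecifics assort, and whether any of it exceeds chance — with
the resampling machinery those answers require.

The pipeline:

1. **Data model** — long or wide (group-by-individual, GBI) observation
   CSVs; transient filtering (birds sighted < 3 times are dropped, once,
   not iteratively).
2. **Association** — edge weights are the Simple Ratio Index,
   `SRI = x / (x + yA + yB)`: the Jaccard index of two birds' sighting
   records, 0 (never together) to 1 (always together).
3. **Network statistics** — density `2E / N(N-1)`, connected components,
   average (unweighted) shortest path length over reachable pairs.
4. **Communities** — Girvan–Newman edge-betweenness removal with
   betweenness recomputed after every removal, returning the partition
   maximising modularity `Q = Σ (e_ii − a_i²)`; weighted categorical
   assortativity `r = (Σ e_ii − Σ a_i b_i) / (1 − Σ a_i b_i)` for species
   and community labels. Betweenness treats SRI as a distance (`1/SRI`),
   modularity as a strength; both can be binarized.
5. **Inference** — the serial datastream permutation (group-membership
   checkerboard swaps preserving flock sizes and sighting counts, statistic
   recomputed after every swap of a single chain), node-label permutations
   for assortativity, and a flock bootstrap yielding `r_community`, the
   assortativity of bootstrap co-membership with respect to the empirical
   partition.
6. **Synthetic data** — a generator of flock observations with planted
   communities, conspecific bias, floater-mediated between-community
   mixing, and imperfect detection; `emulate_site()` presets mirror the
   published low/mid/high-quality site populations.

The community-detection and permutation inner loops are implemented in
C++ (Rcpp); igraph is used only as an independent oracle in the test suite.

## Worked example

```r
library(flocknet)

sim <- simulate_flocks(emulate_site("high", seed = 7))
gbi <- build_gbi(sim$observations) |> filter_individuals(min_sightings = 3)
net <- build_flock_network(gbi, sim_attributes(sim))

glance(net)
#> # A tibble: 1 × 8
#>   n_nodes n_species species_counts  n_edges density n_components component_sizes
#>     <int>     <int> <chr>             <int>   <dbl>        <int> <chr>
#> 1      29         2 CACH=16;TUTI=13      58   0.143            5 10;5;5;5;4

girvan_newman(net)
#> <community_partition> 6 communities, Q = 0.7896

serial_permutation_test(gbi, seed = 1, n_swaps = 1000)
#> <resampling_result> modularity: empirical = 0.7896, p = 0.002
#>   (corrected 0.003, greater, n = 1000)

part <- girvan_newman(net)
r_community(part, bootstrap_flocks(gbi, 1000, seed = 2))
#> [1] 0.9174
species_assortativity(net)
#> [1] 0.5331
```

Reading: this simulated high-quality site yields a sparse (density 0.14),
fragmented network of 29 birds whose 6 communities are far more modular
(Q = 0.79) than any of the 1000 swap-null networks (p = 0.002), are robust
to resampling of flocks (r_community = 0.92), and in which conspecifics
associate preferentially (species assortativity = 0.53).

`run_site_analysis()` chains all stages (with JSON/CSV reports), and
`run_validation_suite()` measures type-I error, power, planted-community
recovery and r_community calibration over replicated synthetic datasets. A
thin command-line front end with `analyze` / `simulate` / `validate`
subcommands is in `inst/scripts/flocknet.R`.

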