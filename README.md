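# crohnet

Network prioritisation and topological analysis of disease
susceptibility genes.

## The problem

Genome-wide association studies nominate hundreds of candidate genes
for complex inflammatory diseases such as Crohn's disease, but give
little guidance on which candidates act together as a disease module.
`crohnet` is for researchers who want to narrow such a candidate list
using a protein–protein interaction network and then ask whether the
resulting sub-network looks like a genuine disease module — denser than
background, wired to hubs, non-random in its small subgraph composition,
fragile to targeted attack, and functionally segregated.

The package implements the full chain as composable, pipe-friendly
functions over tidy data structures:

1. **Prioritisation** — a random walk with restart
   $p^{(t+1)} = (1-r)\,Wp^{(t)} + r\,e$ seeded at a training set of
   established disease genes ranks candidates by diffusion proximity
   (`rwr()`, with `rwr_exact()` as the direct linear solve); the
   diffusion selection is intersected with an externally supplied
   relatedness ranking and united with the training set to form the
   consensus list (`select_by_steady_state()`, `select_external()`,
   `consensus()`).
2. **Disease sub-network** — all interactions touching a prioritised
   gene (`extract_disease_network()`), with density ratio, components
   and node roles.
3. **Characterisation** — topology vs an Erdős–Rényi ensemble
   (`er_ensemble_compare()`), failure–attack robustness with secondary
   extinctions (`removal_trajectory()`), a 3-/4-node motif census with
   Mfinder-style decimal ids against a degree-preserving switching null
   (`motif_zscores()`, `motif_participation()`), and the topological
   segregation index of functional classes,
   $S^j = \langle \langle S^j(d)\rangle / f_j \rangle_d$
   (`segregation_index()`).
4. **Enrichment statistics** — hypergeometric hub over-representation,
   Fisher tests for differential-expression enrichment and per-protein
   hub-neighbour contingency, and a Bonferroni-corrected binomial
   category test (`identify_hubs()`, `de_enrichment()`,
   `hub_neighbour_test()`, `category_overrep()`).
5. **Synthetic studies** — a scale-free interactome with a planted,
   denser disease module plus matching gene sets, rankings, DE tables
   and cohesive functional classes (`crohnet_scenario()`,
   `simulate_study()`), so every stage runs and is validated without
   external downloads.

`run_pipeline()` orchestrates all stages from a single seeded
configuration, writing deterministic TSV/JSON artifacts;
`inst/scripts/crohnet-run.R` is a thin command-line wrapper.

## Worked example

```r
library(crohnet)

sc    <- crohnet_scenario(seed = 1)      # 500-gene interactome, 30-gene module
study <- simulate_study(sc)
study$network
#> <interactome> 500 nodes, 1182 edges

res <- rwr(study$network, study$training)
glance(res)
#> # A tibble: 1 × 7
#>   n_nodes n_training     r          tol iterations converged total_probability
#> 1     500         10   0.5 0.0000000001         25 TRUE                      1

sel  <- select_by_steady_state(res, study$candidates, "top_k", 30)
ext  <- select_external(study$ranking, 0.1)
cons <- consensus(sel, ext, study$training, nodes = net_nodes(study$network))
cons
#> <prioritisation_result> 30 consensus genes (intersection of 30
#>   diffusion-selected and 49 externally selected, plus 10 training)

disease <- extract_disease_network(study$network, cons$consensus)
disease
#> <interactome> 114 nodes, 231 edges
density_ratio(disease, study$network)
#> [1] 3.79

list_segregation(disease, intersect(cons$consensus, net_nodes(disease)))
#> <segregation_profile> S = 1.528 over d = 1..3 (class 30 of 114 nodes)

motif_zscores(disease, 3, n_random = 100, seed = 1)
#> # A tibble: 2 × 6
#>      id real_count null_mean null_sd     z call
#> 1    78       1811     1743.    33.1  2.07 motif
#> 2   238        114      137.    11.0 -2.07 anti-motif

de_enrichment(cons$consensus, study$de_table)
#> # A tibble: 1 × 9
#>   test              a     b     c     d  p_value ...
#> 1 de_enrichment    22     8    26   444 7.85e-19 ...
```

Reading the numbers: the walk converges in 25 iterations with unit
probability mass; the consensus recovers the 30-gene planted module
exactly; its sub-network is 3.8× denser than the interactome at large;
the prioritised list is topologically segregated (S = 1.53, against 1
for randomly placed genes); 3-paths are over- and triangles
under-represented relative to the degree-preserving null; and the
prioritised list is strongly enriched in differentially expressed genes
(22 of 30 DE, Fisher p ≈ 8 × 10⁻¹⁹).

Result objects have `tidy()`, `glance()` and `autoplot()` methods, so
`autoplot(removal_trajectory(disease, "degree_desc", 0.05))` or
`plot_attack_tolerance(disease)` give publication-style attack curves
directly.

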