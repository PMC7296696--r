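# sscentrality

Source/Sink Centrality (SSC) for directed biological pathway graphs, with
the full statistical pipeline for validating centrality models against
a-priori important gene sets.

## The problem

Signaling pathways have an upstream-to-downstream organization: receptors
send signals, cascades propagate them, effectors receive them. Standard
directed graph centralities (PageRank, Katz) score a node either as a
*sender* or as a *receiver* of signal, so one of the two pathway ends is
always scored as topologically irrelevant — yet biologically important
genes (cancer drivers, essential genes) sit at both ends. SSC fixes this
by computing a model's **source** component (importance as a sender) and
its **sink** component (the same model on the transposed graph, importance
as a receiver) with the same parameters and summing them:

```
C_ssc(v) = C_source(v) + C_sink(v)
```

The package implements, for a directed pathway graph with 0/1 adjacency
`A` and clamped diagonal degree matrices `D_out`, `D_in`
(`[D]_ii = max(deg, 1)`):

| model      | source                              | sink                                  |
|------------|-------------------------------------|---------------------------------------|
| degree     | out-degree                          | in-degree                             |
| PageRank   | `(I − α A D_in⁻¹)⁻¹ β`              | `(I − α Aᵀ D_out⁻¹)⁻¹ β`              |
| Katz       | `(I − α A)⁻¹ β`                     | `(I − α Aᵀ)⁻¹ β`                      |
| Laplacian  | `(I − α D_out⁻¹ A)⁻¹ β`             | `(I − α D_in⁻¹ Aᵀ)⁻¹ β`               |
| closeness  | `Σ_u 1/d(v,u)` (harmonic)           | `Σ_u 1/d(u,v)`                        |

plus undirected variants where meaningful (PageRank, closeness, degree).
Note the PageRank here is the literal linear-system form with a constant
restart vector `β` — no dangling-node redistribution, no sum-to-one
normalization — which differs from textbook PageRank implementations.
Defaults: PageRank `α = 0.85, β = 0.15`; Katz `α = 0.1, β = 1` (refused
unless `α < 1/λ₁`); Laplacian `α = 0.85, β = 1`.

The validation pipeline asks whether a centrality model concentrates
a-priori important genes at high centrality: within-pathway quantile
ranking (`Q(v) = ⌈100·rank(v)/n⌉`), pooling of importance fractions per
quantile across pathways, OLS of fraction on quantile
(`F_i = a₁·i + a₀`), one-sided two-sample KS comparison of pooled
z-normalized score CDFs, per-pathway one-sided Welch and Wilcoxon tests
with Benjamini–Hochberg FDR control, and a Fisher-Z sensitivity scan of
the PageRank `α`.

Inputs: KEGG KGML pathway XML, plain edge-list TSV, GMT or per-line gene
sets. A synthetic generator of layered pathway-like DAGs with planted
important genes (at the terminal layers, at hubs, or uniformly) lets the
whole pipeline run with no external data.

## Worked example

```r
library(sscentrality)

cohort <- generate_cohort(synthetic_spec(n_pathways = 150, seed = 1))
cohort
#> <synthetic_cohort> 150 pathways (terminal_ends importance), 1047 planted important genes

v <- ssc_validation(cohort)   # filters, ranks, regresses, tests
v
#> <ssc_validation> 115 pathways, 12 model/variants
#>        model    variant estimate  p.value adj_r_squared
#> 1     degree        ssc   0.1175 3.24e-04       0.11863
#> 2   pagerank     source   0.0759 2.19e-01       0.00555
#> 3   pagerank       sink   0.0473 4.10e-01      -0.00332
#> 4   pagerank        ssc   0.3406 6.33e-11       0.35690
#> 5   pagerank undirected   0.1588 1.82e-07       0.24228
#> 6       katz     source   0.0457 3.71e-01      -0.00202
#> 7       katz       sink   0.0402 4.30e-01      -0.00393
#> 8       katz        ssc   0.2959 1.00e-14       0.46372
#> 9  laplacian     source   0.0151 8.28e-01      -0.01070
#> 10 laplacian       sink  -0.0206 7.43e-01      -0.01012
#> 11 laplacian        ssc  -0.3567 5.38e-12       0.38891
#> 12 closeness        ssc   0.3250 3.15e-15       0.47650
```

Reading the table: `estimate` is the slope `a₁` of the importance
fraction (percent) per centrality quantile. On this cohort — important
genes planted at both pathway ends — SSC Katz and SSC PageRank recover a
strongly positive slope (each extra quantile adds ~0.3 percentage points
of important genes; p ≈ 1e-14 and 6e-11), while the pure source and sink
variants find nothing (p ≈ 0.2–0.4): exactly the contrast SSC is designed
to expose. The undirected PageRank is positive but explains less variance
than SSC (adjusted r² 0.24 vs 0.36). Laplacian SSC is negative on these
homogeneous layered DAGs — its neighbor-averaging recurrence peaks
mid-cascade; see the methods vignette. 115 of 150 pathways pass the
quality filters (the rest mostly have too few planted important genes).

`summary(v)` adds the KS comparisons and FDR-significant pathway counts;
`plot(v, "pagerank", "ssc")` shows the fitted quantile regression.
Individual pieces are exported too: `katz_centrality()`,
`pagerank_centrality()`, `quantile_ranks()`, `welch_test()`,
`sensitivity_scan()`, `read_kgml()`, `filter_pathways()`, ...

A command-line front end wrapping the same functions ships in
`inst/cli/sscpath.R` with `simulate`, `compute`, `validate`, and
`sensitivity` subcommands driven by a YAML config.

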