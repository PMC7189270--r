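# evembed — event embedding of temporal contact networks

`evembed` is for researchers working with snapshot-resolved contact data
(proximity-sensor studies in conferences, schools, hospitals; any event
list of the form *timestamp, node, node*) who want a low-dimensional
representation of the **events** of a temporal network — not of its nodes
— and a way to validate that representation against spreading dynamics.

## The method

A temporal network `G_T = (N, E_T, T)` of undirected events `e = (i, j, t)`
is projected onto its *weighted event graph*: a static DAG whose nodes are
the events, with a directed edge `e1 → e2` whenever the two events share a
node, `t1 < t2 ≤ t1 + δt`, and `e2` is the earliest later event on its
static link. Each edge carries

* a temporal-path weight `w_path = 1 / (1 + (t2 − t1))`, and
* a co-occurrence weight `w_co`, the number of snapshots in which the two
  underlying static links fire simultaneously.

Contexts ("environments") for each center event are sampled from its
combined predecessor/successor set with probability

    p(e_l) = α · F(w_path) + (1 − α) · F(w_co),      F(w) = w / Σ_{N_k} w,

`nb` environments of length `s` per event, and fed as sentences to a
Skip-Gram model with negative sampling, giving each event a `d`-dimensional
vector. The embedding dimension can be chosen by an entropy stability
criterion (pairwise-distance entropy across training realisations, first
crossing of the curve with its horizontal fit). Validation: a deterministic
SI epidemic (transmission probability 1) is seeded at every event; final
sizes are regressed on the `2d + 1` features (coordinates, squares,
distance to first event) with 10-fold cross-validated OLS, reported as
held-out `r²`, optionally against three randomized reference models
(snapshot, timeline and link shuffling). A non-negative CP factorization
of the `n × n × t` contact tensor with core-consistency (CORCONDIA) rank
selection labels events with mesoscale structures.

## Worked example

```r
library(evembed)

# two groups of 10 nodes, each active in its own 15-snapshot window
tn <- make_planted_communities(n_groups = 2, nodes_per_group = 10,
                               snapshots_per_group = 15, p_in = 0.2,
                               p_out = 0.01, seed = 42)
tn
#> temporal_network: 321 events, 20 nodes, horizon 29 snapshots (20 s each)

g <- build_event_graph(tn)
g
#> event_graph: 321 events, 4515 edges, delta_t = 29

corpus <- sample_environments(g, sampling_config(alpha = 0.5, nb = 10,
                                                 s = 10, seed = 1))
emb <- train_embedding(corpus, d = 8, seed = 1)

sizes <- epidemic_sizes_all_seeds(tn)
fit_and_score(build_features(emb, sizes), folds = 10, seed = 1)
#> prediction_report: held-out r2 = 0.718 +/- 0.133 over 10 folds (321 rows)
```

The held-out `r² = 0.72` says that event coordinates explain most of the
variance in final epidemic size. Destroying temporal correlations while
keeping the structure (snapshot shuffling) should hurt — and does:

```r
null_tn <- snapshot_shuffle(tn, seed = 1)
g0 <- build_event_graph(null_tn)
c0 <- sample_environments(g0, sampling_config(alpha = 0.5, nb = 10,
                                              s = 10, seed = 1))
e0 <- train_embedding(c0, d = 8, seed = 1)
fit_and_score(build_features(e0, epidemic_sizes_all_seeds(null_tn)),
              folds = 10, seed = 1)
#> prediction_report: held-out r2 = 0.393 +/- 0.216 over 10 folds (321 rows)
```

Mesoscale structures via the contact tensor (three planted groups):

```r
tn3 <- make_planted_communities(n_groups = 3, nodes_per_group = 8,
                                snapshots_per_group = 12, p_in = 0.6,
                                p_out = 0.01, seed = 5)
ct <- build_contact_tensor(tn3)
sel <- select_rank(ct, ranks = 2:6, seed = 5)
sel$rank
#> [1] 3
round(sel$diagnostics, 2)
#>   rank core_consistency  fit
#> 1    2           100.00 0.18
#> 2    3            99.94 0.28
#> 3    4          -460.55 0.29
#> 4    5          -585.49 0.29
#> 5    6          -930.79 0.30

lab <- assign_components(decompose_tensor(ct, sel$rank, seed = 5), tn3)
table(component = lab, window = attr(tn3, "labels"))
#>          window
#> component   1   2   3
#>         1   1   2 213
#>         2   2 222   2
#>         3 222   0   0
```

Core consistency collapses past the planted rank, and the selected
3-component model recovers the planted activity windows almost perfectly
(off-diagonal counts are the `p_out` noise events).

A command-line wrapper for ingestion, synthetic generation, shuffling and
the full pipeline ships in `inst/cli/evembed.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/evembed.R", package="evembed"))')" \
    synth --kind chain --n 100 --out chain.tsv
```

## Scope

Events are undirected point contacts at snapshot resolution: no interval
events, directed/weighted events, streaming input, stochastic (β < 1)
epidemics, or node-seeded spreading. See the methods vignette
(`vignettes/event-embedding-methods.Rmd`) for the model details, parameter
guidance and limitations.
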