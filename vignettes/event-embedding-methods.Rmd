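---
title: "Embedding the events of a temporal contact network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding the events of a temporal contact network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evembed)
```

## The problem and the model

Face-to-face contact data (conferences, schools, hospitals) comes as a
sequence of network snapshots: every `Δt` seconds (20 s for typical
proximity sensors) the set of currently interacting pairs is recorded. The
atomic object is the *event* `(i, j, t)` — an undirected contact between
nodes `i` and `j` in snapshot `t`. Events are not independent: they are
threaded together by time-respecting paths (event `e1` can causally
precede `e2` if they share a node and `t1 < t2`) and by co-activation
(groups of links that tend to fire in the same snapshots). `evembed`
learns a `d`-dimensional vector for every event such that events with
similar temporal-structural neighborhoods — which tend to influence a
similar set of nodes later on — lie close together.

The pipeline has three stages.

**1. Weighted event graph.** Events become the nodes of a static directed
acyclic graph. A directed edge `e1 → e2` exists when the events share at
least one node, `t1 < t2 ≤ t1 + δt`, and `e2` is the *earliest* later
event on its static link (one successor per destination link; `δt`
defaults to the whole observation window). Each edge carries two weights:

* `w_path = 1 / (1 + (t2 − t1))` — large for temporally close, potentially
  causal event pairs;
* `w_co` — the number of snapshots in which the two underlying static
  links fire simultaneously, a co-activation count shared by every edge
  on the same link pair.

Events inside one snapshot are never adjacent (time order is strict);
their relation enters only through `w_co`. For an edge joining two events
of the *same* link we use that link's timeline length as `w_co` (a
timeline trivially co-occurs with itself); this case is not pinned down
by the construction and is our convention.

**2. Neighborhood sampling.** For a center event with combined
predecessor/successor set `N_k`, a context event `e_l` is drawn with
probability

```
p(e_l) = alpha * F(w_path) + (1 - alpha) * F(w_co),
```

where `F` normalizes each weight over `N_k`. `alpha = 1` samples by
temporal proximity only, `alpha = 0` by co-activation only. `nb`
environments of `s` events each are drawn per event, i.i.d. with
replacement (with replacement keeps environments well defined when
`|N_k| < s`; a neighborhood whose `w_co` are all zero gets a uniform
co-activation term, the least-informative completion of 0/0). Events
with empty neighborhoods are skipped and never receive a vector. A
`predecessors_only` mode restricts contexts to the past, making the
method usable online.

**3. Skip-Gram.** Each environment is one training sentence (center
first, then contexts); the window spans the whole sentence, so every
context co-occurs with its center. Training is
skip-gram-with-negative-sampling, single-threaded with its own seeded RNG
for bit reproducibility.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta_t` | `"full"` | adjacency horizon, snapshots |
| `alpha` | 0.5 | path vs co-occurrence mix, `[0, 1]` |
| `nb`, `s` | 10, 10 | environments per event, events per environment |
| `d` | 8 (or `"auto"`) | embedding dimension |
| `negative` | 15 | negative samples per positive pair |
| `epochs` | 5 | training passes |
| `learning_rate` | 0.025 | initial learning rate, linear decay |

`alpha = 0.5, nb = 10, s = 10` are the showcase settings used throughout;
the `nb × s` surface is strongly compensatory (a longer environment buys
the same information as more environments), so fixing both at 10 is
usually enough.

**Why 15 negative samples and not the word2vec large-corpus default 5?**
Event corpora are tiny by word-embedding standards: the vocabulary *is*
the event set, and the corpus holds `nb · E` sentences. In this regime
the original negative-sampling guidance is 15–20 samples. The choice is
measurable: on the deterministic chain benchmark below, `negative = 5`
leaves the embedded chain partly folded (held-out `r² ≈ 0.73`), while
`negative = 15` unfolds it (`r² ≈ 0.88`). More epochs do *not* substitute
— prolonged training on so few distinct pairs lets the chain refold
(measured `r²` drops to ~0.48 at 20 epochs). The exposed `vectors`
argument can return the input/output-averaged matrix instead of the input
vectors; it measured worse here and is not the default.

## Choosing the dimension

Past the useful dimensionality, extra coordinates code redundant
information, so the *relative* geometry stops moving between independent
training runs. `entropy_curve()` quantifies this: for each `d` it trains
`realisations` independent embeddings, splits the event sequence into
consecutive blocks, and for every within-block event pair computes the
Shannon entropy (natural log, 10 bins spanning the global distance range
of the whole experiment) of that pair's distance across realisations;
pair entropies are averaged per block, then over blocks. The curve
decreases and flattens; `optimal_dimension()` returns the first crossing
of the curve with its best-fitting horizontal line (which is its mean).
Two caveats we implement literally but flag: with `realisations = 10`
distances per pair and 10 bins the per-pair histograms are sparse, so
absolute entropy values are noisy even where the ranking in `d` is
stable; and the entropy sign convention follows the standard non-negative
Shannon form.

## Epidemic-size prediction as validation

With transmission probability 1 and no recovery, an SI epidemic seeded at
an event is deterministic: both endpoints are infected at the seed's
snapshot, and every strictly later event with exactly one infected
endpoint transmits. Within one later snapshot we iterate to a fixed point
(a snapshot is an undirected graph; infection covers the connected
component containing infected nodes) — the data gives no ordering inside
a snapshot, so the fixed point is the only order-free choice; a
`single_pass` flag restricts to one sweep for comparison. Events
simultaneous with the seed do not transmit, consistent with strict
adjacency.

The validation regresses final size on the `2d + 1` features
(coordinates, their squares, euclidean distance to the first embedded
event) by OLS under 10-fold cross-validation, reporting held-out
`r² = 1 − SS_res/SS_tot` (computable below zero; fold assignment is a
seeded permutation; an exactly singular design falls back to a tiny
ridge with a warning). Three shuffled baselines calibrate what the
embedding actually uses: snapshot shuffling (destroys all temporal
correlations), timeline shuffling (destroys link–timeline matching), and
link shuffling (keeps only within-timeline dynamics on a `G(n, m)`
random structure).

## What the synthetic generators do and do not establish

* `make_chain(n)` — a path traversed once; sizes are exactly `n − k`, so
  prediction quality isolates embedding geometry from epidemic noise.
* `make_planted_communities()` — groups of nodes pairwise active with
  probability `p_in` per snapshot during disjoint consecutive windows,
  plus cross-group noise `p_out`. This plants both mesoscale structure
  and time-localized activity, the two signals the method claims to
  capture.
* `make_random_events()` — uniform distinct (pair, snapshot) draws, used
  by the brute-force equivalence tests.

These generators emulate snapshot resolution, group structure and
time-localized activity. They do **not** emulate burstiness, circadian
rhythms, heavy-tailed degrees or weight-structure correlations of real
contact data; a green test establishes correctness of the machinery and
directional behavior on planted structure, not performance figures on
empirical networks.

## Mesoscale structures by tensor factorization

The contact sequence is also a binary `n × n × t` tensor. A non-negative
CP decomposition with a shared node factor (contacts are undirected, so
separate row/column factors would be redundant; a flag disables sharing)
is fitted by multiplicative updates with several random restarts, factor
columns normalized to unit length. Each event is labeled by the component
with the largest reconstruction `λ_c a_ic a_jc g_tc` at its link and
snapshot, ties to the lowest index — well defined precisely because of
the normalization. Rank is chosen by the core-consistency diagnostic:
`select_rank()` fits candidate ranks (2–20 by default) and keeps the
largest whose consistency stays above 90. Non-negativity is a modeling
choice: contact activity is additive, and non-negative parts are the
interpretable ones.

## Numerical and degenerate-input choices

* Node identifiers compare in the C locale everywhere (canonical
  `i < j`, event order `(t, i, j)`), so results are locale-independent.
* Timestamps are rebased so the earliest snapshot is 0; raw seconds are
  floor-divided by the snapshot width on ingestion.
* Duplicate `(i, j, t)` records collapse to one event; whether raw
  sensor data can repeat a pair within one snapshot is ambiguous, and
  collapsing is the conservative reading.
* Snapshot shuffling repairs timestamp-permutation collisions (two
  events of one pair landing in one snapshot) by seed-deterministic
  swaps, so the event count is conserved exactly.
* A degenerate global distance range in the entropy computation puts all
  mass in one bin (`H = 0`); an entropy curve probed at fewer than three
  dimensions reports `optimal_d = NA`.
* Networks with fewer than two events yield an edgeless event graph;
  isolated events produce no environments and are excluded from the
  feature table with a logged count.

## Known limitations

* Interval events, directed or weighted events, and streaming input are
  out of scope; events are point contacts at snapshot resolution.
* The co-occurrence weight counts simultaneity within single snapshots
  only, which may undercount co-occurrence when `δt` exceeds the
  snapshot width.
* Embedding coordinates are seed-reproducible but not canonical; only
  geometry (distances, prediction skill) is meaningful across runs.
* The entropy criterion ranks dimensions; it does not certify that the
  selected `d` is optimal for any particular downstream task.
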