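# synthetic: generators with built-in ground truth, so tests never
# re-derive expected values from the code under test

#' Deterministic chain network
#'
#' Events `(v_k, v_{k+1}, k)` for `k = 0..n-2`: a path traversed once in
#' time order. An SI epidemic seeded at event `k` infects every
#' downstream node, so its final size is exactly `n - k`; the expected
#' sizes are attached as ground truth (attribute `"expected_sizes"`, a
#' named vector by event token).
#'
#' @param n_nodes chain length (`>= 2`).
#' @return a `temporal_network`.
#' @export
make_chain <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("need at least 2 nodes")
  nodes <- sprintf("v%04d", seq_len(n_nodes))
  k <- seq_len(n_nodes - 1L)
  tn <- temporal_network(nodes[k], nodes[k + 1L], k - 1L)
  sizes <- setNames(n_nodes - (k - 1L),
                    event_token(nodes[k], nodes[k + 1L], k - 1L))
  attr(tn, "expected_sizes") <- sizes
  tn
}

#' Planted temporal communities
#'
#' Emulates snapshot-resolved contact sequences with group structure and
#' time-localized group activity: each group's nodes interact pairwise
#' with probability `p_in` per snapshot during the group's own
#' consecutive activity window; cross-group pairs interact with
#' probability `p_out` in every snapshot. Ground truth attached:
#' `"labels"` (named by event token, the group whose window the event
#' falls in) and `"group_of_node"`.
#'
#' @param n_groups number of groups.
#' @param nodes_per_group nodes in each group.
#' @param snapshots_per_group length of each group's activity window.
#' @param p_in within-group contact probability per pair per snapshot
#'   inside the window.
#' @param p_out cross-group contact probability per pair per snapshot
#'   (throughout the whole observation).
#' @param seed RNG seed.
#' @return a `temporal_network` with ground-truth attributes.
#' @export
make_planted_communities <- function(n_groups = 2L, nodes_per_group = 15L,
                                     snapshots_per_group = 20L, p_in = 0.2,
                                     p_out = 0.01, seed = 1L) {
  n_groups <- as.integer(n_groups)
  nodes_per_group <- as.integer(nodes_per_group)
  S <- as.integer(snapshots_per_group)
  nodes <- sprintf("g%02dn%03d", rep(seq_len(n_groups), each = nodes_per_group),
                   rep(seq_len(nodes_per_group), n_groups))
  group_of <- setNames(rep(seq_len(n_groups), each = nodes_per_group), nodes)
  total_T <- n_groups * S
  i <- j <- character(0); t <- integer(0)
  with_seed(seed, {
    # within-group events during the group's window
    for (grp in seq_len(n_groups)) {
      gn <- nodes[group_of == grp]
      prs <- utils::combn(gn, 2L)
      window <- ((grp - 1L) * S):((grp * S) - 1L)
      for (tt in window) {
        fire <- runif(ncol(prs)) < p_in
        if (any(fire)) {
          i <- c(i, prs[1L, fire]); j <- c(j, prs[2L, fire])
          t <- c(t, rep(tt, sum(fire)))
        }
      }
    }
    # cross-group events at any snapshot
    if (p_out > 0 && n_groups > 1L) {
      all_prs <- utils::combn(nodes, 2L)
      cross <- group_of[all_prs[1L, ]] != group_of[all_prs[2L, ]]
      cprs <- all_prs[, cross, drop = FALSE]
      for (tt in 0:(total_T - 1L)) {
        fire <- runif(ncol(cprs)) < p_out
        if (any(fire)) {
          i <- c(i, cprs[1L, fire]); j <- c(j, cprs[2L, fire])
          t <- c(t, rep(tt, sum(fire)))
        }
      }
    }
  })
  if (length(t) == 0L) stop("no events generated; increase p_in")
  tn <- temporal_network(i, j, t, nodes = nodes)
  # label = the activity window the event falls in (1-based group index);
  # note the constructor rebases time, so recover window from raw t
  shift <- min(t)
  lab <- setNames(pmin((tn$events$t + shift) %/% S + 1L, n_groups),
                  tn$events$token)
  attr(tn, "labels") <- lab
  attr(tn, "group_of_node") <- group_of
  tn
}

#' Uniform random events
#'
#' Draws `n_events` distinct (node pair, snapshot) combinations uniformly
#' at random — the workhorse input of the brute-force oracle equivalence
#' tests.
#'
#' @param n_nodes number of nodes.
#' @param n_events number of distinct events.
#' @param horizon number of snapshots (timestamps drawn from
#'   `0..horizon - 1`).
#' @param seed RNG seed.
#' @return a `temporal_network`.
#' @export
make_random_events <- function(n_nodes, n_events, horizon, seed = 1L) {
  n_nodes <- as.integer(n_nodes); n_events <- as.integer(n_events)
  horizon <- as.integer(horizon)
  if (n_nodes < 2L) stop("need at least 2 nodes")
  n_pairs <- n_nodes * (n_nodes - 1L) / 2
  total <- n_pairs * horizon
  if (n_events > total)
    stop("cannot draw ", n_events, " distinct events from ", total,
         " (pair, snapshot) slots")
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  prs <- utils::combn(nodes, 2L)
  with_seed(seed, {
    slot <- sample.int(total, n_events)
    pair_idx <- ((slot - 1L) %% n_pairs) + 1L
    t <- (slot - 1L) %/% n_pairs
    temporal_network(prs[1L, pair_idx], prs[2L, pair_idx], t, nodes = nodes)
  })
}
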