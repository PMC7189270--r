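# null_models: randomized reference models (shufflings) of a temporal network
#
# Conservation ledger:
#   snapshot_shuffle  keeps the aggregated graph, per-link event counts and
#                     the global activity profile; destroys all temporal
#                     correlations between events.
#   timeline_shuffle  keeps the static graph and the multiset of whole
#                     timelines; destroys the link-timeline matching and
#                     causal correlations on adjacent links.
#   link_shuffle      keeps only the number of links and the timeline
#                     multiset (local temporal correlations); replaces the
#                     static structure by a uniform G(n, m) draw.

#' Snapshot shuffling
#'
#' Randomly permutes the timestamps across events while keeping each
#' event's node pair. When a permutation collides two events of the same
#' pair into one snapshot, seed-deterministic timestamp swaps repair the
#' draw until the event multiset is duplicate-free.
#'
#' @param tn a `temporal_network`.
#' @param seed RNG seed.
#' @param max_tries cap on repair iterations.
#' @return a valid `temporal_network`.
#' @export
snapshot_shuffle <- function(tn, seed = NULL, max_tries = 10000L) {
  validate_temporal_network(tn)
  ev <- tn$events
  with_seed(seed, {
    tt <- sample(ev$t)
    tries <- 0L
    repeat {
      key <- paste(ev$i, ev$j, tt, sep = "|")
      dup <- which(duplicated(key))
      if (length(dup) == 0L) break
      tries <- tries + 1L
      if (tries > max_tries)
        stop("snapshot_shuffle: could not resolve timestamp collisions")
      d <- dup[1L]
      p <- sample.int(length(tt), 1L)
      tmp <- tt[d]; tt[d] <- tt[p]; tt[p] <- tmp
    }
    temporal_network(ev$i, ev$j, tt, delta_t_seconds = tn$delta_t_seconds,
                     nodes = tn$nodes)
  })
}

#' Timeline shuffling
#'
#' Randomly permutes the whole per-link timelines among the links of the
#' aggregated graph (the uniform limit of repeated pairwise timeline
#' swaps). The static graph and the multiset of timelines are unchanged.
#'
#' @inheritParams snapshot_shuffle
#' @return a valid `temporal_network`.
#' @export
timeline_shuffle <- function(tn, seed = NULL) {
  validate_temporal_network(tn)
  g <- aggregate_static(tn)
  L <- nrow(g$links)
  if (L == 0L) return(tn)
  with_seed(seed, {
    perm <- sample.int(L)
    new_t <- g$timelines[perm]
    i <- rep(g$links$i, lengths(new_t))
    j <- rep(g$links$j, lengths(new_t))
    temporal_network(i, j, unlist(new_t, use.names = FALSE),
                     delta_t_seconds = tn$delta_t_seconds, nodes = tn$nodes)
  })
}

#' Link shuffling
#'
#' Draws a new static structure uniformly among simple graphs with the
#' same node set and number of links (an Erdős–Rényi G(n, m) realization),
#' then assigns the original timelines to the new links by a random
#' bijection. Local temporal correlations within timelines survive; all
#' structural and structure–timeline correlations are destroyed. No
#' connectivity is enforced.
#'
#' @inheritParams snapshot_shuffle
#' @return a valid `temporal_network`.
#' @export
link_shuffle <- function(tn, seed = NULL) {
  validate_temporal_network(tn)
  g <- aggregate_static(tn)
  m <- nrow(g$links)
  if (m == 0L) return(tn)
  nodes <- tn$nodes
  n <- length(nodes)
  n_pairs <- n * (n - 1) / 2
  if (m > n_pairs) stop("more links than node pairs")
  with_seed(seed, {
    pair_id <- sample.int(n_pairs, m)        # uniform G(n, m)
    # decode pair index k (1-based, column-major over the strict lower triangle)
    b <- cumsum((n - 1L):1L)
    a_idx <- findInterval(pair_id - 1L, c(0L, b), rightmost.closed = FALSE)
    i_new <- nodes[a_idx]
    offset <- pair_id - c(0L, b)[a_idx]
    j_new <- nodes[a_idx + offset]
    perm <- sample.int(m)                    # random timeline bijection
    new_t <- g$timelines[perm]
    temporal_network(rep(i_new, lengths(new_t)), rep(j_new, lengths(new_t)),
                     unlist(new_t, use.names = FALSE),
                     delta_t_seconds = tn$delta_t_seconds, nodes = tn$nodes)
  })
}
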