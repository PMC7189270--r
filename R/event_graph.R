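# event_graph: the weighted directed acyclic event graph

#' Temporal-path weight of an adjacent event pair
#'
#' `w_path = 1 / (1 + (t2 - t1))`, strictly decreasing in the time gap, so
#' temporally close (potentially causal) event pairs weigh more. Because
#' adjacency requires `t2 > t1`, `w_path <= 1/2` always.
#'
#' @param t1,t2 snapshot timestamps with `t2 > t1`.
#' @return numeric in (0, 1/2].
#' @export
compute_w_path <- function(t1, t2) {
  if (any(t2 <= t1)) stop("w_path requires t2 > t1")
  1 / (1 + (t2 - t1))
}

#' Co-occurrence weight of a pair of adjacent static links
#'
#' Counts the snapshots in which both links fire simultaneously. Snapshot
#' data leaves event order within one snapshot ambiguous, so simultaneity
#' within a single snapshot is the operational co-occurrence definition.
#' Every event-graph edge whose endpoints lie on the same pair of static
#' links shares this value. For an edge between two events of the *same*
#' link the value is that link's timeline length (every snapshot of a link
#' trivially co-occurs with itself).
#'
#' @param g a `static_graph` from [aggregate_static()].
#' @param l1,l2 link keys `"i|j"` (or length-2 character vectors of node
#'   ids) which must share at least one node.
#' @return non-negative integer.
#' @export
compute_w_co <- function(g, l1, l2) {
  as_key <- function(l) {
    if (length(l) == 2L) {
      cp <- canonicalize_pairs(l[1L], l[2L])
      paste(cp$i, cp$j, sep = "|")
    } else l
  }
  k1 <- as_key(l1); k2 <- as_key(l2)
  if (!k1 %in% names(g$timelines) || !k2 %in% names(g$timelines))
    stop("unknown link")
  n1 <- strsplit(k1, "|", fixed = TRUE)[[1L]]
  n2 <- strsplit(k2, "|", fixed = TRUE)[[1L]]
  if (length(intersect(n1, n2)) == 0L)
    stop("links are not adjacent (no shared node)")
  if (k1 == k2) return(length(g$timelines[[k1]]))
  length(intersect(g$timelines[[k1]], g$timelines[[k2]]))
}

#' Build the weighted event graph of a temporal network
#'
#' Events become graph nodes. A directed edge `e1 -> e2` exists when the
#' two events share at least one node, `t1 < t2 <= t1 + delta_t`, and `e2`
#' is the *earliest* such event on its static link (at most one successor
#' per destination link). Each edge carries `w_path = 1/(1 + gap)` and the
#' link-pair co-occurrence count `w_co`. Strict time ordering makes the
#' graph acyclic; it is a temporal line graph coding all time-respecting
#' paths of the contact sequence.
#'
#' @param tn a `temporal_network`.
#' @param delta_t adjacency horizon in snapshots (`>= 1`), or `"full"` for
#'   the whole observation window.
#' @return an object of class `event_graph`: `events` (the network's event
#'   table), `edges` (data.frame `src`, `dst` row indices, `w_path`,
#'   `w_co`), `delta_t`, `n_events`.
#' @export
build_event_graph <- function(tn, delta_t = "full") {
  validate_temporal_network(tn)
  ev <- tn$events
  E <- nrow(ev)
  dt <- if (identical(delta_t, "full")) max(tn$horizon, 1L)
        else as.integer(delta_t)
  if (is.na(dt) || dt < 1L) stop("delta_t must be >= 1 or \"full\"")
  empty <- data.frame(src = integer(), dst = integer(),
                      w_path = numeric(), w_co = numeric())
  if (E < 2L)
    return(structure(list(events = ev, edges = empty, delta_t = dt,
                          n_events = E), class = "event_graph"))

  link_key <- paste(ev$i, ev$j, sep = "|")
  ukey <- unique(link_key)
  lid <- match(link_key, ukey)
  idx_by_link <- split(seq_len(E), lid)        # event rows, ascending t
  t_by_link <- split(ev$t, lid)
  nlink <- length(ukey)
  parts <- strsplit(ukey, "|", fixed = TRUE)
  li <- vapply(parts, `[`, "", 1L); lj <- vapply(parts, `[`, "", 2L)

  # links adjacent to each link (shared node), including the link itself
  by_node <- split(rep(seq_len(nlink), 2L), c(li, lj))
  adj <- vector("list", nlink)
  for (l in seq_len(nlink))
    adj[[l]] <- sort(unique(c(by_node[[li[l]]], by_node[[lj[l]]])))

  # co-occurrence weights per adjacent link pair (shared by all edges on it)
  wco_cache <- new.env(parent = emptyenv())
  wco <- function(l1, l2) {
    if (l1 == l2) return(length(t_by_link[[l1]]))
    k <- paste(min(l1, l2), max(l1, l2))
    v <- wco_cache[[k]]
    if (is.null(v)) {
      v <- length(intersect(t_by_link[[l1]], t_by_link[[l2]]))
      wco_cache[[k]] <- v
    }
    v
  }

  src <- dst <- integer(0); wp <- wc <- numeric(0)
  n_alloc <- 0L
  srcs <- vector("list", E)
  for (e in seq_len(E)) {
    l <- lid[e]; t0 <- ev$t[e]
    cand_dst <- integer(0); cand_wp <- numeric(0); cand_wc <- numeric(0)
    for (l2 in adj[[l]]) {
      tl <- t_by_link[[l2]]
      pos <- findInterval(t0, tl) + 1L     # first index with tl > t0
      if (pos <= length(tl) && tl[pos] - t0 <= dt) {
        gap <- tl[pos] - t0
        cand_dst <- c(cand_dst, idx_by_link[[l2]][pos])
        cand_wp <- c(cand_wp, 1 / (1 + gap))
        cand_wc <- c(cand_wc, wco(l, l2))
      }
    }
    if (length(cand_dst))
      srcs[[e]] <- data.frame(src = e, dst = cand_dst,
                              w_path = cand_wp, w_co = cand_wc)
  }
  keep <- !vapply(srcs, is.null, TRUE)
  edges <- if (any(keep)) do.call(rbind, srcs[keep]) else empty
  rownames(edges) <- NULL
  structure(list(events = ev, edges = edges, delta_t = dt, n_events = E),
            class = "event_graph")
}

resolve_event <- function(g, e) {
  if (is.numeric(e)) {
    e <- as.integer(e)
    if (e < 1L || e > g$n_events) stop("event index out of range")
    return(e)
  }
  idx <- match(e, g$events$token)
  if (is.na(idx)) stop("unknown event: ", e)
  idx
}

#' In- and out-neighborhoods of an event in the event graph
#'
#' Predecessors are earlier adjacent events (in-neighbors), successors
#' later adjacent events (out-neighbors); both come with the edge weights
#' attached.
#'
#' @param g an `event_graph`.
#' @param e an event token `"i|j|t"` or event row index.
#' @return data.frame with columns `event` (token), `index`, `w_path`,
#'   `w_co`.
#' @export
predecessors <- function(g, e) {
  idx <- resolve_event(g, e)
  sel <- g$edges$src[g$edges$dst == idx]
  rows <- g$edges[g$edges$dst == idx, , drop = FALSE]
  data.frame(event = g$events$token[sel], index = sel,
             w_path = rows$w_path, w_co = rows$w_co,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname predecessors
#' @export
successors <- function(g, e) {
  idx <- resolve_event(g, e)
  sel <- g$edges$dst[g$edges$src == idx]
  rows <- g$edges[g$edges$src == idx, , drop = FALSE]
  data.frame(event = g$events$token[sel], index = sel,
             w_path = rows$w_path, w_co = rows$w_co,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export an event graph as a tab-separated edge list
#'
#' Columns: `src`, `dst` (event tokens), `w_path`, `w_co`.
#'
#' @param g an `event_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_graph <- function(g, path) {
  out <- data.frame(src = g$events$token[g$edges$src],
                    dst = g$events$token[g$edges$dst],
                    w_path = g$edges$w_path, w_co = g$edges$w_co)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.event_graph <- function(x, ...) {
  cat("event_graph:", x$n_events, "events,", nrow(x$edges),
      "edges, delta_t =", x$delta_t, "\n")
  invisible(x)
}
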