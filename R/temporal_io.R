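# temporal_io: read/write/validate snapshot-resolved temporal networks

#' Construct a temporal network
#'
#' A temporal network is an ordered collection of undirected, timestamped
#' events `(i, j, t)` with `t` measured in integer snapshot units (the
#' native resolution of proximity-sensor contact data, 20 s by default).
#' Events are canonicalized (`i < j` in the C-locale node order),
#' de-duplicated, sorted by `(t, i, j)` and rebased so the earliest
#' snapshot is 0.
#'
#' @param i,j character vectors of node identifiers.
#' @param t integer vector of snapshot timestamps.
#' @param delta_t_seconds snapshot width in wall-clock seconds (metadata
#'   only; weights and simulations operate in snapshot units).
#' @param nodes optional superset of node identifiers to retain (e.g. to
#'   keep nodes isolated by a shuffle); defaults to the nodes appearing in
#'   the events.
#' @return an object of class `temporal_network` with fields `events`
#'   (data.frame `i`, `j`, `t`, `token`), `nodes`, `delta_t_seconds` and
#'   `horizon` (`max t - min t`).
#' @export
temporal_network <- function(i, j, t, delta_t_seconds = 20, nodes = NULL) {
  i <- as.character(i); j <- as.character(j)
  if (length(i) != length(j) || length(i) != length(t))
    stop("i, j, t must have equal length")
  t <- as.integer(round(t))
  if (any(i == j)) stop("self events are not allowed (i == j)")
  cp <- canonicalize_pairs(i, j)
  i <- cp$i; j <- cp$j
  if (length(t) > 0L) t <- t - min(t)
  ev <- data.frame(i = i, j = j, t = t, stringsAsFactors = FALSE)
  ev <- ev[!duplicated(paste(ev$i, ev$j, ev$t, sep = "|")), , drop = FALSE]
  ev <- ev[event_order(ev$t, ev$i, ev$j), , drop = FALSE]
  rownames(ev) <- NULL
  ev$token <- event_token(ev$i, ev$j, ev$t)
  all_nodes <- sort(unique(c(ev$i, ev$j, as.character(nodes))), method = "radix")
  structure(
    list(
      events = ev,
      nodes = all_nodes,
      delta_t_seconds = delta_t_seconds,
      horizon = if (nrow(ev) > 0L) max(ev$t) - min(ev$t) else 0L
    ),
    class = "temporal_network"
  )
}

#' Validate a temporal network object
#'
#' Checks the structural invariants: canonical undirected storage, no self
#' events, no duplicates, deterministic sort order, non-negative rebased
#' timestamps, node-set consistency.
#'
#' @param tn a `temporal_network`.
#' @return `tn`, invisibly; errors describe the violated invariant.
#' @export
validate_temporal_network <- function(tn) {
  stopifnot(inherits(tn, "temporal_network"))
  ev <- tn$events
  if (any(ev$i == ev$j)) stop("invariant violated: self event present")
  u <- sort(unique(c(ev$i, ev$j)), method = "radix")
  if (nrow(ev) > 0L && any(match(ev$i, u) >= match(ev$j, u)))
    stop("invariant violated: events not stored canonically (i < j)")
  if (anyDuplicated(ev$token)) stop("invariant violated: duplicate events")
  if (nrow(ev) > 0L && min(ev$t) != 0L) stop("invariant violated: min t != 0")
  if (!identical(event_order(ev$t, ev$i, ev$j), seq_len(nrow(ev))) &&
      nrow(ev) > 1L)
    stop("invariant violated: events not sorted by (t, i, j)")
  if (!all(c(ev$i, ev$j) %in% tn$nodes))
    stop("invariant violated: event node missing from node set")
  invisible(tn)
}

#' Read a temporal network from a plain-text event list
#'
#' One event per line, whitespace-separated fields, `#`-prefixed comment
#' lines skipped and trailing extra columns ignored — the common dialect of
#' published face-to-face contact event lists. Raw timestamps are rebased
#' to start at 0 and converted to snapshot units by integer division by the
#' snapshot width.
#'
#' @param path file path.
#' @param column_order `"t_i_j"` (default) or `"i_j_t"`.
#' @param delta_t_seconds snapshot width in seconds used to convert raw
#'   timestamps; `NULL` infers it as the smallest positive gap between
#'   distinct raw timestamps.
#' @return a validated [temporal_network].
#' @export
read_event_list <- function(path, column_order = c("t_i_j", "i_j_t"),
                            delta_t_seconds = 20) {
  column_order <- match.arg(column_order)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty event list: ", path)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed line ", idx[which(nf < 3L)[1L]], ": fewer than 3 fields")
  f1 <- vapply(fields, `[`, "", 1L)
  f2 <- vapply(fields, `[`, "", 2L)
  f3 <- vapply(fields, `[`, "", 3L)
  if (column_order == "t_i_j") {
    traw <- suppressWarnings(as.numeric(f1)); i <- f2; j <- f3
  } else {
    i <- f1; j <- f2; traw <- suppressWarnings(as.numeric(f3))
  }
  if (anyNA(traw))
    stop("malformed line ", idx[which(is.na(traw))[1L]],
         ": non-numeric timestamp")
  if (any(i == j))
    stop("validation error at line ", idx[which(i == j)[1L]],
         ": self event (i == j)")
  if (is.null(delta_t_seconds)) {
    gaps <- diff(sort(unique(traw)))
    delta_t_seconds <- if (length(gaps)) min(gaps) else 1
  }
  if (delta_t_seconds <= 0) stop("delta_t_seconds must be positive")
  snap <- as.integer(floor((traw - min(traw)) / delta_t_seconds))
  temporal_network(i, j, snap, delta_t_seconds = delta_t_seconds)
}

#' Write a temporal network as a plain-text event list
#'
#' Events are written in canonical `(t, i, j)` order, tab-separated,
#' timestamps in snapshot units. `read_event_list(path,
#' delta_t_seconds = 1)` recovers the identical network.
#'
#' @param tn a `temporal_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_list <- function(tn, path) {
  validate_temporal_network(tn)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(paste(tn$events$t, tn$events$i, tn$events$j, sep = "\t"), con)
  invisible(path)
}

#' Aggregate a temporal network into its static graph
#'
#' Two nodes are linked iff they interacted at least once; every link
#' carries its timeline, the sorted list of snapshots in which it fired.
#'
#' @param tn a `temporal_network`.
#' @return an object of class `static_graph` with fields `nodes`, `links`
#'   (data.frame `i`, `j`, `key`) and `timelines` (named list of sorted
#'   integer vectors, one per link key `"i|j"`).
#' @export
aggregate_static <- function(tn) {
  validate_temporal_network(tn)
  ev <- tn$events
  key <- paste(ev$i, ev$j, sep = "|")
  ukey <- unique(key)
  timelines <- lapply(split(ev$t, factor(key, levels = ukey)), sort)
  links <- if (length(ukey)) {
    parts <- strsplit(ukey, "|", fixed = TRUE)
    data.frame(
      i = vapply(parts, `[`, "", 1L),
      j = vapply(parts, `[`, "", 2L),
      key = ukey, stringsAsFactors = FALSE
    )
  } else {
    data.frame(i = character(), j = character(), key = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(nodes = tn$nodes, links = links, timelines = timelines),
            class = "static_graph")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("temporal_network:", nrow(x$events), "events,", length(x$nodes),
      "nodes, horizon", x$horizon, "snapshots",
      sprintf("(%g s each)\n", x$delta_t_seconds))
  invisible(x)
}

#' @export
print.static_graph <- function(x, ...) {
  cat("static_graph:", length(x$nodes), "nodes,", nrow(x$links), "links,",
      sum(lengths(x$timelines)), "events in timelines\n")
  invisible(x)
}
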