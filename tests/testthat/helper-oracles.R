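# Independent oracles used by the equivalence tests. These re-derive the
# expected results by different algorithms than the package implements
# (brute-force double loops, event-relaxation closures), on small inputs.

# O(E^2) brute-force event graph: all ordered pairs, adjacency + earliest-
# per-destination-link filtering; weights recomputed from first principles.
oracle_event_graph <- function(tn, delta_t = "full") {
  ev <- tn$events
  E <- nrow(ev)
  dt <- if (identical(delta_t, "full")) max(tn$horizon, 1L) else delta_t
  link <- paste(ev$i, ev$j, sep = "|")
  # timeline timestamp sets per link for w_co, by an independent route
  tl <- split(ev$t, link)
  edges <- list()
  for (a in seq_len(E)) {
    # candidate successors grouped by destination link, keep earliest
    cand <- data.frame(dst = integer(), gap = integer(), dlink = character())
    for (b in seq_len(E)) {
      if (ev$t[b] <= ev$t[a]) next
      if (ev$t[b] - ev$t[a] > dt) next
      if (length(intersect(c(ev$i[a], ev$j[a]), c(ev$i[b], ev$j[b]))) == 0L) next
      cand <- rbind(cand, data.frame(dst = b, gap = ev$t[b] - ev$t[a],
                                     dlink = link[b]))
    }
    if (nrow(cand) == 0L) next
    for (dl in unique(cand$dlink)) {
      sub <- cand[cand$dlink == dl, , drop = FALSE]
      best <- sub[which.min(sub$gap), ]
      wco <- if (link[a] == dl) length(tl[[dl]])
             else length(intersect(tl[[link[a]]], tl[[dl]]))
      edges[[length(edges) + 1L]] <-
        data.frame(src = a, dst = best$dst, w_path = 1 / (1 + best$gap),
                   w_co = wco)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(src = integer(), dst = integer(),
                         w_path = numeric(), w_co = numeric())
  out[order(out$src, out$dst), , drop = FALSE]
}

# SI final size by repeated relaxation over the event list (Bellman-Ford
# style fixed point, no chronological sweep): a node infected at time t_u
# transmits at any event with t > t_u, or t == t_u unless t_u is the seed
# time itself (seed endpoints transmit strictly later only).
oracle_si_size <- function(tn, seed_idx) {
  ev <- tn$events
  t0 <- ev$t[seed_idx]
  inf_time <- setNames(rep(Inf, length(tn$nodes)), tn$nodes)
  inf_time[c(ev$i[seed_idx], ev$j[seed_idx])] <- t0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(ev))) {
      u <- ev$i[k]; v <- ev$j[k]; t <- ev$t[k]
      can_u <- inf_time[u] < t || (inf_time[u] == t && inf_time[u] > t0)
      can_v <- inf_time[v] < t || (inf_time[v] == t && inf_time[v] > t0)
      if (can_u && t < inf_time[v]) { inf_time[v] <- t; changed <- TRUE }
      if (can_v && t < inf_time[u]) { inf_time[u] <- t; changed <- TRUE }
    }
    if (!changed) break
  }
  sum(is.finite(inf_time))
}

# Eq.-style mixing probabilities recomputed directly from a neighbor table
oracle_mix_probs <- function(w_path, w_co, alpha) {
  fp <- w_path / sum(w_path)
  fc <- if (sum(w_co) > 0) w_co / sum(w_co) else rep(1 / length(w_co), length(w_co))
  p <- alpha * fp + (1 - alpha) * fc
  p / sum(p)
}

# 4-sigma multinomial bound check: counts of N draws vs probabilities p
expect_multinomial_close <- function(counts, p, N) {
  expect_equal(sum(counts), N)
  bound <- 4 * sqrt(N * p * (1 - p))
  expect_true(all(abs(counts - N * p) <= pmax(bound, 4)),
              label = paste("multinomial 4-sigma check; max dev",
                            max(abs(counts - N * p) / pmax(bound, 1e-12))))
}

# small hand-made network used across files
tiny_network <- function() {
  # A=(a,b,0) B=(b,c,1) C=(b,c,3) D=(c,d,4) E=(a,d,6)
  temporal_network(c("a", "b", "b", "c", "a"),
                   c("b", "c", "c", "d", "d"),
                   c(0, 1, 3, 4, 6))
}

# best label-permutation accuracy for planted-structure recovery
match_accuracy <- function(pred, truth) {
  k <- max(truth)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (x in seq_along(v))
      for (rest in perms(v[-x])) out[[length(out) + 1L]] <- c(v[x], rest)
    out
  }
  best <- 0
  for (pm in perms(seq_len(k))) {
    acc <- mean(pm[pred] == truth)
    if (acc > best) best <- acc
  }
  best
}
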