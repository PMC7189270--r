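sorted_timelines <- function(tn) {
  tls <- aggregate_static(tn)$timelines
  sort(unname(vapply(tls, paste, "", collapse = ",")))
}

test_that("snapshot shuffling preserves structure and activity, moves timestamps", {
  tn <- make_planted_communities(2, 6, 10, p_in = 0.4, p_out = 0.05, seed = 1)
  sh <- snapshot_shuffle(tn, seed = 11)
  validate_temporal_network(sh)
  expect_equal(nrow(sh$events), nrow(tn$events))
  expect_equal(sort(sh$events$t), sort(tn$events$t))      # timestamp multiset
  expect_setequal(aggregate_static(sh)$links$key,
                  aggregate_static(tn)$links$key)
  # per-link event counts conserved
  expect_equal(sort(unname(lengths(aggregate_static(sh)$timelines))),
               sort(unname(lengths(aggregate_static(tn)$timelines))))
  # with high probability some event moved
  expect_false(identical(sh$events$token, tn$events$token))
  # deterministic under seed
  expect_identical(snapshot_shuffle(tn, seed = 11)$events, sh$events)
})

test_that("timeline shuffling permutes whole timelines over a fixed static graph", {
  tn <- make_planted_communities(2, 6, 10, p_in = 0.4, p_out = 0.05, seed = 2)
  sh <- timeline_shuffle(tn, seed = 5)
  validate_temporal_network(sh)
  expect_setequal(aggregate_static(sh)$links$key,
                  aggregate_static(tn)$links$key)
  expect_identical(sorted_timelines(sh), sorted_timelines(tn))
  # single-link network is a fixed point
  single <- temporal_network(c("a", "a"), c("b", "b"), c(0, 3))
  expect_identical(timeline_shuffle(single, seed = 1)$events, single$events)
})

test_that("link shuffling redraws the static graph, keeps timeline contents", {
  tn <- make_planted_communities(2, 6, 10, p_in = 0.4, p_out = 0.05, seed = 3)
  sh <- link_shuffle(tn, seed = 7)
  validate_temporal_network(sh)
  expect_equal(nrow(aggregate_static(sh)$links),
               nrow(aggregate_static(tn)$links))
  expect_equal(nrow(sh$events), nrow(tn$events))
  expect_identical(sorted_timelines(sh), sorted_timelines(tn))
  expect_identical(sh$nodes, tn$nodes)           # node set kept
})

test_that("link shuffle degree variance matches the G(n,m) closed form", {
  # star: all timelines hang off one hub, maximally non-random structure
  n <- 12L
  hub <- "n001"
  leaves <- sprintf("n%03d", 2:n)
  tn <- temporal_network(rep(hub, n - 1L), leaves, seq_len(n - 1L) - 1L)
  m <- n - 1L
  M <- n * (n - 1) / 2
  p <- m / M
  p2 <- m * (m - 1) / (M * (M - 1))
  var_closed <- (n - 1) * p * (1 - p) + (n - 1) * (n - 2) * (p2 - p^2)
  stat <- vapply(1:200, function(seed) {
    sh <- link_shuffle(tn, seed = seed)
    deg <- table(factor(c(aggregate_static(sh)$links$i,
                          aggregate_static(sh)$links$j), levels = sh$nodes))
    mean((as.numeric(deg) - 2 * m / n)^2)
  }, 0)
  se <- stats::sd(stat) / sqrt(length(stat))
  expect_lt(abs(mean(stat) - var_closed), 3 * se + 1e-12)
})

test_that("all shuffles feed the downstream pipeline unchanged in contract", {
  tn <- make_random_events(8, 40, 30, seed = 9)
  for (sh in list(snapshot_shuffle(tn, 1), timeline_shuffle(tn, 1),
                  link_shuffle(tn, 1))) {
    g <- build_event_graph(sh)
    expect_s3_class(g, "event_graph")
    sizes <- epidemic_sizes_all_seeds(sh)
    expect_true(all(sizes >= 2 & sizes <= length(sh$nodes)))
  }
})
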