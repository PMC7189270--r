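test_that("mixing probabilities implement the two-term weighted mix", {
  # hand-built graph: center event 1 with two out-neighbors
  g <- structure(list(
    events = data.frame(i = c("a", "b", "a"), j = c("b", "c", "c"),
                        t = c(0L, 1L, 1L),
                        token = c("a|b|0", "b|c|1", "a|c|1"),
                        stringsAsFactors = FALSE),
    edges = data.frame(src = c(1L, 1L), dst = c(2L, 3L),
                       w_path = c(0.5, 0.5), w_co = c(1, 3)),
    delta_t = 10L, n_events = 3L), class = "event_graph")
  # alpha = 0.5: p = (0.5*0.5 + 0.5*0.25, 0.5*0.5 + 0.5*0.75)
  p <- sampling_probabilities(g, "a|b|0", alpha = 0.5)
  expect_equal(unname(p), c(0.375, 0.625))
  # alpha = 1 depends on w_path only (here equal)
  expect_equal(unname(sampling_probabilities(g, 1, alpha = 1)), c(0.5, 0.5))
  # alpha = 0 depends on w_co only
  expect_equal(unname(sampling_probabilities(g, 1, alpha = 0)),
               c(0.25, 0.75))
  # single neighbor -> p = 1 regardless of alpha
  expect_equal(unname(sampling_probabilities(g, 2, alpha = 0.3,
                                             mode = "predecessors_only")), 1)
  # empty neighborhood -> sentinel NULL
  expect_null(sampling_probabilities(g, 1, mode = "predecessors_only"))
})

test_that("probabilities normalize, are affine in alpha, and honor the 0/0 guard", {
  tn <- make_random_events(8, 50, 30, seed = 5)
  g <- build_event_graph(tn)
  for (e in seq_len(g$n_events)) {
    p0 <- sampling_probabilities(g, e, alpha = 0)
    p5 <- sampling_probabilities(g, e, alpha = 0.5)
    p1 <- sampling_probabilities(g, e, alpha = 1)
    if (is.null(p1)) next
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(unname(p5), unname((p0 + p1) / 2), tolerance = 1e-12)
  }
  # all-zero w_co neighborhood: alpha = 0 must give uniform
  chain <- make_chain(5)
  gc <- build_event_graph(chain)
  p <- sampling_probabilities(gc, "v0002|v0003|1", alpha = 0)
  expect_equal(unname(p), rep(1 / length(p), length(p)))
})

test_that("sample_environments respects counts, determinism and mode", {
  tn <- make_random_events(8, 40, 25, seed = 9)
  g <- build_event_graph(tn)
  cfg <- sampling_config(alpha = 0.5, nb = 3, s = 7, seed = 42)
  envs <- sample_environments(g, cfg)
  n_active <- g$n_events - length(attr(envs, "skipped"))
  expect_length(envs, 3L * n_active)
  expect_true(all(lengths(envs) == 8L))          # center + s
  # deterministic under the same seed
  envs2 <- sample_environments(g, cfg)
  expect_identical(unclass(envs), unclass(envs2))
  # every context member is a first neighbor of its center
  for (k in sample(seq_along(envs), 10)) {
    ctr <- envs[[k]][1L]
    nbrs <- c(predecessors(g, ctr)$event, successors(g, ctr)$event)
    expect_true(all(envs[[k]][-1L] %in% nbrs))
  }
  # predecessors_only never samples the future
  cfgp <- sampling_config(mode = "predecessors_only", nb = 2, s = 5, seed = 1)
  envp <- sample_environments(g, cfgp)
  for (env in envp) {
    tc <- parse_event_token(env[1L])$t
    expect_true(all(parse_event_token(env[-1L])$t < tc))
  }
})

test_that("an event with one neighbor fills every context slot with it", {
  tn <- temporal_network(c("a", "b"), c("b", "c"), c(0, 1))
  g <- build_event_graph(tn)
  envs <- sample_environments(g, sampling_config(nb = 2, s = 4, seed = 3))
  expect_length(envs, 4L)                        # both events have 1 neighbor
  expect_true(all(vapply(envs, function(e)
    length(unique(e[-1L])) == 1L, TRUE)))
})

test_that("corpus export writes one environment per line", {
  tn <- make_chain(6)
  g <- build_event_graph(tn)
  envs <- sample_environments(g, sampling_config(nb = 2, s = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_corpus(envs, path)
  lines <- readLines(path)
  expect_length(lines, length(envs))
  expect_equal(strsplit(lines[1], " ")[[1]], envs[[1]])
})
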