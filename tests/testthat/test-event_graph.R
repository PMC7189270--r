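test_that("w_path follows the inverse-gap formula", {
  expect_equal(compute_w_path(0, 1), 0.5)
  expect_equal(compute_w_path(3, 4), 0.5)        # gap invariance
  expect_equal(compute_w_path(0, 9), 0.1)
  expect_error(compute_w_path(2, 2), "t2 > t1")
})

test_that("w_co counts shared snapshots of adjacent links", {
  tn <- temporal_network(rep(c("a", "b"), c(3, 3)), rep(c("b", "c"), c(3, 3)),
                         c(0, 2, 5, 2, 5, 7))
  g <- aggregate_static(tn)
  expect_equal(compute_w_co(g, "a|b", "b|c"), 2L)  # shared {2, 5}
  expect_equal(compute_w_co(g, "a|b", "a|b"), 3L)  # same-link convention
  tn2 <- temporal_network(c("a", "b"), c("b", "c"), c(0, 4))
  expect_equal(compute_w_co(aggregate_static(tn2), "a|b", "b|c"), 0L)
  tn3 <- temporal_network(c("a", "c"), c("b", "d"), c(0, 1))
  expect_error(compute_w_co(aggregate_static(tn3), "a|b", "c|d"),
               "not adjacent")
})

test_that("earliest-successor rule picks one edge per destination link", {
  # A=(a,b,0), B=(b,c,1), C=(b,c,3): A->B and B->C, but no A->C
  tn <- temporal_network(c("a", "b", "b"), c("b", "c", "c"), c(0, 1, 3))
  g <- build_event_graph(tn)
  ed <- g$edges[order(g$edges$src, g$edges$dst), ]
  expect_equal(unname(cbind(ed$src, ed$dst)), rbind(c(1, 2), c(2, 3)))
  # no shared node -> no edge
  tn2 <- temporal_network(c("a", "c"), c("b", "d"), c(0, 1))
  expect_equal(nrow(build_event_graph(tn2)$edges), 0L)
  # fewer than 2 events -> edgeless graph
  expect_equal(nrow(build_event_graph(
    temporal_network("a", "b", 0))$edges), 0L)
})

test_that("event graph equals the brute-force oracle (weights included)", {
  for (seed in 1:25) {
    n_ev <- sample(5:30, 1)
    tn <- make_random_events(8, n_ev, sample(10:40, 1), seed = seed)
    for (dt in list("full", 3L)) {
      got <- build_event_graph(tn, dt)$edges
      got <- got[order(got$src, got$dst), ]
      want <- oracle_event_graph(tn, dt)
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                   tolerance = 1e-12,
                   label = paste("seed", seed, "dt", dt))
    }
  }
})

test_that("DAG property and horizon monotonicity hold", {
  tn <- make_random_events(10, 60, 40, seed = 11)
  g <- build_event_graph(tn)
  expect_true(all(tn$events$t[g$edges$dst] > tn$events$t[g$edges$src]))
  # every edge at horizon h1 with gap <= h1 also appears at h2 >= h1
  g3 <- build_event_graph(tn, 3L)
  g9 <- build_event_graph(tn, 9L)
  key <- function(e) paste(e$src, e$dst)
  expect_true(all(key(g3$edges) %in% key(g9$edges)))
})

test_that("predecessors/successors expose weighted neighborhoods", {
  tn <- temporal_network(c("a", "b", "b"), c("b", "c", "c"), c(0, 1, 3))
  g <- build_event_graph(tn)
  expect_equal(predecessors(g, "b|c|1")$event, "a|b|0")
  expect_equal(successors(g, "b|c|1")$event, "b|c|3")
  expect_equal(nrow(predecessors(g, "a|b|0")), 0L)   # first event
  expect_error(predecessors(g, "x|y|0"), "unknown event")
  # handshake identity
  tot <- sum(vapply(seq_len(g$n_events),
                    function(k) nrow(successors(g, k)), 0L))
  expect_equal(tot, nrow(g$edges))
})

test_that("edge-list export carries tokens and both weights", {
  tn <- tiny_network()
  g <- build_event_graph(tn)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_graph(g, path)
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(out), nrow(g$edges))
  expect_named(out, c("src", "dst", "w_path", "w_co"))
  expect_true(all(out$src %in% tn$events$token))
})
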