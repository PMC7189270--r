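test_that("contact tensor is binary, symmetric and slice-consistent", {
  tn <- make_random_events(6, 30, 15, seed = 1)
  ct <- build_contact_tensor(tn)
  X <- ct$data
  expect_equal(sum(X), 2 * nrow(tn$events))        # both orientations
  expect_true(all(X %in% c(0, 1)))
  expect_equal(X, aperm(X, c(2, 1, 3)))            # node-mode symmetry
  # one slice equals that snapshot's adjacency matrix
  t0 <- tn$events$t[1]
  snap <- tn$events[tn$events$t == t0, ]
  A <- matrix(0, length(tn$nodes), length(tn$nodes))
  A[cbind(match(snap$i, tn$nodes), match(snap$j, tn$nodes))] <- 1
  expect_equal(X[, , t0 + 1], A + t(A))
  # empty network -> all-zero tensor
  expect_equal(sum(build_contact_tensor(
    temporal_network(character(), character(), integer()))$data), 0)
})

test_that("an exact rank-1 tensor is recovered with perfect core consistency", {
  # planted outer product a o a o g, strictly positive
  a <- c(0.2, 0.9, 0.4, 0.7, 0.1)
  g <- c(1, 0.5, 0.25, 0.8)
  ct <- structure(list(data = outer(outer(a, a), g),
                       nodes = sprintf("n%03d", 1:5), times = 0:3),
                  class = "contact_tensor")
  m <- decompose_tensor(ct, 1, seed = 1, n_iter = 1000, tol = 1e-12)
  expect_gt(m$fit, 0.999)                          # reconstruction ~ exact
  expect_equal(core_consistency(ct, m), 100, tolerance = 1e-3)
  # rank-1 model labels every event 1
  tn <- make_random_events(5, 12, 4, seed = 2)
  m2 <- decompose_tensor(build_contact_tensor(tn), 1, seed = 1)
  expect_equal(unname(assign_components(m2, tn)), rep(1L, 12))
})

test_that("planted structures are recovered and rank selected correctly", {
  tn <- make_planted_communities(3, 8, 12, p_in = 0.6, p_out = 0.01,
                                 seed = 5)
  ct <- build_contact_tensor(tn)
  m <- decompose_tensor(ct, 3, seed = 5)
  expect_true(all(m$node_factors >= 0) && all(m$time_factors >= 0))
  expect_equal(sqrt(colSums(m$node_factors^2)), rep(1, 3),
               tolerance = 1e-8)                   # unit-norm columns
  lab <- assign_components(m, tn)
  expect_true(all(lab %in% 1:3))
  expect_gt(match_accuracy(unname(lab), unname(attr(tn, "labels"))), 0.85)
  sel <- select_rank(ct, ranks = 2:5, seed = 5)
  expect_equal(sel$rank, 3L)
  expect_true(all(sel$diagnostics$core_consistency <= 100))
})

test_that("permuting node labels permutes the fit equivariantly", {
  tn <- make_planted_communities(2, 5, 8, p_in = 0.5, p_out = 0.02, seed = 7)
  ct <- build_contact_tensor(tn)
  m <- decompose_tensor(ct, 2, seed = 3)
  # rename nodes by a cyclic map; refit with identical seeds
  map <- setNames(c(tn$nodes[-1], tn$nodes[1]), tn$nodes)
  tn2 <- temporal_network(unname(map[tn$events$i]), unname(map[tn$events$j]),
                          tn$events$t)
  m2 <- decompose_tensor(build_contact_tensor(tn2), 2, seed = 3)
  expect_equal(m2$fit, m$fit, tolerance = 0.05)
  expect_equal(sort(m2$lambda), sort(m$lambda), tolerance = 0.2)
})

test_that("component labels export as TSV", {
  tn <- make_planted_communities(2, 5, 6, p_in = 0.5, p_out = 0, seed = 9)
  ct <- build_contact_tensor(tn)
  lab <- assign_components(decompose_tensor(ct, 2, seed = 1), tn)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_components(lab, path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tab), nrow(tn$events))
  expect_true(all(tab$component %in% 1:2))
})
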