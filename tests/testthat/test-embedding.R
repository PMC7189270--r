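toy_corpus <- function(n = 1000, seed = 1) {
  # two disjoint 3-token sentences: A,B always co-occur (sharing context
  # C); D,E,F never appear with them
  c(replicate(n, c("A", "B", "C"), simplify = FALSE),
    replicate(n, c("D", "E", "F"), simplify = FALSE))
}

test_that("training produces vectors of the requested shape, deterministically", {
  corpus <- toy_corpus(50)
  emb <- train_embedding(corpus, d = 16, seed = 7)
  expect_equal(ncol(emb$vectors), 16L)
  expect_setequal(rownames(emb$vectors), c("A", "B", "C", "D", "E", "F"))
  emb2 <- train_embedding(corpus, d = 16, seed = 7)
  expect_identical(emb$vectors, emb2$vectors)     # bit reproducible
  emb3 <- train_embedding(corpus, d = 16, seed = 8)
  expect_false(identical(emb$vectors, emb3$vectors))
  expect_error(train_embedding(list(), 4), "empty corpus")
  expect_error(train_embedding(corpus, 0), ">= 1")
})

test_that("co-occurring tokens end up closer than never-co-occurring ones", {
  wins <- 0L
  for (seed in 1:10) {
    emb <- train_embedding(toy_corpus(1000, seed), d = 8, seed = seed)
    cos <- function(a, b) {
      va <- emb$vectors[a, ]; vb <- emb$vectors[b, ]
      sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    }
    wins <- wins + (cos("A", "B") > cos("A", "D"))
  }
  expect_gte(wins, 6L)                            # majority over 10 seeds
})

test_that("euclidean distance is a metric on embedded events", {
  emb <- structure(list(
    vectors = rbind(a = c(0, 0), b = c(3, 4), c = c(3, 4)),
    dimension = 2L, params = list()), class = "event_embedding")
  expect_equal(euclidean_distance(emb, "a", "b"), 5)
  expect_equal(euclidean_distance(emb, "b", "a"), 5)
  expect_equal(euclidean_distance(emb, "a", "a"), 0)
  expect_equal(euclidean_distance(emb, "b", "c"), 0)  # zero iff identical
  expect_error(euclidean_distance(emb, "a", "zz"), "not in embedding")
})

test_that("word2vec text format round-trips", {
  emb <- train_embedding(toy_corpus(20), d = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".w2v")
  write_embedding(emb, path)
  hdr <- strsplit(readLines(path, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(nrow(emb$vectors), 5L))
  back <- read_embedding(path)
  expect_equal(back$vectors[rownames(emb$vectors), ], emb$vectors,
               tolerance = 1e-12)
})

test_that("temporally separated communities separate in the embedding", {
  # two node-disjoint groups active in disjoint windows; means over 5 seeds
  intra <- inter <- numeric(0)
  for (seed in 1:5) {
    tn <- make_planted_communities(2, 8, 10, p_in = 0.25, p_out = 0,
                                   seed = seed)
    g <- build_event_graph(tn)
    corpus <- sample_environments(g, sampling_config(nb = 5, s = 5,
                                                     seed = seed))
    emb <- train_embedding(corpus, d = 8, seed = seed)
    lab <- attr(tn, "labels")[rownames(emb$vectors)]
    D <- as.matrix(stats::dist(emb$vectors))
    same <- outer(lab, lab, "==") & upper.tri(D)
    diff <- outer(lab, lab, "!=") & upper.tri(D)
    intra <- c(intra, mean(D[same])); inter <- c(inter, mean(D[diff]))
  }
  expect_lt(mean(intra), mean(inter))
})

test_that("linked events sit closer than random event pairs", {
  tn <- make_planted_communities(2, 8, 10, p_in = 0.25, p_out = 0.02,
                                 seed = 4)
  g <- build_event_graph(tn)
  corpus <- sample_environments(g, sampling_config(nb = 5, s = 5, seed = 4))
  emb <- train_embedding(corpus, d = 8, seed = 4)
  tok <- rownames(emb$vectors)
  idx <- match(tok, g$events$token)
  D <- as.matrix(stats::dist(emb$vectors))
  ed <- g$edges[g$events$token[g$edges$src] %in% tok &
                g$events$token[g$edges$dst] %in% tok, ]
  linked <- D[cbind(match(g$events$token[ed$src], tok),
                    match(g$events$token[ed$dst], tok))]
  rnd <- withr::with_seed(1, D[cbind(sample(nrow(D), 2000, TRUE),
                                     sample(nrow(D), 2000, TRUE))])
  expect_lt(mean(linked), mean(rnd[rnd > 0]))
})
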