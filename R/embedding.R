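# embedding: Skip-Gram training on the environment corpus
#
# Defaults target the corpus sizes this package actually sees (nb * E
# sentences, typically 10^3-10^5 tokens): 15 negative samples — the
# word2vec recommendation for small training sets; the large-corpus
# value 5 demonstrably under-separates events here — and 5 epochs.

#' Train a Skip-Gram embedding of events
#'
#' Each environment is one training sentence (center token followed by its
#' context tokens); the default window spans the whole sentence so every
#' context token co-occurs with its center. Training uses
#' skip-gram-with-negative-sampling, single-threaded with its own seeded
#' RNG, so identical inputs give identical vectors.
#'
#' Hyper-parameter defaults: 15 negative samples (the word2vec
#' small-dataset recommendation; event corpora have small vocabularies),
#' 5 epochs, initial learning rate 0.025 (linear decay), `min_count = 1`
#' since every event token is meaningful.
#'
#' @param corpus list of character sentences from [sample_environments()]
#'   (or any list of token vectors).
#' @param d embedding dimension (`>= 2` recommended).
#' @param window context window half-width; `NULL` (default) uses the
#'   longest sentence length, i.e. the full environment.
#' @param negative number of negative samples per positive pair.
#' @param epochs training passes over the corpus.
#' @param learning_rate initial learning rate (decays linearly to 1e-4 of
#'   its value).
#' @param min_count minimum token frequency to enter the vocabulary.
#' @param seed integer training seed.
#' @param vectors which trained matrix to expose: the `"input"` vectors
#'   (default, the conventional word2vec choice) or the `"average"` of
#'   input and output vectors.
#' @return an `event_embedding`: `vectors` (matrix, one row per token),
#'   `dimension`, `params`.
#' @export
train_embedding <- function(corpus, d, window = NULL, negative = 15L,
                            epochs = 5L, learning_rate = 0.025,
                            min_count = 1L, seed = 1L,
                            vectors = c("input", "average")) {
  if (length(corpus) == 0L) stop("empty corpus")
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("embedding dimension must be >= 1")
  toks <- unlist(corpus, use.names = FALSE)
  tab <- table(toks)
  vocab <- names(tab)[tab >= min_count]
  if (length(vocab) == 0L) stop("no token reaches min_count")
  counts <- as.numeric(tab[vocab])
  sents <- lapply(corpus, function(s) {
    m <- match(s, vocab)
    m[!is.na(m)] - 1L
  })
  sents <- sents[lengths(sents) >= 2L]
  if (length(sents) == 0L) stop("no trainable sentence after min_count filtering")
  if (is.null(window)) window <- max(lengths(sents))
  vectors <- match.arg(vectors)
  fit <- sgns_train(sents, length(vocab), counts, d, as.integer(window),
                    as.integer(negative), as.integer(epochs), learning_rate,
                    learning_rate * 1e-4, as.integer(seed))
  M <- switch(vectors,
              input = fit$input,
              average = (fit$input + fit$output) / 2)
  rownames(M) <- vocab
  structure(
    list(vectors = M, dimension = d,
         params = list(window = as.integer(window),
                       negative_samples = as.integer(negative),
                       epochs = as.integer(epochs),
                       initial_learning_rate = learning_rate,
                       min_count = as.integer(min_count),
                       seed = as.integer(seed))),
    class = "event_embedding"
  )
}

embedding_vector <- function(emb, token) {
  idx <- match(token, rownames(emb$vectors))
  if (anyNA(idx)) stop("token not in embedding: ", token[is.na(idx)][1L])
  emb$vectors[idx, , drop = FALSE]
}

#' Euclidean distance between two embedded events
#'
#' @param emb an `event_embedding`.
#' @param a,b event tokens.
#' @return non-negative numeric.
#' @export
euclidean_distance <- function(emb, a, b) {
  va <- embedding_vector(emb, a); vb <- embedding_vector(emb, b)
  sqrt(sum((va - vb)^2))
}

#' Save / load an embedding in word2vec text format
#'
#' Header line `"<n_tokens> <d>"`, then one `"token v1 ... vd"` line per
#' token.
#'
#' @param emb an `event_embedding`.
#' @param path file path.
#' @return `path` invisibly (write) or an `event_embedding` (read).
#' @export
write_embedding <- function(emb, path) {
  M <- emb$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(M), ncol(M)), con)
  writeLines(paste(rownames(M),
                   apply(M, 1L, function(v)
                     paste(sprintf("%.17g", v), collapse = " "))), con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  n <- hd[1L]; d <- hd[2L]
  parts <- strsplit(lines[1L + seq_len(n)], " ", fixed = TRUE)
  M <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(M) <- vapply(parts, `[`, "", 1L)
  structure(list(vectors = M, dimension = d, params = list()),
            class = "event_embedding")
}

#' @export
print.event_embedding <- function(x, ...) {
  cat("event_embedding:", nrow(x$vectors), "events, d =", x$dimension, "\n")
  invisible(x)
}
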