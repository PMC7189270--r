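# dim_select: entropy-based choice of the embedding dimension
#
# Rationale: past the optimal dimension, extra coordinates code redundant
# information, so pairwise euclidean distances stop moving between
# independent training realisations. The fluctuation of each pair's
# distance across realisations is summarized by a Shannon entropy; the
# curve of mean entropy against d stabilizes at the optimum.

#' Pairwise distances of consecutive event blocks across realisations
#'
#' Trains `realisations` independent embeddings (fresh sampling and
#' training seeds) for every dimension, splits the canonical event
#' sequence into `n_samples` consecutive blocks of `sample_size`
#' consecutive embedded events, and records all within-block pairwise
#' euclidean distances.
#'
#' @param tn a `temporal_network`.
#' @param dims increasing vector of dimensions to probe.
#' @param realisations embeddings per dimension.
#' @param sample_size events per block (blocks shrink, with a warning,
#'   when the network is smaller than `n_samples * sample_size`).
#' @param n_samples number of consecutive blocks.
#' @param alpha,nb,s,mode,delta_t sampling parameters (see
#'   [sampling_config()] and [build_event_graph()]).
#' @param seed base seed; per-(dimension, realisation) seeds derive from it.
#' @param ... further arguments to [train_embedding()] (epochs, window, ...).
#' @return list with `dims`, `blocks` (token vectors), and `distances`
#'   `[[dim]][[realisation]][[block]]` numeric vectors in a fixed pair
#'   order, plus the `global_range` over everything.
#' @export
pairwise_distance_tensor <- function(tn, dims = seq(2L, 100L, 2L),
                                     realisations = 10L, sample_size = 1000L,
                                     n_samples = 10L, alpha = 0.5, nb = 10L,
                                     s = 10L, mode = "combined",
                                     delta_t = "full", seed = 1L, ...) {
  g <- build_event_graph(tn, delta_t)
  # events that will be embedded (nonempty neighborhood, fixed across runs)
  ed <- g$edges
  embedded <- if (mode == "combined") sort(unique(c(ed$src, ed$dst)))
              else sort(unique(ed$dst))  # needs at least one predecessor
  tokens <- g$events$token[embedded]
  n <- length(tokens)
  if (n < 2L) stop("not enough embedded events for distance sampling")
  if (n < n_samples * sample_size) {
    sample_size <- max(2L, n %/% n_samples)
    warning("shrinking blocks to ", sample_size, " events")
  }
  n_blocks <- min(n_samples, n %/% sample_size)
  blocks <- lapply(seq_len(n_blocks), function(b)
    tokens[((b - 1L) * sample_size + 1L):(b * sample_size)])

  distances <- vector("list", length(dims))
  for (di in seq_along(dims)) {
    d <- dims[di]
    distances[[di]] <- vector("list", realisations)
    for (r in seq_len(realisations)) {
      run_seed <- (as.numeric(seed) * 1000 + di * 101 + r) %% 2^31
      corpus <- sample_environments(
        g, sampling_config(alpha = alpha, nb = nb, s = s, mode = mode,
                           seed = run_seed))
      emb <- train_embedding(corpus, d = d, seed = run_seed, ...)
      distances[[di]][[r]] <- lapply(blocks, function(bl) {
        V <- emb$vectors[match(bl, rownames(emb$vectors)), , drop = FALSE]
        as.numeric(stats::dist(V))
      })
    }
  }
  rng <- range(unlist(distances), finite = TRUE)
  list(dims = dims, blocks = blocks, distances = distances,
       global_range = rng)
}

#' Shannon entropy of a set of distances over fixed bins
#'
#' Bins `values` into the histogram defined by `bin_edges` (10 bins over
#' the *global* distance range of the whole experiment) and returns
#' `H = -sum(p_k log p_k)` with natural logarithm and `0 log 0 := 0`.
#' A degenerate global range puts all mass in one bin, giving `H = 0`.
#'
#' @param values nonempty numeric vector of distances.
#' @param bin_edges increasing vector of `k + 1` edges.
#' @return entropy in `[0, log(k)]`.
#' @export
distance_entropy <- function(values, bin_edges) {
  if (length(values) == 0L) stop("empty distance set")
  k <- length(bin_edges) - 1L
  if (k < 1L || diff(range(bin_edges)) == 0) return(0)
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  shannon_entropy(tabulate(idx, nbins = k) / length(values))
}

# entropy per row of a (pairs x realisations) distance matrix, vectorized
row_entropies <- function(D, bin_edges) {
  k <- length(bin_edges) - 1L
  idx <- findInterval(D, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  dim(idx) <- dim(D)
  R <- ncol(D)
  counts <- vapply(seq_len(k), function(b) rowSums(idx == b),
                   numeric(nrow(D)))
  P <- counts / R
  H <- -rowSums(ifelse(P > 0, P * log(P), 0))
  H
}

#' Entropy stability curve over embedding dimensions
#'
#' For every dimension, each selected event pair contributes the entropy
#' of its distance distribution over the `realisations` independent
#' embeddings (histogram of 10 bins spanning the global distance range);
#' pair entropies are averaged within each block, and the block means give
#' the per-dimension mean and variance. The optimal dimension is where the
#' mean curve first crosses its best-fitting horizontal line.
#'
#' @inheritParams pairwise_distance_tensor
#' @param bins histogram bin count (10 by default).
#' @return an `entropy_curve`: `dimensions`, `mean_entropy`, `var_entropy`,
#'   `optimal_d`, `bin_edges`.
#' @export
entropy_curve <- function(tn, dims = seq(2L, 100L, 2L), realisations = 10L,
                          sample_size = 1000L, n_samples = 10L, alpha = 0.5,
                          nb = 10L, s = 10L, mode = "combined",
                          delta_t = "full", seed = 1L, bins = 10L, ...) {
  pdt <- pairwise_distance_tensor(tn, dims = dims, realisations = realisations,
                                  sample_size = sample_size,
                                  n_samples = n_samples, alpha = alpha,
                                  nb = nb, s = s, mode = mode,
                                  delta_t = delta_t, seed = seed, ...)
  edges <- seq(pdt$global_range[1L], pdt$global_range[2L],
               length.out = bins + 1L)
  n_blocks <- length(pdt$blocks)
  mean_H <- var_H <- numeric(length(dims))
  for (di in seq_along(dims)) {
    block_means <- vapply(seq_len(n_blocks), function(b) {
      D <- vapply(seq_len(realisations),
                  function(r) pdt$distances[[di]][[r]][[b]],
                  numeric(length(pdt$distances[[di]][[1L]][[b]])))
      mean(row_entropies(D, edges))
    }, 0)
    mean_H[di] <- mean(block_means)
    var_H[di] <- if (n_blocks > 1L) stats::var(block_means) else 0
  }
  opt <- if (length(pdt$dims) >= 3L) optimal_dimension(pdt$dims, mean_H)
         else NA_integer_  # crossing rule needs at least 3 points
  structure(
    list(dimensions = pdt$dims, mean_entropy = mean_H, var_entropy = var_H,
         optimal_d = opt, bin_edges = edges),
    class = "entropy_curve"
  )
}

#' Optimal dimension from a mean-entropy curve
#'
#' The best least-squares horizontal fit to the curve is its mean; the
#' selected dimension is the first point at which the curve crosses (or
#' touches) that line. A curve that never crosses returns the last
#' dimension with a warning.
#'
#' @param dimensions increasing dimension values (length >= 3).
#' @param mean_entropy matching mean entropies.
#' @return the selected dimension.
#' @export
optimal_dimension <- function(dimensions, mean_entropy) {
  stopifnot(length(dimensions) == length(mean_entropy),
            length(dimensions) >= 3L)
  m <- mean(mean_entropy)
  dev <- mean_entropy - m
  if (dev[1L] == 0) return(dimensions[1L])
  for (k in 2L:length(dev)) {
    if (dev[k] == 0 || sign(dev[k]) != sign(dev[k - 1L]))
      return(dimensions[k])
  }
  warning("entropy curve never crosses its horizontal fit; returning last d")
  dimensions[length(dimensions)]
}

#' Export an entropy curve as TSV
#'
#' Columns: `d`, `mean_entropy`, `var_entropy`.
#'
#' @param curve an `entropy_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_entropy_curve <- function(curve, path) {
  write.table(data.frame(d = curve$dimensions,
                         mean_entropy = curve$mean_entropy,
                         var_entropy = curve$var_entropy),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.entropy_curve <- function(x, ...) {
  cat("entropy_curve over d =", paste(range(x$dimensions), collapse = ".."),
      "; optimal d =", x$optimal_d, "\n")
  invisible(x)
}
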