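# mesoscale: non-negative CP factorization of the contact tensor
#
# The contact sequence is a binary three-way tensor (node x node x
# snapshot). A rank-r non-negative CP model X ~ sum_c lambda_c a_c o b_c
# o g_c groups events into r mesoscale structures: each event is labeled
# by the component whose reconstruction at that link and time is largest.
# Contacts are undirected, so the two node modes share one factor by
# default. Rank is chosen by the core-consistency diagnostic (CORCONDIA).

#' Contact tensor of a temporal network
#'
#' Binary array of shape `n x n x t` (nodes x nodes x snapshots),
#' symmetric in the node modes, entry 1 iff the contact exists in that
#' snapshot.
#'
#' @param tn a `temporal_network`.
#' @return a `contact_tensor`: `data` (array), `nodes`, `times`
#'   (snapshot values 0-based).
#' @export
build_contact_tensor <- function(tn) {
  validate_temporal_network(tn)
  n <- length(tn$nodes)
  Tt <- as.integer(tn$horizon + 1L)
  arr <- array(0, dim = c(n, n, max(Tt, 1L)))
  ev <- tn$events
  if (nrow(ev)) {
    ii <- match(ev$i, tn$nodes); jj <- match(ev$j, tn$nodes)
    tt <- ev$t + 1L
    arr[cbind(ii, jj, tt)] <- 1
    arr[cbind(jj, ii, tt)] <- 1
  }
  structure(list(data = arr, nodes = tn$nodes,
                 times = seq_len(dim(arr)[3L]) - 1L),
            class = "contact_tensor")
}

khatri_rao <- function(P, Q) {
  # rows: P slow, Q fast -> result[(p-1)*nq + q, c] = P[p,c] * Q[q,c]
  P[rep(seq_len(nrow(P)), each = nrow(Q)), , drop = FALSE] *
    Q[rep(seq_len(nrow(Q)), nrow(P)), , drop = FALSE]
}

unfold <- function(arr, mode) {
  d <- dim(arr)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(arr, perm), nrow = d[mode])
}

# mode-k product of a 3-way array with a matrix M (rows replace mode k)
ttm <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- c(mode, setdiff(1:3, mode))
  Y <- M %*% matrix(aperm(arr, perm), nrow = d[mode])
  d2 <- d; d2[mode] <- nrow(M)
  aperm(array(Y, dim = c(nrow(M), d[setdiff(1:3, mode)])),
        order(perm))
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Non-negative CP decomposition of a contact tensor
#'
#' Multiplicative-update alternating minimization of the Frobenius error
#' with non-negative factors; the two node modes share one factor when
#' `symmetric = TRUE` (the default — contacts are undirected). Factor
#' columns are normalized to unit length and scales collected in
#' `lambda`, which makes per-event component assignment well defined.
#' Deterministic under `seed`.
#'
#' @param tensor a `contact_tensor`.
#' @param r rank (number of mesoscale structures).
#' @param seed RNG seed for the random positive initializations.
#' @param n_iter maximum iterations per start.
#' @param tol relative-fit convergence tolerance.
#' @param symmetric share the node factor across both node modes.
#' @param n_starts random restarts; the best-fitting solution is kept
#'   (multiplicative updates are local-optimum-prone).
#' @return a `cp_model`: `rank`, `node_factors` (n x r), `node_factors2`,
#'   `time_factors` (t x r), `lambda`, `fit` (1 - relative error),
#'   `iterations`.
#' @export
decompose_tensor <- function(tensor, r, seed = 1L, n_iter = 300L,
                             tol = 1e-9, symmetric = TRUE, n_starts = 3L) {
  best <- NULL
  for (start in seq_len(n_starts)) {
    m <- decompose_once(tensor, r,
                        seed = (as.numeric(seed) * 131 + start) %% 2^31,
                        n_iter = n_iter, tol = tol, symmetric = symmetric)
    if (is.null(best) || m$fit > best$fit) best <- m
  }
  best
}

decompose_once <- function(tensor, r, seed, n_iter, tol, symmetric) {
  stopifnot(inherits(tensor, "contact_tensor"))
  r <- as.integer(r)
  if (r < 1L) stop("rank must be >= 1")
  X <- tensor$data
  n <- dim(X)[1L]; Tt <- dim(X)[3L]
  if (r > min(n, Tt))
    warning("rank exceeds the smallest tensor dimension")
  X1 <- unfold(X, 1L); X2 <- unfold(X, 2L); X3 <- unfold(X, 3L)
  normX <- sqrt(sum(X^2))
  eps <- 1e-12
  with_seed(seed, {
    A <- matrix(runif(n * r, 0.1, 1), n, r)
    B <- if (symmetric) A else matrix(runif(n * r, 0.1, 1), n, r)
    C <- matrix(runif(Tt * r, 0.1, 1), Tt, r)
    fit_old <- -Inf; it <- 0L
    repeat {
      it <- it + 1L
      Z <- khatri_rao(C, B)
      A <- A * (X1 %*% Z) / (A %*% crossprod(Z) + eps)
      if (symmetric) B <- A
      else {
        Z <- khatri_rao(C, A)
        B <- B * (X2 %*% Z) / (B %*% crossprod(Z) + eps)
      }
      Z <- khatri_rao(B, A)
      C <- C * (X3 %*% Z) / (C %*% crossprod(Z) + eps)
      if (it %% 10L == 0L || it >= n_iter) {
        err <- sqrt(max(0, normX^2 - 2 * sum(X3 * (C %*% t(Z))) +
                          sum(crossprod(Z) * crossprod(C))))
        fit <- 1 - err / normX
        if (it >= n_iter || abs(fit - fit_old) < tol) break
        fit_old <- fit
      }
    }
    na <- pmax(sqrt(colSums(A^2)), eps)
    nb <- pmax(sqrt(colSums(B^2)), eps)
    nc <- pmax(sqrt(colSums(C^2)), eps)
    structure(list(rank = r,
                   node_factors = sweep(A, 2L, na, "/"),
                   node_factors2 = sweep(B, 2L, nb, "/"),
                   time_factors = sweep(C, 2L, nc, "/"),
                   lambda = na * nb * nc, fit = fit, iterations = it),
              class = "cp_model")
  })
}

#' Assign each event to a mesoscale component
#'
#' Event `(i, j, t)` is labeled by the component `c` maximizing
#' `lambda_c * a_ic * b_jc * g_tc` (the component's reconstruction at
#' that link and time); ties break to the lowest component index.
#'
#' @param model a `cp_model` fitted on `tn`'s contact tensor.
#' @param tn the `temporal_network`.
#' @return named integer vector of component labels (1..rank), names are
#'   event tokens.
#' @export
assign_components <- function(model, tn) {
  stopifnot(inherits(model, "cp_model"))
  ev <- tn$events
  ii <- match(ev$i, tn$nodes); jj <- match(ev$j, tn$nodes)
  tt <- ev$t + 1L
  V <- model$node_factors[ii, , drop = FALSE] *
       model$node_factors2[jj, , drop = FALSE] *
       model$time_factors[tt, , drop = FALSE]
  V <- sweep(V, 2L, model$lambda, "*")
  setNames(max.col(V, ties.method = "first"), ev$token)
}

#' Core consistency (CORCONDIA) of a CP model
#'
#' Computes the least-squares Tucker core implied by the CP factors and
#' measures its distance from the ideal superdiagonal identity core, on
#' the usual percentage scale: `100 * (1 - sum((G - I)^2) / r)`. Values
#' near 100 indicate an appropriate rank; degenerate fits can go
#' negative.
#'
#' @param tensor the `contact_tensor` the model was fitted on.
#' @param model a `cp_model`.
#' @return numeric `<= 100`.
#' @export
core_consistency <- function(tensor, model) {
  A <- model$node_factors
  B <- model$node_factors2
  C <- sweep(model$time_factors, 2L, model$lambda, "*")
  G <- ttm(ttm(ttm(tensor$data, pinv(A), 1L), pinv(B), 2L), pinv(C), 3L)
  r <- model$rank
  ideal <- array(0, dim = c(r, r, r))
  ideal[cbind(1:r, 1:r, 1:r)] <- 1
  100 * (1 - sum((G - ideal)^2) / r)
}

#' Select the CP rank by core consistency
#'
#' Fits each candidate rank and returns the largest one whose core
#' consistency stays at or above `threshold` (default 90); when no rank
#' qualifies, the rank with maximal consistency is returned with a
#' warning.
#'
#' @param tensor a `contact_tensor`.
#' @param ranks candidate ranks (default 2..20).
#' @param threshold core-consistency acceptance level.
#' @param seed seed forwarded to [decompose_tensor()].
#' @param ... further arguments to [decompose_tensor()].
#' @return a `rank_selection`: `rank`, `diagnostics` (data.frame `rank`,
#'   `core_consistency`, `fit`).
#' @export
select_rank <- function(tensor, ranks = 2:20, threshold = 90, seed = 1L,
                        ...) {
  cc <- fit <- numeric(length(ranks))
  for (k in seq_along(ranks)) {
    model <- decompose_tensor(tensor, ranks[k], seed = seed, ...)
    cc[k] <- core_consistency(tensor, model)
    fit[k] <- model$fit
  }
  ok <- which(cc >= threshold)
  rank <- if (length(ok)) max(ranks[ok]) else {
    warning("no rank reaches the core-consistency threshold")
    ranks[which.max(cc)]
  }
  structure(list(rank = rank,
                 diagnostics = data.frame(rank = ranks,
                                          core_consistency = cc, fit = fit)),
            class = "rank_selection")
}

#' Export component labels as TSV
#'
#' Columns: `event` (token), `component`.
#'
#' @param labels named vector from [assign_components()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_components <- function(labels, path) {
  write.table(data.frame(event = names(labels),
                         component = as.integer(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf("cp_model: rank %d, fit %.4f, %d iterations\n",
              x$rank, x$fit, x$iterations))
  invisible(x)
}
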