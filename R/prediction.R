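# prediction: epidemic-size regression from event coordinates

#' Build the regression feature table
#'
#' One row per embedded event; predictors are the `d` coordinates, their
#' squares, and the euclidean distance to the temporally first embedded
#' event (2d + 1 predictors); target `y` is the simulated final epidemic
#' size.
#'
#' @param emb an `event_embedding` over event tokens.
#' @param sizes named vector of final sizes (e.g.
#'   [epidemic_sizes_all_seeds()]); every embedded token must have one.
#' @return data.frame with columns `x1..xd`, `xsq1..xsqd`, `dist_first`,
#'   `y`; rownames are event tokens in canonical order. Attribute
#'   `"first_event"` records the reference token.
#' @export
build_features <- function(emb, sizes) {
  tokens <- rownames(emb$vectors)
  if (length(tokens) == 0L) stop("empty embedding")
  missing <- setdiff(tokens, names(sizes))
  if (length(missing))
    stop("no epidemic size for embedded events: ",
         paste(head(missing, 5L), collapse = ", "))
  meta <- parse_event_token(tokens)
  ord <- event_order(meta$t, meta$i, meta$j)
  tokens <- tokens[ord]
  X <- emb$vectors[match(tokens, rownames(emb$vectors)), , drop = FALSE]
  first_vec <- X[1L, ]
  dist_first <- sqrt(rowSums(sweep(X, 2L, first_vec)^2))
  d <- ncol(X)
  tab <- data.frame(X, X^2, dist_first = dist_first,
                    y = as.numeric(sizes[tokens]))
  colnames(tab) <- c(paste0("x", seq_len(d)), paste0("xsq", seq_len(d)),
                     "dist_first", "y")
  rownames(tab) <- tokens
  attr(tab, "first_event") <- tokens[1L]
  tab
}

ols_fit_predict <- function(Xtr, ytr, Xte) {
  Xtr1 <- cbind(1, Xtr); Xte1 <- cbind(1, Xte)
  qr_ <- qr(Xtr1)
  if (qr_$rank < ncol(Xtr1)) {
    # singular design: tiny ridge fallback keeps the fit defined
    warning("singular design; using ridge fallback")
    XtX <- crossprod(Xtr1)
    beta <- solve(XtX + 1e-8 * diag(ncol(Xtr1)), crossprod(Xtr1, ytr))
  } else {
    beta <- qr.coef(qr_, ytr)
  }
  drop(Xte1 %*% beta)
}

#' Cross-validated linear prediction of epidemic sizes
#'
#' Ordinary least squares of `y` on the 2d + 1 predictors under k-fold
#' cross-validation: rows are randomly partitioned into `folds` equal
#' sub-samples; each fold in turn is held out, the model is trained on
#' the rest, and the held-out coefficient of determination
#' `r^2 = 1 - SS_res / SS_tot` is recorded (it can be negative). A
#' singular design triggers a tiny-ridge fallback with a warning.
#'
#' @param table a feature table from [build_features()].
#' @param folds number of cross-validation folds (default 10).
#' @param seed seed of the fold-assignment permutation.
#' @return a `prediction_report`: `r2_mean`, `r2_std`, `per_fold_r2`,
#'   `n_realisations`, `n_rows`.
#' @export
fit_and_score <- function(table, folds = 10L, seed = 1L) {
  n <- nrow(table)
  folds <- as.integer(folds)
  if (n < folds) stop("need at least `folds` rows")
  y <- table$y
  X <- as.matrix(table[, setdiff(colnames(table), "y"), drop = FALSE])
  assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  r2 <- vapply(seq_len(folds), function(f) {
    te <- assign_fold == f
    pred <- ols_fit_predict(X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE])
    ss_res <- sum((y[te] - pred)^2)
    ss_tot <- sum((y[te] - mean(y[te]))^2)
    if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
    1 - ss_res / ss_tot
  }, 0)
  structure(list(r2_mean = mean(r2), r2_std = stats::sd(r2),
                 per_fold_r2 = r2, n_realisations = 1L, n_rows = n),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: held-out r2 = %.3f +/- %.3f over %d folds (%d rows)\n",
              x$r2_mean, x$r2_std, length(x$per_fold_r2), x$n_rows))
  invisible(x)
}
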