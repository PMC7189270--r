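# pipeline: end-to-end orchestration and parameter sweeps

#' Run the full embedding-and-prediction pipeline
#'
#' Input event list -> weighted event graph -> sampled environments ->
#' Skip-Gram embedding -> SI epidemic sizes -> cross-validated size
#' prediction. Every artifact (graph edge list, corpus, embedding, sizes,
#' prediction report) and a manifest echoing all parameters and seeds are
#' written to `out_dir`; identical configurations and seeds give
#' byte-identical outputs.
#'
#' @param input a `temporal_network` or the path of an event-list file.
#' @param out_dir run directory (created if missing).
#' @param alpha,nb,s,mode sampling parameters; defaults `alpha = 0.5`,
#'   `nb = 10`, `s = 10` are the showcase settings.
#' @param d embedding dimension, or `"auto"` to select it with
#'   [entropy_curve()].
#' @param delta_t event-graph adjacency horizon (`"full"` or snapshots).
#' @param sampling_seed,training_seed,cv_seed named seeds of the three
#'   random stages.
#' @param folds cross-validation folds.
#' @param dims candidate dimensions for `d = "auto"`.
#' @param realisations embedding realisations for `d = "auto"`.
#' @param intra_snapshot SI intra-snapshot rule (see [simulate_si()]).
#' @param column_order,delta_t_seconds passed to [read_event_list()] when
#'   `input` is a path.
#' @param ... further arguments to [train_embedding()].
#' @return invisibly, a list with `network`, `graph`, `embedding`,
#'   `sizes`, `features`, `report`, `d`, `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, alpha = 0.5, nb = 10L, s = 10L,
                         mode = "combined", d = 8L, delta_t = "full",
                         sampling_seed = 1L, training_seed = 1L, cv_seed = 1L,
                         folds = 10L, dims = seq(2L, 40L, 2L),
                         realisations = 5L,
                         intra_snapshot = "fixed_point",
                         column_order = "t_i_j", delta_t_seconds = 20, ...) {
  tn <- if (is.character(input))
    read_event_list(input, column_order = column_order,
                    delta_t_seconds = delta_t_seconds)
  else input
  validate_temporal_network(tn)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  g <- build_event_graph(tn, delta_t)
  write_event_graph(g, file.path(out_dir, "event_graph.tsv"))

  if (identical(d, "auto")) {
    curve <- entropy_curve(tn, dims = dims, realisations = realisations,
                           sample_size = min(1000L, max(2L, g$n_events)),
                           n_samples = min(10L, max(1L, g$n_events %/% 2L)),
                           alpha = alpha, nb = nb, s = s, mode = mode,
                           delta_t = delta_t, seed = sampling_seed, ...)
    write_entropy_curve(curve, file.path(out_dir, "entropy_curve.tsv"))
    d <- curve$optimal_d
  }

  corpus <- sample_environments(
    g, sampling_config(alpha = alpha, nb = nb, s = s, mode = mode,
                       seed = sampling_seed))
  if (length(corpus) == 0L) stop("no environments could be sampled")
  write_corpus(corpus, file.path(out_dir, "corpus.txt"))

  emb <- train_embedding(corpus, d = d, seed = training_seed, ...)
  write_embedding(emb, file.path(out_dir, "embedding.w2v"))

  sizes <- epidemic_sizes_all_seeds(tn, intra_snapshot)
  write_epidemic_sizes(sizes, file.path(out_dir, "epidemic_sizes.tsv"))

  features <- build_features(emb, sizes)
  report <- fit_and_score(features, folds = folds, seed = cv_seed)

  manifest <- c(
    sprintf("alpha=%g", alpha), sprintf("nb=%d", as.integer(nb)),
    sprintf("s=%d", as.integer(s)), sprintf("mode=%s", mode),
    sprintf("d=%d", as.integer(d)),
    sprintf("delta_t=%s", as.character(delta_t)),
    sprintf("sampling_seed=%d", as.integer(sampling_seed)),
    sprintf("training_seed=%d", as.integer(training_seed)),
    sprintf("cv_seed=%d", as.integer(cv_seed)),
    sprintf("folds=%d", as.integer(folds)),
    sprintf("intra_snapshot=%s", intra_snapshot),
    sprintf("n_events=%d", nrow(tn$events)),
    sprintf("n_embedded=%d", nrow(emb$vectors)),
    sprintf("n_skipped=%d", length(attr(corpus, "skipped"))),
    sprintf("r2_mean=%.6f", report$r2_mean),
    sprintf("r2_std=%.6f", report$r2_std)
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  writeLines(c(sprintf("r2_mean=%.6f", report$r2_mean),
               sprintf("r2_std=%.6f", report$r2_std),
               sprintf("n_rows=%d", report$n_rows),
               sprintf("excluded_events=%d", length(attr(corpus, "skipped"))),
               paste0("per_fold_r2=",
                      paste(sprintf("%.6f", report$per_fold_r2),
                            collapse = ","))),
             file.path(out_dir, "prediction_report.txt"))
  invisible(list(network = tn, graph = g, embedding = emb, sizes = sizes,
                 features = features, report = report, d = d,
                 out_dir = out_dir))
}

#' Sweep sampling / embedding parameters against prediction skill
#'
#' Evaluates the held-out mean r^2 of the pipeline over a parameter grid
#' (any of `nb`, `s`, `d`, `alpha` as columns), averaging over
#' `realisations` embedding realisations per cell.
#'
#' @param tn a `temporal_network`.
#' @param grid data.frame whose columns are a subset of `nb`, `s`, `d`,
#'   `alpha`; one row per cell.
#' @param realisations realisations per cell.
#' @param mode,delta_t,folds fixed pipeline parameters.
#' @param seed base seed; per-cell, per-realisation seeds derive from it.
#' @param ... further arguments to [train_embedding()].
#' @return the grid with columns `r2_mean` and `r2_std` appended.
#' @export
sweep_r2 <- function(tn, grid, realisations = 2L, mode = "combined",
                     delta_t = "full", folds = 10L, seed = 1L, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0L,
            all(colnames(grid) %in% c("nb", "s", "d", "alpha")))
  g <- build_event_graph(tn, delta_t)
  sizes <- epidemic_sizes_all_seeds(tn)
  get_par <- function(row, name, default)
    if (name %in% colnames(grid)) grid[[name]][row] else default
  r2m <- r2s <- numeric(nrow(grid))
  for (row in seq_len(nrow(grid))) {
    vals <- vapply(seq_len(realisations), function(rl) {
      run_seed <- (as.numeric(seed) * 1000 + row * 37 + rl) %% 2^31
      corpus <- sample_environments(
        g, sampling_config(alpha = get_par(row, "alpha", 0.5),
                           nb = get_par(row, "nb", 10L),
                           s = get_par(row, "s", 10L), mode = mode,
                           seed = run_seed))
      emb <- train_embedding(corpus, d = get_par(row, "d", 8L),
                             seed = run_seed, ...)
      fit_and_score(build_features(emb, sizes), folds = folds,
                    seed = run_seed)$r2_mean
    }, 0)
    r2m[row] <- mean(vals)
    r2s[row] <- if (realisations > 1L) stats::sd(vals) else 0
  }
  grid$r2_mean <- r2m
  grid$r2_std <- r2s
  grid
}
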