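# sampling: per-event environments drawn from the event-graph neighborhood

#' Configuration for environment sampling
#'
#' @param alpha mix between the two edge weights in `[0, 1]`: 1 samples by
#'   temporal-path weight only, 0 by co-occurrence weight only.
#' @param nb number of environments drawn per event.
#' @param s environment length (context events per environment).
#' @param mode `"combined"` (predecessors and successors, the default) or
#'   `"predecessors_only"` (past-only contexts, the online variant).
#' @param seed RNG seed for the single sampling stream (`NULL` = current
#'   stream).
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(alpha = 0.5, nb = 10L, s = 10L,
                            mode = c("combined", "predecessors_only"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  nb <- as.integer(nb); s <- as.integer(s)
  if (nb < 1L || s < 1L) stop("nb and s must be >= 1")
  structure(list(alpha = alpha, nb = nb, s = s, mode = mode, seed = seed),
            class = "sampling_config")
}

neighborhood_of <- function(g, idx, mode) {
  ed <- g$edges
  if (mode == "combined") {
    sel_in <- which(ed$dst == idx); sel_out <- which(ed$src == idx)
    list(index = c(ed$src[sel_in], ed$dst[sel_out]),
         w_path = c(ed$w_path[sel_in], ed$w_path[sel_out]),
         w_co = c(ed$w_co[sel_in], ed$w_co[sel_out]))
  } else {
    sel_in <- which(ed$dst == idx)
    list(index = ed$src[sel_in], w_path = ed$w_path[sel_in],
         w_co = ed$w_co[sel_in])
  }
}

mix_probabilities <- function(w_path, w_co, alpha) {
  f_path <- w_path / sum(w_path)
  f_co <- if (sum(w_co) > 0) w_co / sum(w_co)
          else rep(1 / length(w_co), length(w_co))  # 0/0 guard: uniform
  p <- alpha * f_path + (1 - alpha) * f_co
  p / sum(p)
}

#' Context-sampling probabilities of an event
#'
#' For center event `e_k` with neighborhood `N_k`, the probability of
#' drawing neighbor `e_l` is
#' `p(e_l) = alpha * F(w_path) + (1 - alpha) * F(w_co)` where `F`
#' normalizes each weight over `N_k`. When every `w_co` in the
#' neighborhood is zero the co-occurrence term degenerates to the uniform
#' distribution (least-informative completion of 0/0).
#'
#' @param g an `event_graph`.
#' @param e event token or index.
#' @param alpha weight-mix coefficient in `[0, 1]`.
#' @param mode `"combined"` or `"predecessors_only"`.
#' @return named numeric vector of probabilities (names are event tokens)
#'   summing to 1, or `NULL` when the neighborhood is empty (the event is
#'   skipped downstream).
#' @export
sampling_probabilities <- function(g, e, alpha = 0.5,
                                   mode = c("combined", "predecessors_only")) {
  mode <- match.arg(mode)
  idx <- resolve_event(g, e)
  nb <- neighborhood_of(g, idx, mode)
  if (length(nb$index) == 0L) return(NULL)
  setNames(mix_probabilities(nb$w_path, nb$w_co, alpha),
           g$events$token[nb$index])
}

#' Sample environments for every event
#'
#' Draws `nb` environments of `s` context events for each event with a
#' nonempty neighborhood, i.i.d. with replacement from the categorical
#' distribution of [sampling_probabilities()]. Events are processed in
#' canonical order from one seeded RNG stream, so output is reproducible.
#'
#' @param g an `event_graph`.
#' @param cfg a [sampling_config()].
#' @return list of character vectors, each `c(center, context_1, ...,
#'   context_s)`; attribute `"skipped"` lists tokens of events with empty
#'   neighborhoods (they receive no environments and hence no vector).
#' @export
sample_environments <- function(g, cfg) {
  stopifnot(inherits(cfg, "sampling_config"))
  tokens <- g$events$token
  E <- g$n_events
  ed <- g$edges
  in_by <- split(seq_len(nrow(ed)), factor(ed$dst, levels = seq_len(E)))
  out_by <- split(seq_len(nrow(ed)), factor(ed$src, levels = seq_len(E)))
  env_list <- vector("list", E * cfg$nb)
  skipped <- character(0)
  n_env <- 0L
  with_seed(cfg$seed, {
    for (k in seq_len(E)) {
      rows_in <- in_by[[k]]
      rows_out <- if (cfg$mode == "combined") out_by[[k]] else integer(0)
      rows <- c(rows_in, rows_out)
      nbr <- c(ed$src[rows_in], ed$dst[rows_out])
      if (length(nbr) == 0L) { skipped <- c(skipped, tokens[k]); next }
      p <- mix_probabilities(ed$w_path[rows], ed$w_co[rows], cfg$alpha)
      for (b in seq_len(cfg$nb)) {
        ctx <- nbr[sample.int(length(nbr), cfg$s, replace = TRUE, prob = p)]
        n_env <- n_env + 1L
        env_list[[n_env]] <- c(tokens[k], tokens[ctx])
      }
    }
  })
  structure(env_list[seq_len(n_env)], skipped = skipped)
}

#' Write an environment corpus as plain text
#'
#' One environment per line: center token first, then the `s` context
#' tokens, space-separated — the sentence format consumed by
#' [train_embedding()].
#'
#' @param corpus list of character vectors from [sample_environments()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, "", collapse = " "), path)
  invisible(path)
}
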