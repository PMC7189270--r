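# shared internal helpers

#' Build the canonical token of an event
#'
#' Events are referred to throughout the package by a string token
#' `"i|j|t"` with `i < j` under the canonical (C-locale) node order.
#'
#' @param i,j node identifiers (character).
#' @param t integer snapshot timestamp.
#' @return character vector of tokens.
#' @export
event_token <- function(i, j, t) paste(i, j, t, sep = "|")

#' Parse event tokens back into (i, j, t) triples
#'
#' @param tokens character vector of `"i|j|t"` tokens.
#' @return data.frame with columns `i`, `j` (character) and `t` (integer).
#' @export
parse_event_token <- function(tokens) {
  parts <- strsplit(tokens, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed event token: ", tokens[which(bad)[1L]])
  data.frame(
    i = vapply(parts, `[`, "", 1L),
    j = vapply(parts, `[`, "", 2L),
    t = as.integer(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

# locale-independent total order on node identifiers: rank within the
# radix-sorted unique set.  Used for canonicalization so results do not
# depend on the session locale.
canonicalize_pairs <- function(i, j) {
  u <- sort(unique(c(i, j)), method = "radix")
  swap <- match(i, u) > match(j, u)
  list(i = ifelse(swap, j, i), j = ifelse(swap, i, j))
}

# deterministic order by (t, i, j), strings compared in the C locale
event_order <- function(t, i, j) order(t, i, j, method = "radix")

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Shannon entropy (natural log) of a probability vector; 0 log 0 := 0
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
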