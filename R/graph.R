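#' Build the matching graph of a sentence
#'
#' Each dictionary match contributes one directed edge from its first token
#' to its last token: `a_out[i, j] = 1` iff some match spans `[i, j + 1)`
#' (0-based, so in the stored 1-based matrices the edge for a match with
#' span `[s, e)` sits at row `s + 1`, column `e`). Single-token matches
#' become self-loops on the diagonal. `a_in` is the transpose of `a_out` --
#' the reversed graph fed to the backward GCN branch. The adjacency is
#' binary and type-agnostic: several entries sharing a span still yield a
#' single edge; types stay on the match list for diagnostics.
#'
#' @param length sentence length in tokens.
#' @param matches a match data frame from [find_matches()] (columns
#'   `start`, `end`), or any span data frame.
#' @param self_loops keep edges of single-token matches (default TRUE).
#' @return An object of class `match_graph`: list with `a_out`, `a_in`
#'   (L x L 0/1 matrices) and `matches`.
#' @export
match_graph <- function(length, matches, self_loops = TRUE) {
  L <- as.integer(length)
  stopifnot(L >= 1L)
  a_out <- matrix(0, L, L)
  if (!is.null(matches) && nrow(matches) > 0L) {
    if (any(matches$start < 0L) || any(matches$end > L))
      stop("match span outside sentence of length ", L)
    keep <- if (self_loops) seq_len(nrow(matches)) else
      which(matches$end - matches$start > 1L)
    a_out[cbind(matches$start[keep] + 1L, matches$end[keep])] <- 1
  }
  structure(list(a_out = a_out, a_in = t(a_out),
                 matches = matches), class = "match_graph")
}

#' @export
print.match_graph <- function(x, ...) {
  cat(sprintf("Matching graph: %d tokens, %d edge(s), %d match(es)\n",
              nrow(x$a_out), sum(x$a_out),
              if (is.null(x$matches)) 0L else nrow(x$matches)))
  invisible(x)
}

#' Greedy masked-manner dictionary feature
#'
#' The classic baseline: scan left to right and, at each position, take the
#' longest dictionary match starting there (ties broken by lowest entry
#' id), mark its tokens `B-t / M-t / E-t` (`S-t` for a single token), and
#' jump past it. This leftmost-longest cover handles disjoint matches only:
#' when matches overlap or nest, the greedy choice can shadow the true
#' entity or produce an overlong mask -- the failure mode the matching
#' graph is designed to avoid.
#'
#' @param tokens character vector of sentence tokens.
#' @param dict an [entity_dictionary()].
#' @return Character vector of length `length(tokens)` over
#'   `O, B-t, M-t, E-t, S-t`.
#' @export
masked_baseline <- function(tokens, dict) {
  L <- length(tokens)
  m <- find_matches(tokens, dict)
  mask <- rep("O", L)
  pos <- 0L
  while (pos < L) {
    here <- m[m$start == pos, , drop = FALSE]
    if (nrow(here) == 0L) { pos <- pos + 1L; next }
    best <- here[order(-here$end, here$entry_id)[1L], ]
    s <- best$start; e <- best$end; t <- best$type
    if (e - s == 1L) {
      mask[s + 1L] <- paste0("S-", t)
    } else {
      mask[s + 1L] <- paste0("B-", t)
      if (e - s > 2L) mask[(s + 2L):(e - 1L)] <- paste0("M-", t)
      mask[e] <- paste0("E-", t)
    }
    pos <- e
  }
  mask
}
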