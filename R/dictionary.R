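#' Build an entity dictionary
#'
#' Entries are tokenized surface forms with an entity type. Matching is
#' exact at the token level after normalization; the default policy folds
#' case (so "RCC" in text still matches a dictionary "rcc") while leaving
#' the text itself untouched for the encoder. Duplicate (surface, type)
#' pairs are dropped; entry ids are assigned deterministically in order of
#' first appearance.
#'
#' A token-level Aho-Corasick automaton is built over the entries so that a
#' sentence of length L is scanned in one left-to-right pass, reporting
#' every match -- including overlapping and nested ones.
#'
#' @param surfaces character vector of surface forms (whitespace-tokenized),
#'   or a list of character vectors of tokens.
#' @param types character vector of entity types, recycled; defaults to a
#'   single generic type `"entity"`.
#' @param normalize `"casefold"` (default) or `"none"`.
#' @return An object of class `entity_dictionary`.
#' @examples
#' d <- entity_dictionary(c("Wilms ' tumor"), "disease")
#' find_matches(c("Wilms", "'", "tumor", "suppressor", "gene"), d)
#' @export
entity_dictionary <- function(surfaces, types = NULL,
                              normalize = c("casefold", "none")) {
  normalize <- match.arg(normalize)
  if (length(surfaces) == 0L) stop("empty dictionary")
  if (!is.list(surfaces))
    surfaces <- strsplit(as.character(surfaces), "[ \t]+")
  if (is.null(types)) types <- "entity"
  types <- rep_len(as.character(types), length(surfaces))
  toks <- lapply(surfaces, function(x) {
    x <- x[nzchar(x)]
    normalize_tokens(x, normalize)
  })
  nt <- lengths(toks)
  if (any(nt == 0L))
    stop("entry tokenizes to zero tokens at position ",
         which(nt == 0L)[1L])
  key <- paste(vapply(toks, paste, "", collapse = "\r"), types, sep = "\x1f")
  keep <- !duplicated(key)
  toks <- toks[keep]; types <- types[keep]
  d <- list(tokens = toks, type = types, normalize = normalize,
            max_len = max(lengths(toks)))
  d$automaton <- build_automaton(toks)
  class(d) <- "entity_dictionary"
  d
}

normalize_tokens <- function(tokens, policy) {
  switch(policy, casefold = tolower(tokens), none = tokens,
         stop("unknown normalization policy: ", policy))
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf(
    "Entity dictionary: %d entries, %d type(s), normalization '%s'\n",
    length(x$tokens), length(unique(x$type)), x$normalize))
  invisible(x)
}

#' @export
length.entity_dictionary <- function(x) length(x$tokens)

#' Read a dictionary file
#'
#' One entry per line: `surface<TAB>type`. A missing type column defaults
#' to the generic type `"entity"`; lines starting with `#` and blank lines
#' are skipped.
#'
#' @param path file path.
#' @param normalize token normalization policy, see [entity_dictionary()].
#' @return An `entity_dictionary`.
#' @export
read_dictionary <- function(path, normalize = c("casefold", "none")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("empty dictionary file: ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  surfaces <- vapply(parts, `[[`, "", 1L)
  types <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "entity", "")
  empty <- !nzchar(trimws(surfaces))
  if (any(empty))
    stop("entry tokenizes to zero tokens at line ", keep[which(empty)[1L]])
  entity_dictionary(surfaces, types, match.arg(normalize))
}

# ---- token-level Aho-Corasick automaton -----------------------------------
# States are integers, 1 = root. Transitions live in a hash environment
# keyed "state\rtoken". Outputs (entry ids ending at a state) are
# fail-propagated at build time so the scan only reads out[[state]].

build_automaton <- function(toks) {
  trans <- new.env(hash = TRUE, parent = emptyenv())
  n_states <- 1L
  out <- list(integer())
  children <- list(character())  # per state, tokens with a goto edge
  for (e in seq_along(toks)) {
    s <- 1L
    for (a in toks[[e]]) {
      k <- paste0(s, "\r", a)
      nxt <- trans[[k]]
      if (is.null(nxt)) {
        n_states <- n_states + 1L
        nxt <- n_states
        trans[[k]] <- nxt
        out[[nxt]] <- integer()
        children[[nxt]] <- character()
        children[[s]] <- c(children[[s]], a)
      }
      s <- nxt
    }
    out[[s]] <- c(out[[s]], e)
  }
  fail <- rep(1L, n_states)
  queue <- integer()
  for (a in children[[1L]]) queue <- c(queue, trans[[paste0("1\r", a)]])
  qi <- 1L
  while (qi <= length(queue)) {
    s <- queue[qi]; qi <- qi + 1L
    for (a in children[[s]]) {
      c_ <- trans[[paste0(s, "\r", a)]]
      f <- fail[s]
      repeat {
        nxt <- trans[[paste0(f, "\r", a)]]
        if (!is.null(nxt)) { fail[c_] <- nxt; break }
        if (f == 1L) { fail[c_] <- 1L; break }
        f <- fail[f]
      }
      out[[c_]] <- c(out[[c_]], out[[fail[c_]]])
      queue <- c(queue, c_)
    }
  }
  list(trans = trans, fail = fail, out = out)
}

#' Find all dictionary matches in a sentence
#'
#' Returns every span `[i, j)` whose normalized tokens equal a dictionary
#' entry -- one row per (span, entry) pair, so overlapping and nested
#' matches and multiple entries sharing a span are all reported. Rows are
#' ordered by start, then end, then entry id.
#'
#' @param tokens character vector of sentence tokens.
#' @param dict an [entity_dictionary()].
#' @return A data frame with columns `start`, `end` (0-based, half-open),
#'   `type`, `entry_id`.
#' @export
find_matches <- function(tokens, dict) {
  stopifnot(inherits(dict, "entity_dictionary"))
  if (length(tokens) == 0L || any(!nzchar(tokens)))
    stop("tokens must be a non-empty vector of non-empty strings")
  norm <- normalize_tokens(tokens, dict$normalize)
  au <- dict$automaton
  lens <- lengths(dict$tokens)
  start <- integer(); end <- integer(); eid <- integer()
  s <- 1L
  for (j in seq_along(norm)) {
    a <- norm[j]
    repeat {
      nxt <- au$trans[[paste0(s, "\r", a)]]
      if (!is.null(nxt)) { s <- nxt; break }
      if (s == 1L) break
      s <- au$fail[s]
    }
    hits <- au$out[[s]]
    if (length(hits) > 0L) {
      start <- c(start, j - lens[hits])
      end <- c(end, rep(j, length(hits)))
      eid <- c(eid, hits)
    }
  }
  o <- order(start, end, eid)
  data.frame(start = start[o], end = end[o], type = dict$type[eid[o]],
             entry_id = eid[o], stringsAsFactors = FALSE)
}
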