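#' Entity spans
#'
#' Spans are represented throughout the package as a data frame with integer
#' columns `start` and `end` and a character column `type`. Indices are
#' 0-based and half-open at the word level: a span covers tokens
#' `start, ..., end - 1`, so `end - start` is its length in tokens.
#'
#' @param start,end integer vectors of 0-based half-open word offsets.
#' @param type character vector of entity-type labels.
#' @return A `data.frame` with columns `start`, `end`, `type`.
#' @examples
#' entity_spans(0, 3, "disease")
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         type = character()) {
  start <- as.integer(start)
  end <- as.integer(end)
  type <- as.character(type)
  stopifnot(length(start) == length(end), length(start) == length(type))
  if (any(start < 0L)) stop("span start must be >= 0")
  if (any(end <= start)) stop("every span must cover at least one token")
  data.frame(start = start, end = end, type = type,
             stringsAsFactors = FALSE)
}

# canonical ordering used whenever span sets are compared
sort_spans <- function(spans) {
  spans[order(spans$start, spans$end, spans$type), , drop = FALSE]
}

#' BIOES tagset for a set of entity types
#'
#' The closed tagset is `O` plus `B-t`, `I-t`, `E-t`, `S-t` for every type
#' `t`. It is derived once, at model setup, from the training corpus and the
#' dictionary types; tags outside it are an error, never silently remapped.
#'
#' @param types character vector of entity-type labels.
#' @return Character vector of tags, `O` first.
#' @export
bioes_tagset <- function(types) {
  types <- sort(unique(as.character(types)))
  if (any(!nzchar(types))) stop("entity types must be non-empty strings")
  c("O", as.vector(t(outer(c("B", "I", "E", "S"), types, paste, sep = "-"))))
}

split_tag <- function(tag) {
  # -> list(prefix, type); O has type ""
  if (tag == "O") return(list(prefix = "O", type = ""))
  dash <- regexpr("-", tag, fixed = TRUE)
  if (dash < 0L) stop("malformed tag: '", tag, "'")
  list(prefix = substr(tag, 1L, dash - 1L), type = substring(tag, dash + 1L))
}

#' Encode non-overlapping entity spans as a BIOES tag sequence
#'
#' Single-token spans become `S-t`; longer spans `B-t`, `I-t` ..., `E-t`;
#' uncovered positions `O`. For example the disease mention covering the
#' first three tokens of "Wilms ' tumor suppressor gene" encodes as
#' `B-disease I-disease E-disease O O`.
#'
#' @param spans a span data frame (see [entity_spans()]); must be
#'   non-overlapping and lie within `[0, length)`.
#' @param length sentence length in tokens.
#' @return Character vector of `length` BIOES tags.
#' @export
encode_bioes <- function(spans, length) {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  tags <- rep("O", length)
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  spans <- sort_spans(spans)
  if (any(spans$start < 0L) || any(spans$end > length))
    stop("span out of range for sentence of length ", length)
  if (any(spans$end <= spans$start))
    stop("every span must cover at least one token")
  if (nrow(spans) > 1L) {
    prev_end <- spans$end[-nrow(spans)]
    nxt_start <- spans$start[-1L]
    bad <- which(nxt_start < prev_end)
    if (length(bad) > 0L)
      stop(sprintf("overlapping spans: [%d,%d) and [%d,%d)",
                   spans$start[bad[1L]], spans$end[bad[1L]],
                   spans$start[bad[1L] + 1L], spans$end[bad[1L] + 1L]))
  }
  for (k in seq_len(nrow(spans))) {
    s <- spans$start[k]; e <- spans$end[k]; t <- spans$type[k]
    if (e - s == 1L) {
      tags[s + 1L] <- paste0("S-", t)
    } else {
      tags[s + 1L] <- paste0("B-", t)
      if (e - s > 2L) tags[(s + 2L):(e - 1L)] <- paste0("I-", t)
      tags[e] <- paste0("E-", t)
    }
  }
  tags
}

#' Decode a BIOES tag sequence into entity spans
#'
#' Decoding is total: well-formed runs (`S-t`, or `B-t I-t* E-t`) decode
#' exactly, so `decode_bioes(encode_bioes(S, L))` recovers `S` for any valid
#' span set. Ill-formed runs -- which model output can produce -- are
#' repaired conservatively: a maximal contiguous run of same-type non-`O`
#' tags that does not parse becomes a single span of that type.
#'
#' @param tags character vector of BIOES tags.
#' @return A span data frame, ordered by start then end.
#' @export
decode_bioes <- function(tags) {
  L <- length(tags)
  starts <- integer(); ends <- integer(); types <- character()
  info <- lapply(tags, split_tag)
  pre <- vapply(info, `[[`, "", "prefix")
  typ <- vapply(info, `[[`, "", "type")
  if (!all(pre %in% c("O", "B", "I", "E", "S")))
    stop("unknown tag prefix in: ",
         paste(unique(tags[!pre %in% c("O", "B", "I", "E", "S")]),
               collapse = ", "))
  emit <- function(s, e, t) {
    starts <<- c(starts, s); ends <<- c(ends, e); types <<- c(types, t)
  }
  i <- 1L
  while (i <= L) {
    if (pre[i] == "O") { i <- i + 1L; next }
    if (pre[i] == "S") { emit(i - 1L, i, typ[i]); i <- i + 1L; next }
    if (pre[i] == "B") {
      j <- i + 1L
      while (j <= L && pre[j] == "I" && typ[j] == typ[i]) j <- j + 1L
      if (j <= L && pre[j] == "E" && typ[j] == typ[i]) {
        emit(i - 1L, j, typ[i]); i <- j + 1L; next
      }
    }
    # ill-formed opener (stray I/E, or B without a matching E): merge the
    # maximal same-type run of non-O tags into one span
    j <- i
    while (j + 1L <= L && pre[j + 1L] != "O" && typ[j + 1L] == typ[i])
      j <- j + 1L
    emit(i - 1L, j, typ[i])
    i <- j + 1L
  }
  sort_spans(entity_spans(starts, ends, types))
}

#' Convert BIO tags to BIOES
#'
#' Corpora distributed with plain BIO tags are converted on load so the
#' model always sees BIOES. The conversion is deterministic: the last token
#' of each entity gets `E-` (or `S-` for single-token entities).
#'
#' @param tags character vector of BIO tags (`O`, `B-t`, `I-t`).
#' @return Character vector of BIOES tags.
#' @export
bio_to_bioes <- function(tags) {
  L <- length(tags)
  if (L == 0L) return(character())
  info <- lapply(tags, split_tag)
  pre <- vapply(info, `[[`, "", "prefix")
  typ <- vapply(info, `[[`, "", "type")
  if (!all(pre %in% c("O", "B", "I")))
    stop("not a BIO tag sequence: found prefix ",
         paste(setdiff(unique(pre), c("O", "B", "I")), collapse = ", "))
  out <- tags
  for (i in seq_len(L)) {
    if (pre[i] == "O") next
    nxt_inside <- i < L && pre[i + 1L] == "I" && typ[i + 1L] == typ[i]
    if (pre[i] == "B") {
      out[i] <- paste0(if (nxt_inside) "B-" else "S-", typ[i])
    } else {
      out[i] <- paste0(if (nxt_inside) "I-" else "E-", typ[i])
    }
  }
  out
}
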