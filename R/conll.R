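#' A corpus of tagged sentences
#'
#' A thin container: a list of sentences, each `list(tokens, tags)` with
#' equal lengths and optional `doc_id`. This is the in-memory form of the
#' two-column CoNLL format (one `token<TAB>tag` per line, blank line
#' between sentences).
#'
#' @param sentences list of `list(tokens, tags, doc_id = NULL)`.
#' @return An object of class `conll_document`.
#' @export
conll_document <- function(sentences) {
  stopifnot(is.list(sentences))
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]
    if (is.null(s$tokens) || length(s$tokens) == 0L)
      stop("sentence ", i, " has no tokens")
    if (!is.null(s$tags) && length(s$tags) != length(s$tokens))
      stop("sentence ", i, ": ", length(s$tags), " tags for ",
           length(s$tokens), " tokens")
  }
  structure(list(sentences = sentences), class = "conll_document")
}

#' @export
print.conll_document <- function(x, ...) {
  n <- length(x$sentences)
  lens <- vapply(x$sentences, function(s) length(s$tokens), 0L)
  cat(sprintf("CoNLL document: %d sentence(s), %d token(s), lengths %d-%d\n",
              n, sum(lens), min(lens), max(lens)))
  invisible(x)
}

#' @export
length.conll_document <- function(x) length(x$sentences)

#' Read a two-column CoNLL file
#'
#' Expects UTF-8, `token<WS>tag` per line, blank lines separating
#' sentences. Ragged lines are an error naming the line number. When a
#' `tagset` is given, every tag is checked against it; with
#' `scheme = "bio"` tags are converted to BIOES on load.
#'
#' @param path file path.
#' @param tagset optional closed tagset to validate against.
#' @param scheme `"bioes"` (default, taken as-is) or `"bio"` (converted).
#' @return A [conll_document()].
#' @export
read_conll <- function(path, tagset = NULL, scheme = c("bioes", "bio")) {
  scheme <- match.arg(scheme)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(); tags <- character()
  flush <- function() {
    if (length(toks) > 0L) {
      tg <- if (scheme == "bio") bio_to_bioes(tags) else tags
      sentences[[length(sentences) + 1L]] <<-
        list(tokens = toks, tags = tg)
      toks <<- character(); tags <<- character()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(parts) != 2L)
      stop("line ", i, " of ", path, ": expected 2 columns, found ",
           length(parts))
    toks <- c(toks, parts[1L]); tags <- c(tags, parts[2L])
  }
  flush()
  if (length(sentences) == 0L) stop("no sentences in ", path)
  if (!is.null(tagset)) {
    all_tags <- unique(unlist(lapply(sentences, `[[`, "tags")))
    bad <- setdiff(all_tags, tagset)
    if (length(bad) > 0L)
      stop("tag(s) outside the tagset: ", paste(bad, collapse = ", "))
  }
  conll_document(sentences)
}

#' Write a corpus in two-column CoNLL format
#'
#' @param doc a [conll_document()] (sentences without tags are written
#'   with tag `O`).
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_conll <- function(doc, path) {
  sents <- as_sentence_list(doc)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sents) {
    tg <- if (is.null(s$tags)) rep("O", length(s$tokens)) else s$tags
    writeLines(paste(s$tokens, tg, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a structured configuration file
#'
#' YAML with optional `encoder`, `graph`, `training` and `ablation`
#' sections; every key of [mgner_control()] can be set, nested keys are
#' flattened, unknown keys are an error.
#'
#' @param path YAML file.
#' @return An [mgner_control()].
#' @export
read_mgner_config <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v)) for (k2 in names(v)) flat[[k2]] <- v[[k2]]
    else flat[[k]] <- v
  }
  known <- names(formals(mgner_control))
  bad <- setdiff(names(flat), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(mgner_control, flat)
}
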