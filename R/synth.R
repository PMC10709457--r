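#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the dictionary-matching structure the tagger is
#' built for: sentences carry non-overlapping gold entities whose surfaces
#' are (with probability `p_gold_in_dict`) dictionary entries, and the
#' dictionary additionally carries distractor entries that overlap or nest
#' with the gold spans, so a sentence exhibits overlapping, nested and
#' disjoint matches. Every entity type has a dedicated marker token that
#' is placed immediately before the gold span -- the planted rule "the
#' match directly preceded by a type marker is the entity, with that
#' marker's type" makes the gold tags derivable from the matching graph
#' plus local context, but not from the greedy leftmost-longest mask.
#'
#' Tokens come from two disjoint pools -- ordinary filler words and
#' entity-like words that dictionary surfaces (and a short padding after
#' each gold span) are drawn from -- so token identity reveals the entity
#' *region* but only the matching graph reveals the exact boundary.
#'
#' @param vocab_size word types per pool (marker tokens are extra).
#' @param n_sentences sentences to generate.
#' @param sentence_length inclusive length range in tokens.
#' @param n_dict_entries base dictionary entries (before distractors).
#' @param entry_length inclusive entry length range in tokens.
#' @param n_types entity types.
#' @param p_gold_in_dict probability a gold surface is a dictionary entry.
#' @param distractor_rate expected overlapping/nested distractor entries
#'   planted per sentence.
#' @param seed integer seed; everything is reproducible from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(vocab_size = 60L, n_sentences = 200L,
                         sentence_length = c(8L, 14L),
                         n_dict_entries = 50L, entry_length = c(1L, 4L),
                         n_types = 2L, p_gold_in_dict = 1,
                         distractor_rate = 2, seed = 1L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              n_sentences = as.integer(n_sentences),
              sentence_length = as.integer(sentence_length),
              n_dict_entries = as.integer(n_dict_entries),
              entry_length = as.integer(entry_length),
              n_types = as.integer(n_types),
              p_gold_in_dict = p_gold_in_dict,
              distractor_rate = distractor_rate, seed = as.integer(seed))
  stopifnot(cfg$vocab_size > 0L, cfg$n_sentences > 0L,
            length(cfg$sentence_length) == 2L,
            cfg$sentence_length[1L] >= 4L,
            diff(cfg$sentence_length) >= 0L,
            cfg$n_dict_entries > 0L, length(cfg$entry_length) == 2L,
            cfg$entry_length[1L] >= 1L, cfg$entry_length[2L] <= 5L,
            cfg$n_types >= 1L, cfg$p_gold_in_dict >= 0,
            cfg$p_gold_in_dict <= 1, cfg$distractor_rate >= 0)
  n_possible <- sum(as.numeric(cfg$vocab_size) ^
                      (cfg$entry_length[1L]:cfg$entry_length[2L]))
  if (cfg$n_dict_entries > n_possible)
    stop("config demands more distinct entries (", cfg$n_dict_entries,
         ") than the surface space allows (", n_possible, ")")
  class(cfg) <- "synth_config"
  cfg
}

# two disjoint word pools: filler words ("w...") and entity-like words
# ("e...") that dictionary surfaces and span padding are built from --
# mimicking the way biomedical entity tokens look different from ordinary
# prose while individual tokens do not identify entity boundaries
synth_word <- function(cfg, n) sprintf("w%03d", sample.int(cfg$vocab_size, n,
                                                           replace = TRUE))
synth_entity_word <- function(cfg, n)
  sprintf("e%03d", sample.int(cfg$vocab_size, n, replace = TRUE))
synth_types <- function(cfg) sprintf("T%d", seq_len(cfg$n_types))
synth_marker <- function(type) paste0("mk", sub("^T", "", type))

# draw n distinct random surfaces (character vectors of tokens)
draw_surfaces <- function(cfg, n, avoid = character()) {
  seen <- new.env(parent = emptyenv())
  for (k in avoid) seen[[k]] <- TRUE
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("config demands more distinct entries than the surface space ",
           "allows in practice")
    len <- sample(cfg$entry_length[1L]:cfg$entry_length[2L], 1L)
    toks <- synth_entity_word(cfg, len)
    key <- paste(toks, collapse = " ")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- toks
    }
  }
  out
}

# build one corpus against a fixed base-entry table; returns sentences,
# per-sentence manifest rows, and distractor entries to add to the dict
gen_corpus <- function(cfg, n_sentences, base, pool_ids, doc_prefix) {
  sentences <- vector("list", n_sentences)
  manifest <- vector("list", n_sentences)
  distractors <- list()
  types <- synth_types(cfg)
  for (s in seq_len(n_sentences)) {
    target_len <- sample(cfg$sentence_length[1L]:cfg$sentence_length[2L], 1L)
    # one gold entity, two when the sentence is long enough
    max_entry <- cfg$entry_length[2L]
    n_gold <- if (target_len >= 2L * (max_entry + 2L) &&
                  stats::runif(1) < 0.3) 2L else 1L
    toks <- character(); starts <- integer(); ends <- integer()
    gtypes <- character(); gsurf <- character(); in_dict <- logical()
    for (g in seq_len(n_gold)) {
      toks <- c(toks, synth_word(cfg, 1L + stats::rpois(1L, 1)))
      from_dict <- stats::runif(1) < cfg$p_gold_in_dict
      if (from_dict) {
        eid <- pool_ids[sample.int(length(pool_ids), 1L)]
        surf <- base$tokens[[eid]]; ty <- base$type[eid]
      } else {
        surf <- draw_surfaces(cfg, 1L,
                              avoid = vapply(base$tokens, paste, "",
                                             collapse = " "))[[1L]]
        ty <- sample(types, 1L)
      }
      toks <- c(toks, synth_marker(ty))
      starts <- c(starts, length(toks))      # 0-based span start
      toks <- c(toks, surf)
      ends <- c(ends, length(toks))
      # entity-like padding after the span: the lexical "entity region"
      # extends past the gold boundary, so the exact end is only visible
      # in the matching graph
      n_pad <- sample(0:2, 1L)
      if (n_pad > 0L) toks <- c(toks, synth_entity_word(cfg, n_pad))
      gtypes <- c(gtypes, ty)
      gsurf <- c(gsurf, paste(surf, collapse = " "))
      in_dict <- c(in_dict, from_dict)
    }
    if (length(toks) < target_len)
      toks <- c(toks, synth_word(cfg, target_len - length(toks)))
    L <- length(toks)
    # distractor entries overlapping/nesting the golds, never sharing a
    # gold start position: suffix, extension, super-span (incl. marker),
    # inner sub-span
    n_dis <- stats::rpois(1L, cfg$distractor_rate)
    dis_here <- character()
    for (k in seq_len(n_dis)) {
      g <- sample.int(n_gold, 1L)
      s0 <- starts[g]; e0 <- ends[g]; len <- e0 - s0
      kinds <- c(if (len >= 2L) "suffix",
                 if (e0 < L) "extend",
                 "super",
                 if (len >= 3L) "inner")
      kind <- kinds[sample.int(length(kinds), 1L)]
      span <- switch(kind,
                     suffix = c(s0 + 1L, e0),
                     extend = c(s0 + 1L, min(e0 + 1L, L)),
                     super  = c(s0 - 1L, e0),
                     inner  = c(s0 + 1L, e0 - 1L))
      if (span[2L] <= span[1L]) next
      surf <- paste(toks[(span[1L] + 1L):span[2L]], collapse = " ")
      ty <- sample(types, 1L)
      distractors[[length(distractors) + 1L]] <-
        list(surface = surf, type = ty)
      dis_here <- c(dis_here, surf)
    }
    tags <- encode_bioes(entity_spans(starts, ends, gtypes), L)
    doc_id <- sprintf("%s%04d", doc_prefix, s)
    sentences[[s]] <- list(tokens = toks, tags = tags, doc_id = doc_id)
    manifest[[s]] <- list(doc_id = doc_id, tokens = toks,
                          gold = data.frame(start = starts, end = ends,
                                            type = gtypes,
                                            surface = gsurf,
                                            in_dict = in_dict,
                                            stringsAsFactors = FALSE),
                          distractors = dis_here)
  }
  list(sentences = sentences, manifest = manifest,
       distractors = distractors)
}

#' Generate a synthetic corpus, dictionary and manifest
#'
#' Fully reproducible from `config$seed`. Gold spans never overlap each
#' other; distractor dictionary entries are planted as suffix / extension /
#' super-span / inner variants of gold spans so that dictionary matches
#' overlap and nest. The manifest enumerates every planted gold span (with
#' its surface and whether it is in the dictionary) and every distractor
#' surface, for exact assertions in tests.
#'
#' @param config a [synth_config()].
#' @return List with `corpus` (a [conll_document()]), `dictionary`
#'   (an [entity_dictionary()]), `entries` (data frame of dictionary rows
#'   with a `source` column, `base` or `distractor`), and `manifest`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  types <- synth_types(config)
  surfaces <- draw_surfaces(config, config$n_dict_entries)
  base <- list(tokens = surfaces,
               type = sample(types, config$n_dict_entries, replace = TRUE))
  gc <- gen_corpus(config, config$n_sentences, base,
                   seq_len(config$n_dict_entries), "synth")
  entries <- data.frame(
    surface = vapply(base$tokens, paste, "", collapse = " "),
    type = base$type, source = "base", stringsAsFactors = FALSE)
  if (length(gc$distractors) > 0L)
    entries <- rbind(entries, data.frame(
      surface = vapply(gc$distractors, `[[`, "", "surface"),
      type = vapply(gc$distractors, `[[`, "", "type"),
      source = "distractor", stringsAsFactors = FALSE))
  entries <- entries[!duplicated(paste(entries$surface, entries$type)), ]
  dict <- entity_dictionary(entries$surface, entries$type)
  list(corpus = conll_document(gc$sentences),
       dictionary = dict, entries = entries, manifest = gc$manifest)
}

#' Generate a train/test task with held-out dictionary entries
#'
#' The scenario the matching graph is designed for: part of the dictionary
#' (`holdout_frac`) is reserved for the test split, so test gold entities
#' have surfaces never seen as training golds, yet still matched by the
#' dictionary. A model that only memorizes training surfaces cannot
#' recover their boundaries; one that reads the matching graph can.
#'
#' @param config a [synth_config()]; `n_sentences` is the training size.
#' @param holdout_frac fraction of base entries reserved for test golds.
#' @param n_test test sentences (default 30% of training size, >= 30).
#' @return List with `train`, `test` (conll documents), `dictionary`,
#'   `entries`, `manifest` (list with `train` and `test`).
#' @export
synth_task <- function(config, holdout_frac = 0.25,
                       n_test = max(30L, round(config$n_sentences * 0.3))) {
  stopifnot(inherits(config, "synth_config"),
            holdout_frac > 0, holdout_frac < 1)
  set.seed(config$seed)
  types <- synth_types(config)
  surfaces <- draw_surfaces(config, config$n_dict_entries)
  base <- list(tokens = surfaces,
               type = sample(types, config$n_dict_entries, replace = TRUE))
  n_hold <- max(1L, round(holdout_frac * config$n_dict_entries))
  hold_ids <- sample.int(config$n_dict_entries, n_hold)
  train_ids <- setdiff(seq_len(config$n_dict_entries), hold_ids)
  tr <- gen_corpus(config, config$n_sentences, base, train_ids, "train")
  te <- gen_corpus(config, as.integer(n_test), base, hold_ids, "test")
  entries <- data.frame(
    surface = vapply(base$tokens, paste, "", collapse = " "),
    type = base$type, source = "base", stringsAsFactors = FALSE)
  dis <- c(tr$distractors, te$distractors)
  if (length(dis) > 0L)
    entries <- rbind(entries, data.frame(
      surface = vapply(dis, `[[`, "", "surface"),
      type = vapply(dis, `[[`, "", "type"),
      source = "distractor", stringsAsFactors = FALSE))
  entries <- entries[!duplicated(paste(entries$surface, entries$type)), ]
  dict <- entity_dictionary(entries$surface, entries$type)
  list(train = conll_document(tr$sentences),
       test = conll_document(te$sentences),
       dictionary = dict, entries = entries,
       holdout_ids = hold_ids,
       manifest = list(train = tr$manifest, test = te$manifest))
}

#' Hand-built overlapping-match fixture
#'
#' The canonical failure mode of the greedy masked feature: the gold
#' disease mention "Wilms ' tumor" is a dictionary entry, but a longer
#' dictionary entry ("Wilms ' tumor suppressor gene") starts at the same
#' token, so the leftmost-longest mask covers a strict super-span of the
#' gold entity. The full match list still contains the gold span.
#'
#' @return List with `tokens`, `dictionary`, `gold` (span data frame),
#'   `tags` (gold BIOES tags).
#' @export
fig_fixture_overlap <- function() {
  tokens <- c("the", "Wilms", "'", "tumor", "suppressor", "gene",
              "is", "mutated")
  dict <- entity_dictionary(
    c("Wilms ' tumor",
      "Wilms ' tumor suppressor gene",
      "tumor suppressor",
      "suppressor gene"),
    c("disease", "gene", "gene", "gene"))
  gold <- entity_spans(1L, 4L, "disease")
  list(tokens = tokens, dictionary = dict, gold = gold,
       tags = encode_bioes(gold, length(tokens)))
}

#' Write a generated corpus, dictionary and manifest to disk
#'
#' Emits the two-column CoNLL corpus, the tab-separated dictionary and a
#' JSON-lines manifest.
#'
#' @param synth output of [synth_generate()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_conll(synth$corpus, file.path(dir, "corpus.conll"))
  writeLines(paste(synth$entries$surface, synth$entries$type, sep = "\t"),
             file.path(dir, "dictionary.tsv"))
  con <- file(file.path(dir, "manifest.jsonl"), "w")
  on.exit(close(con))
  for (m in synth$manifest)
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA), con)
  invisible(dir)
}
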