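# Independent oracles kept deliberately naive; they never share code with
# the implementation paths they check.

# O(L^2) substring scan against a hash set of normalized entry surfaces.
# The reference for the automaton-based matcher.
brute_force_matches <- function(tokens, dict) {
  norm <- tolower(tokens)
  keys <- vapply(dict$tokens, paste, "", collapse = "\r")
  L <- length(tokens)
  out <- NULL
  for (i in seq_len(L)) for (j in i:L) {
    key <- paste(norm[i:j], collapse = "\r")
    hits <- which(keys == key)
    for (e in hits)
      out <- rbind(out, data.frame(start = i - 1L, end = j,
                                   type = dict$type[e], entry_id = e,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      type = character(), entry_id = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$end, out$entry_id), ]
  rownames(out) <- NULL
  out
}

sort_spans_oracle <- function(s) {
  s <- s[order(s$start, s$end, s$type), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# random non-overlapping span set over a sentence of length L
random_span_set <- function(L, types = c("gene", "disease")) {
  starts <- integer(); ends <- integer(); tps <- character()
  pos <- 0L
  while (pos < L) {
    if (stats::runif(1) < 0.4) {
      len <- sample.int(min(4L, L - pos), 1L)
      starts <- c(starts, pos); ends <- c(ends, pos + len)
      tps <- c(tps, sample(types, 1L))
      pos <- pos + len
    } else pos <- pos + 1L
  }
  if (length(starts) == 0L)
    entity_spans() else entity_spans(starts, ends, tps)
}

# random syntactically valid BIOES tag sequence (well-formed spans)
random_valid_tags <- function(L, types = c("gene", "disease")) {
  encode_bioes(random_span_set(L, types), L)
}

# independent exact-match pooled scorer: extracts spans with its own
# strict reader (valid sequences only) and counts multiset intersections
reference_pooled_prf <- function(pred_tags, gold_tags) {
  strict_spans <- function(tags) {
    out <- character()
    i <- 1L; L <- length(tags)
    while (i <= L) {
      tg <- tags[i]
      if (tg == "O") { i <- i + 1L; next }
      pre <- substr(tg, 1L, 1L); ty <- substring(tg, 3L)
      if (pre == "S") { out <- c(out, paste(i, i, ty)); i <- i + 1L; next }
      stopifnot(pre == "B")
      j <- i + 1L
      while (j <= L && tags[j] == paste0("I-", ty)) j <- j + 1L
      stopifnot(j <= L, tags[j] == paste0("E-", ty))
      out <- c(out, paste(i, j, ty))
      i <- j + 1L
    }
    out
  }
  cc <- 0L; pp <- 0L; gg <- 0L
  for (i in seq_along(pred_tags)) {
    ps <- strict_spans(pred_tags[[i]]); gs <- strict_spans(gold_tags[[i]])
    pp <- pp + length(ps); gg <- gg + length(gs)
    for (k in unique(ps))
      cc <- cc + min(sum(ps == k), sum(gs == k))
  }
  P <- if (pp > 0) cc / pp else 0
  R <- if (gg > 0) cc / gg else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = F1)
}

# shared tiny model setup used across neural tests
tiny_setup <- function(n_sentences = 3, seed = 2, ctl_args = list()) {
  syn <- synth_generate(synth_config(n_sentences = n_sentences,
                                     seed = seed))
  sents <- syn$corpus$sentences
  ctl <- do.call(mgner_control,
                 c(list(lstm_hidden = 3L, emb_dim = 4L, dropout = 0,
                        seed = 5L), ctl_args))
  types <- c("T1", "T2")
  tagset <- bioes_tagset(types)
  vocab <- sort(unique(unlist(lapply(sents, `[[`, "tokens"))))
  mask_symbols <- c("O", as.vector(t(outer(c("B", "M", "E", "S"), types,
                                           paste, sep = "-"))))
  list(syn = syn, sents = sents, ctl = ctl, tagset = tagset,
       vocab = vocab, mask_symbols = mask_symbols)
}

tiny_prep <- function(setup, i = 1L) {
  s <- setup$sents[[i]]
  mgner:::prepare_sentence(s$tokens, s$tags, setup$vocab, setup$tagset,
                           setup$syn$dictionary, setup$ctl,
                           setup$mask_symbols)
}

# central-difference numerical gradient vs analytic, worst relative error
# over a few sampled coordinates per parameter block
worst_grad_error <- function(p, prep, ctl, eps = 1e-6, per_block = 3L) {
  lossfun <- function(p) {
    acc <- new.env(parent = emptyenv())
    acc$g <- mgner:::zero_like(p)
    mgner:::sentence_loss_grad(p, prep, ctl, acc, train = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  acc$g <- mgner:::zero_like(p)
  mgner:::sentence_loss_grad(p, prep, ctl, acc, train = FALSE)
  worst <- 0
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(per_block, length(p[[nm]])))
    for (k in idx) {
      p1 <- p; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] - eps
      num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      ana <- acc$g[[nm]][k]
      worst <- max(worst, abs(num - ana) / max(1, abs(num), abs(ana)))
    }
  }
  worst
}
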