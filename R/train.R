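#' Learning-rate schedule
#'
#' Pure exponential decay: the rate at (0-based) epoch `e` is
#' `lr0 * decay^e`.
#'
#' @param lr0 initial learning rate.
#' @param decay multiplicative per-epoch decay (default 0.98).
#' @param epoch 0-based epoch index (vectorized).
#' @return Numeric vector of learning rates.
#' @export
lr_schedule <- function(lr0, decay, epoch) lr0 * decay^epoch

# map tokens/tags of one sentence into model-ready arrays; when a
# contextual-encoder adapter is given its subword vectors are summed per
# word here and used as fixed input features
prepare_sentence <- function(tokens, tags, vocab, tagset, dict, ctl,
                             mask_symbols = NULL, encoder = NULL) {
  L <- length(tokens)
  if (L < 1L) stop("empty sentence")
  if (any(!nzchar(tokens))) stop("empty token in sentence")
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- length(vocab) + 1L   # reserved unknown row
  gold <- NULL
  if (!is.null(tags)) {
    gold <- match(tags, tagset)
    if (anyNA(gold))
      stop("tag not in tagset: ", paste(unique(tags[is.na(gold)]),
                                        collapse = ", "))
  }
  matches <- find_matches(tokens, dict)
  mg <- match_graph(L, matches, self_loops = ctl$self_loops)
  mask_ids <- NULL
  if (ctl$use_mask_feature) {
    msk <- masked_baseline(tokens, dict)
    mask_ids <- match(msk, mask_symbols)
    if (anyNA(mask_ids))
      stop("mask symbol outside the known set: ",
           paste(unique(msk[is.na(mask_ids)]), collapse = ", "))
  }
  X_fixed <- NULL
  if (!is.null(encoder)) {
    out <- encoder(tokens)
    agg <- rowsum(out$vectors, group = out$word_map)
    X_fixed <- agg[order(as.integer(rownames(agg))), , drop = FALSE]
    if (nrow(X_fixed) != L)
      stop("encoder adapter returned ", nrow(X_fixed),
           " word vectors for a sentence of length ", L)
  }
  list(tokens = tokens, ids = ids, gold = gold,
       An_out = row_normalize(mg$a_out), An_in = row_normalize(mg$a_in),
       matches = matches, mask_ids = mask_ids, X_fixed = X_fixed)
}

adam_update <- function(p, g, state, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(p)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  p
}

predict_sentence <- function(p, prep, ctl, tagset) {
  fw <- model_forward(p, prep, ctl, train = FALSE)
  idx <- if (ctl$use_crf)
    crf_viterbi(fw$logits, p$crf_trans, p$crf_start, p$crf_end)
  else
    apply(fw$logits, 1L, which.max)
  tagset[idx]
}

corpus_f1 <- function(p, preps, ctl, tagset) {
  pred <- lapply(preps, function(pr) decode_bioes(
    predict_sentence(p, pr, ctl, tagset)))
  gold <- lapply(preps, function(pr) decode_bioes(tagset[pr$gold]))
  evaluate_ner(pred, gold)$pooled
}

#' Fit the matching-graph neural tagger
#'
#' Trains the full model -- trainable word embeddings (or an attached
#' contextual encoder), BiLSTM, T-layer bidirectional GCN over the
#' dictionary matching graph, and a token-softmax (optionally CRF)
#' classifier -- on a BIOES-tagged corpus with Adam, per-epoch learning
#' rate decay, embedding dropout, batch shuffling, and an L2 penalty on
#' the classifier projection. The tagset is closed at startup from the
#' corpus tags plus the dictionary types.
#'
#' @param corpus a [conll_document()] or list of `list(tokens, tags)`.
#' @param dictionary an [entity_dictionary()].
#' @param control an [mgner_control()].
#' @param dev optional held-out corpus; when given, the returned model is
#'   the best-dev-F1 checkpoint and the log carries dev scores.
#' @param encoder optional contextual-encoder adapter: a function taking a
#'   character vector of word tokens and returning
#'   `list(vectors = <n_subwords x d matrix>, word_map = <integer>)`; the
#'   subword vectors are summed per word and replace the embedding table
#'   (they are treated as fixed features).
#' @return An object of class `mgner`.
#' @examples
#' \donttest{
#' syn <- synth_task(synth_config(n_sentences = 30, seed = 1))
#' ctl <- mgner_control(lstm_hidden = 8, emb_dim = 8, max_epochs = 2,
#'                      batch_size = 10, seed = 1)
#' fit <- mgner(syn$train, syn$dictionary, ctl)
#' predict(fit, syn$test$sentences[[1]]$tokens)
#' }
#' @export
mgner <- function(corpus, dictionary, control = mgner_control(),
                  dev = NULL, encoder = NULL) {
  ctl <- control
  stopifnot(inherits(dictionary, "entity_dictionary"))
  sents <- as_sentence_list(corpus)
  if (length(sents) == 0L) stop("empty corpus")
  set.seed(ctl$seed)
  types <- sort(unique(c(
    unlist(lapply(sents, function(s) span_types(s$tags))),
    dictionary$type)))
  tagset <- bioes_tagset(types)
  vocab <- sort(unique(unlist(lapply(sents, `[[`, "tokens"))))
  mask_symbols <- if (ctl$use_mask_feature)
    c("O", as.vector(t(outer(c("B", "M", "E", "S"), types, paste,
                             sep = "-"))))
  else NULL
  if (!is.null(encoder)) {
    probe <- encoder("probe")
    ctl$emb_dim <- ncol(probe$vectors)   # adapter feature width
  }
  preps <- lapply(sents, function(s)
    prepare_sentence(s$tokens, s$tags, vocab, tagset, dictionary, ctl,
                     mask_symbols, encoder))
  dev_preps <- if (!is.null(dev))
    lapply(as_sentence_list(dev), function(s)
      prepare_sentence(s$tokens, s$tags, vocab, tagset, dictionary, ctl,
                       mask_symbols, encoder))
  p <- init_params(ctl, length(vocab), length(tagset),
                   length(mask_symbols))
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- zero_like(p); state$v <- zero_like(p)
  n <- length(preps)
  log_rows <- list()
  best <- list(f1 = -Inf, params = p, epoch = 0L)
  for (epoch in seq_len(ctl$max_epochs)) {
    lr <- lr_schedule(ctl$lr_model, ctl$lr_decay, epoch - 1L)
    ord <- sample.int(n)
    epoch_loss <- 0
    for (b in seq_len(ceiling(n / ctl$batch_size))) {
      take <- ord[((b - 1L) * ctl$batch_size + 1L):
                    min(b * ctl$batch_size, n)]
      acc <- new.env(parent = emptyenv())
      acc$g <- zero_like(p)
      for (i in take)
        epoch_loss <- epoch_loss +
          sentence_loss_grad(p, preps[[i]], ctl, acc, train = TRUE)
      acc$g$W_p <- acc$g$W_p + 2 * ctl$l2_softmax * p$W_p
      p <- adam_update(p, acc$g, state, lr)
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = epoch_loss / n,
                      train_p = NA_real_, train_r = NA_real_,
                      train_f1 = NA_real_, dev_p = NA_real_,
                      dev_r = NA_real_, dev_f1 = NA_real_)
    monitored <- NA_real_
    if (epoch %% ctl$eval_every == 0L || epoch == ctl$max_epochs) {
      tr <- corpus_f1(p, preps, ctl, tagset)
      row$train_p <- tr["precision"]; row$train_r <- tr["recall"]
      row$train_f1 <- tr["f1"]
      monitored <- tr["f1"]
      if (!is.null(dev_preps)) {
        dv <- corpus_f1(p, dev_preps, ctl, tagset)
        row$dev_p <- dv["precision"]; row$dev_r <- dv["recall"]
        row$dev_f1 <- dv["f1"]
        monitored <- dv["f1"]
      }
      if (monitored > best$f1)
        best <- list(f1 = monitored, params = p, epoch = epoch)
    }
    log_rows[[epoch]] <- row
    if (ctl$verbose)
      message(sprintf(
        "epoch %3d  lr %.5f  loss %8.4f  train F1 %s  dev F1 %s",
        epoch, lr, row$loss,
        ifelse(is.na(row$train_f1), "-", sprintf("%.4f", row$train_f1)),
        ifelse(is.na(row$dev_f1), "-", sprintf("%.4f", row$dev_f1))))
    if (!is.null(ctl$early_stop_f1) && !is.na(monitored) &&
        monitored >= ctl$early_stop_f1) break
  }
  use_best <- !is.null(dev_preps) && best$f1 > -Inf
  structure(list(
    params = if (use_best) best$params else p,
    final_params = p,
    control = ctl, tagset = tagset, vocab = vocab, types = types,
    mask_symbols = mask_symbols, dictionary = dictionary,
    encoder = encoder,
    log = do.call(rbind, log_rows),
    best_epoch = if (use_best) best$epoch else length(log_rows),
    n_train = n), class = "mgner")
}

# entity types occurring in a BIOES tag vector
span_types <- function(tags) {
  t <- vapply(tags, function(x) split_tag(x)$type, "")
  unique(t[nzchar(t)])
}

as_sentence_list <- function(corpus) {
  if (inherits(corpus, "conll_document")) return(corpus$sentences)
  stopifnot(is.list(corpus))
  if (!is.null(corpus$sentences)) return(corpus$sentences)
  corpus
}
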