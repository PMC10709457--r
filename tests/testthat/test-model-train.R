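# small end-to-end training checks; dimensions are kept tiny so the whole
# file runs in well under a minute

test_that("the learning rate decays exponentially per epoch", {
  expect_equal(lr_schedule(1e-3, 0.98, 0:3),
               1e-3 * 0.98^(0:3))
  syn <- synth_generate(synth_config(n_sentences = 6, seed = 2))
  ctl <- mgner_control(lstm_hidden = 4, emb_dim = 4, batch_size = 3,
                       max_epochs = 3, seed = 1)
  fit <- mgner(syn$corpus, syn$dictionary, ctl)
  expect_equal(fit$log$lr, lr_schedule(ctl$lr_model, ctl$lr_decay, 0:2))
})

test_that("training is deterministic given the seed", {
  syn <- synth_generate(synth_config(n_sentences = 8, seed = 3))
  ctl <- mgner_control(lstm_hidden = 4, emb_dim = 4, batch_size = 4,
                       max_epochs = 1, seed = 11)
  f1 <- mgner(syn$corpus, syn$dictionary, ctl)
  f2 <- mgner(syn$corpus, syn$dictionary, ctl)
  expect_identical(f1$log$loss[1], f2$log$loss[1])
  expect_identical(f1$params$W_p, f2$params$W_p)
})

test_that("a small model overfits a small corpus to perfect training F1", {
  syn <- synth_generate(synth_config(n_sentences = 20, seed = 11))
  ctl <- mgner_control(lstm_hidden = 24, emb_dim = 24, batch_size = 5,
                       max_epochs = 50, seed = 1, early_stop_f1 = 1)
  fit <- mgner(syn$corpus, syn$dictionary, ctl)
  final <- fit$log$train_f1[!is.na(fit$log$train_f1)]
  expect_equal(final[length(final)], 1)
})

test_that("empty corpora and tags outside the closed tagset are rejected", {
  syn <- synth_generate(synth_config(n_sentences = 3, seed = 4))
  expect_error(mgner(list(), syn$dictionary), "empty corpus")
  # the tagset is closed over the training corpus + dictionary types at
  # startup; a dev sentence with a foreign tag must fail, not be remapped
  bad_dev <- syn$corpus
  bad_dev$sentences[[1]]$tags[1] <- "B-unknowntype"
  ctl <- mgner_control(lstm_hidden = 2, emb_dim = 2, max_epochs = 1)
  expect_error(mgner(syn$corpus, syn$dictionary, ctl, dev = bad_dev),
               "unknowntype")
})

test_that("an empty dictionary cannot be built, and T = 0 ignores the graph", {
  # the no-graph model is the layers = 0 configuration; with it, the
  # predictions do not depend on the dictionary content at all
  syn <- synth_generate(synth_config(n_sentences = 6, seed = 5))
  other_dict <- entity_dictionary("zzz qqq", "T1")
  ctl <- mgner_control(lstm_hidden = 4, emb_dim = 4, batch_size = 3,
                       max_epochs = 2, seed = 1, layers = 0)
  f1 <- mgner(syn$corpus, syn$dictionary, ctl)
  f2 <- mgner(syn$corpus, other_dict, ctl)
  s <- syn$corpus$sentences[[1]]$tokens
  expect_identical(predict(f1, s), predict(f2, s))
})

test_that("predict returns parseable tags and spans for new sentences", {
  syn <- synth_generate(synth_config(n_sentences = 10, seed = 6))
  ctl <- mgner_control(lstm_hidden = 4, emb_dim = 4, batch_size = 5,
                       max_epochs = 2, seed = 1)
  fit <- mgner(syn$corpus, syn$dictionary, ctl)
  toks <- c("w001", "never-seen-token", "mk1", "e003")
  tags <- predict(fit, toks)
  expect_length(tags, 4)
  expect_true(all(tags %in% fit$tagset))
  spans <- predict(fit, toks, type = "spans")
  expect_s3_class(spans, "data.frame")
  both <- predict(fit, list(toks, toks))
  expect_identical(both[[1]], both[[2]])
})

test_that("checkpoints round-trip through disk", {
  syn <- synth_generate(synth_config(n_sentences = 5, seed = 7))
  ctl <- mgner_control(lstm_hidden = 3, emb_dim = 3, batch_size = 5,
                       max_epochs = 1, seed = 1)
  fit <- mgner(syn$corpus, syn$dictionary, ctl)
  f <- withr::local_tempfile(fileext = ".rds")
  save_mgner(fit, f)
  back <- load_mgner(f)
  toks <- syn$corpus$sentences[[2]]$tokens
  expect_identical(predict(fit, toks), predict(back, toks))
  expect_error(load_mgner(withr::local_tempfile(fileext = ".rds",
                                                lines = "x")),
               "checkpoint")
})

test_that("the dev split drives checkpoint selection and logging", {
  syn <- synth_task(synth_config(n_sentences = 12, seed = 8), n_test = 5)
  ctl <- mgner_control(lstm_hidden = 4, emb_dim = 4, batch_size = 6,
                       max_epochs = 3, seed = 1)
  fit <- mgner(syn$train, syn$dictionary, ctl, dev = syn$test)
  expect_false(all(is.na(fit$log$dev_f1)))
  expect_true(fit$best_epoch %in% fit$log$epoch)
})

test_that("a subword adapter feeds summed word vectors through the model", {
  # toy adapter: each word splits into one subword per character, each
  # subword vector is a 3-dim character statistic
  adapter <- function(tokens) {
    chars <- strsplit(tokens, "")
    n <- lengths(chars)
    vecs <- do.call(rbind, lapply(unlist(chars), function(ch)
      c(utf8ToInt(ch) %% 7, utf8ToInt(ch) %% 3, 1)))
    list(vectors = vecs, word_map = rep(seq_along(tokens), n))
  }
  syn <- synth_generate(synth_config(n_sentences = 6, seed = 9))
  ctl <- mgner_control(lstm_hidden = 4, emb_dim = 99, batch_size = 3,
                       max_epochs = 2, seed = 1)
  fit <- mgner(syn$corpus, syn$dictionary, ctl, encoder = adapter)
  expect_equal(fit$control$emb_dim, 3L)  # adapter width replaces emb_dim
  toks <- syn$corpus$sentences[[1]]$tokens
  expect_length(predict(fit, toks), length(toks))
})

test_that("masked-manner feature and CRF head train end to end", {
  syn <- synth_generate(synth_config(n_sentences = 8, seed = 10))
  for (args in list(list(use_mask_feature = TRUE, mask_emb_dim = 3),
                    list(use_crf = TRUE))) {
    ctl <- do.call(mgner_control,
                   c(list(lstm_hidden = 4, emb_dim = 4, batch_size = 4,
                          max_epochs = 2, seed = 1), args))
    fit <- mgner(syn$corpus, syn$dictionary, ctl)
    expect_true(all(is.finite(fit$log$loss)))
    toks <- syn$corpus$sentences[[1]]$tokens
    expect_length(predict(fit, toks), length(toks))
  }
})
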