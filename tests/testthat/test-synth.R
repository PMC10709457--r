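test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_sentences = 20, seed = 9)
  a <- synth_generate(cfg)
  b <- synth_generate(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$entries, b$entries)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth(a, d1); write_synth(b, d2)
  for (f in c("corpus.conll", "dictionary.tsv", "manifest.jsonl"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("with p_gold_in_dict = 1 every gold span is matched", {
  syn <- synth_generate(synth_config(n_sentences = 40, seed = 5,
                                     p_gold_in_dict = 1))
  for (i in seq_along(syn$corpus$sentences)) {
    s <- syn$corpus$sentences[[i]]
    gold <- decode_bioes(s$tags)
    m <- find_matches(s$tokens, syn$dictionary)
    for (k in seq_len(nrow(gold)))
      expect_true(any(m$start == gold$start[k] & m$end == gold$end[k]),
                  label = sprintf("gold span %d of sentence %d matched",
                                  k, i))
  }
})

test_that("distractors push matches-per-sentence above golds-per-sentence", {
  syn <- synth_generate(synth_config(n_sentences = 100, seed = 6,
                                     distractor_rate = 2))
  n_matches <- 0; n_gold <- 0
  for (s in syn$corpus$sentences) {
    n_matches <- n_matches + nrow(find_matches(s$tokens, syn$dictionary))
    n_gold <- n_gold + nrow(decode_bioes(s$tags))
  }
  expect_gt(n_matches / 100, n_gold / 100)
})

test_that("the manifest enumerates exactly the planted structure", {
  syn <- synth_generate(synth_config(n_sentences = 15, seed = 7))
  expect_length(syn$manifest, 15)
  for (i in 1:15) {
    m <- syn$manifest[[i]]
    s <- syn$corpus$sentences[[i]]
    expect_identical(m$tokens, s$tokens)
    planted <- entity_spans(m$gold$start, m$gold$end, m$gold$type)
    expect_equal(sort_spans_oracle(decode_bioes(s$tags)),
                 sort_spans_oracle(planted), ignore_attr = TRUE)
    # every distractor surface really is a dictionary entry
    for (surf in m$distractors)
      expect_true(surf %in% syn$entries$surface)
  }
})

test_that("generated corpora survive round-trips and the matcher oracle", {
  syn <- synth_generate(synth_config(n_sentences = 10, seed = 8))
  for (s in syn$corpus$sentences) {
    spans <- decode_bioes(s$tags)
    expect_equal(encode_bioes(spans, length(s$tokens)), s$tags)
    got <- find_matches(s$tokens, syn$dictionary)
    rownames(got) <- NULL
    expect_equal(got, brute_force_matches(s$tokens, syn$dictionary))
  }
})

test_that("impossible configurations are rejected", {
  expect_error(synth_config(vocab_size = 2, entry_length = c(1, 1),
                            n_dict_entries = 10),
               "more distinct entries")
})

test_that("the train/test task holds dictionary entries out of training", {
  task <- synth_task(synth_config(n_sentences = 40, seed = 10),
                     holdout_frac = 0.25)
  held <- vapply(seq_along(task$holdout_ids), function(i)
    task$entries$surface[task$holdout_ids[i]], "")
  train_surfaces <- unlist(lapply(task$manifest$train,
                                  function(m) m$gold$surface))
  test_surfaces <- unlist(lapply(task$manifest$test,
                                 function(m) m$gold$surface))
  expect_length(intersect(held, train_surfaces), 0)
  expect_true(all(test_surfaces %in% held))
})

test_that("the overlap fixture exhibits the overlong-mask failure mode", {
  fx <- fig_fixture_overlap()
  gold <- fx$gold
  m <- find_matches(fx$tokens, fx$dictionary)
  # the gold span itself is in the dictionary ...
  expect_true(any(m$start == gold$start & m$end == gold$end &
                    m$type == gold$type))
  # ... but the greedy mask recovers a strict super-span of it
  mask <- masked_baseline(fx$tokens, fx$dictionary)
  covered <- which(mask != "O") - 1L
  expect_true(all(gold$start:(gold$end - 1) %in% covered))
  expect_gt(length(covered), gold$end - gold$start)
  first <- min(covered); last <- max(covered) + 1L
  expect_true(first <= gold$start && last >= gold$end &&
                (last - first) > (gold$end - gold$start))
})
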