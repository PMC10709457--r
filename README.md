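# mgner — dictionary matching-graph neural tagger for biomedical NER

`mgner` is an R package for biomedical named entity recognition (BioNER)
that uses an entity dictionary (gazetteer) as a **matching graph** instead
of the classic greedy masked feature. It is aimed at text-mining
practitioners who have a token-level annotated corpus (CoNLL two-column
format, BIOES or BIO tags) and a list of known entity surface forms, and
want the dictionary to help with entities that never occur in training
data.

## The idea

A sentence can match many dictionary entries at once, and the matches
overlap and nest: in *"Wilms ' tumor suppressor gene ..."* the disease
`Wilms ' tumor` sits inside the gene `Wilms ' tumor suppressor gene`.
A greedy longest-match mask commits to one candidate — here the overlong
gene — and misleads the model. `mgner` instead keeps **every** match as a
directed edge from its first to its last token, giving binary adjacencies
$A^{out}$ and $A^{in} = (A^{out})^\top$ over the sentence. On top of a
BiLSTM encoder (states $h_i = [h_i^f, h_i^b]$), a bidirectional graph
convolutional network encodes the graph, per layer:

    Q_out  = Relu( rownorm(A_out) H_t W_out )
    Q_in   = Relu( rownorm(A_in)  H_t W_in  )
    H_{t+1} = LayerNorm( H_t + Relu([Q_out, Q_in] W_O) )

with the two directions fused in every layer and a residual connection.
After `T` layers (default 2), tokens are classified into BIOES tags with a
softmax head, `p(y_i | X) = softmax(h_i W_p)`, trained by summed
negative log-likelihood (a linear-chain CRF head is available via
`use_crf = TRUE`). Scoring is exact-match entity F1 from pooled counts:
`P = Σc/Σp`, `R = Σc/Σg`, `F1 = 2PR/(P+R)`.

Because no benchmark corpus ships with the package, a seeded synthetic
generator (`synth_config()`, `synth_generate()`, `synth_task()`) builds
corpora with exactly the overlapping/nested/disjoint match structure the
method targets, including a held-out-dictionary-entry task where test
entities are covered by the dictionary but never seen in training.

## Worked example

```r
library(mgner)

# a seeded synthetic task: 60 training sentences; test entities are drawn
# from dictionary entries never used as training golds
task <- synth_task(synth_config(n_sentences = 60, seed = 7))
task$dictionary
#> Entity dictionary: 184 entries, 2 type(s), normalization 'casefold'

ctl <- mgner_control(lstm_hidden = 24, emb_dim = 24, batch_size = 10,
                     max_epochs = 30, layers = 2, seed = 1, use_crf = TRUE)
fit <- mgner(task$train, task$dictionary, ctl)
fit
#> Matching-graph neural tagger (BiLSTM + BiGCN + CRF)
#>   60 training sentences, vocab 117, tagset 9 (T1, T2)
#>   dictionary: 184 entries; BiGCN layers T = 2
#>   trained 30 epoch(s); final mean loss 1.1022; train F1 0.9577

# in this corpus "mk1" marks a type-1 entity whose exact extent is only
# knowable from the dictionary match edge ("e..." words are entity-like)
s <- task$train$sentences[[2]]$tokens
s
#>  [1] "w057" "w008" "mk1"  "e039" "e057" "e057" "e056" "w014" "w026"
#> [10] "w044" "w046" "w028" "w005" "w013"
predict(fit, s)
#>  [1] "O" "O" "O" "B-T1" "I-T1" "I-T1" "E-T1" "O" "O" "O" "O" "O" "O" "O"

# exact-match entity scores on the held-out-entry test split
pred <- predict(fit, task$test, type = "spans")
gold <- lapply(task$test$sentences, function(x) decode_bioes(x$tags))
evaluate_ner(pred, gold)
#> Exact-match entity scores (pooled counts)
#>   P = 0.4286  R = 0.4167  F1 = 0.4225   (c=15 p=35 g=36)
#> Per type:
#>  type  c  p  g precision recall     f1
#>    T1 10 19 17    0.5263 0.5882 0.5556
#>    T2  5 16 19    0.3125 0.2632 0.2857
#> Macro average over types: P = 0.4194  R = 0.4257  F1 = 0.4206
```

The tiny 60-sentence model already recovers about 42% of test entities it
never saw in training exactly (boundaries and type), because the
dictionary edge tells it where an unseen entity ends; the same model
without the graph module (`layers = 0`, everything else identical) scores
0.0 here, which is the package's central ablation (see the vignette and
`scripts/acceptance.R`).

The printed report gives the pooled count-ratio scores (the headline),
the per-type table, and the cross-type macro average. `plot(fit)` shows
the loss/F1 training curve; `coef(fit)` returns the parameter blocks;
`summary(fit)` adds the parameter count and the last log rows.

The same pipeline is scriptable from a shell via the bundled CLI:

```sh
mgner synth --out data --seed 7
mgner train --train data/corpus.conll --dict data/dictionary.tsv --model m.rds
mgner predict --model m.rds --input data/corpus.conll --output pred.conll
mgner evaluate --pred pred.conll --gold data/corpus.conll
mgner build-graph --input data/corpus.conll --dict data/dictionary.tsv --output edges.tsv
```

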