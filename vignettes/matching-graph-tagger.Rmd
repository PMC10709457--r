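---
title: "The dictionary matching-graph tagger: model, design choices, and what the synthetic studies show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dictionary matching-graph tagger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgner)
```

## The problem

Biomedical named entity recognition (BioNER) locates and types gene,
chemical and disease mentions in text. Neural taggers learn this from
labeled data, but many entities occur rarely or never in any training set,
while large curated dictionaries (gazetteers) of entity surface forms
exist. The classic way to inject a dictionary is a *masked* input feature:
greedily mark the tokens of the longest dictionary match at each position
and feed the marks to the encoder. That works only when matches are
disjoint. Real sentences produce overlapping and nested matches --
`Wilms ' tumor` (a disease) sits inside `Wilms ' tumor suppressor gene`
(a gene), which overlaps `tumor suppressor` -- and a greedy mask then
commits to one, often overlong, candidate and actively misleads the model.

`mgner` implements the alternative this package is organized around: keep
*every* match. Each dictionary match becomes one directed edge of a
*matching graph* over the sentence's tokens, from the match's first token
to its last. A bidirectional graph convolutional network (BiGCN) encodes
that graph on top of a BiLSTM sentence encoder, and each token is
classified into BIOES tags.

## The model

Tokens are embedded (a trainable table by default; a frozen contextual
encoder can be attached through an adapter that sums subword vectors per
word) and passed through a bidirectional LSTM with the standard
input/forget/output gate equations; the per-token state is the
concatenation of the forward and backward hidden states,
$h_i = [h_i^f, h_i^b]$, giving $H_0 \in \mathbb{R}^{L \times d_h}$.

A sentence of length $L$ with match set $M$ yields a binary forward
adjacency $A^{out}$ with $A^{out}_{s,e-1} = 1$ for every match spanning
$[s, e)$, and $A^{in} = (A^{out})^\top$. One BiGCN layer computes

$$Q_{out} = \mathrm{Relu}\!\left(\tfrac{1}{|A^{out}|} A^{out} H_t W_{out}\right),
\qquad
Q_{in} = \mathrm{Relu}\!\left(\tfrac{1}{|A^{in}|} A^{in} H_t W_{in}\right),$$

$$H_{t+1} = \mathrm{Norm}\!\left(H_t + \mathrm{Relu}([Q_{out}, Q_{in}]\, W_O)\right),$$

where $\tfrac{1}{|A|}$ denotes row normalization (each nonzero row of the
adjacency divided by its row sum, i.e. a mean over graph neighbors;
all-zero rows stay zero), $[\cdot,\cdot]$ is column concatenation, and the
two directions are fused in *every* layer, not only after the last. After
$T$ layers, token $i$ is classified by
$p(y_i \mid X) = \mathrm{softmax}(h_i^T W_p)$ and training minimizes the
sum (not mean) of per-token negative log-likelihoods,
$\sum_i -\log p(y_i = y_i^\ell \mid X)$.

Three reading choices in the update were genuinely open and are fixed here
as follows:

* **Norm** is layer normalization over the hidden dimension, with
  learnable gain and bias. It is the standard residual companion, and it
  keeps the zero-graph case analyzable: with an empty adjacency the layer
  reduces *exactly* to $\mathrm{Norm}(H_t)$ (a unit test asserts this).
* **Shapes**: $W_{out}, W_{in} \in \mathbb{R}^{d_h \times d_h}$ and
  $W_O \in \mathbb{R}^{2 d_h \times d_h}$, so the residual addition
  type-checks without extra projections.
* **Weights are untied across layers** by default
  (`share_gcn_weights = TRUE` ties them).

Edge conventions: the edge runs from the match's first to its *last*
token (index `end - 1`; spans are 0-based half-open everywhere else).
Single-token matches become self-loops, so the graph still carries their
signal (`self_loops = FALSE` drops them). The adjacency is binary and
type-agnostic -- several entries sharing a span still give one edge;
entry types stay on the match list for the masked baseline and
diagnostics.

### Heads: softmax and CRF

The default head is the token-wise softmax loss above. A linear-chain CRF
head (`use_crf = TRUE`) is also provided, with exact forward-backward
gradients and Viterbi decoding, because the two are not interchangeable on
this architecture: matching-graph edges touch only the *endpoints* of a
candidate span. Under a token-independent softmax, an interior token of a
long entity receives no graph signal at all and cannot be distinguished
from a token just past the entity's end. The CRF turns confident
endpoint predictions into complete spans through its transition structure.
The ablation study below therefore runs all variants with the CRF head;
the softmax head remains the default because it is the literal reading of
the loss definition.

### Ablation switches

* `single_gcn`: forward branch only; the fusion weight shrinks to
  $d_h \times d_h$. The backward branch is what lets an entity's *last*
  token see its marker-adjacent start, so this ablation primarily breaks
  end-boundary detection.
* `no_residual`: drop the $H_t$ term inside Norm.
* `late_fusion`: each direction keeps its own residual stream
  ($H^{dir}_{t+1} = \mathrm{Norm}(H^{dir}_t + Q^{dir})$) and the streams
  are fused once, after layer $T$, against the encoder output.
* `no_bilstm`: replace the BiLSTM with a linear projection of the
  embeddings.
* `layers = 0`: no graph module at all (the no-graph baseline).
* `use_mask_feature`: embed the greedy masked-manner sequence and
  concatenate it to the encoder input -- the classic baseline the
  matching graph replaces, kept for comparison.

### Training protocol and defaults

Adam (the optimizer named in the reference protocol; the loss section's
"SGD" is read as generic terminology for gradient descent) with model
learning rate $10^{-3}$ decayed by $0.98$ per epoch
($\mathrm{lr}_e = \mathrm{lr}_0 \cdot 0.98^{e}$, $e$ 0-based), batch
shuffling, batch size 50, dropout 0.1 on embeddings only, L2 penalty
$10^{-4}$ on the classifier projection $W_p$ only, at most 50 epochs,
BiLSTM hidden size 256 per direction, embedding size 100, and $T = 2$
BiGCN layers. All of these are `mgner_control()` defaults. One master
seed controls initialization, batch order and dropout; two runs with the
same seed produce identical losses. With a dev split, the best-dev-F1
checkpoint is kept.

All gradients -- BiLSTM backpropagation through time, the BiGCN layers in
every ablation variant, layer norm, both heads, embeddings -- are
hand-derived and verified in the test suite against central-difference
numerical gradients at $10^{-6}$ step, to relative error below $10^{-4}$
(the loose end of that tolerance is ReLU-kink finite-difference noise, not
gradient error).

## Evaluation

Scoring is exact-match at the entity level: a predicted span counts only
if start, end and type all equal a gold span's, each gold matched at most
once. The headline numbers pool counts over all sentences and types:
$P = \sum c_i / \sum p_i$, $R = \sum c_i / \sum g_i$,
$F_1 = 2PR/(P+R)$. Because "macro-averaged" is ambiguous for these
count-ratio formulas, the per-type table and the unweighted cross-type
macro average are reported alongside, clearly labeled; the pooled scores
are the headline. Zero denominators give 0 by convention.

Model output can be ill-formed BIOES; decoding is total. Well-formed runs
decode exactly (so decode-after-encode is the identity, property-tested),
and an ill-formed run -- a stray `I`/`E`, a `B` without closure -- is
repaired conservatively: the maximal same-type run of non-`O` tags
becomes one span. The repair rule is a package choice; the reference
protocol never states one.

## The synthetic corpus generator

No benchmark corpus or curated dictionary ships with the package;
`synth_config()` / `synth_generate()` build seeded corpora that reproduce
the *structure* the method targets, so every pipeline stage is testable
offline:

* Two disjoint word pools: filler words (`w013`) and entity-like words
  (`e027`) that dictionary surfaces are drawn from. This mirrors
  biomedical text, where entity tokens look different from ordinary prose
  but single tokens do not determine boundaries.
* Every entity type has a marker token (`mk1`, `mk2`) placed immediately
  before each gold span -- the planted disambiguation rule is "the match
  that starts right after a marker is the entity, typed by the marker".
* After each gold span, 0--2 entity-like *padding* tokens follow, so the
  lexical "entity region" extends past the true boundary: token identity
  reveals the region, only the matching-graph edge reveals the exact end.
* Distractor dictionary entries are planted as suffix / extension /
  super-span / inner variants of gold placements (never sharing the gold
  start), so matches overlap and nest; `distractor_rate` sets their
  expected number per sentence. The super-span distractor starts at the
  marker, which is what makes the greedy mask overlong.
* With `p_gold_in_dict` < 1 a gold surface is a fresh non-dictionary
  sequence, emulating dictionary incompleteness.

Defaults (`vocab_size = 60` per pool, 200 sentences of length 8--14, 50
base entries of 1--4 tokens, 2 types, `p_gold_in_dict = 1`,
`distractor_rate = 2`) were fixed once, as a corpus in which a typical
sentence carries one or two gold entities and more dictionary matches
than entities. `synth_task()` additionally reserves a fraction
(default 25%) of the dictionary for test-split golds only: test entities
are covered by the dictionary but never seen as training golds -- the
exact scenario dictionary knowledge is supposed to solve.

An earlier generator drew entity surfaces from the same pool as filler.
That version was discarded for a structural reason worth recording:
interior tokens of length-3+ entities then carry no information (edges
touch only endpoints), so the gold tags were *not* derivable from matches
plus context, and measured recall on held-out long entities was zero
regardless of the graph. The planted-rule property -- graph information
sufficient for high F1 -- drove the redesign above.

What the generator does **not** emulate: real token statistics, subword
structure, type ambiguity of real dictionaries, discontinuous or nested
*gold* entities (nesting exists only among dictionary matches, as in the
benchmark corpora). Passing the synthetic studies therefore shows the
machinery works and the graph carries the designed signal; it does not
certify benchmark-level accuracy on real corpora, which requires the full
datasets, a curated dictionary and a fine-tuned contextual encoder.

## The two synthetic studies

**Overfit capacity.** A 200-sentence corpus, embedding and hidden size
32, $T = 2$, pinned seed: training-set F1 must reach 1.0 within 50
epochs. This is a pure capacity/correctness check of the whole training
loop (it typically converges in well under half the epoch budget).

**Graph utility.** On the held-out-entry task (`synth_task`, 150 training
sentences), the full model, the `single_gcn` ablation and the no-graph
model are each trained for 30 epochs with the CRF head at three seeds.
The median test F1 of the full model must exceed both ablations by at
least 5 F1 points. The direction is forced by the design: the no-graph
model cannot know where an unseen entity ends; the forward-only GCN
informs starts but not ends. The sizes (hidden 24, 3 seeds, 30 epochs)
are the package's desk-scale study configuration; they trade statistical
tightness for runtime, which is why the margin is asserted on medians,
not means. Longer training at larger widths raises all three scores
without changing the ordering.

A deterministic companion fixture (`fig_fixture_overlap()`) pins the
structural premise: a gold `Wilms ' tumor` that is in the dictionary
while the greedy mask commits to the overlong
`Wilms ' tumor suppressor gene` super-span.

## Numerical and degenerate-input choices

* Row normalization leaves all-zero adjacency rows zero; tokens in no
  match receive only the residual path, with no special casing.
* Layer norm uses $\varepsilon = 10^{-5}$; softmax subtracts the row max.
* Matching is exact token matching after case-folding (configurable to
  `none`); the original casing is preserved for the encoder. Case-folding
  is the mildest recall-friendly normalization, chosen because the
  reference protocol is silent.
* Ties in the greedy mask (equal-length matches at one position) break by
  lowest entry id; dictionary entry ids are assigned in order of first
  appearance after deduplication, so the mask is deterministic.
* LSTM forget-gate biases initialize to 1 (standard practice for gradient
  flow); other weights are Glorot-uniform; embeddings are
  $\mathcal{N}(0, 0.1^2)$.
* Unknown tokens at prediction time map to a reserved embedding row;
  unknown *tags* in input are an error, never silently remapped, because
  the tagset is closed at model setup from the corpus tags plus the
  dictionary types.

## Known limitations

* Training is plain R; it is comfortable at the desk scale used in the
  studies (seconds per epoch) but not meant for the full benchmark
  corpora at their reference dimensions.
* The CRF head uses unconstrained learned transitions; illegal BIOES
  transitions are discouraged by training, not forbidden, and the total
  decoder repairs any remaining ill-formed runs.
* The contextual-encoder adapter treats the encoder as frozen features;
  fine-tuning through the adapter is out of scope (the
  `lr_encoder_adapter` setting is reserved for it).
* The masked-manner baseline is implemented as an input feature
  (`use_mask_feature`), the strongest common form of that baseline; other
  published variants (binary masks, type-free marks) can be emulated by
  editing the mask alphabet but are not separately implemented.
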