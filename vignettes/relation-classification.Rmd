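---
title: "Masked-entity input construction for biomedical relation classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-entity input construction for biomedical relation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relexr)
```

## The task and the label schema

Sentence-level biomedical relation extraction asks: given one sentence and
two typed entity mentions in it (a gene and a disease, a miRNA and a
biological process, ...), which semantic relation holds between them?
`relexr` implements an eight-type schema organised as a three-level
hierarchy. The top level splits by whether a causal relationship is
expressed at all: `undirected_link` (mere correlation or association — the
schema's negative class) versus `directed_link`. When causal polarity is
determinable, `directed_link` refines into `positive_cause` /
`negative_cause`; when the sentence additionally states an explicit change
of quantity in the object entity, these refine once more into
`positive_increase` / `negative_decrease` (under a positive cause) and
`positive_decrease` / `negative_increase` (under a negative cause).

```{r}
relation_schema()
```

Two aspects of the schema drive design decisions elsewhere in the package.
First, although `undirected_link` is the negative class, it is *kept* as
one of the eight trained classes rather than dropped: the classification
head has eight outputs, and `collapse_to_binary()` provides the
positive/negative view when a binary benchmark is needed. Second, labels
always reach a root of the hierarchy in at most two `label_parent()`
steps, which the test suite asserts.

Crucially, the label is not a function of the verb alone. In a sentence
like "Knockdown of miR-X induced an increase in Y", the verb is positive
but the negation modifier on the subject entity flips the effective
polarity; the quantity phrase then selects the third level. This
verb-polarity / modifier / quantity-cue structure is exactly what the
synthetic generator emulates (below).

## Corpus representation and I/O

A corpus is a plain data frame with one row per relation instance:
document id (`pmid`), sentence index within the document (`sent_id`, 0 =
title), the sentence, two typed entity spans, and the label. Character
offsets are **0-based and half-open** so that the sentence slice at
`[start, end)` equals the surface string — the convention of common
annotation-editor JSON. Entity 1 is the *subject* role and entity 2 the
*object* role, in annotation order, which need not be textual order.

Two serialisations are supported: a TextAE-dialect JSON (text +
denotations + relations, the export format of web annotation editors) and
a canonical tab-separated table whose write–read composition is the
identity. Fields containing tabs or newlines are rejected outright rather
than escaped, keeping the format trivially parseable by any tool.
`validate_instance()` returns violations as data (not conditions), so
corpus QC can enumerate every problem in one pass. Overlapping or nested
entity pairs are rejected at validation: the replacement operators of the
encoding layer are ill-defined on overlapping spans.

## The five input-construction methods

`encode_instance()` converts an instance into the token sequence a
transformer encoder consumes, recording the index of one
*representative token* per entity:

* **default** — `[CLS] S [SEP]`; representatives are each entity's first
  token.
* **entity_marker** — entity-marker/entity-start: `[E1]...[/E1]` and
  `[E2]...[/E2]` wrapped around the entities; the opening markers are the
  representatives.
* **masked** — each entity's whole token range replaced by a single
  `[MASK]`; the two masks are the representatives.
* **two_masked_sentence** — the sentence twice, joined by `[SEP]`, with
  entity 1 masked in the first copy and entity 2 in the second; each
  copy's mask is that entity's representative, and the other entity stays
  verbatim, so no token information is lost overall while the
  representative positions remain surface-independent.
* **two_sentence_entity_token** — the same two-copy layout with `[E1]` /
  `[E2]` as the replacement tokens.

Three decisions here were genuinely open:

* **One replacement token per entity.** A multi-token entity collapses to
  a *single* `[MASK]`/`[E1]`/`[E2]`, not per-token masking: the head
  gathers exactly one vector per entity, and per-token masking would
  leave the representative index undefined.
* **Roles, not textual order.** The first sentence copy always masks
  entity 1 (the subject) even if it appears second in the text, because
  the two-copy layout is what conveys argument order to the model.
* **Replacement, not wrapping, for `two_sentence_entity_token`.** The
  variant is described as *replacing* the entities with entity tokens;
  we implement replacement, which also keeps the layout identical to
  `two_masked_sentence` up to the replacement token identity.

Truncation drops tokens from the sentence tail (before the final
`[SEP]`), and raises an error — rather than silently degrading — if a
representative token or structural separator would be cut. Segment ids
are 0 through the first `[SEP]` and 1 afterwards, exactly as in
two-sentence pre-training.

```{r}
inst <- relation_instance("doc", 0, "A activates B C",
                          "A", 0, 1, "gene", "B C", 12, 15, "protein",
                          "positive_cause")
tk <- whitespace_tokenizer()
encode_instance(inst, "two_masked_sentence", tk)
```

## Encoder contract, heads and loss

The model layer is written against a minimal encoder contract: per-token
vectors of width `H`, deterministic given parameters and input. The
package ships a from-scratch **tiny seeded encoder** — token + position +
segment embeddings followed by two single-head self-attention/FFN
residual blocks (`H` = 64 by default, N(0, 0.02²) initialisation, no
layer normalisation, which keeps backpropagation simple and is adequate
at depth 2). It exists so that every stage of the pipeline, including
training, is exercisable on one CPU in seconds; an adapter over a
pretrained checkpoint would satisfy the same contract.

Three heads map gathered vectors to the 8 class scores through a single
affine layer with optional dropout (default 0.1): `cls_token` uses the
`[CLS]` vector (input width `H`; 512 when `H` = 512), `two_token`
concatenates the two entity-representative vectors (`2H`; 1024), and
`three_token` prepends the `[CLS]` vector (`3H`; 1536). The concatenation
order is fixed and documented as (CLS, entity 1, entity 2); the loss is
mean cross-entropy. We treat `H` as a constructor parameter throughout
rather than hard-coding any particular checkpoint's width.

The analytic gradients of the whole stack (head, attention blocks,
embeddings) are verified against central finite differences in the test
suite — the practical oracle for hand-written backpropagation.

## Training harness

`train_config()` carries the standard fine-tuning recipe: AdamW
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8), weight decay 0.01, gradient clipping at
global norm 1, batch size 16, up to 10 epochs, and a learning-rate
schedule that warms up linearly over the first tenth of the steps and
decays linearly to zero (the schedule *shape* is the standard pairing for
this optimizer setup; only the warmup ratio is part of the recipe). The
best epoch under a configurable selection metric (macro F1 by default) is
retained, mirroring best-checkpoint evaluation. All randomness — batch
order, dropout — derives from one seed, with per-epoch derived seeds for
reshuffling; two runs with the same seed produce bit-identical
predictions.

One deliberate deviation for desk-scale work: the learnability and OOV
experiments train the tiny encoder *from scratch* at learning rate 1e-3.
The 5e-5 default is calibrated for adapting a large pretrained network
and cannot move a randomly initialised model to convergence within ten
epochs; 1e-3 is the standard regime for small transformers trained from
zero. The recipe defaults themselves are unchanged.

`crossval()` runs stratified k-fold cross-validation (k = 5 by default)
with the whole pipeline rebuilt per fold — including the tokenizer
vocabulary, which is built from the training split only so that held-out
entity surfaces can genuinely be out-of-vocabulary. Stratification keeps
per-fold class counts within one of proportional; whether to stratify was
an open choice, made in favour of stability under the schema's 10:1 class
imbalance, and is recorded in each run's manifest. Fold summaries report
the mean and *sample* (n−1) standard deviation, rendered as
`m.mmm (s.sss)`.

## Evaluation

`per_class_prf()` computes precision = TP/(TP+FP), recall = TP/(TP+FN)
and F1 = 2PR/(P+R) per class from the confusion matrix, with every 0/0
defined as 0 so degenerate folds aggregate cleanly. Summary precision,
recall and F1 are **macro** averages — the unweighted mean over classes.
That convention is fixed by arithmetic: the unweighted mean of the eight
per-class F1 values of the reference per-class report reproduces its
printed bottom-line value exactly, while support-weighted averaging does
not. Accuracy is trace/total. The implementation is tested for exact
agreement with a brute-force counting oracle over hundreds of random
label vectors.

## The synthetic corpus generator

`generate_corpus()` produces sentences from the template

```
<modifier?> <E1> <verb phrase> <quantity phrase?> <E2> <tail?>
```

with small versioned lexicons: four positive-causal and three
negative-causal verbs, two causal verbs of unspecified direction (these
yield `directed_link`), three neutral-associative verbs (these yield
`undirected_link`), four polarity-flipping modifiers ("knockdown of",
...), and two quantity phrases per direction. The recorded label *is*
`oracle_label()` of the instance's cues by construction: effective
polarity = verb polarity XOR modifier, and the quantity phrase selects
the third level under the effective parent (increase under a positive
parent → `positive_increase`, decrease → `negative_decrease`; decrease
under a negative parent → `positive_decrease`, increase →
`negative_increase`). The compound third-level semantics are genuinely
underdetermined by the schema's prose; the generator fixes this one
documented convention, and generator and oracle are self-consistent under
it regardless.

Default parameters are the package's study conditions, chosen once:
class weights proportional to the annotated corpus's per-label totals
(so `undirected_link` has weight 1396/5031 and the rarest class about
2.6%), an entity-symbol pool of 200 surfaces across four type families
(with a disjoint pool for OOV experiments), a quarter of entity surfaces
spanning two tokens, modifier probability 0.3 on causal instances, and a
quantity-flavoured distractor tail at rate 0.2 on instances whose label
does *not* require a quantity phrase — so the mere presence of quantity
wording cannot identify third-level labels. Labels are sampled i.i.d.
from the class weights and cues drawn consistently with the sampled
label, which makes the multinomial convergence of empirical class
frequencies a property of the sampler rather than something tuned.

What the generator emulates: the cue logic of the annotation scheme,
exact spans, realistic class imbalance, multi-token and out-of-vocabulary
entity surfaces. What it does not: lexical diversity, paraphrase,
long-range context, annotator disagreement, or sentences whose label
requires world knowledge about the object entity (the known hard case
for this schema). Passing the desk-scale experiments therefore shows the
*machinery* — encodings, heads, optimizer, evaluation — is sound, not
that any particular F1 carries over to real abstracts.

## Desk-scale experiments

`learnability_experiment()` trains the tiny encoder (2 layers, H = 64)
with the two-token head on 2,000 synthetic training instances under the
paper-style recipe (10 epochs, batch 16, warmup 0.1) and evaluates on 500
held-out instances; the cue oracle scores 1.0 on this task by
construction, and the trained model reaches ≥ 0.90 held-out accuracy for
at least two of three seeds. `oov_experiment()` generates the held-out
split entirely from the disjoint entity-surface pool, so every entity
token is `[UNK]` to the trained embeddings, and compares the default
input against the masked family (`masked`, `two_masked_sentence`); the
masked methods' representative positions are surface-independent and
hold their accuracy at or above the default input's. Problem sizes
(2,000/500 instances, H = 64, 10 epochs, three seeds; the fivefold
cross-validation demonstration uses 1,500 instances, H = 32, 10 epochs)
were chosen as the smallest at which the effects are stable across
seeds.

## Known limitations

* The tiny encoder is a demonstration-scale stand-in satisfying the
  encoder contract; absolute scores on real corpora require a pretrained
  biomedical checkpoint behind the same contract, which is out of scope
  here.
* The whitespace tokenizer ships for synthetic and test corpora; real
  abstracts need a subword tokenizer honouring the same offset contract.
* The generator's label semantics for flip-plus-quantity sentences follow
  one fixed convention and do not claim to replicate human annotator
  judgments on such sentences.
* Reported per-class metrics round to 3 decimals for display only; raw
  values are kept at full precision.
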