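# cidre — chemical-induced disease relation extraction

`cidre` extracts **chemical-induced disease (CID) relations** from
title/abstract documents of the kind curated in toxicogenomics databases:
given a PubMed-style abstract whose chemical and disease mentions are
normalized to MeSH-style concept identifiers, it decides for every
candidate pair `<Chemical ID, Disease ID>` whether the document asserts
that the chemical induces the disease. The intended users are biomedical
text-mining practitioners and database curators who need document-level
relation lists (the BioCreative V CDR task setting) rather than
sentence-level annotations.

## The method

The task is cast as binary classification of concept pairs. For one
document, every chemical concept is paired with every disease concept;
each pair receives one merged feature vector and a linear support vector
machine scores it.

Five feature families are extracted:

* **Bag-of-words** — lemmas in a window of size 5 (the mention plus two
  tokens on each side, never crossing a sentence boundary) around every
  occurrence of each concept, with document-accumulated frequencies.
* **Bag-of-ngrams** — uni/bi/trigrams over the lemma sequence running from
  the chemical to the disease within a sentence, with the mentions
  replaced by their concept IDs so the features generalize across surface
  names.
* **Trigger patterns** — four Boolean features, one per trigger lemma
  (*cause, induce, associate, produce*), each testing the single rule
  `Chemical ← arg0 ← trigger → arg1 → Disease` on the Extended Dependency
  Graph (EDG) of a sentence. The EDG augments the parser's collapsed
  dependencies with numbered-argument edges (`arg0` agent, `arg1`
  patient/theme) that unify active, passive and nominalized realizations,
  and with semantic edges (`member-collection`, `is-a`). Argument
  propagation carries `argK` edges through collections ("a number of X
  such as A and B") and through generic core-term heads ("a **case** of
  tardive dyskinesia caused by metoclopramide"), so the one rule covers
  many surface constructions.
* **Shortest-path walks** — direction-annotated v-walks (two vertices and
  their connecting edge) and e-walks (a vertex and its two incident edge
  labels) over all minimum-length EDG paths between the pair, plus the
  decayed length weight `mean(λ^length)` with λ = 0.9.
* **Statistical features** — 19 document-level signals: mention counts,
  title / first / last-abstract-sentence membership, same-sentence
  co-occurrence, knowledge-base membership of the pair (CTD-style
  relations, MeSH co-indexing), and contextual keyword tests (therapy
  terms, dosages, increase/decrease, p-values, demographics).

Mention-level vectors are merged per concept pair: Booleans by OR, numeric
singletons by averaging, bag features by summation. Beyond gold corpora,
the package implements **distant supervision**: a curated table of
document-level `<PMID, chemical, disease>` rows plus raw abstracts is
turned into a weakly labeled training corpus by dictionary-matching
mentions, keeping only relations whose two concepts are both grounded in
the abstract, and excluding any gold-corpus document.

All corpora use the PubTator text format; dependency parses enter through
a sidecar-file adapter so any parser can drive the system, and a
deterministic synthetic corpus generator (templates that emit both text
and parses) exercises the whole pipeline without downloads.

## Worked example

Train on a synthetic corpus, evaluate on held-out documents, and compare
with the co-occurrence baseline:

```r
library(cidre)

train <- generate_corpus(synthetic_config(n_docs = 60, seed = 42, doc_id_start = 1000))
test  <- generate_corpus(synthetic_config(n_docs = 20, seed = 43, doc_id_start = 5000))

prep <- function(corpus)
  lapply(corpus$documents, function(d) attach_parses(split_sentences(d), corpus$parses))
train_docs <- prep(train); test_docs <- prep(test)

train_inst <- unlist(lapply(train_docs, build_instances), recursive = FALSE)
test_inst  <- unlist(lapply(test_docs, function(d) build_instances(d, labeled = FALSE)),
                     recursive = FALSE)

model <- train_cid_model(train_inst, seed = 1)
model
#> <cid_model: linear SVM, C = 1, 420 features, 32 support vectors>

preds <- predict_relations(model, test_inst)
pair_prf(gold_relations(test_docs), preds)
#> P = 1.0000  R = 1.0000  F1 = 1.0000  (tp 20, fp 0, fn 0)

pair_prf(gold_relations(test_docs), cooccurrence_baseline(test_docs))
#> P = 0.3846  R = 1.0000  F1 = 0.5556  (tp 20, fp 32, fn 0)
```

The classifier recovers all 20 held-out relations without false positives;
the baseline, which predicts every co-mentioned pair, attains the same
recall at 38% precision — the gap is exactly the non-causal co-mentions
(treatment sentences and incidental pairs) the feature families are built
to reject.

A command-line front-end wraps the same pipeline
(`inst/cli/cidre <train|predict|evaluate|weaklabel|synth|ablate>`), driven
by flat key-value config files with `--key value` overrides.

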