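---
title: "Extracting chemical-induced disease relations with cidre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-induced disease relations with cidre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidre)
```

## The problem and the model

Toxicogenomics databases curate *chemical-induced disease* (CID)
assertions at the document level: a PubMed abstract is linked to pairs of
MeSH-style concept identifiers `<Chemical ID, Disease ID>` without
marking which sentences or mentions express the relation. `cidre` models
extraction the same way the curation is recorded: as binary
classification of the cross product of a document's chemical and disease
concepts. This document-level framing has two consequences that shape the
whole design. First, a relation may be asserted across sentences, so
purely sentence-level evidence cannot be sufficient — the feature vector
mixes sentence-scoped families (n-grams, trigger patterns, path walks)
with document-scoped ones (bags of context words, positional and
co-occurrence statistics, knowledge-base membership). Second, one concept
pair usually has several mention pairs; mention-level evidence is merged
into a single pair vector with OR for Booleans, arithmetic mean for
numeric singletons, and summation for bags.

The classifier is a linear-kernel support vector machine (libsvm through
`e1071`). CID data are label-imbalanced — most co-mentioned pairs are not
causal — so class weights default to balanced (inverse class frequency).
Kernel, cost `C = 1` and the decision threshold 0 are exposed in the
training and prediction interfaces; the threshold trades precision for
recall monotonically, which the test suite asserts as an invariant.

## The Extended Dependency Graph

The trigger-pattern and path families operate on a per-sentence
multigraph whose vertices are tokens (with lemma, part of speech and any
entity label) and whose edges come in three layers:

* **syntactic** — collapsed dependencies straight from the parse adapter,
  treated as opaque labels;
* **numbered arguments** — `arg0` (agent) and `arg1` (patient/theme)
  edges derived by rule: active nominal subjects, direct objects, passive
  subjects, agents, premodifying participles ("X-induced Y") and the
  `of`/`by` complements of nominal predicates. Each rule is individually
  switchable in `edg_config()`. Assignment is restricted by default to
  the trigger inventory (*cause, induce, associate, produce* and their
  nominalizations): the downstream consumers — the single extraction rule
  `Chemical ← arg0 ← trigger → arg1 → Disease` and the walk features —
  only need argument structure at trigger predicates, and keeping other
  predicates out of the argument layer keeps propagation output exactly
  characterizable (the collection example below adds precisely two
  edges). Setting `predicate_lemmas = NULL` lifts the restriction.
* **semantic** — `member-collection` for quantifier heads with an
  `of`-complement ("a *number* of inhibitors") and `is-a` for
  "Y such as X" and appositions, distributed over coordination.

Argument propagation closes the argument layer under two rules applied to
a fixpoint: the *collection* rule (`argK(p, c)` + `member-collection(c, g)`
+ `is-a(x, g)` ⇒ `argK(p, x)`) and the *core-term* rule (`argK(p, h)` with
`h` neither an entity nor a collection quantifier, plus an
`of`-complement `x` of `h`, ⇒ `argK(p, x)`). The quantifier exclusion in
the core-term rule is deliberate: a collection head like "number" must
propagate only through its members, not through its raw `of`-complement,
otherwise the collection construction would also attach the argument to
the collection noun itself. Propagation is monotone and idempotent; the
iteration cap equals the vertex count and exceeding it is an error rather
than a silent truncation.

For a multi-token mention the entity label sits on the span's syntactic
head (the token whose governor lies outside the span) — standard head
percolation; paths and patterns anchor there.

## Shortest-path walk features

All minimum-length simple paths between the chemical and disease vertices
are enumerated at the edge level: parallel edges of different labels give
distinct paths, every edge is traversable both ways, and each step
records whether it runs with or against the edge's orientation. Ties are
not broken — every minimal path contributes, and the numeric weight
feature is the mean of `λ^length` over them (`λ = 0.9` by default;
`λ = 1` disables the decay). v-walks render an edge with its own
orientation (`cause->arg0->Chemical`), e-walks render an interior vertex
with the directions of its two incident edges (`arg0<-cause->arg1`);
entity endpoints render as the generic tokens `Chemical`/`Disease` so
walks generalize across concepts. Since graphs are per sentence, a pair
co-mentioned in several sentences contributes paths from each such
sentence; no cross-sentence graph is built (cross-sentence evidence is
carried by the document-scoped families instead).

## Windows, n-grams and statistical features

The context window is "size 5": the mention occupies one slot and two
tokens on each side are context, clipped at sentence boundaries; the
mention's own tokens are excluded from its context bag, which is
accumulated over every occurrence of the concept in the document. The
same radius defines "around" for the contextual keyword features
(#12–#19 of the statistical family) — the one window semantics is reused
rather than inventing a second. The keyword lists ship as editable
configuration (`stat_keyword_config()`) seeded with the canonical
exemplars (therapy/complicating/affect; dosage units plus a number
pattern; increase/decrease; p-value; men/women/patient). N-grams run from
the chemical to the disease in textual order, orders 1–3, with the two
pair mentions replaced by their concept IDs; a mention pair spanning two
sentences contributes no n-grams. Numeric statistical features are used
unscaled by default; optional min-max scaling exists in the training
interface for experimentation but is off, as nothing indicates the
original pipeline scaled them.

Composite mentions (several IDs on one annotation) contribute each ID;
mentions that failed normalization carry the sentinel ID `-1` and are
excluded from pair generation, which maximizes precision at no recall
cost since such a mention cannot produce a correctly normalized pair
anyway.

## Distant supervision

`build_weak_corpus()` converts a curated `<doc, chemical, disease>` table
plus raw abstracts into training documents: mentions come from a
dictionary matcher (case-insensitive longest match over token boundaries;
ambiguous names yield composite mentions) optionally merged with an
external tagger's output (exact duplicates prefer the tagger, overlaps
keep the longer span); a curated relation is kept only if both concepts
are grounded in the abstract's mentions; documents retaining no relation,
and documents on the gold-corpus exclusion list, are dropped. Relations
grounded only through the dictionary (not the tagger) are kept — the
recall-maximizing reading of the procedure. Retained relations become
positives and all other candidate pairs negatives, which is the standard
distant-supervision assumption and its standard noise source: an
unexpressed curated pair or an uncurated expressed pair yields a wrong
label. Weak instances are flagged; training concatenates them with gold
instances at full weight (the libsvm backend has no per-instance weights,
so no down-weighting option is offered).

## The synthetic generator

`generate_corpus()` emulates the study conditions end to end: documents
built from sentence templates that emit their own dependency parses —
trigger sentences (simple active, the collection construction mirroring
"a number of inhibitors such as ... cause ...", the core-term passive
"a case of ... caused by ..."), cross-sentence assertions, treatment-
distractor co-mentions, and unrelated single-entity sentences — plus a
matching dictionary and the document-level relation table for the
distant-supervision path. Defaults: 30 chemical and 30 disease concepts
(reserved `XC`/`XD` ID prefixes, so no collision with real MeSH
descriptors), 1–2 concepts of each type per document, 30% of candidate
pairs positive, 90% of positives expressed by a trigger sentence, 50% of
negative co-mentions phrased as treatment sentences. These rates give
corpora in which trigger patterns are strong but not sufficient evidence
(cross-sentence positives and distractors both occur), which is the
regime the feature mix is designed for. Normalization noise is modeled by
`corrupt_mention_ids()`: with a configurable probability per distinct
surface name, all of that name's mentions in a document are re-normalized
to one wrong same-type ID. Corruption is name-consistent because a
dictionary or tagger maps surface forms — a name it gets wrong, it gets
wrong everywhere in the abstract; per-occurrence corruption would
manufacture within-document inconsistencies no real normalizer produces.

What the generator does *not* emulate: lexical diversity (a small closed
vocabulary of pseudo-words), parser errors (template parses are gold by
construction), boundary-detection noise, relations expressed by
non-trigger verbs, and the long-tail discourse phenomena of real
abstracts. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that the learner recovers the planted signal
under controlled noise — not that real-corpus accuracy is attained; on
real data, performance is bounded by the parser and normalizer quality
the adapter interfaces import.

## Benchmark conditions and numerical choices

The parameter-recovery experiments (`synthetic_benchmark()`, also run by
`scripts/acceptance.R`) use 200 training and 50 test documents per seed
over five seeds, with a 200-document weak corpus built through the full
distant-supervision path at a 10% corruption rate — sizes at which the
suite completes in minutes on one core while estimates are stable to a
few percent. Observed behavior: held-out F1 above 0.97 on every seed,
weak augmentation within a fraction of a percent of the gold-only model
(and above it on some seeds), and a co-occurrence baseline near 50% F1
with perfect recall.

Smaller numerical decisions, collected: sentence splitting is
regex-based (terminal punctuation + whitespace + capital, abbreviation
stop-list) with the title always one sentence, and any boundary that
would cut a mention is repaired by merging the adjacent sentences;
parse/text alignment tolerates dropped punctuation between tokens but
nothing else; degenerate evaluation denominators report 0 with an
`undefined` flag rather than NaN or an error; `pair_prf()` refuses
predictions for documents outside the gold corpus (corpus mismatch is a
bug, not a score); feature vectors are sparse name-value maps and the
feature index is frozen on the training set, unseen features being
dropped at prediction time; model archives store the config snapshot,
index and weights, and reload to bit-identical predictions.

## Known limitations

Only `arg0`/`arg1` are assigned (no deeper role inventory); semantic
edges cover the two defined constructions (`member-collection`, `is-a`)
and no more; the trigger inventory is fixed at four lemmas, so causal
verbs outside it ("aggravate") are invisible to the pattern family and
must be caught by the lexical families; no cross-sentence dependency
structure is built; and the SVM's implementation details (tolerance,
shrinking) are libsvm's defaults, documented but not claimed identical to
any other implementation.
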