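# Self-contained benchmark experiments on synthetic corpora.

#' Synthetic parameter-recovery benchmark
#'
#' Runs the full pipeline under the package's study conditions: generate a
#' training corpus and a held-out test corpus, train the pair classifier on
#' gold labels and score it; optionally repeat training with a weakly
#' labeled corpus appended, where the weak corpus is produced through the
#' distant-supervision path (dictionary matching over raw abstracts with
#' name-level ID corruption, grounding against the curated relation table,
#' exclusion of all gold document IDs). Also scores the co-occurrence
#' baseline on the test corpus.
#'
#' All derived seeds are small fixed offsets of \code{seed}.
#'
#' @param seed base RNG seed.
#' @param n_train,n_test,n_weak corpus sizes (documents).
#' @param p_trigger fraction of true relations expressed by trigger-verb
#'   sentences.
#' @param id_corruption normalization-noise rate applied to the weak
#'   corpus mentions.
#' @param with_weak run the weak-augmentation arm?
#' @return a list of [prf()] records: \code{gold}, \code{baseline}, and
#'   (when requested) \code{weak}, plus bookkeeping counts.
#' @export
synthetic_benchmark <- function(seed, n_train = 200L, n_test = 50L,
                                n_weak = 200L, p_trigger = 0.9,
                                id_corruption = 0.1, with_weak = TRUE) {
  seed <- as.integer(seed)
  tr <- generate_corpus(synthetic_config(n_docs = n_train, p_trigger = p_trigger,
                                         seed = seed, doc_id_start = 100000L))
  te <- generate_corpus(synthetic_config(n_docs = n_test, p_trigger = p_trigger,
                                         seed = seed + 500L,
                                         doc_id_start = 500000L))
  prep <- function(docs, parses) {
    lapply(docs, function(d) attach_parses(split_sentences(d), parses))
  }
  train_docs <- prep(tr$documents, tr$parses)
  test_docs <- prep(te$documents, te$parses)
  train_inst <- unlist(lapply(train_docs, build_instances), recursive = FALSE)
  test_inst <- unlist(lapply(test_docs, function(d) {
    build_instances(d, labeled = FALSE)
  }), recursive = FALSE)
  gold <- gold_relations(test_docs)

  model <- train_cid_model(train_inst, seed = seed)
  out <- list(
    gold = pair_prf(gold, predict_relations(model, test_inst)),
    baseline = pair_prf(gold, cooccurrence_baseline(test_docs)),
    n_train_instances = length(train_inst)
  )

  if (with_weak) {
    wk <- generate_corpus(synthetic_config(n_docs = n_weak,
                                           p_trigger = p_trigger,
                                           seed = seed + 900L,
                                           doc_id_start = 900000L))
    chem_vocab <- synth_vocab(wk$config$n_chemicals, "chemical")
    dis_vocab <- synth_vocab(wk$config$n_diseases, "disease")
    raw <- lapply(wk$documents, function(d) {
      d$relations <- relation_frame()
      d$mentions <- dictionary_match(d, wk$dictionary)
      d
    })
    raw <- with_seed(seed + 77L, lapply(raw, function(d) {
      d$mentions <- corrupt_mention_ids(d$mentions, id_corruption,
                                        chem_vocab, dis_vocab)
      d
    }))
    exclude <- vapply(c(tr$documents, te$documents), function(d) d$doc_id, "")
    weak_docs <- build_weak_corpus(wk$relation_table, raw, exclude)
    weak_parsed <- prep(weak_docs, wk$parses)
    weak_inst <- unlist(lapply(weak_parsed, function(d) {
      build_instances(d, weak = TRUE)
    }), recursive = FALSE)
    model_w <- train_cid_model(c(train_inst, weak_inst), seed = seed)
    out$weak <- pair_prf(gold, predict_relations(model_w, test_inst))
    out$n_weak_documents <- length(weak_docs)
    out$n_weak_instances <- length(weak_inst)
  }
  out
}
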