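# Deterministic synthetic corpora.
#
# Documents are assembled from sentence templates that emit their own
# dependency parses, so the whole pipeline (corpus I/O, sentence splitting,
# parse attachment, EDG construction, features, training, weak labeling)
# runs without an external parser or any downloaded corpus. Templates:
#   simple_active      "<Chem> induced/caused/produced <adj> <Dis> in patients."
#   collection         "A number of agents such as <Chem> have been found to
#                       cause <adj> <Dis>."  (member-collection / is-a)
#   coreterm_passive   "A case of <adj> <Dis> caused by <Chem> was reported."
#   cross_sentence     two sentences asserting the relation across a boundary
#   treatment          "<Chem> effectively treated patients with <Dis>."
#                      (distractor co-mention, NOT a CID)
#   comention          unrelated single-entity sentences (negative)
# Vocabulary IDs use the reserved synthetic prefixes XC/XD to avoid any
# collision with real MeSH descriptors.

#' Synthetic corpus configuration
#'
#' The generator's defaults define the study conditions of the package's
#' parameter-recovery experiments; see the methods vignette.
#'
#' @param n_docs number of documents.
#' @param n_chemicals,n_diseases vocabulary sizes (disjoint ID spaces).
#' @param p_positive fraction of candidate pairs that are true CIDs.
#' @param p_trigger fraction of true CIDs expressed by a trigger-verb
#'   sentence (the rest are asserted across sentences).
#' @param p_distractor fraction of non-CID co-mentions expressed as
#'   treatment sentences (the rest never share a sentence).
#' @param id_corruption fraction of mentions whose concept ID is replaced
#'   by a random same-type ID (simulated normalization noise; 0 = clean).
#' @param seed RNG seed; identical configs generate byte-identical corpora.
#' @param doc_id_start first numeric document ID (IDs are sequential).
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_docs = 50L, n_chemicals = 30L, n_diseases = 30L,
                             p_positive = 0.3, p_trigger = 0.9,
                             p_distractor = 0.5, id_corruption = 0,
                             seed = 1L, doc_id_start = 1L) {
  probs <- c(p_positive, p_trigger, p_distractor, id_corruption)
  if (any(probs < 0 | probs > 1)) stop_cid("probabilities must lie in [0, 1]")
  if (p_positive > 0 && (n_chemicals < 1L || n_diseases < 1L)) {
    stop_cid("p_positive > 0 requires a non-empty vocabulary of both types")
  }
  structure(list(n_docs = as.integer(n_docs),
                 n_chemicals = as.integer(n_chemicals),
                 n_diseases = as.integer(n_diseases),
                 p_positive = p_positive, p_trigger = p_trigger,
                 p_distractor = p_distractor, id_corruption = id_corruption,
                 seed = as.integer(seed),
                 doc_id_start = as.integer(doc_id_start)),
            class = "synthetic_config")
}

# deterministic pseudo-word vocabularies -----------------------------------

#' @noRd
synth_vocab <- function(n, type) {
  syl <- if (type == "chemical") {
    c("dar", "vel", "mor", "tas", "nol", "zeb", "quin", "fex", "lam", "cor")
  } else {
    c("neph", "card", "hep", "derm", "enceph", "pulm", "myel", "gastr",
      "arthr", "neur")
  }
  suffix <- if (type == "chemical") "il" else "osis"
  prefix <- if (type == "chemical") "XC" else "XD"
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  names_ <- vapply(seq_len(n), function(i) {
    a <- syl[((i - 1L) %% 10L) + 1L]
    b <- syl[(((i - 1L) %/% 10L) %% 10L) + 1L]
    paste0(a, b, suffix)
  }, "")
  data.frame(id = ids, name = names_, type = type, stringsAsFactors = FALSE)
}

# sentence templates --------------------------------------------------------

#' @noRd
tok_row <- function(text, lemma, pos, head, label) {
  data.frame(text = text, lemma = lemma, pos = pos, head = head,
             label = label, stringsAsFactors = FALSE)
}

# Each template returns list(tokens, extra, entities) where entities maps
# token index -> list(type, id). Entity names are single tokens.
#' @noRd
synth_templates <- function() {
  list(
    title = function(chem, adj) {
      tokens <- rbind(
        tok_row("Adverse", "adverse", "JJ", 1L, "amod"),
        tok_row("events", "event", "NNS", -1L, "root"),
        tok_row("of", "of", "IN", -1L, "root"),
        tok_row(chem$name, chem$name, "NN", 1L, "prep_of")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`3` = list(type = "chemical", id = chem$id)))
    },
    simple_active = function(chem, dis, verb, adj) {
      tokens <- rbind(
        tok_row(chem$name, chem$name, "NN", 1L, "nsubj"),
        tok_row(paste0(verb, "d"), verb, "VBD", -1L, "root"),
        tok_row(adj, adj, "JJ", 3L, "amod"),
        tok_row(dis$name, dis$name, "NN", 1L, "dobj"),
        tok_row("in", "in", "IN", -1L, "root"),
        tok_row("patients", "patient", "NNS", 1L, "prep_in")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`0` = list(type = "chemical", id = chem$id),
                           `3` = list(type = "disease", id = dis$id)))
    },
    collection = function(chem, dis, verb, adj) {
      tokens <- rbind(
        tok_row("A", "a", "DT", 1L, "det"),
        tok_row("number", "number", "NN", 9L, "nsubjpass"),
        tok_row("of", "of", "IN", -1L, "root"),
        tok_row("agents", "agent", "NNS", 1L, "prep_of"),
        tok_row("such", "such", "JJ", -1L, "root"),
        tok_row("as", "as", "IN", -1L, "root"),
        tok_row(chem$name, chem$name, "NN", 3L, "prep_such_as"),
        tok_row("have", "have", "VBP", 9L, "aux"),
        tok_row("been", "be", "VBN", 9L, "auxpass"),
        tok_row("found", "find", "VBN", -1L, "root"),
        tok_row("to", "to", "TO", 11L, "aux"),
        tok_row(verb, verb, "VB", 9L, "xcomp"),
        tok_row(adj, adj, "JJ", 13L, "amod"),
        tok_row(dis$name, dis$name, "NN", 11L, "dobj")
      )
      extra <- data.frame(label = "xsubj", head = 11L, dep = 1L,
                          stringsAsFactors = FALSE)
      list(tokens = tokens, extra = extra,
           entities = list(`6` = list(type = "chemical", id = chem$id),
                           `13` = list(type = "disease", id = dis$id)))
    },
    coreterm_passive = function(chem, dis, verb, adj) {
      tokens <- rbind(
        tok_row("A", "a", "DT", 1L, "det"),
        tok_row("case", "case", "NN", 9L, "nsubjpass"),
        tok_row("of", "of", "IN", -1L, "root"),
        tok_row(adj, adj, "JJ", 4L, "amod"),
        tok_row(dis$name, dis$name, "NN", 1L, "prep_of"),
        tok_row(paste0(verb, "d"), verb, "VBN", 1L, "vmod"),
        tok_row("by", "by", "IN", -1L, "root"),
        tok_row(chem$name, chem$name, "NN", 5L, "agent"),
        tok_row("was", "be", "VBD", 9L, "auxpass"),
        tok_row("reported", "report", "VBN", -1L, "root")
      )
      extra <- data.frame(label = "nsubjpass", head = 5L, dep = 1L,
                          stringsAsFactors = FALSE)
      list(tokens = tokens, extra = extra,
           entities = list(`7` = list(type = "chemical", id = chem$id),
                           `4` = list(type = "disease", id = dis$id)))
    },
    cross_chem = function(chem, adj) {
      tokens <- rbind(
        tok_row(chem$name, chem$name, "NN", 2L, "nsubjpass"),
        tok_row("was", "be", "VBD", 2L, "auxpass"),
        tok_row("administered", "administer", "VBN", -1L, "root"),
        tok_row("to", "to", "IN", -1L, "root"),
        tok_row("the", "the", "DT", 5L, "det"),
        tok_row("cohort", "cohort", "NN", 2L, "prep_to")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`0` = list(type = "chemical", id = chem$id)))
    },
    cross_dis = function(dis, adj) {
      tokens <- rbind(
        tok_row(first_upper(adj), adj, "JJ", 1L, "amod"),
        tok_row(dis$name, dis$name, "NN", 2L, "nsubj"),
        tok_row("developed", "develop", "VBD", -1L, "root"),
        tok_row("subsequently", "subsequently", "RB", 2L, "advmod")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`1` = list(type = "disease", id = dis$id)))
    },
    treatment = function(chem, dis, adj) {
      tokens <- rbind(
        tok_row(chem$name, chem$name, "NN", 2L, "nsubj"),
        tok_row("effectively", "effectively", "RB", 2L, "advmod"),
        tok_row("treated", "treat", "VBD", -1L, "root"),
        tok_row("patients", "patient", "NNS", 2L, "dobj"),
        tok_row("with", "with", "IN", -1L, "root"),
        tok_row(dis$name, dis$name, "NN", 3L, "prep_with")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`0` = list(type = "chemical", id = chem$id),
                           `5` = list(type = "disease", id = dis$id)))
    },
    comention_chem = function(chem, adj) {
      tokens <- rbind(
        tok_row(chem$name, chem$name, "NN", 1L, "nn"),
        tok_row("levels", "level", "NNS", 3L, "nsubjpass"),
        tok_row("were", "be", "VBD", 3L, "auxpass"),
        tok_row("measured", "measure", "VBN", -1L, "root"),
        tok_row("at", "at", "IN", -1L, "root"),
        tok_row("baseline", "baseline", "NN", 3L, "prep_at")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`0` = list(type = "chemical", id = chem$id)))
    },
    comention_dis = function(dis, adj) {
      tokens <- rbind(
        tok_row(dis$name, dis$name, "NN", 2L, "nsubjpass"),
        tok_row("was", "be", "VBD", 2L, "auxpass"),
        tok_row("documented", "document", "VBN", -1L, "root"),
        tok_row("in", "in", "IN", -1L, "root"),
        tok_row("the", "the", "DT", 5L, "det"),
        tok_row("registry", "registry", "NN", 2L, "prep_in")
      )
      list(tokens = tokens, extra = NULL,
           entities = list(`0` = list(type = "disease", id = dis$id)))
    }
  )
}

#' @noRd
first_upper <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

#' Instantiate one sentence template
#'
#' Returns the filled template: token frame (text/lemma/pos/head/label),
#' optional extra edges, the sentence surface text and the entity slots.
#' An unknown template name is a hard error.
#'
#' @param template template name (see package source for the inventory).
#' @param ... slot fills: \code{chem}/\code{dis} rows of the vocabulary
#'   frame, \code{verb}, \code{adj} strings.
#' @return a template instance list.
#' @export
generate_parse <- function(template, ...) {
  tpl <- synth_templates()[[template]]
  if (is.null(tpl)) stop_cid("unknown sentence template '%s'", template)
  inst <- tpl(...)
  inst$template <- template
  # sentence-initial capitalization; surface text with a trailing period
  inst$tokens$text[1] <- first_upper(inst$tokens$text[1])
  inst$text <- paste0(paste(inst$tokens$text, collapse = " "), ".")
  inst
}

#' Generate a synthetic corpus
#'
#' Builds \code{n_docs} documents, their parse sidecar records, a concept
#' dictionary covering the vocabulary and the document-level relation table
#' of the true CIDs (the distant-supervision input). The same seed yields
#' byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @return a list with \code{documents} (mentions and gold relations
#'   attached), \code{parses} (sidecar records keyed by doc ID),
#'   \code{dictionary}, \code{relation_table} and \code{config}.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  chem_vocab <- synth_vocab(config$n_chemicals, "chemical")
  dis_vocab <- synth_vocab(config$n_diseases, "disease")
  adjectives <- c("severe", "acute", "mild", "progressive")
  verbs <- c("induce", "cause", "produce")

  out_docs <- list()
  out_parses <- list()
  rel_rows <- list()

  with_seed(config$seed, {
    for (d in seq_len(config$n_docs)) {
      doc_id <- as.character(config$doc_id_start + d - 1L)
      n_chem <- sample(1:2, 1L)
      n_dis <- sample(1:2, 1L)
      chems <- chem_vocab[sample(nrow(chem_vocab), n_chem), , drop = FALSE]
      diss <- dis_vocab[sample(nrow(dis_vocab), n_dis), , drop = FALSE]

      sents <- list(generate_parse("title", chem = chems[1, ],
                                   adj = sample(adjectives, 1L)))
      doc_rels <- relation_frame()
      for (ci in seq_len(n_chem)) for (di in seq_len(n_dis)) {
        chem <- chems[ci, ]; dis <- diss[di, ]
        adj <- sample(adjectives, 1L)
        if (stats::runif(1) < config$p_positive) {
          doc_rels <- rbind(doc_rels, relation_frame(chem$id, dis$id))
          rel_rows[[length(rel_rows) + 1L]] <-
            data.frame(doc_id = doc_id, chemical_id = chem$id,
                       disease_id = dis$id, stringsAsFactors = FALSE)
          if (stats::runif(1) < config$p_trigger) {
            tpl <- sample(c("simple_active", "collection", "coreterm_passive"), 1L)
            verb <- if (tpl == "coreterm_passive") {
              sample(c("induce", "cause"), 1L)
            } else sample(verbs, 1L)
            sents[[length(sents) + 1L]] <-
              generate_parse(tpl, chem = chem, dis = dis, verb = verb, adj = adj)
          } else {
            sents[[length(sents) + 1L]] <-
              generate_parse("cross_chem", chem = chem, adj = adj)
            sents[[length(sents) + 1L]] <-
              generate_parse("cross_dis", dis = dis, adj = adj)
          }
        } else {
          if (stats::runif(1) < config$p_distractor) {
            sents[[length(sents) + 1L]] <-
              generate_parse("treatment", chem = chem, dis = dis, adj = adj)
          } else {
            sents[[length(sents) + 1L]] <-
              generate_parse("comention_chem", chem = chem, adj = adj)
            sents[[length(sents) + 1L]] <-
              generate_parse("comention_dis", dis = dis, adj = adj)
          }
        }
      }

      assembled <- assemble_document(doc_id, sents, doc_rels)
      doc <- assembled$doc
      if (config$id_corruption > 0 && nrow(doc$mentions)) {
        doc$mentions <- corrupt_mention_ids(doc$mentions, config$id_corruption,
                                            chem_vocab, dis_vocab)
      }
      out_docs[[length(out_docs) + 1L]] <- doc
      out_parses[[doc_id]] <- assembled$records
    }
  })

  dict_lines <- c(
    sprintf("%s\tchemical\t%s", chem_vocab$id, chem_vocab$name),
    sprintf("%s\tdisease\t%s", dis_vocab$id, dis_vocab$name)
  )
  dictionary <- load_dictionary(textConnection(dict_lines))
  relation_table <- if (length(rel_rows)) {
    unique(do.call(rbind, rel_rows))
  } else {
    data.frame(doc_id = character(0), chemical_id = character(0),
               disease_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(relation_table) <- NULL
  list(documents = out_docs, parses = out_parses, dictionary = dictionary,
       relation_table = relation_table, config = config)
}

# join template instances into a document + sidecar records
#' @noRd
assemble_document <- function(doc_id, sents, relations) {
  title <- sents[[1]]$text
  abstract <- if (length(sents) > 1L) {
    paste(vapply(sents[-1], function(s) s$text, ""), collapse = " ")
  } else ""
  starts <- integer(0); ends <- integer(0); texts <- character(0)
  types <- character(0); cids <- list()
  records <- list()
  offset <- 0L
  for (si in seq_along(sents)) {
    s <- sents[[si]]
    tk <- s$tokens
    n <- nrow(tk)
    # token offsets within the assembled text (single spaces, trailing ".")
    tok_starts <- integer(n); pos <- offset
    for (i in seq_len(n)) {
      tok_starts[i] <- pos
      pos <- pos + nchar(tk$text[i]) + 1L  # token + following space
    }
    sent_len <- nchar(s$text)
    for (key in names(s$entities)) {
      ti <- as.integer(key)
      ent <- s$entities[[key]]
      starts <- c(starts, tok_starts[ti + 1L])
      ends <- c(ends, tok_starts[ti + 1L] + nchar(tk$text[ti + 1L]))
      texts <- c(texts, tk$text[ti + 1L])
      types <- c(types, ent$type)
      cids <- c(cids, list(ent$id))
    }
    extra <- s$extra
    if (is.null(extra)) {
      extra <- data.frame(label = character(0), head = integer(0),
                          dep = integer(0), stringsAsFactors = FALSE)
    }
    records[[si]] <- list(
      doc_id = doc_id, sent_index = si - 1L,
      tokens = data.frame(index = seq_len(n) - 1L, text = tk$text,
                          lemma = tk$lemma, pos = tk$pos, head = tk$head,
                          label = tk$label, stringsAsFactors = FALSE),
      extra_edges = extra
    )
    offset <- offset + sent_len + 1L  # sentence + single joining space
  }
  doc <- cid_document(doc_id, title, abstract,
                      mentions = mention_frame(starts, ends, texts, types, cids),
                      relations = relations)
  list(doc = doc, records = records)
}

#' Corrupt mention concept IDs
#'
#' The generator's model of normalization noise in text-mined mentions:
#' with probability \code{rate} per distinct surface name, every mention of
#' that name in the document is re-normalized to one uniformly drawn wrong
#' same-type ID. Corruption is name-consistent within a document because a
#' normalizer maps surface forms, not individual occurrences — a name it
#' gets wrong it gets wrong everywhere in the abstract. Uses the current
#' RNG stream.
#'
#' @param mentions a mention frame.
#' @param rate corruption probability per distinct surface name.
#' @param chem_vocab,dis_vocab vocabulary frames (columns \code{id},
#'   \code{type}).
#' @return the mention frame with some \code{concept_ids} replaced.
#' @export
corrupt_mention_ids <- function(mentions, rate, chem_vocab, dis_vocab) {
  for (nm in unique(tolower(mentions$text))) {
    rows <- which(tolower(mentions$text) == nm)
    if (stats::runif(1) < rate) {
      vocab <- if (mentions$type[rows[1]] == "chemical") chem_vocab else dis_vocab
      pool <- setdiff(vocab$id, unlist(mentions$concept_ids[rows]))
      if (length(pool)) {
        bad_id <- sample(pool, 1L)
        for (i in rows) mentions$concept_ids[[i]] <- bad_id
      }
    }
  }
  mentions
}

#' Write a synthetic corpus to disk
#'
#' PubTator corpus, parse sidecar, dictionary TSV and relation-table TSV in
#' the package's external formats.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(corpus = file.path(dir, "corpus.pubtator"),
             parses = file.path(dir, "parses.sidecar"),
             dictionary = file.path(dir, "dictionary.tsv"),
             relations = file.path(dir, "relations.tsv"))
  write_pubtator(corpus$documents, paths[["corpus"]])
  write_parse_sidecar(corpus$parses, paths[["parses"]])
  dict_rows <- vapply(names(corpus$dictionary$concepts), function(id) {
    e <- corpus$dictionary$concepts[[id]]
    sprintf("%s\t%s\t%s", id, e$type, paste(e$names, collapse = "|"))
  }, "")
  write_lines_utf8(unname(dict_rows), paths[["dictionary"]])
  rt <- corpus$relation_table
  write_lines_utf8(sprintf("%s\t%s\t%s", rt$doc_id, rt$chemical_id,
                           rt$disease_id), paths[["relations"]])
  invisible(paths)
}
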