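# Synthetic fixture documents built in code. They are constructed stand-ins
# (no real abstracts): each reproduces a documented structural property of
# the CID extraction task — mention/relation layout, worked-example feature
# values, EDG propagation behavior.

# locate the n-th occurrence of each surface string and build a mention
fx_mentions <- function(text, specs) {
  starts <- integer(0); ends <- integer(0); texts <- character(0)
  types <- character(0); cids <- list()
  for (sp in specs) {
    hits <- gregexpr(sp$text, text, fixed = TRUE)[[1]]
    stopifnot(hits[1] != -1L)
    occs <- if (is.null(sp$occ)) seq_along(hits) else sp$occ
    for (k in occs) {
      starts <- c(starts, as.integer(hits[k]) - 1L)
      ends <- c(ends, as.integer(hits[k]) - 1L + nchar(sp$text))
      texts <- c(texts, sp$text)
      types <- c(types, sp$type)
      cids <- c(cids, list(sp$ids))
    }
  }
  mention_frame(starts, ends, texts, types, cids)
}

fx_document <- function(doc_id, title, abstract, specs, relations = relation_frame()) {
  txt <- if (nzchar(abstract)) paste(title, abstract) else title
  cid_document(doc_id, title, abstract,
               mentions = fx_mentions(txt, specs),
               relations = relations)
}

# a flat (star-shaped) parse: token 0 is the root, everything hangs off it.
# Sufficient for window/position features that only need tokens and lemmas.
fx_flat_record <- function(doc_id, sent_index, words, lemmas = NULL) {
  n <- length(words)
  if (is.null(lemmas)) lemmas <- tolower(words)
  list(doc_id = doc_id, sent_index = sent_index,
       tokens = data.frame(
         index = seq_len(n) - 1L, text = words, lemma = lemmas,
         pos = rep("NN", n),
         head = c(-1L, rep(0L, n - 1L)),
         label = c("root", rep("dep", n - 1L)),
         stringsAsFactors = FALSE),
       extra_edges = data.frame(label = character(0), head = integer(0),
                                dep = integer(0), stringsAsFactors = FALSE))
}

fx_record <- function(doc_id, sent_index, tokens, extra = NULL) {
  if (is.null(extra)) {
    extra <- data.frame(label = character(0), head = integer(0),
                        dep = integer(0), stringsAsFactors = FALSE)
  }
  list(doc_id = doc_id, sent_index = sent_index, tokens = tokens,
       extra_edges = extra)
}

fx_tokens <- function(...) {
  rows <- list(...)
  data.frame(
    index = vapply(rows, `[[`, 1L, 1L),
    text = vapply(rows, `[[`, "", 2L),
    lemma = vapply(rows, `[[`, "", 3L),
    pos = vapply(rows, `[[`, "", 4L),
    head = vapply(rows, `[[`, 1L, 5L),
    label = vapply(rows, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

tk <- function(index, text, lemma, pos, head, label) {
  list(as.integer(index), text, lemma, pos, as.integer(head), label)
}

# --- sample document: one chemical, three diseases, two CID relations -----
# Same-sentence relation (arrest), cross-sentence relation (respiratory
# depression), and a co-mentioned but unrelated concept (death).
fixture_sample_doc <- function() {
  title <- "Cardiorespiratory arrest after sedation with midazolam."
  abstract <- paste(
    "A patient received midazolam for sedation and suffered cardiorespiratory arrest.",
    "Severe respiratory depression was noted on the following day.",
    "The patient later died, and death was attributed to the event."
  )
  specs <- list(
    list(text = "midazolam", type = "chemical", ids = "D008874"),
    list(text = "cardiorespiratory arrest", type = "disease", ids = "D006323"),
    list(text = "Cardiorespiratory arrest", type = "disease", ids = "D006323"),
    list(text = "respiratory depression", type = "disease", ids = "D012140"),
    list(text = "death", type = "disease", ids = "D003643")
  )
  doc <- fx_document("900001", title, abstract, specs,
                     relation_frame(c("D008874", "D008874"),
                                    c("D006323", "D012140")))
  doc <- split_sentences(doc)
  words_by_sent <- lapply(doc$sentences, function(s) {
    m <- gregexpr("[[:alnum:]][[:alnum:]'-]*", s$text)[[1]]
    regmatches(s$text, list(m))[[1]]
  })
  records <- lapply(seq_along(words_by_sent), function(i) {
    fx_flat_record("900001", i - 1L, words_by_sent[[i]])
  })
  doc <- attach_parses(doc, list("900001" = records))
  list(doc = doc, records = list("900001" = records))
}

# --- worked-example document for BOW and bigram features ------------------
# Four occurrences of the chemical concept D011899; context windows give
# the bag {induce x2, acute x2, frequently, is, case, of}.
fixture_bow_doc <- function() {
  title <- "Quinaprex induces acute hemanosis."
  abstract <- paste(
    "A case of quinaprex.",
    "Quinaprex is frequently administered.",
    "Quinaprex induced acute hemanosis in two patients."
  )
  specs <- list(
    list(text = "Quinaprex", type = "chemical", ids = "D011899"),
    list(text = "quinaprex", type = "chemical", ids = "D011899"),
    list(text = "hemanosis", type = "disease", ids = "D009395")
  )
  doc <- fx_document("900002", title, abstract, specs,
                     relation_frame("D011899", "D009395"))
  doc <- split_sentences(doc)
  lemma_map <- c(
    Quinaprex = "quinaprex", quinaprex = "quinaprex", induces = "induce",
    induced = "induce", acute = "acute", hemanosis = "hemanosis", A = "a",
    case = "case", of = "of", is = "is", frequently = "frequently",
    administered = "administer", in. = "in", two = "two", patients = "patient"
  )
  records <- lapply(seq_along(doc$sentences), function(i) {
    s <- doc$sentences[[i]]
    m <- gregexpr("[[:alnum:]][[:alnum:]'-]*", s$text)[[1]]
    words <- regmatches(s$text, list(m))[[1]]
    lem <- unname(ifelse(words %in% names(lemma_map), lemma_map[words],
                         tolower(words)))
    lem[words == "in"] <- "in"
    fx_flat_record("900002", i - 1L, words, lem)
  })
  doc <- attach_parses(doc, list("900002" = records))
  list(doc = doc, records = list("900002" = records))
}

# --- collection construction ("a number of X such as ...") ----------------
# Exercises member-collection, is-a, and the collection propagation rule.
fixture_collection_doc <- function() {
  title <- paste("A number of angiogenesis inhibitors such as sunitinib and",
                 "sorafenib have been found to cause acute hemolysis.")
  specs <- list(
    list(text = "sunitinib", type = "chemical", ids = "C0601"),
    list(text = "sorafenib", type = "chemical", ids = "C0602"),
    list(text = "acute hemolysis", type = "disease", ids = "D0603")
  )
  doc <- fx_document("900003", title, "", specs,
                     relation_frame(c("C0601", "C0602"), c("D0603", "D0603")))
  tokens <- fx_tokens(
    tk(0, "A", "a", "DT", 1, "det"),
    tk(1, "number", "number", "NN", 12, "nsubjpass"),
    tk(2, "of", "of", "IN", -1, "root"),
    tk(3, "angiogenesis", "angiogenesis", "NN", 4, "nn"),
    tk(4, "inhibitors", "inhibitor", "NNS", 1, "prep_of"),
    tk(5, "such", "such", "JJ", -1, "root"),
    tk(6, "as", "as", "IN", -1, "root"),
    tk(7, "sunitinib", "sunitinib", "NN", 4, "prep_such_as"),
    tk(8, "and", "and", "CC", -1, "root"),
    tk(9, "sorafenib", "sorafenib", "NN", 7, "conj_and"),
    tk(10, "have", "have", "VBP", 12, "aux"),
    tk(11, "been", "be", "VBN", 12, "auxpass"),
    tk(12, "found", "find", "VBN", -1, "root"),
    tk(13, "to", "to", "TO", 14, "aux"),
    tk(14, "cause", "cause", "VB", 12, "xcomp"),
    tk(15, "acute", "acute", "JJ", 16, "amod"),
    tk(16, "hemolysis", "hemolysis", "NN", 14, "dobj")
  )
  extra <- data.frame(label = c("xsubj", "prep_such_as"),
                      head = c(14L, 4L), dep = c(1L, 9L),
                      stringsAsFactors = FALSE)
  record <- fx_record("900003", 0L, tokens, extra)
  doc <- split_sentences(doc)
  doc <- attach_parses(doc, list("900003" = list(record)))
  list(doc = doc, records = list("900003" = list(record)))
}

# --- core-term construction ("a case of DIS caused by CHEM") --------------
fixture_coreterm_doc <- function() {
  title <- "A case of tardive dyskinesia caused by metoclopramide."
  specs <- list(
    list(text = "metoclopramide", type = "chemical", ids = "C0703"),
    list(text = "tardive dyskinesia", type = "disease", ids = "D0704")
  )
  doc <- fx_document("900004", title, "", specs,
                     relation_frame("C0703", "D0704"))
  tokens <- fx_tokens(
    tk(0, "A", "a", "DT", 1, "det"),
    tk(1, "case", "case", "NN", -1, "root"),
    tk(2, "of", "of", "IN", -1, "root"),
    tk(3, "tardive", "tardive", "JJ", 4, "amod"),
    tk(4, "dyskinesia", "dyskinesia", "NN", 1, "prep_of"),
    tk(5, "caused", "cause", "VBN", 1, "vmod"),
    tk(6, "by", "by", "IN", -1, "root"),
    tk(7, "metoclopramide", "metoclopramide", "NN", 5, "agent")
  )
  extra <- data.frame(label = "nsubjpass", head = 5L, dep = 1L,
                      stringsAsFactors = FALSE)
  record <- fx_record("900004", 0L, tokens, extra)
  doc <- split_sentences(doc)
  doc <- attach_parses(doc, list("900004" = list(record)))
  list(doc = doc, records = list("900004" = list(record)))
}

# mention row of a document matching a concept ID (first occurrence)
fx_mention_row <- function(doc, id) {
  hit <- which(vapply(doc$mentions$concept_ids, function(x) id %in% x, TRUE))
  doc$mentions[hit[1], , drop = FALSE]
}

# edge set of a given label as "src->tgt" strings, for compact assertions
fx_edge_keys <- function(edg, label, provenance = NULL) {
  e <- edg$edges[edg$edges$label == label, , drop = FALSE]
  if (!is.null(provenance)) e <- e[e$provenance == provenance, , drop = FALSE]
  sort(sprintf("%d->%d", e$src, e$tgt))
}

# lemma of a vertex index (assertion readability)
fx_vertex <- function(edg, lemma) {
  edg$vertices$index[tolower(edg$vertices$lemma) == lemma]
}
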