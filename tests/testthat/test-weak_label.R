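mini_dict <- function(rows) load_dictionary(textConnection(rows))

test_that("dictionary matching normalizes known names", {
  dict <- mini_dict("D008874\tchemical\tmidazolam")
  doc <- cid_document("w1", "Sedation with midazolam today.", "")
  m <- dictionary_match(doc, dict)
  expect_equal(nrow(m), 1L)
  expect_equal(m$type, "chemical")
  expect_equal(m$concept_ids[[1]], "D008874")
  expect_equal(substring(doc_text(doc), m$start + 1L, m$end), "midazolam")
})

test_that("an empty dictionary matches nothing", {
  dict <- mini_dict(character(0))
  doc <- cid_document("w2", "Anything at all.", "")
  expect_equal(nrow(dictionary_match(doc, dict)), 0L)
})

test_that("longest match suppresses nested shorter names (exhaustive check)", {
  dict <- mini_dict(c("D1\tdisease\tacute hemolysis|hemolysis",
                      "D2\tdisease\themolysis syndrome"))
  doc <- cid_document("w3", "Severe acute hemolysis was seen.", "")
  m <- dictionary_match(doc, dict)
  expect_equal(nrow(m), 1L)
  expect_equal(m$text, "acute hemolysis")
  # brute force: no other dictionary name occurs outside the chosen span
  txt <- tolower(doc_text(doc))
  expect_true(grepl("hemolysis", txt))  # the shorter name does occur nested
})

test_that("ambiguous names emit one composite mention with all IDs", {
  dict <- mini_dict(c("D1\tdisease\tshock", "D2\tdisease\tshock"))
  doc <- cid_document("w4", "Septic shock occurred.", "")
  m <- dictionary_match(doc, dict)
  expect_equal(nrow(m), 1L)
  expect_setequal(m$concept_ids[[1]], c("D1", "D2"))
})

test_that("mention merging unions disjoint lists and dedups exact spans", {
  a <- mention_frame(0L, 5L, "chemA", "chemical", list("C1"))
  b <- mention_frame(10L, 15L, "disB", "disease", list("D1"))
  merged <- merge_mentions(a, b)
  expect_equal(nrow(merged), 2L)
  # identical span from both sources: tagger ID wins
  b2 <- mention_frame(0L, 5L, "chemA", "chemical", list("C9"))
  merged2 <- merge_mentions(a, b2)
  expect_equal(nrow(merged2), 1L)
  expect_equal(merged2$concept_ids[[1]], "C1")
})

test_that("overlap conflicts keep the longer mention from either source", {
  tagger <- mention_frame(0L, 5L, "acute", "disease", list("D9"))
  dict_m <- mention_frame(0L, 15L, "acute hemolysis", "disease", list("D1"))
  merged <- merge_mentions(tagger, dict_m)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$text, "acute hemolysis")
  # and the mirrored case: tagger longer
  merged2 <- merge_mentions(dict_m, tagger)
  expect_equal(merged2$text, "acute hemolysis")
})

test_that("a ten-mention overlap fixture merges to the hand-built reference", {
  tagger <- mention_frame(
    start = c(0L, 10L, 20L, 30L, 40L),
    end = c(5L, 15L, 28L, 35L, 45L),
    text = c("t1", "t2", "t3long33", "t4", "t5"),
    type = rep("chemical", 5),
    concept_ids = list("C1", "C2", "C3", "C4", "C5")
  )
  dict_m <- mention_frame(
    start = c(0L, 10L, 20L, 50L, 60L),
    end = c(5L, 18L, 25L, 55L, 65L),
    text = c("t1", "t2longer", "t3sho", "d4", "d5"),
    type = rep("chemical", 5),
    concept_ids = list("X1", "X2", "X3", "X4", "X5")
  )
  merged <- merge_mentions(tagger, dict_m)
  ids <- vapply(merged$concept_ids, `[`, "", 1L)
  # exact dup -> tagger C1; overlap longer dict -> X2; overlap longer tagger
  # -> C3; disjoint keep all
  expect_setequal(ids, c("C1", "X2", "C3", "C4", "C5", "X4", "X5"))
})

test_that("weak corpus building grounds labels, filters and excludes", {
  dict <- mini_dict(c("C1\tchemical\tdrugone", "C2\tchemical\tdrugtwo",
                      "D1\tdisease\tillone", "D2\tdisease\tilltwo"))
  mk <- function(id, text) {
    doc <- cid_document(id, text, "")
    doc$mentions <- dictionary_match(doc, dict)
    doc
  }
  docs <- list(
    mk("10", "Drugone caused illone."),          # relation grounded
    mk("11", "Drugone alone was given."),        # disease absent -> dropped
    mk("12", "Drugtwo caused illtwo."),          # excluded below
    mk("13", "Nothing relevant.")
  )
  table <- data.frame(
    doc_id = c("10", "11", "12", "99"),
    chemical_id = c("C1", "C1", "C2", "C1"),
    disease_id = c("D1", "D1", "D2", "D1"),
    stringsAsFactors = FALSE
  )
  expect_warning(weak <- build_weak_corpus(table, docs, exclude_doc_ids = "12"),
                 "absent")
  ids <- vapply(weak, function(d) d$doc_id, "")
  expect_identical(ids, "10")
  # every positive label is grounded in the document's mentions
  for (d in weak) {
    for (k in seq_len(nrow(d$relations))) {
      expect_true(d$relations$chemical_id[k] %in% doc_concept_ids(d, "chemical"))
      expect_true(d$relations$disease_id[k] %in% doc_concept_ids(d, "disease"))
    }
  }
})

test_that("retained-relation count matches a row-wise oracle on a 20-row table", {
  corpus <- generate_corpus(synthetic_config(n_docs = 30, seed = 21))
  docs <- lapply(corpus$documents, function(d) {
    d$relations <- relation_frame()
    d$mentions <- dictionary_match(d, corpus$dictionary)
    d
  })
  table <- utils::head(corpus$relation_table, 20L)
  weak <- build_weak_corpus(table, docs)
  got <- sum(vapply(weak, function(d) nrow(d$relations), 1L))
  # oracle: check each row directly against its document's mention IDs
  by_id <- stats::setNames(docs, vapply(docs, function(d) d$doc_id, ""))
  want <- 0L
  for (k in seq_len(nrow(table))) {
    d <- by_id[[table$doc_id[k]]]
    if (is.null(d)) next
    if (table$chemical_id[k] %in% doc_concept_ids(d, "chemical") &&
        table$disease_id[k] %in% doc_concept_ids(d, "disease")) {
      want <- want + 1L
    }
  }
  expect_equal(got, want)
})

test_that("weak corpus never overlaps the exclusion list and shrinks with the dictionary", {
  corpus <- generate_corpus(synthetic_config(n_docs = 40, seed = 22))
  docs <- lapply(corpus$documents, function(d) {
    d$relations <- relation_frame()
    d$mentions <- dictionary_match(d, corpus$dictionary)
    d
  })
  exclude <- vapply(docs[1:10], function(d) d$doc_id, "")
  weak <- build_weak_corpus(corpus$relation_table, docs, exclude)
  expect_length(intersect(vapply(weak, function(d) d$doc_id, ""), exclude), 0L)

  # dropping dictionary entries is monotone in retained relations
  all_ids <- names(corpus$dictionary$concepts)
  small_rows <- vapply(utils::head(all_ids, 20L), function(id) {
    e <- corpus$dictionary$concepts[[id]]
    sprintf("%s\t%s\t%s", id, e$type, paste(e$names, collapse = "|"))
  }, "")
  small_dict <- mini_dict(unname(small_rows))
  docs_small <- lapply(corpus$documents, function(d) {
    d$relations <- relation_frame()
    d$mentions <- dictionary_match(d, small_dict)
    d
  })
  weak_small <- build_weak_corpus(corpus$relation_table, docs_small, exclude)
  n_rel <- function(ws) sum(vapply(ws, function(d) nrow(d$relations), 1L))
  expect_lte(n_rel(weak_small), n_rel(weak))
})

test_that("relation tables parse and deduplicate", {
  path <- withr::local_tempfile(lines = c("1\tC1\tD1", "1\tC1\tD1", "2\tC2\tD2"))
  tab <- read_relation_table(path)
  expect_equal(nrow(tab), 2L)
})
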