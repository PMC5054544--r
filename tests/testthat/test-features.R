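test_that("the bag-of-words worked example reproduces exactly", {
  fx <- fixture_bow_doc()
  bow <- bow_features(fx$doc, "D011899")
  want <- c("bow:acute" = 2, "bow:case" = 1, "bow:frequently" = 1,
            "bow:induce" = 2, "bow:is" = 1, "bow:of" = 1)
  expect_equal(bow[order(names(bow))], want)
})

test_that("a mention alone in a one-token sentence has an empty context bag", {
  doc <- cid_document("b1", "Aspirin.", "",
                      mentions = mention_frame(0L, 7L, "Aspirin", "chemical",
                                               list("C1")))
  doc <- split_sentences(doc)
  rec <- fx_record("b1", 0L, fx_tokens(tk(0, "Aspirin", "aspirin", "NN", -1, "root")))
  doc$sentences[[1]] <- attach_parse(doc$sentences[[1]], rec)
  expect_length(bow_features(doc, "C1"), 0L)
})

test_that("bag-of-words windows clip at sentence boundaries (oracle check)", {
  fx1 <- fixture_bow_doc()
  fx2 <- fixture_sample_doc()
  for (doc in list(fx1$doc, fx2$doc)) {
    ids <- unique(unlist(doc$mentions$concept_ids))
    for (id in ids) {
      got <- bow_features(doc, id)
      expect_equal(got[order(names(got))], oracle_bow(doc, id),
                   info = id)
    }
  }
})

test_that("the bigram worked example reproduces exactly", {
  fx <- fixture_bow_doc()
  s <- fx$doc$sentences[[1]]
  bon <- bon_features(s, fx_mention_row(fx$doc, "D011899"),
                      fx_mention_row(fx$doc, "D009395"))
  bigrams <- bon[startsWith(names(bon), "bon2:")]
  expect_setequal(names(bigrams),
                  c("bon2:D011899|induce", "bon2:induce|acute",
                    "bon2:acute|D009395"))
  expect_true(all(bigrams == 1))
})

test_that("adjacent mentions give the single chemical-disease bigram", {
  doc <- cid_document("b2", "Aspirin headache.", "",
                      mentions = mention_frame(c(0L, 8L), c(7L, 16L),
                                               c("Aspirin", "headache"),
                                               c("chemical", "disease"),
                                               list("C1", "D1")))
  doc <- split_sentences(doc)
  rec <- fx_record("b2", 0L, fx_tokens(
    tk(0, "Aspirin", "aspirin", "NN", -1, "root"),
    tk(1, "headache", "headache", "NN", 0, "dep")
  ))
  doc$sentences[[1]] <- attach_parse(doc$sentences[[1]], rec)
  bon <- bon_features(doc$sentences[[1]], doc$mentions[1, ], doc$mentions[2, ])
  expect_equal(unname(bon["bon2:C1|D1"]), 1)
})

test_that("n-gram counts follow the combinatorial formula", {
  # sequence of L items has max(0, L - n + 1) n-grams
  for (gap in 0:6) {
    words <- c("Chem", letters[seq_len(gap)], "Dis")
    text <- paste(words, collapse = " ")
    ends <- cumsum(nchar(words) + 1L) - 1L
    starts <- ends - nchar(words)
    doc <- cid_document("b3", text, "",
                        mentions = mention_frame(
                          c(starts[1], starts[length(words)]),
                          c(ends[1], ends[length(words)]),
                          c("Chem", "Dis"), c("chemical", "disease"),
                          list("C1", "D1")))
    doc <- split_sentences(doc)
    rows <- lapply(seq_along(words), function(i) {
      tk(i - 1L, words[i], tolower(words[i]), "NN",
         if (i == 1L) -1L else 0L, if (i == 1L) "root" else "dep")
    })
    rec <- fx_record("b3", 0L, do.call(fx_tokens, rows))
    doc$sentences[[1]] <- attach_parse(doc$sentences[[1]], rec)
    bon <- bon_features(doc$sentences[[1]], doc$mentions[1, ], doc$mentions[2, ])
    L <- gap + 2L
    for (n in 1:3) {
      expect_equal(sum(bon[startsWith(names(bon), sprintf("bon%d:", n))]),
                   max(0L, L - n + 1L), info = sprintf("gap %d n %d", gap, n))
    }
  }
})

test_that("mentions in different sentences yield no n-gram features", {
  fx <- fixture_sample_doc()
  doc <- fx$doc
  chem <- fx_mention_row(doc, "D008874")
  dep <- fx_mention_row(doc, "D012140")
  s_of_dep <- which(vapply(doc$sentences,
                           function(s) dep$start >= s$start & dep$end <= s$end,
                           TRUE))
  expect_length(bon_features(doc$sentences[[s_of_dep]], chem, dep), 0L)
})

test_that("pattern features fire for the collection pair via propagation", {
  fx <- fixture_collection_doc()
  g <- document_edgs(fx$doc)[[1]]
  pf <- pattern_features(g, fx_mention_row(fx$doc, "C0601"),
                         fx_mention_row(fx$doc, "D0603"))
  expect_equal(unname(pf["pat:cause"]), 1)
  expect_equal(sum(pf), 1)
})

test_that("pattern features fire via the propagated core-term arg1", {
  fx <- fixture_coreterm_doc()
  g <- document_edgs(fx$doc)[[1]]
  pf <- pattern_features(g, fx_mention_row(fx$doc, "C0703"),
                         fx_mention_row(fx$doc, "D0704"))
  expect_equal(unname(pf["pat:cause"]), 1)
  expect_equal(sum(pf), 1)
})

test_that("an EDG without numbered arguments gives four zero pattern features", {
  fx <- fixture_collection_doc()
  g <- build_edg(fx$doc$sentences[[1]], fx$doc$mentions)  # no arg layer
  pf <- pattern_features(g, fx_mention_row(fx$doc, "C0601"),
                         fx_mention_row(fx$doc, "D0603"))
  expect_length(pf, 4L)
  expect_true(all(pf == 0))
})

test_that("walk features reproduce the canonical shortest-path decomposition", {
  for (fx in list(fixture_collection_doc(), fixture_coreterm_doc())) {
    edgs <- document_edgs(fx$doc)
    chem_id <- fx$doc$relations$chemical_id[1]
    dis_id <- fx$doc$relations$disease_id[1]
    pf <- path_features(edgs, chem_id, dis_id)
    expect_true(all(c("path:vwalk:cause->arg0->Chemical",
                      "path:vwalk:cause->arg1->Disease",
                      "path:ewalk:arg0<-cause->arg1") %in% names(pf)))
    expect_equal(unname(pf["path:weight"]), 0.9^2)
  }
})

test_that("lambda = 1 disables the path length decay", {
  fx <- fixture_collection_doc()
  edgs <- document_edgs(fx$doc)
  pf <- path_features(edgs, "C0601", "D0603", path_feature_config(lambda = 1))
  expect_equal(unname(pf["path:weight"]), 1)
})

test_that("pattern hits imply a short path (length <= 2) between the pair", {
  corpus <- generate_corpus(synthetic_config(n_docs = 30, seed = 11))
  for (doc in prep_corpus(corpus)) {
    edgs <- document_edgs(doc)
    for (ci in doc_concept_ids(doc, "chemical")) {
      for (di in doc_concept_ids(doc, "disease")) {
        for (si in seq_along(edgs)) {
          g <- edgs[[si]]
          if (is.null(g)) next
          cvs <- cidre:::edg_entity_vertices(g, ci, "chemical")
          dvs <- cidre:::edg_entity_vertices(g, di, "disease")
          if (length(cvs) == 0L || length(dvs) == 0L) next
          ms <- cidre:::mentions_in_sentence(doc, doc$sentences[[si]])
          cm <- ms[vapply(ms$concept_ids, function(x) ci %in% x, TRUE) &
                     ms$type == "chemical", , drop = FALSE][1, ]
          dm <- ms[vapply(ms$concept_ids, function(x) di %in% x, TRUE) &
                     ms$type == "disease", , drop = FALSE][1, ]
          pf <- pattern_features(g, cm, dm)
          if (any(pf == 1)) {
            paths <- edg_shortest_paths(g, cvs[1], dvs[1])
            expect_true(length(paths) > 0L)
            expect_lte(length(paths[[1]]$edge_rows), 2L)
          }
        }
      }
    }
  }
})

test_that("statistical features capture position, co-occurrence and counts", {
  fx <- fixture_sample_doc()
  sf <- statistical_features(fx$doc, "D008874", "D006323")
  expect_length(sf, 19L)
  expect_equal(unname(sf["stat:same_sentence"]), 1)
  expect_equal(unname(sf["stat:chem_in_title"]), 1)
  expect_equal(unname(sf["stat:dis_in_title"]), 1)
  # direct count oracle: scan the mention list
  n_chem <- sum(vapply(fx$doc$mentions$concept_ids,
                       function(x) "D008874" %in% x, TRUE))
  expect_equal(unname(sf["stat:n_chem_mentions"]), n_chem)
  # the cross-sentence pair does not co-occur
  sf2 <- statistical_features(fx$doc, "D008874", "D012140")
  expect_equal(unname(sf2["stat:same_sentence"]), 0)
})

test_that("the null knowledge base zeroes both curation features", {
  fx <- fixture_sample_doc()
  sf <- statistical_features(fx$doc, "D008874", "D006323", kb_null())
  expect_equal(unname(sf["stat:kb_ctd"]), 0)
  expect_equal(unname(sf["stat:kb_mesh"]), 0)
})

test_that("a loaded knowledge base answers pair membership", {
  ctd <- withr::local_tempfile(lines = "D008874\tD006323")
  mesh <- withr::local_tempfile(lines = c("D008874\tD012140"))
  kb <- kb_load(ctd, mesh, snapshot_date = "2015-01-01")
  expect_true(kb$has_ctd_relation("D008874", "D006323"))
  expect_false(kb$has_ctd_relation("D008874", "D012140"))
  expect_true(kb$comention_in_mesh_indexing("D008874", "D012140"))
  fx <- fixture_sample_doc()
  sf <- statistical_features(fx$doc, "D008874", "D006323", kb)
  expect_equal(unname(sf["stat:kb_ctd"]), 1)
})

test_that("demographic and keyword context features use the window radius", {
  fx <- fixture_sample_doc()
  # "A patient received midazolam": 'patient' is 2 tokens left of the chemical
  sf <- statistical_features(fx$doc, "D008874", "D006323")
  expect_equal(unname(sf["stat:demo_chem"]), 1)
})

test_that("merge combines booleans by OR, numerics by mean, bags by sum", {
  v1 <- c("pat:cause" = 1, "path:weight" = 0.81, "bon2:a|b" = 1)
  v2 <- c("pat:cause" = 0, "path:weight" = 0.9, "bon2:a|b" = 2)
  v3 <- c("pat:cause" = 0, "path:weight" = 0.6)
  m <- merge_to_pair_vector(list(v1, v2, v3))
  expect_equal(unname(m["pat:cause"]), 1)          # OR = max
  expect_equal(unname(m["path:weight"]), mean(c(0.81, 0.9, 0.6)))
  expect_equal(unname(m["bon2:a|b"]), 3)           # bag sum
})

test_that("merging a single vector is the identity and ID features append", {
  v <- c("pat:induce" = 1, "bow:acute" = 2)
  expect_equal(merge_to_pair_vector(list(v))[order(names(v))],
               v[order(names(v))])
  id_vec <- c("stat:same_sentence" = 1)
  m <- merge_to_pair_vector(list(v), id_vec)
  expect_equal(unname(m["stat:same_sentence"]), 1)
})

test_that("adding a mention pair never flips a merged boolean off", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    vecs <- replicate(k, c("pat:cause" = sample(0:1, 1)), simplify = FALSE)
    m1 <- merge_to_pair_vector(vecs)
    m2 <- merge_to_pair_vector(c(vecs, list(c("pat:cause" = sample(0:1, 1)))))
    expect_gte(unname(m2["pat:cause"]), unname(m1["pat:cause"]))
  }
})

test_that("a feature with no declared merge semantics is a hard error", {
  expect_error(merge_to_pair_vector(list(c("mystery:x" = 1))),
               "merge semantics")
})

test_that("path weight lies in (0, 1] and decreases with path length", {
  cfg <- path_feature_config(lambda = 0.9)
  w <- cfg$lambda^(1:6)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) < 0))
  # chain graph: weight follows lambda^distance
  for (len in 1:3) {
    n <- len + 1L
    g <- random_edg(n, 0)
    g$edges <- data.frame(src = 0:(len - 1L), tgt = 1:len, label = "dep",
                          layer = "syntactic", provenance = "parser",
                          stringsAsFactors = FALSE)
    g$vertices$ne_type[1] <- "chemical"; g$vertices$ne_ids[[1]] <- "C1"
    g$vertices$ne_type[n] <- "disease"; g$vertices$ne_ids[[n]] <- "D1"
    pf <- path_features(list(g), "C1", "D1", cfg)
    expect_equal(unname(pf["path:weight"]), 0.9^len)
  }
})

test_that("feature extraction is deterministic", {
  fx <- fixture_collection_doc()
  i1 <- build_instances(fx$doc)
  i2 <- build_instances(fx$doc)
  expect_identical(i1, i2)
})
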