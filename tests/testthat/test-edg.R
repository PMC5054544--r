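test_that("EDG construction matches hand-enumerated vertex and edge counts", {
  fx <- fixture_collection_doc()
  g <- build_edg(fx$doc$sentences[[1]], fx$doc$mentions)
  expect_equal(nrow(g$vertices), 17L)
  # 12 primary dependencies (head >= 0) + 2 extra edges from the sidecar
  expect_equal(sum(g$edges$layer == "syntactic"), 14L)
  expect_equal(sum(g$edges$label == "xsubj"), 1L)
  # entity labels land on the right vertices; the multi-token disease
  # mention is carried by its syntactic head token
  expect_equal(g$vertices$ne_type[g$vertices$text == "sunitinib"], "chemical")
  expect_equal(g$vertices$ne_type[g$vertices$text == "hemolysis"], "disease")
  expect_true(is.na(g$vertices$ne_type[g$vertices$text == "acute"]))
})

test_that("a sentence without mentions builds a graph with no NE labels", {
  doc <- split_sentences(cid_document("n1", "Nothing here.", ""))
  rec <- fx_record("n1", 0L, fx_tokens(
    tk(0, "Nothing", "nothing", "NN", 1, "nsubj"),
    tk(1, "here", "here", "RB", -1, "root")
  ))
  doc$sentences[[1]] <- attach_parse(doc$sentences[[1]], rec)
  g <- build_edg(doc$sentences[[1]])
  expect_true(all(is.na(g$vertices$ne_type)))
})

test_that("numbered arguments reproduce the collection-sentence edges", {
  fx <- fixture_collection_doc()
  g <- assign_numbered_args(build_edg(fx$doc$sentences[[1]], fx$doc$mentions))
  cause <- fx_vertex(g, "cause")
  number <- fx_vertex(g, "number")
  hemolysis <- fx_vertex(g, "hemolysis")
  expect_setequal(fx_edge_keys(g, "arg0"),
                  sprintf("%d->%d", cause, number))
  expect_setequal(fx_edge_keys(g, "arg1"),
                  sprintf("%d->%d", cause, hemolysis))
})

test_that("numbered arguments reproduce the core-term-sentence edges", {
  fx <- fixture_coreterm_doc()
  g <- assign_numbered_args(build_edg(fx$doc$sentences[[1]], fx$doc$mentions))
  cause <- fx_vertex(g, "cause")
  case_ <- fx_vertex(g, "case")
  metoclopramide <- fx_vertex(g, "metoclopramide")
  expect_setequal(fx_edge_keys(g, "arg1"), sprintf("%d->%d", cause, case_))
  expect_setequal(fx_edge_keys(g, "arg0"),
                  sprintf("%d->%d", cause, metoclopramide))
})

test_that("a verbless sentence gains no numbered-argument edges", {
  doc <- split_sentences(cid_document("n2", "Severe headache today.", ""))
  rec <- fx_record("n2", 0L, fx_tokens(
    tk(0, "Severe", "severe", "JJ", 1, "amod"),
    tk(1, "headache", "headache", "NN", -1, "root"),
    tk(2, "today", "today", "RB", 1, "advmod")
  ))
  doc$sentences[[1]] <- attach_parse(doc$sentences[[1]], rec)
  g <- assign_numbered_args(build_edg(doc$sentences[[1]]))
  expect_equal(sum(g$edges$layer == "numbered_arg"), 0L)
})

test_that("semantic edges capture collection and is-a constructions", {
  fx <- fixture_collection_doc()
  g <- add_semantic_edges(build_edg(fx$doc$sentences[[1]], fx$doc$mentions))
  number <- fx_vertex(g, "number")
  inhib <- fx_vertex(g, "inhibitor")
  sun <- fx_vertex(g, "sunitinib")
  sor <- fx_vertex(g, "sorafenib")
  expect_setequal(fx_edge_keys(g, "member-collection"),
                  sprintf("%d->%d", number, inhib))
  expect_setequal(fx_edge_keys(g, "is-a"),
                  sort(sprintf("%d->%d", c(sun, sor), inhib)))
})

test_that("is-a distributes over coordination when only one conjunct is attached", {
  # "drugs such as aspirin and ibuprofen": only aspirin carries prep_such_as
  doc <- split_sentences(cid_document("n3", "Drugs such as aspirin and ibuprofen.", ""))
  rec <- fx_record("n3", 0L, fx_tokens(
    tk(0, "Drugs", "drug", "NNS", -1, "root"),
    tk(1, "such", "such", "JJ", -1, "root"),
    tk(2, "as", "as", "IN", -1, "root"),
    tk(3, "aspirin", "aspirin", "NN", 0, "prep_such_as"),
    tk(4, "and", "and", "CC", -1, "root"),
    tk(5, "ibuprofen", "ibuprofen", "NN", 3, "conj_and")
  ))
  doc$sentences[[1]] <- attach_parse(doc$sentences[[1]], rec)
  g <- add_semantic_edges(build_edg(doc$sentences[[1]]))
  expect_setequal(fx_edge_keys(g, "is-a"), c("3->0", "5->0"))
})

test_that("a sentence without semantic constructions is unchanged", {
  fx <- fixture_coreterm_doc()
  g0 <- build_edg(fx$doc$sentences[[1]], fx$doc$mentions)
  g1 <- add_semantic_edges(g0)
  expect_equal(g1$edges, g0$edges)
})

test_that("propagation adds exactly the collection-derived arg0 edges", {
  fx <- fixture_collection_doc()
  g <- propagate_args(add_semantic_edges(assign_numbered_args(
    build_edg(fx$doc$sentences[[1]], fx$doc$mentions))))
  cause <- fx_vertex(g, "cause")
  sun <- fx_vertex(g, "sunitinib")
  sor <- fx_vertex(g, "sorafenib")
  prop <- g$edges[g$edges$provenance == "propagated", , drop = FALSE]
  expect_equal(nrow(prop), 2L)
  expect_setequal(sprintf("%d->%d:%s", prop$src, prop$tgt, prop$label),
                  sort(sprintf("%d->%d:arg0", c(cause, cause), c(sun, sor))))
})

test_that("propagation skips the generic core-term head onto the entity", {
  fx <- fixture_coreterm_doc()
  g <- propagate_args(add_semantic_edges(assign_numbered_args(
    build_edg(fx$doc$sentences[[1]], fx$doc$mentions))))
  cause <- fx_vertex(g, "cause")
  dysk <- fx_vertex(g, "dyskinesia")
  expect_setequal(fx_edge_keys(g, "arg1", "propagated"),
                  sprintf("%d->%d", cause, dysk))
})

test_that("propagation is idempotent and monotone", {
  for (fx in list(fixture_collection_doc(), fixture_coreterm_doc())) {
    g0 <- add_semantic_edges(assign_numbered_args(
      build_edg(fx$doc$sentences[[1]], fx$doc$mentions)))
    g1 <- propagate_args(g0)
    g2 <- propagate_args(g1)
    expect_equal(g2$edges, g1$edges)  # fixpoint
    key0 <- paste(g0$edges$src, g0$edges$tgt, g0$edges$label)
    key1 <- paste(g1$edges$src, g1$edges$tgt, g1$edges$label)
    expect_true(all(key0 %in% key1))  # only adds edges
  }
})

test_that("shortest paths agree with exhaustive enumeration on random graphs", {
  set.seed(42)
  for (rep in seq_len(500L)) {
    n <- sample(2:8, 1L)
    g <- random_edg(n, sample(1:10, 1L))
    from <- sample(seq_len(n), 1L) - 1L
    to <- sample(seq_len(n), 1L) - 1L
    got <- path_signatures(edg_shortest_paths(g, from, to))
    want <- oracle_min_paths(g$edges, from, to)
    if (from == to) want <- ""  # zero-length convention
    expect_identical(got, if (identical(want, "")) "" else want,
                     info = sprintf("rep %d: n=%d from=%d to=%d", rep, n, from, to))
  }
})

test_that("identical endpoints yield a single zero-length path", {
  g <- random_edg(3, 3)
  paths <- edg_shortest_paths(g, 1L, 1L)
  expect_length(paths, 1L)
  expect_length(paths[[1]]$edge_rows, 0L)
})

test_that("disconnected vertices yield no path", {
  g <- random_edg(4, 0)
  expect_length(edg_shortest_paths(g, 0L, 3L), 0L)
})

test_that("rule switches disable individual numbered-argument rules", {
  fx <- fixture_coreterm_doc()
  cfg <- edg_config()
  cfg$rules$agent_arg0 <- FALSE
  g <- assign_numbered_args(build_edg(fx$doc$sentences[[1]], fx$doc$mentions),
                            cfg)
  expect_length(fx_edge_keys(g, "arg0"), 0L)
  expect_length(fx_edge_keys(g, "arg1"), 1L)
})
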