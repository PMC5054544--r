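# Feature families for <Chemical ID, Disease ID> candidate pairs.
#
# All extractors return sparse named numeric vectors. Namespaces:
#   bow:<lemma>            document-accumulated context lemma counts
#   bon1:/bon2:/bon3:      n-grams over the lemma span between the mentions
#   pat:<trigger>          the four trigger-pattern booleans
#   path:vwalk:/path:ewalk direction-annotated walk decompositions
#   path:weight            mean lambda^length over minimal paths
#   stat:<name>            the 19 statistical features

#' Path/window feature configuration
#'
#' @param lambda exponential length decay of the shortest-path weight
#'   feature, in (0, 1]; default 0.9.
#' @param max_ngram largest n-gram order for the bag-of-ngram family;
#'   default 3 (unigrams, bigrams, trigrams).
#' @param bow_radius context tokens taken on each side of a mention;
#'   default 2, i.e. a window of size 5 with the mention as one slot.
#' @return a list of class \code{path_feature_config}.
#' @export
path_feature_config <- function(lambda = 0.9, max_ngram = 3L, bow_radius = 2L) {
  stopifnot(lambda > 0, lambda <= 1, max_ngram >= 1L, bow_radius >= 0L)
  structure(list(lambda = lambda, max_ngram = as.integer(max_ngram),
                 bow_radius = as.integer(bow_radius)),
            class = "path_feature_config")
}

#' Contextual keyword lists for the statistical features
#'
#' Editable lists seeded with the canonical exemplars: disease-context
#' keywords (therapy, complicating, affect, ...), a dosage detector for
#' chemical context (a number followed by a unit, or a unit token such as
#' \code{mg} or \code{mEq/L}), increase/decrease, p-value and
#' demographic keywords.
#'
#' @param disease_keywords lemmas flagged around disease mentions.
#' @param dosage_units unit tokens flagged around chemical mentions.
#' @param incdec_keywords,demographic_keywords,pvalue_pattern as named.
#' @return a list of class \code{stat_keyword_config}.
#' @export
stat_keyword_config <- function(
    disease_keywords = c("therapy", "therapies", "complicating", "affect",
                         "treatment", "complication"),
    dosage_units = c("mg", "g", "kg", "ml", "l", "mcg", "ug", "meq/l",
                     "mg/kg", "mg/dl", "mmol/l"),
    incdec_keywords = c("increase", "decrease"),
    demographic_keywords = c("men", "women", "patient"),
    pvalue_pattern = "^p-?values?$") {
  structure(list(disease_keywords = tolower(disease_keywords),
                 dosage_units = tolower(dosage_units),
                 incdec_keywords = tolower(incdec_keywords),
                 demographic_keywords = tolower(demographic_keywords),
                 pvalue_pattern = pvalue_pattern),
            class = "stat_keyword_config")
}

# token rows covering a mention span within one sentence's token frame
#' @noRd
mention_token_rows <- function(tokens, m_start, m_end) {
  which(tokens$start < m_end & tokens$end > m_start)
}

# occurrences of a concept ID: list of (sentence index, token row range)
#' @noRd
concept_occurrences <- function(doc, concept_id) {
  occ <- list()
  m <- doc$mentions
  keep <- vapply(m$concept_ids, function(ids) concept_id %in% ids, TRUE)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(occ)
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    if (is.null(s$tokens)) next
    in_s <- which(m$start >= s$start & m$end <= s$end)
    for (mi in in_s) {
      rows <- mention_token_rows(s$tokens, m$start[mi], m$end[mi])
      if (length(rows)) {
        occ[[length(occ) + 1L]] <- list(sent = si, rows = rows, mention = m[mi, ])
      }
    }
  }
  occ
}

# context token rows (radius each side, clipped to the sentence, mention
# tokens excluded)
#' @noRd
window_rows <- function(tokens, mention_rows, radius) {
  lo <- min(mention_rows); hi <- max(mention_rows)
  ctx <- c(seq(max(1L, lo - radius), lo - 1L),
           seq(hi + 1L, min(nrow(tokens), hi + radius)))
  ctx <- ctx[ctx >= 1L & ctx <= nrow(tokens)]
  setdiff(ctx, mention_rows)
}

#' Bag-of-words features of a concept
#'
#' Context lemmas in a window around every occurrence of the concept ID in
#' the document, with their accumulated frequencies. The window spans the
#' mention plus \code{bow_radius} tokens on each side (default radius 2,
#' window size 5); the mention's own tokens are excluded from the context
#' bag, and the window never crosses a sentence boundary.
#'
#' @param doc a document with parsed sentences.
#' @param concept_id concept ID whose occurrences are windowed.
#' @param config a [path_feature_config()].
#' @return named numeric vector of \code{bow:} lemma counts.
#' @export
bow_features <- function(doc, concept_id, config = path_feature_config()) {
  out <- empty_fv()
  for (occ in concept_occurrences(doc, concept_id)) {
    tokens <- doc$sentences[[occ$sent]]$tokens
    ctx <- window_rows(tokens, occ$rows, config$bow_radius)
    if (length(ctx)) out <- fv_add(out, fv_count(tolower(tokens$lemma[ctx]), "bow:"))
  }
  out
}

#' Bag-of-ngram features between two mentions
#'
#' N-grams (orders 1..\code{max_ngram}) over the lemma sequence running
#' from the chemical mention to the disease mention (inclusive, in textual
#' order) within one sentence. Each of the two mentions is replaced by its
#' concept ID, so the features generalize across surface names. Mentions in
#' different sentences yield an empty vector.
#'
#' @param sentence a parsed sentence.
#' @param chem_mention,dis_mention single mention rows (data frames of one
#'   row) lying in the sentence.
#' @param config a [path_feature_config()].
#' @return named numeric vector of \code{bon<k>:} counts.
#' @export
bon_features <- function(sentence, chem_mention, dis_mention,
                         config = path_feature_config()) {
  tokens <- sentence$tokens
  if (is.null(tokens)) return(empty_fv())
  cr <- mention_token_rows(tokens, chem_mention$start, chem_mention$end)
  dr <- mention_token_rows(tokens, dis_mention$start, dis_mention$end)
  if (length(cr) == 0L || length(dr) == 0L) return(empty_fv())
  # replace each mention span by its concept-ID token, take the in-between span
  cid <- chem_mention$concept_ids[[1]][1]
  did <- dis_mention$concept_ids[[1]][1]
  seq_items <- character(0)
  if (max(cr) < min(dr)) {
    mid <- setdiff(seq(max(cr) + 1L, min(dr) - 1L), integer(0))
    mid <- mid[mid > max(cr) & mid < min(dr)]
    seq_items <- c(cid, tolower(tokens$lemma[mid]), did)
  } else if (max(dr) < min(cr)) {
    mid <- seq_len(nrow(tokens))
    mid <- mid[mid > max(dr) & mid < min(cr)]
    seq_items <- c(did, tolower(tokens$lemma[mid]), cid)
  } else {
    return(empty_fv())  # overlapping spans: no defined in-between sequence
  }
  out <- empty_fv()
  for (n in seq_len(config$max_ngram)) {
    if (length(seq_items) < n) break
    grams <- vapply(seq_len(length(seq_items) - n + 1L), function(i) {
      paste(seq_items[i:(i + n - 1L)], collapse = "|")
    }, "")
    out <- fv_add(out, fv_count(grams, sprintf("bon%d:", n)))
  }
  out
}

.cid_triggers <- c("cause", "induce", "associate", "produce")

#' Trigger-pattern features
#'
#' The rule \emph{Chemical <- arg0 <- trigger -> arg1 -> Disease} applied
#' for each of the four trigger lemmas (cause, induce, associate, produce):
#' \code{pat:<t>} is 1 iff some vertex with lemma \code{t} has an
#' \code{arg0} edge to the chemical vertex and an \code{arg1} edge to the
#' disease vertex (propagated edges count). Always returns exactly four
#' 0/1 features.
#'
#' @param edg a fully built and propagated \code{cid_edg}.
#' @param chem_mention,dis_mention single mention rows in the sentence.
#' @return named numeric vector of the four \code{pat:} booleans.
#' @export
pattern_features <- function(edg, chem_mention, dis_mention) {
  out <- rep(0, length(.cid_triggers))
  names(out) <- paste0("pat:", .cid_triggers)
  cv <- edg_vertices_for_mention(edg, chem_mention)
  dv <- edg_vertices_for_mention(edg, dis_mention)
  if (length(cv) == 0L || length(dv) == 0L) return(out)
  args <- edg$edges[edg$edges$layer == "numbered_arg", , drop = FALSE]
  for (t in .cid_triggers) {
    tv <- edg$vertices$index[tolower(edg$vertices$lemma) == t]
    hit <- FALSE
    for (v in tv) {
      a0 <- args$tgt[args$src == v & args$label == "arg0"]
      a1 <- args$tgt[args$src == v & args$label == "arg1"]
      if (any(a0 %in% cv) && any(a1 %in% dv)) { hit <- TRUE; break }
    }
    out[paste0("pat:", t)] <- as.numeric(hit)
  }
  out
}

# vertex indices labeled with the mention's type and any of its IDs
#' @noRd
edg_vertices_for_mention <- function(edg, mention) {
  ids <- mention$concept_ids[[1]]
  unique(unlist(lapply(ids, function(id) {
    edg_entity_vertices(edg, id, mention$type)
  })))
}

# render one path into v-walk / e-walk feature names
#' @noRd
path_walk_features <- function(edg, path, chem_vs, dis_vs) {
  render_vertex <- function(v) {
    if (v %in% chem_vs) return("Chemical")
    if (v %in% dis_vs) return("Disease")
    tolower(edg$vertices$lemma[match(v, edg$vertices$index)])
  }
  e <- edg$edges
  feats <- character(0)
  k <- length(path$edge_rows)
  # v-walks: each edge rendered with its own orientation src -> label -> tgt
  for (i in seq_len(k)) {
    row <- path$edge_rows[i]
    feats <- c(feats, sprintf("path:vwalk:%s->%s->%s",
                              render_vertex(e$src[row]), e$label[row],
                              render_vertex(e$tgt[row])))
  }
  # e-walks: interior vertex with its two incident edge labels and directions
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      v <- path$vertices[i + 1L]
      r1 <- path$edge_rows[i]; r2 <- path$edge_rows[i + 1L]
      s1 <- if (e$src[r1] == v) "<-" else "->"  # edge out of v points left
      s2 <- if (e$src[r2] == v) "->" else "<-"
      feats <- c(feats, sprintf("path:ewalk:%s%s%s%s%s",
                                e$label[r1], s1, render_vertex(v), s2,
                                e$label[r2]))
    }
  }
  feats
}

#' Shortest-path walk features of a concept pair
#'
#' For every sentence whose EDG contains a vertex of the chemical ID and a
#' vertex of the disease ID, all minimum-length paths between them are
#' decomposed into direction-annotated v-walks (two vertices and their
#' connecting edge, rendered with the edge's own orientation) and e-walks
#' (an interior vertex and its two incident directed edge labels). Mention
#' vertices render as the generic tokens \code{Chemical}/\code{Disease}.
#' One numeric feature \code{path:weight} holds the mean of
#' \code{lambda^length} over all minimal paths found.
#'
#' @param edgs list of per-sentence \code{cid_edg} (NULLs skipped).
#' @param chem_id,dis_id concept IDs.
#' @param config a [path_feature_config()].
#' @return named numeric vector; empty when the pair never co-occurs in a
#'   sentence or is disconnected everywhere.
#' @export
path_features <- function(edgs, chem_id, dis_id,
                          config = path_feature_config()) {
  out <- empty_fv()
  weights <- numeric(0)
  for (edg in edgs) {
    if (is.null(edg)) next
    cvs <- edg_entity_vertices(edg, chem_id, "chemical")
    dvs <- edg_entity_vertices(edg, dis_id, "disease")
    if (length(cvs) == 0L || length(dvs) == 0L) next
    for (cv in cvs) for (dv in dvs) {
      paths <- edg_shortest_paths(edg, cv, dv)
      for (p in paths) {
        weights <- c(weights, config$lambda^length(p$edge_rows))
        out <- fv_add(out, fv_count(path_walk_features(edg, p, cvs, dvs)))
      }
    }
  }
  if (length(weights)) out <- fv_add(out, c("path:weight" = mean(weights)))
  out
}

#' The 19 statistical features of a concept pair
#'
#' Mention-count, positional, co-occurrence, knowledge-base and contextual
#' keyword features, computed directly at the concept-ID level (the
#' mention-level OR/average merge is built in):
#' \enumerate{
#'   \item \code{stat:n_chem_mentions}, 2. \code{stat:n_dis_mentions}
#'     (numeric counts);
#'   \item[3-8] chemical/disease membership in the title, the first
#'     abstract sentence, the last abstract sentence (booleans);
#'   \item[9] \code{stat:same_sentence} co-occurrence;
#'   \item[10-11] \code{stat:kb_ctd}, \code{stat:kb_mesh} from the
#'     knowledge base;
#'   \item[12-19] contextual keyword booleans over the same window radius
#'     as the bag-of-words family.
#' }
#'
#' @param doc a document with parsed sentences.
#' @param chem_id,dis_id concept IDs.
#' @param kb a knowledge base, e.g. [kb_null()].
#' @param keywords a [stat_keyword_config()].
#' @param config a [path_feature_config()] (window radius).
#' @return named numeric vector of the 19 \code{stat:} features.
#' @export
statistical_features <- function(doc, chem_id, dis_id, kb = kb_null(),
                                 keywords = stat_keyword_config(),
                                 config = path_feature_config()) {
  occ_c <- concept_occurrences(doc, chem_id)
  occ_d <- concept_occurrences(doc, dis_id)
  n_sent <- length(doc$sentences)
  sent_of <- function(occs) vapply(occs, function(o) o$sent, 1L)
  # abstract sentences are 2..n_sent (title is sentence 1)
  first_abs <- if (n_sent >= 2L) 2L else NA_integer_
  last_abs <- if (n_sent >= 2L) n_sent else NA_integer_

  in_sent <- function(occs, si) !is.na(si) && si %in% sent_of(occs)
  ctx_lemmas <- function(occs) {
    unlist(lapply(occs, function(o) {
      tokens <- doc$sentences[[o$sent]]$tokens
      tolower(tokens$lemma[window_rows(tokens, o$rows, config$bow_radius)])
    }))
  }
  ctx_c <- ctx_lemmas(occ_c) %||% character(0)
  ctx_d <- ctx_lemmas(occ_d) %||% character(0)
  is_dosage <- function(lems) {
    any(lems %in% keywords$dosage_units) ||
      any(grepl("^[0-9]+(\\.[0-9]+)?$", lems)) ||
      any(grepl("^[0-9]+(\\.[0-9]+)?(mg|g|kg|ml|l|mcg|ug|meq)", lems))
  }
  has_pvalue <- function(lems) {
    any(grepl(keywords$pvalue_pattern, lems)) ||
      (any(lems == "p") && any(lems == "value"))
  }
  c(
    "stat:n_chem_mentions" = length(occ_c),
    "stat:n_dis_mentions" = length(occ_d),
    "stat:chem_in_title" = as.numeric(in_sent(occ_c, 1L)),
    "stat:dis_in_title" = as.numeric(in_sent(occ_d, 1L)),
    "stat:chem_in_first_abs" = as.numeric(in_sent(occ_c, first_abs)),
    "stat:dis_in_first_abs" = as.numeric(in_sent(occ_d, first_abs)),
    "stat:chem_in_last_abs" = as.numeric(in_sent(occ_c, last_abs)),
    "stat:dis_in_last_abs" = as.numeric(in_sent(occ_d, last_abs)),
    "stat:same_sentence" = as.numeric(length(intersect(sent_of(occ_c),
                                                       sent_of(occ_d))) > 0L),
    "stat:kb_ctd" = as.numeric(kb$has_ctd_relation(chem_id, dis_id)),
    "stat:kb_mesh" = as.numeric(kb$comention_in_mesh_indexing(chem_id, dis_id)),
    "stat:kw_dis_context" = as.numeric(any(ctx_d %in% keywords$disease_keywords)),
    "stat:dosage_chem_context" = as.numeric(is_dosage(ctx_c)),
    "stat:incdec_chem" = as.numeric(any(ctx_c %in% keywords$incdec_keywords)),
    "stat:incdec_dis" = as.numeric(any(ctx_d %in% keywords$incdec_keywords)),
    "stat:pvalue_chem" = as.numeric(has_pvalue(ctx_c)),
    "stat:pvalue_dis" = as.numeric(has_pvalue(ctx_d)),
    "stat:demo_chem" = as.numeric(any(ctx_c %in% keywords$demographic_keywords)),
    "stat:demo_dis" = as.numeric(any(ctx_d %in% keywords$demographic_keywords))
  )
}

# feature-name classification for the merge -------------------------------

.boolean_prefixes <- c("pat:", "stat:chem_in", "stat:dis_in",
                       "stat:same_sentence", "stat:kb_", "stat:kw_",
                       "stat:dosage_", "stat:incdec_", "stat:pvalue_",
                       "stat:demo_")
.mean_prefixes <- c("path:weight", "stat:n_chem_mentions",
                    "stat:n_dis_mentions")
.bag_prefixes <- c("bow:", "bon", "path:vwalk:", "path:ewalk:")

#' @noRd
classify_feature <- function(name) {
  is_b <- any(startsWith(name, .boolean_prefixes))
  is_m <- any(startsWith(name, .mean_prefixes))
  is_g <- any(startsWith(name, .bag_prefixes))
  if (sum(is_b, is_m, is_g) > 1L) {
    stop_cid("feature '%s' classified as more than one merge type", name)
  }
  if (is_b) return("boolean")
  if (is_m) return("mean")
  if (is_g) return("bag")
  stop_cid("feature '%s' has no declared merge semantics", name)
}

#' Merge mention-level feature vectors into one pair vector
#'
#' Boolean features combine with OR (max), numeric singleton features are
#' averaged over the vectors in which they appear, bag features (BOW,
#' n-gram, walks) are summed. ID-level features are appended unchanged; a
#' feature name claimed by more than one merge class is a hard error.
#'
#' @param mention_vectors list of named numeric vectors, one per mention
#'   pair.
#' @param id_vector a named numeric vector of ID-level features.
#' @return the merged named numeric vector.
#' @export
merge_to_pair_vector <- function(mention_vectors, id_vector = empty_fv()) {
  all_names <- unique(unlist(lapply(mention_vectors, names)))
  out <- empty_fv()
  if (length(all_names)) {
    vals <- numeric(length(all_names))
    names(vals) <- all_names
    for (nm in all_names) {
      cls <- classify_feature(nm)
      xs <- unlist(lapply(mention_vectors, function(v) {
        if (nm %in% names(v)) v[[nm]] else NULL
      }))
      vals[[nm]] <- switch(cls,
        boolean = max(xs),
        mean = mean(xs),
        bag = sum(xs)
      )
    }
    out <- vals
  }
  if (length(id_vector)) {
    for (nm in names(id_vector)) classify_feature(nm)  # consistency check
    clash <- intersect(names(out), names(id_vector))
    if (length(clash)) {
      stop_cid("feature '%s' present at both mention and ID level", clash[1])
    }
    out <- c(out, id_vector)
  }
  out
}

# knowledge base -----------------------------------------------------------

#' Null knowledge base
#'
#' Returns FALSE for every query; use when no curated resource snapshot is
#' available.
#' @return an object of class \code{cid_kb}.
#' @export
kb_null <- function() {
  structure(list(
    has_ctd_relation = function(chem_id, dis_id) FALSE,
    comention_in_mesh_indexing = function(chem_id, dis_id) FALSE,
    snapshot_date = NA_character_
  ), class = "cid_kb")
}

#' Load a knowledge base from relation-pair TSV files
#'
#' Both files carry rows \code{chemical_id TAB disease_id}; the first holds
#' CTD-style curated relations, the second MeSH co-indexing pairs. Either
#' may be \code{NULL} (treated as empty).
#'
#' @param ctd_path,mesh_path file paths or NULL.
#' @param snapshot_date provenance string recorded on the object.
#' @return an object of class \code{cid_kb}.
#' @export
kb_load <- function(ctd_path = NULL, mesh_path = NULL,
                    snapshot_date = NA_character_) {
  read_pairs <- function(path) {
    if (is.null(path)) return(character(0))
    lines <- read_lines_utf8(path)
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(lines, "\t", fixed = TRUE)
    vapply(f, function(x) paste(x[1], x[2], sep = "\r"), "")
  }
  ctd <- read_pairs(ctd_path)
  mesh <- read_pairs(mesh_path)
  structure(list(
    has_ctd_relation = function(chem_id, dis_id) {
      paste(chem_id, dis_id, sep = "\r") %in% ctd
    },
    comention_in_mesh_indexing = function(chem_id, dis_id) {
      paste(chem_id, dis_id, sep = "\r") %in% mesh
    },
    snapshot_date = snapshot_date
  ), class = "cid_kb")
}
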