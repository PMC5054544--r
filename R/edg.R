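# Extended Dependency Graph (EDG).
#
# A per-sentence multigraph over tokens. Three edge layers:
#   syntactic    -- collapsed dependency edges straight from the parser
#   numbered_arg -- arg0 (agent) / arg1 (patient, theme) / arg2 edges derived
#                   by rule from the syntactic layer, unifying active,
#                   passive and nominalized realizations of a predicate
#   semantic     -- member-collection ("a number of X") and is-a
#                   ("Y such as X", "X, a Y") edges
# Argument propagation then carries argK edges through collections and
# non-entity core-term heads so that e.g. "a case of tardive dyskinesia
# caused by metoclopramide" yields arg1(cause, dyskinesia) even though the
# parser attaches the argument to "case".

#' EDG construction configuration
#'
#' Each numbered-argument rule is individually switchable so its
#' contribution can be audited. Numbered arguments are assigned only for
#' predicates whose lemma is in the trigger inventory (verbal
#' \code{predicate_lemmas}, nominal \code{nominal_predicate_lemmas});
#' set either to \code{NULL} to apply the rules to every predicate.
#'
#' @param rules named logical list of rule switches.
#' @param predicate_lemmas lemmas of verbal predicates that take numbered
#'   arguments (case-insensitive).
#' @param nominal_predicate_lemmas lemmas of nominal predicates.
#' @param quantifier_lemmas collection heads for member-collection edges.
#' @return a list of class \code{edg_config}.
#' @export
edg_config <- function(rules = list(
                         nsubj_arg0 = TRUE,
                         dobj_arg1 = TRUE,
                         nsubjpass_arg1 = TRUE,
                         agent_arg0 = TRUE,
                         premod_participle = TRUE,
                         nominal_of_arg1 = TRUE
                       ),
                       predicate_lemmas = c("cause", "induce", "associate",
                                            "produce"),
                       nominal_predicate_lemmas = c("cause", "induction",
                                                    "association",
                                                    "production"),
                       quantifier_lemmas = c("number", "variety", "series",
                                             "group", "range", "set")) {
  structure(list(rules = rules,
                 predicate_lemmas = predicate_lemmas,
                 nominal_predicate_lemmas = nominal_predicate_lemmas,
                 quantifier_lemmas = quantifier_lemmas),
            class = "edg_config")
}

#' @noRd
edg_edge_frame <- function(src = integer(0), tgt = integer(0),
                           label = character(0), layer = character(0),
                           provenance = character(0)) {
  data.frame(src = as.integer(src), tgt = as.integer(tgt),
             label = as.character(label), layer = as.character(layer),
             provenance = as.character(provenance), stringsAsFactors = FALSE)
}

#' Build the EDG of a parsed sentence
#'
#' Creates one vertex per token, copies the syntactic layer from the
#' attached dependency edges, folds in any \code{#edge} sidecar lines
#' (classified by label: \code{arg0/arg1/arg2} to the numbered-argument
#' layer, \code{member-collection}/\code{is-a} to the semantic layer,
#' anything else syntactic), and marks named-entity vertices from the
#' mentions overlapping the sentence. For a multi-token mention the
#' syntactic head token — the token in the span whose governor lies outside
#' the span (or is the root) — carries the entity label and anchors paths.
#'
#' @param sentence a parsed sentence (see [attach_parse()]).
#' @param mentions mention rows of the owning document (any rows outside
#'   the sentence are ignored).
#' @return an object of class \code{cid_edg} with \code{vertices} and
#'   \code{edges} data frames.
#' @export
build_edg <- function(sentence, mentions = mention_frame()) {
  if (is.null(sentence$tokens)) stop_cid("build_edg: sentence has no parse attached")
  tok <- sentence$tokens
  n <- nrow(tok)
  vertices <- data.frame(
    index = tok$index, start = tok$start, end = tok$end,
    text = tok$text, lemma = tok$lemma, pos = tok$pos,
    ne_type = NA_character_,
    stringsAsFactors = FALSE
  )
  vertices$ne_ids <- replicate(n, character(0), simplify = FALSE)

  edges <- edg_edge_frame()
  d <- sentence$deps
  if (!is.null(d) && nrow(d)) {
    edges <- rbind(edges, edg_edge_frame(d$head, d$dep, d$label,
                                         "syntactic", "parser"))
  }
  ee <- sentence$extra_edges
  if (!is.null(ee) && nrow(ee)) {
    layer <- ifelse(ee$label %in% c("arg0", "arg1", "arg2"), "numbered_arg",
                    ifelse(ee$label %in% c("member-collection", "is-a"),
                           "semantic", "syntactic"))
    prov <- ifelse(layer == "syntactic", "parser", "rule")
    edges <- rbind(edges, edg_edge_frame(ee$head, ee$dep, ee$label, layer, prov))
  }

  # primary governor of each token, for mention head finding
  head_of <- rep(-1L, n)
  if (!is.null(d) && nrow(d)) head_of[d$dep + 1L] <- d$head

  m <- mentions[mentions$start >= min(tok$start) & mentions$end <= max(tok$end), ,
                drop = FALSE]
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      span_tok <- which(tok$start < m$end[i] & tok$end > m$start[i])
      if (length(span_tok) == 0L) next
      span_idx <- tok$index[span_tok]
      is_head <- vapply(span_idx, function(ti) {
        g <- head_of[ti + 1L]
        g < 0L || !(g %in% span_idx)
      }, TRUE)
      h <- span_tok[which(is_head)[1] %||% 1L]
      if (is.na(h)) h <- span_tok[1]
      vertices$ne_type[h] <- m$type[i]
      vertices$ne_ids[[h]] <- union(vertices$ne_ids[[h]],
                                    setdiff(m$concept_ids[[i]], character(0)))
    }
  }

  structure(list(vertices = vertices, edges = edges,
                 sent_start = sentence$start, sent_end = sentence$end),
            class = "cid_edg")
}

#' @export
print.cid_edg <- function(x, ...) {
  cat(sprintf("<cid_edg: %d vertices, %d edges (%d syntactic, %d arg, %d semantic)>\n",
              nrow(x$vertices), nrow(x$edges),
              sum(x$edges$layer == "syntactic"),
              sum(x$edges$layer == "numbered_arg"),
              sum(x$edges$layer == "semantic")))
  invisible(x)
}

#' @noRd
edg_add_edges <- function(edg, src, tgt, label, layer, provenance) {
  if (length(src) == 0L) return(edg)
  new <- edg_edge_frame(src, tgt, label, layer, provenance)
  key_old <- paste(edg$edges$src, edg$edges$tgt, edg$edges$label)
  key_new <- paste(new$src, new$tgt, new$label)
  new <- new[!(key_new %in% key_old) & !duplicated(key_new), , drop = FALSE]
  edg$edges <- rbind(edg$edges, new)
  edg
}

# syntactic edges with a given label (or label set)
#' @noRd
syn_edges <- function(edg, labels) {
  e <- edg$edges
  e[e$layer == "syntactic" & e$label %in% labels, , drop = FALSE]
}

#' @noRd
lemma_of <- function(edg, idx) tolower(edg$vertices$lemma[match(idx, edg$vertices$index)])

#' @noRd
pos_of <- function(edg, idx) edg$vertices$pos[match(idx, edg$vertices$index)]

# vertices that head a passive construction (nsubjpass or auxpass incident)
#' @noRd
passive_heads <- function(edg) {
  e <- syn_edges(edg, c("nsubjpass", "nsubj:pass", "auxpass", "aux:pass"))
  unique(e$src)
}

#' Assign numbered-argument edges
#'
#' Derives \code{arg0} (agent) and \code{arg1} (patient/theme) edges from
#' the syntactic layer for trigger predicates, unifying active, passive and
#' nominalized realizations:
#' \itemize{
#'   \item active nominal subject (\code{nsubj}, \code{xsubj}) of a
#'     non-passive verbal predicate -> \code{arg0};
#'   \item direct object (\code{dobj}, \code{obj}) -> \code{arg1};
#'   \item passive subject (\code{nsubjpass}) -> \code{arg1};
#'   \item agent (\code{agent}, or \code{prep_by} on a passive predicate)
#'     -> \code{arg0};
#'   \item premodifying participle ("X-induced Y": participle with an
#'     \code{amod} attachment to the head noun and an incorporated modifier
#'     noun) -> modifier \code{arg0}, head noun \code{arg1};
#'   \item nominal trigger predicate: its \code{prep_of} complement ->
#'     \code{arg1}, its \code{prep_by} complement -> \code{arg0}.
#' }
#'
#' @param edg a [build_edg()] graph.
#' @param config an [edg_config()].
#' @return the graph with numbered-argument edges added (provenance
#'   \code{"rule"}).
#' @export
assign_numbered_args <- function(edg, config = edg_config()) {
  r <- config$rules
  is_pred <- function(idx) {
    if (is.null(config$predicate_lemmas)) return(rep(TRUE, length(idx)))
    lemma_of(edg, idx) %in% tolower(config$predicate_lemmas)
  }
  is_nom_pred <- function(idx) {
    if (is.null(config$nominal_predicate_lemmas)) return(rep(TRUE, length(idx)))
    lemma_of(edg, idx) %in% tolower(config$nominal_predicate_lemmas)
  }
  pas <- passive_heads(edg)

  if (isTRUE(r$nsubj_arg0)) {
    e <- syn_edges(edg, c("nsubj", "xsubj"))
    e <- e[is_pred(e$src) & !(e$src %in% pas), , drop = FALSE]
    edg <- edg_add_edges(edg, e$src, e$tgt, "arg0", "numbered_arg", "rule")
  }
  if (isTRUE(r$dobj_arg1)) {
    e <- syn_edges(edg, c("dobj", "obj"))
    e <- e[is_pred(e$src), , drop = FALSE]
    edg <- edg_add_edges(edg, e$src, e$tgt, "arg1", "numbered_arg", "rule")
  }
  if (isTRUE(r$nsubjpass_arg1)) {
    e <- syn_edges(edg, c("nsubjpass", "nsubj:pass"))
    e <- e[is_pred(e$src), , drop = FALSE]
    edg <- edg_add_edges(edg, e$src, e$tgt, "arg1", "numbered_arg", "rule")
  }
  if (isTRUE(r$agent_arg0)) {
    e1 <- syn_edges(edg, "agent")
    e2 <- syn_edges(edg, "prep_by")
    e2 <- e2[e2$src %in% pas, , drop = FALSE]
    e <- rbind(e1, e2)
    e <- e[is_pred(e$src), , drop = FALSE]
    edg <- edg_add_edges(edg, e$src, e$tgt, "arg0", "numbered_arg", "rule")
  }
  if (isTRUE(r$premod_participle)) {
    # "<modifier>-induced <head>": participle t with amod(head, t) and an
    # incorporated modifier noun attached to t
    am <- syn_edges(edg, "amod")
    am <- am[is_pred(am$tgt), , drop = FALSE]
    if (nrow(am)) {
      mod_e <- syn_edges(edg, c("npadvmod", "nn", "compound", "advmod", "dep"))
      for (i in seq_len(nrow(am))) {
        t <- am$tgt[i]; y <- am$src[i]
        xs <- mod_e$tgt[mod_e$src == t]
        if (length(xs)) {
          edg <- edg_add_edges(edg, rep(t, length(xs)), xs, "arg0",
                               "numbered_arg", "rule")
          edg <- edg_add_edges(edg, t, y, "arg1", "numbered_arg", "rule")
        }
      }
    }
  }
  if (isTRUE(r$nominal_of_arg1)) {
    po <- syn_edges(edg, "prep_of")
    po <- po[is_nom_pred(po$src) & startsWith(pos_of(edg, po$src), "NN"), ,
             drop = FALSE]
    edg <- edg_add_edges(edg, po$src, po$tgt, "arg1", "numbered_arg", "rule")
    pb <- syn_edges(edg, "prep_by")
    pb <- pb[is_nom_pred(pb$src) & startsWith(pos_of(edg, pb$src), "NN"), ,
             drop = FALSE]
    edg <- edg_add_edges(edg, pb$src, pb$tgt, "arg0", "numbered_arg", "rule")
  }
  edg
}

#' Add semantic edges
#'
#' Two constructions are recognized:
#' \itemize{
#'   \item member-collection: a quantifier head with a \code{prep_of}
#'     complement ("a number of inhibitors") yields
#'     \code{member-collection(quantifier, complement)};
#'   \item is-a: \code{prep_such_as(Y, X)} ("Y such as X") yields
#'     \code{is-a(X, Y)}; an apposition \code{appos(X, Y)} ("X, a Y")
#'     yields \code{is-a(X, Y)}. is-a edges are distributed over
#'     coordination: \code{is-a(x, g)} and \code{conj*(x, x2)} add
#'     \code{is-a(x2, g)}.
#' }
#'
#' @inheritParams assign_numbered_args
#' @return the graph with semantic edges added.
#' @export
add_semantic_edges <- function(edg, config = edg_config()) {
  po <- syn_edges(edg, "prep_of")
  po <- po[lemma_of(edg, po$src) %in% tolower(config$quantifier_lemmas), ,
           drop = FALSE]
  edg <- edg_add_edges(edg, po$src, po$tgt, "member-collection", "semantic",
                       "rule")

  sa <- syn_edges(edg, c("prep_such_as", "prep_like"))
  edg <- edg_add_edges(edg, sa$tgt, sa$src, "is-a", "semantic", "rule")
  ap <- syn_edges(edg, "appos")
  edg <- edg_add_edges(edg, ap$src, ap$tgt, "is-a", "semantic", "rule")

  # distribute is-a over coordination, to fixpoint
  conj <- edg$edges[edg$edges$layer == "syntactic" &
                      startsWith(edg$edges$label, "conj"), , drop = FALSE]
  if (nrow(conj)) {
    repeat {
      isa <- edg$edges[edg$edges$label == "is-a", , drop = FALSE]
      add_src <- integer(0); add_tgt <- integer(0)
      for (i in seq_len(nrow(isa))) {
        x2 <- unique(c(conj$tgt[conj$src == isa$src[i]],
                       conj$src[conj$tgt == isa$src[i]]))
        for (x in x2) {
          key <- paste(x, isa$tgt[i], "is-a")
          if (!key %in% paste(edg$edges$src, edg$edges$tgt, edg$edges$label)) {
            add_src <- c(add_src, x); add_tgt <- c(add_tgt, isa$tgt[i])
          }
        }
      }
      if (length(add_src) == 0L) break
      edg <- edg_add_edges(edg, add_src, add_tgt, "is-a", "semantic", "rule")
    }
  }
  edg
}

#' Propagate numbered arguments
#'
#' Applies two closure rules to a fixpoint, flagging every added edge with
#' provenance \code{"propagated"}:
#' \enumerate{
#'   \item collection rule: \code{argK(p, c)}, \code{member-collection(c, g)}
#'     and \code{is-a(x, g)} imply \code{argK(p, x)};
#'   \item core-term rule: \code{argK(p, h)} where \code{h} is not a named
#'     entity and not a collection quantifier, with an \code{of}-complement
#'     \code{x}, implies \code{argK(p, x)} (the generic head noun, e.g.
#'     "case" in "a case of tardive dyskinesia", is skipped).
#' }
#' Propagation is monotone (only adds edges) and idempotent. The iteration
#' cap equals the vertex count; exceeding it is a hard error.
#'
#' @inheritParams assign_numbered_args
#' @return the graph with propagated argument edges.
#' @export
propagate_args <- function(edg, config = edg_config()) {
  n_cap <- max(nrow(edg$vertices), 1L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > n_cap + 1L) stop_cid("propagate_args: iteration cap exceeded")
    before <- nrow(edg$edges)
    args <- edg$edges[edg$edges$layer == "numbered_arg", , drop = FALSE]
    mc <- edg$edges[edg$edges$label == "member-collection", , drop = FALSE]
    isa <- edg$edges[edg$edges$label == "is-a", , drop = FALSE]
    po <- syn_edges(edg, "prep_of")
    for (i in seq_len(nrow(args))) {
      p <- args$src[i]; cc <- args$tgt[i]; k <- args$label[i]
      # (1) collection rule
      gs <- mc$tgt[mc$src == cc]
      for (g in gs) {
        xs <- isa$src[isa$tgt == g]
        if (length(xs)) {
          edg <- edg_add_edges(edg, rep(p, length(xs)), xs, k,
                               "numbered_arg", "propagated")
        }
      }
      # (2) core-term rule
      v <- match(cc, edg$vertices$index)
      is_entity <- !is.na(edg$vertices$ne_type[v])
      is_quant <- any(mc$src == cc)
      if (!is_entity && !is_quant) {
        xs <- po$tgt[po$src == cc]
        if (length(xs)) {
          edg <- edg_add_edges(edg, rep(p, length(xs)), xs, k,
                               "numbered_arg", "propagated")
        }
      }
    }
    if (nrow(edg$edges) == before) break
  }
  edg
}

#' Build, decorate and propagate the EDG of every sentence in a document
#'
#' Convenience wrapper: [build_edg()], [assign_numbered_args()],
#' [add_semantic_edges()], [propagate_args()] per parsed sentence.
#'
#' @param doc a document with parsed sentences.
#' @param config an [edg_config()].
#' @return list of \code{cid_edg} (NULL for unparsed sentences), one per
#'   sentence.
#' @export
document_edgs <- function(doc, config = edg_config()) {
  lapply(doc$sentences, function(s) {
    if (is.null(s$tokens)) return(NULL)
    g <- build_edg(s, mentions_in_sentence(doc, s))
    g <- assign_numbered_args(g, config)
    g <- add_semantic_edges(g, config)
    propagate_args(g, config)
  })
}

#' All minimum-length simple paths between two vertices
#'
#' Edges are traversable in both directions for reachability, but every
#' step records whether it runs with (\code{+1}) or against (\code{-1}) the
#' edge's orientation, as the walk features encode edge direction. Parallel
#' edges with different labels give distinct paths. All layers are
#' searched.
#'
#' @param edg a \code{cid_edg}.
#' @param v_from,v_to vertex (token) indices.
#' @return a list of paths; each path is a list with \code{vertices}
#'   (integer vector of token indices), \code{edge_rows} (row indices into
#'   \code{edg$edges}) and \code{dirs} (+1/-1 per edge). Empty list when
#'   disconnected; a single zero-length path when \code{v_from == v_to}.
#' @export
edg_shortest_paths <- function(edg, v_from, v_to) {
  verts <- edg$vertices$index
  if (!(v_from %in% verts) || !(v_to %in% verts)) {
    stop_cid("edg_shortest_paths: vertex not in graph")
  }
  if (v_from == v_to) {
    return(list(list(vertices = v_from, edge_rows = integer(0),
                     dirs = integer(0))))
  }
  e <- edg$edges
  # vertex-level BFS distance from v_to
  adj <- split(c(seq_len(nrow(e)), seq_len(nrow(e))), c(e$src, e$tgt))
  neighbor <- function(v, row) if (e$src[row] == v) e$tgt[row] else e$src[row]
  dist <- rep(NA_integer_, max(verts) + 1L)
  dist[v_to + 1L] <- 0L
  frontier <- v_to
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (row in adj[[as.character(v)]] %||% integer(0)) {
        u <- neighbor(v, row)
        if (is.na(dist[u + 1L])) {
          dist[u + 1L] <- dist[v + 1L] + 1L
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.na(dist[v_from + 1L])) return(list())

  paths <- list()
  walk <- function(v, vert_acc, row_acc, dir_acc) {
    if (v == v_to) {
      paths[[length(paths) + 1L]] <<- list(vertices = vert_acc,
                                           edge_rows = row_acc,
                                           dirs = dir_acc)
      return()
    }
    for (row in adj[[as.character(v)]] %||% integer(0)) {
      u <- neighbor(v, row)
      if (!is.na(dist[u + 1L]) && dist[u + 1L] == dist[v + 1L] - 1L) {
        walk(u, c(vert_acc, u), c(row_acc, row),
             c(dir_acc, if (e$src[row] == v) 1L else -1L))
      }
    }
  }
  walk(v_from, v_from, integer(0), integer(0))
  paths
}

# Vertex indices carrying a given concept ID (of a given type) in an EDG.
#' @noRd
edg_entity_vertices <- function(edg, concept_id, type = NULL) {
  v <- edg$vertices
  hit <- vapply(seq_len(nrow(v)), function(i) {
    if (is.na(v$ne_type[i])) return(FALSE)
    if (!is.null(type) && v$ne_type[i] != type) return(FALSE)
    concept_id %in% v$ne_ids[[i]]
  }, TRUE)
  v$index[hit]
}
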