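# Independent oracles. These deliberately re-derive quantities by brute
# force (exhaustive enumeration, direct scans) and stay independent of the
# implementation paths they check.

# exhaustive DFS over all simple edge-level paths; returns the minimal ones
# as canonical signature strings "row:dir|row:dir|..."
oracle_min_paths <- function(edges, from, to) {
  if (from == to) return("")
  sigs <- character(0)
  best <- Inf
  dfs <- function(v, visited, rows, dirs) {
    if (v == to) {
      len <- length(rows)
      sig <- paste(sprintf("%d:%d", rows, dirs), collapse = "|")
      if (len < best) {
        best <<- len
        sigs <<- sig
      } else if (len == best) {
        sigs <<- c(sigs, sig)
      }
      return()
    }
    if (length(rows) >= best) return()
    for (r in seq_len(nrow(edges))) {
      if (edges$src[r] == v && !(edges$tgt[r] %in% visited)) {
        dfs(edges$tgt[r], c(visited, edges$tgt[r]), c(rows, r), c(dirs, 1L))
      } else if (edges$tgt[r] == v && !(edges$src[r] %in% visited)) {
        dfs(edges$src[r], c(visited, edges$src[r]), c(rows, r), c(dirs, -1L))
      }
    }
  }
  dfs(from, from, integer(0), integer(0))
  sort(unique(sigs))
}

# signatures of edg_shortest_paths output, same canonical form
path_signatures <- function(paths) {
  if (length(paths) == 0L) return(character(0))
  sort(unique(vapply(paths, function(p) {
    paste(sprintf("%d:%d", p$edge_rows, p$dirs), collapse = "|")
  }, "")))
}

# a random small multigraph wrapped as a cid_edg
random_edg <- function(n_vertices, n_edges) {
  vertices <- data.frame(
    index = seq_len(n_vertices) - 1L,
    start = 0L, end = 1L,
    text = paste0("w", seq_len(n_vertices)),
    lemma = paste0("w", seq_len(n_vertices)),
    pos = "NN", ne_type = NA_character_,
    stringsAsFactors = FALSE
  )
  vertices$ne_ids <- replicate(n_vertices, character(0), simplify = FALSE)
  src <- integer(0); tgt <- integer(0)
  while (length(src) < n_edges) {
    a <- sample.int(n_vertices, 1L) - 1L
    b <- sample.int(n_vertices, 1L) - 1L
    if (a != b) { src <- c(src, a); tgt <- c(tgt, b) }
  }
  edges <- data.frame(
    src = src, tgt = tgt,
    label = sample(c("dep", "arg0", "arg1", "prep_of"), length(src),
                   replace = TRUE),
    layer = rep("syntactic", length(src)),
    provenance = rep("parser", length(src)),
    stringsAsFactors = FALSE
  )
  structure(list(vertices = vertices, edges = edges,
                 sent_start = 0L, sent_end = 1L), class = "cid_edg")
}

# brute-force BOW oracle: direct scan over sentences and token positions
oracle_bow <- function(doc, concept_id, radius = 2L) {
  bag <- character(0)
  for (s in doc$sentences) {
    if (is.null(s$tokens)) next
    tokens <- s$tokens
    m <- doc$mentions
    for (i in seq_len(nrow(m))) {
      if (!(concept_id %in% m$concept_ids[[i]])) next
      if (m$start[i] < s$start || m$end[i] > s$end) next
      span <- which(tokens$start < m$end[i] & tokens$end > m$start[i])
      if (length(span) == 0L) next
      for (j in seq_len(nrow(tokens))) {
        if (j %in% span) next
        d_left <- min(span) - j
        d_right <- j - max(span)
        if ((d_left >= 1 && d_left <= radius) ||
            (d_right >= 1 && d_right <= radius)) {
          bag <- c(bag, tolower(tokens$lemma[j]))
        }
      }
    }
  }
  tab <- table(bag)
  out <- as.numeric(tab)
  names(out) <- paste0("bow:", names(tab))
  out[order(names(out))]
}

# documents -> parsed documents, generator output in one step
prep_corpus <- function(corpus) {
  lapply(corpus$documents, function(d) {
    attach_parses(split_sentences(d), corpus$parses)
  })
}

corpus_instances_all <- function(docs, labeled = TRUE, weak = FALSE) {
  unlist(lapply(docs, function(d) {
    build_instances(d, labeled = labeled, weak = weak)
  }), recursive = FALSE)
}
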