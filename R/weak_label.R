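# Distant supervision: turning a curated document-level relation table plus
# raw abstracts into a weakly labeled training corpus.

#' Dictionary-based entity matching
#'
#' Case-insensitive longest-match scan over token boundaries of the
#' document text. At each token position the longest dictionary name
#' starting there wins and the scan resumes after it, so nested shorter
#' names ("hemolysis" inside "acute hemolysis") are suppressed. Ambiguous
#' names mapping to several concept IDs emit one composite mention carrying
#' all IDs.
#'
#' @param doc a [cid_document] (mentions not required).
#' @param dict a [load_dictionary()] dictionary.
#' @return a mention data frame ([mention_frame()]).
#' @export
dictionary_match <- function(doc, dict) {
  txt <- doc_text(doc)
  toks <- simple_tokens(txt)
  n <- nrow(toks)
  if (n == 0L || length(dict$index) == 0L) return(mention_frame())
  max_len <- max(vapply(strsplit(names(dict$index), " ", fixed = TRUE),
                        length, 1L))
  starts <- integer(0); ends <- integer(0); texts <- character(0)
  types <- character(0); cids <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      j <- i + len - 1L
      key <- tolower(paste(toks$text[i:j], collapse = " "))
      ids <- dict$index[[key]]
      if (!is.null(ids)) {
        type <- dict$concepts[[ids[1]]]$type
        starts <- c(starts, toks$start[i])
        ends <- c(ends, toks$end[j])
        texts <- c(texts, substring(txt, toks$start[i] + 1L, toks$end[j]))
        types <- c(types, type)
        cids <- c(cids, list(ids))
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  mention_frame(starts, ends, texts, types, cids)
}

# whitespace/punctuation tokenization with 0-based half-open offsets;
# inner punctuation is kept ("3.0", "mEq/L") but trailing sentence
# punctuation is trimmed off the token
#' @noRd
simple_tokens <- function(txt) {
  m <- gregexpr("[[:alnum:]][[:alnum:].'/-]*", txt)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  text <- substring(txt, starts + 1L, ends)
  trimmed <- sub("[.'/-]+$", "", text)
  keep <- nzchar(trimmed)
  ends <- ends - (nchar(text) - nchar(trimmed))
  data.frame(start = starts[keep], end = ends[keep],
             text = trimmed[keep],
             stringsAsFactors = FALSE)
}

#' Merge tagger and dictionary mentions
#'
#' Union of two offset-anchored mention lists over the same document.
#' Exact-duplicate spans are deduplicated preferring the tagger's concept
#' IDs; overlapping conflicting spans keep the longer mention (ties go to
#' the tagger).
#'
#' @param tagger_mentions,dictionary_mentions mention frames.
#' @return a merged mention frame sorted by start offset.
#' @export
merge_mentions <- function(tagger_mentions, dictionary_mentions) {
  tm <- tagger_mentions; dm <- dictionary_mentions
  if (nrow(tm) == 0L) return(dm[order(dm$start, dm$end), , drop = FALSE])
  if (nrow(dm) == 0L) return(tm[order(tm$start, tm$end), , drop = FALSE])
  keep_d <- rep(TRUE, nrow(dm))
  for (k in seq_len(nrow(dm))) {
    ov <- which(tm$start < dm$end[k] & tm$end > dm$start[k])
    for (o in ov) {
      if (tm$start[o] == dm$start[k] && tm$end[o] == dm$end[k]) {
        keep_d[k] <- FALSE  # exact duplicate: tagger wins
      } else {
        len_t <- tm$end[o] - tm$start[o]
        len_d <- dm$end[k] - dm$start[k]
        if (len_d <= len_t) keep_d[k] <- FALSE else {
          # dictionary span longer: drop the tagger mention
          tm <- tm[-o, , drop = FALSE]
          return(merge_mentions(tm, dm[keep_d, , drop = FALSE]))
        }
      }
    }
  }
  out <- rbind(tm, dm[keep_d, , drop = FALSE])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a curated relation table
#'
#' TSV rows \code{doc_id TAB chemical_id TAB disease_id}; duplicate rows
#' collapse.
#'
#' @param stream file path or connection.
#' @return a data frame with those three columns.
#' @export
read_relation_table <- function(stream) {
  lines <- read_lines_utf8(stream)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, 1L) < 3L
  if (any(bad)) stop_cid("malformed relation table row: '%s'", lines[bad][1])
  out <- unique(data.frame(doc_id = vapply(f, `[`, "", 1L),
                           chemical_id = vapply(f, `[`, "", 2L),
                           disease_id = vapply(f, `[`, "", 3L),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Build a weakly labeled corpus from a curated relation table
#'
#' For every document: keep the curated relations whose chemical ID and
#' disease ID both appear among the document's mentions (relations asserted
#' only in the full text thus drop out), make the retained relations the
#' document's positive labels (every other candidate pair is an implicit
#' negative), and drop documents that retain zero relations or appear in
#' the exclusion list (the gold-corpus document IDs, so weak and gold data
#' never overlap). Table rows referencing absent documents are skipped with
#' a warning.
#'
#' @param table a [read_relation_table()] data frame.
#' @param documents list of documents carrying mentions (e.g. from
#'   [dictionary_match()] / [merge_mentions()]).
#' @param exclude_doc_ids character vector of document IDs to drop.
#' @return list of documents with relations set.
#' @export
build_weak_corpus <- function(table, documents, exclude_doc_ids = character(0)) {
  by_id <- stats::setNames(documents,
                           vapply(documents, function(d) d$doc_id, ""))
  missing <- setdiff(unique(table$doc_id), names(by_id))
  if (length(missing)) {
    warn_cid("relation table references %d absent document(s): %s",
             length(missing), paste(utils::head(missing, 3), collapse = ", "))
  }
  out <- list()
  for (di in setdiff(unique(table$doc_id), missing)) {
    if (di %in% exclude_doc_ids) next
    doc <- by_id[[di]]
    chem_ids <- doc_concept_ids(doc, "chemical")
    dis_ids <- doc_concept_ids(doc, "disease")
    rows <- table[table$doc_id == di, , drop = FALSE]
    keep <- rows$chemical_id %in% chem_ids & rows$disease_id %in% dis_ids
    if (!any(keep)) next
    doc$relations <- canonical_relations(
      relation_frame(rows$chemical_id[keep], rows$disease_id[keep])
    )
    out[[length(out) + 1L]] <- doc
  }
  out
}
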