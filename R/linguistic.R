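# Sentence splitting and the pluggable parse-adapter layer.
#
# Live parsing is deliberately behind an adapter contract: any tokenizer /
# dependency parser that can produce the sidecar records below can drive the
# feature extractor. The package ships a deterministic fixture parser
# (read_parse_sidecar + attach_parse) so the whole pipeline runs without an
# external parser; dependency labels are treated as opaque strings downstream.

# Abbreviations that do not end a sentence even before a capital.
.abbrev_stoplist <- c(
  "e.g", "i.e", "vs", "cf", "al", "etc", "dr", "mr", "mrs", "ms", "prof",
  "fig", "figs", "no", "st", "ca", "approx"
)

#' Split a document into sentences
#'
#' The title is always a single sentence. The abstract is split after
#' sentence-final punctuation (\code{. ! ?}) followed by whitespace and a
#' capital letter, with an abbreviation stop-list. Any candidate boundary
#' that would cut an entity mention in two is repaired by merging the two
#' sentences, so after splitting no mention straddles a sentence boundary.
#'
#' @param doc a [cid_document].
#' @return the document with \code{$sentences} filled: each sentence is a
#'   list with \code{start}, \code{end} (document offsets, 0-based
#'   half-open), \code{text}, and empty parse slots.
#' @export
split_sentences <- function(doc) {
  spans <- list(c(0L, nchar(doc$title)))
  if (nzchar(doc$abstract)) {
    off <- nchar(doc$title) + 1L
    for (sp in split_text_spans(doc$abstract)) {
      spans[[length(spans) + 1L]] <- sp + off
    }
  }
  spans <- repair_straddles(spans, doc$mentions)
  txt <- doc_text(doc)
  doc$sentences <- lapply(spans, function(sp) {
    list(start = sp[1], end = sp[2],
         text = substring(txt, sp[1] + 1L, sp[2]),
         tokens = NULL, deps = NULL, extra_edges = NULL)
  })
  doc
}

# Candidate sentence spans (0-based half-open) within one text field.
#' @noRd
split_text_spans <- function(text) {
  n <- nchar(text)
  if (n == 0L) return(list())
  m <- gregexpr("[.!?]+(?=\\s+[A-Z])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      # word immediately before the punctuation run
      head_txt <- substring(text, 1L, starts[k] - 1L)
      word <- sub("^.*?([[:alnum:].]*)$", "\\1", head_txt)
      word <- sub("\\.+$", "", word)
      if (tolower(word) %in% .abbrev_stoplist) next
      cuts <- c(cuts, starts[k] + lens[k] - 1L)  # ends after this char (1-based)
    }
  }
  spans <- list()
  begin <- 1L
  for (cut in cuts) {
    spans[[length(spans) + 1L]] <- c(begin - 1L, cut)  # to 0-based half-open
    begin <- cut + 1L
    while (begin <= n && substring(text, begin, begin) == " ") begin <- begin + 1L
  }
  if (begin <= n) spans[[length(spans) + 1L]] <- c(begin - 1L, n)
  spans
}

# Merge adjacent spans when a mention crosses their boundary.
#' @noRd
repair_straddles <- function(spans, mentions) {
  if (nrow(mentions) == 0L || length(spans) < 2L) return(spans)
  repeat {
    merged <- FALSE
    for (i in seq_len(length(spans) - 1L)) {
      b <- spans[[i]][2]
      straddle <- any(mentions$start < b & mentions$end > b)
      if (straddle) {
        spans[[i]] <- c(spans[[i]][1], spans[[i + 1L]][2])
        spans[[i + 1L]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  spans
}

#' Read a parse sidecar file
#'
#' The sidecar format carries one record per sentence: a header line
#' \code{#sent <doc_id> <sent_index>}, then one line per token
#' \code{index TAB text TAB lemma TAB pos TAB head_index TAB dep_label}
#' (the root token has head index \code{-1} and label \code{"root"}), and
#' optional \code{#edge <label> <head_index> <dep_index>} lines carrying
#' extra syntactic, numbered-argument or semantic edges so gold graphs can
#' be expressed in fixtures.
#'
#' @param stream file path or connection.
#' @return a named list: \code{records[[doc_id]][[sent_index + 1]]} is a
#'   parse record (list with \code{tokens}, \code{extra_edges}).
#' @export
read_parse_sidecar <- function(stream) {
  lines <- read_lines_utf8(stream)
  records <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    rec <- finish_parse_record(cur)
    di <- rec$doc_id
    if (is.null(records[[di]])) records[[di]] <<- list()
    records[[di]][[rec$sent_index + 1L]] <<- rec
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#sent")) {
      flush()
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(doc_id = f[2], sent_index = as.integer(f[3]),
                  tok_lines = character(0), edge_lines = character(0))
    } else if (startsWith(ln, "#edge")) {
      cur$edge_lines <- c(cur$edge_lines, ln)
    } else {
      cur$tok_lines <- c(cur$tok_lines, ln)
    }
  }
  flush()
  records
}

#' @noRd
finish_parse_record <- function(cur) {
  tk <- lapply(cur$tok_lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  bad <- vapply(tk, length, 1L) != 6L
  if (any(bad)) stop_cid("malformed sidecar token line: '%s'", cur$tok_lines[bad][1])
  tokens <- data.frame(
    index = as.integer(vapply(tk, `[`, "", 1L)),
    text = vapply(tk, `[`, "", 2L),
    lemma = vapply(tk, `[`, "", 3L),
    pos = vapply(tk, `[`, "", 4L),
    head = as.integer(vapply(tk, `[`, "", 5L)),
    label = vapply(tk, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  tokens <- tokens[order(tokens$index), , drop = FALSE]
  ed <- lapply(cur$edge_lines, function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  extra <- data.frame(
    label = vapply(ed, `[`, "", 2L) %||% character(0),
    head = as.integer(vapply(ed, `[`, "", 3L)),
    dep = as.integer(vapply(ed, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (length(ed) == 0L) {
    extra <- data.frame(label = character(0), head = integer(0),
                        dep = integer(0), stringsAsFactors = FALSE)
  }
  list(doc_id = cur$doc_id, sent_index = cur$sent_index,
       tokens = tokens, extra_edges = extra)
}

#' Write parse records to a sidecar file
#'
#' Inverse of [read_parse_sidecar()]; re-reading the output is a fixpoint.
#'
#' @param records nested record list as returned by [read_parse_sidecar()].
#' @param stream file path or connection.
#' @export
write_parse_sidecar <- function(records, stream) {
  out <- character(0)
  for (di in names(records)) {
    for (rec in records[[di]]) {
      if (is.null(rec)) next
      out <- c(out, sprintf("#sent %s %d", rec$doc_id, rec$sent_index))
      tk <- rec$tokens
      out <- c(out, sprintf("%d\t%s\t%s\t%s\t%d\t%s",
                            tk$index, tk$text, tk$lemma, tk$pos, tk$head,
                            tk$label))
      ee <- rec$extra_edges
      if (nrow(ee)) {
        out <- c(out, sprintf("#edge %s %d %d", ee$label, ee$head, ee$dep))
      }
    }
  }
  write_lines_utf8(out, stream)
  invisible(NULL)
}

#' Attach a parse record to a sentence
#'
#' Tokens are aligned to the sentence text left to right; the gap between
#' consecutive tokens may contain only whitespace and punctuation (so a
#' tokenizer that drops punctuation still aligns). Misalignment is a hard
#' error naming the offending token. Dependency edges are derived from the
#' per-token head/label columns; \code{#edge} lines are kept separately and
#' folded into the graph by [build_edg()].
#'
#' @param sentence a sentence list from [split_sentences()].
#' @param parse_record a record from [read_parse_sidecar()].
#' @return the sentence with \code{tokens}, \code{deps} and
#'   \code{extra_edges} attached; token offsets are document offsets.
#' @export
attach_parse <- function(sentence, parse_record) {
  tk <- parse_record$tokens
  txt <- sentence$text
  cursor <- 1L  # 1-based within sentence text
  starts <- integer(nrow(tk)); ends <- integer(nrow(tk))
  for (i in seq_len(nrow(tk))) {
    hit <- regexpr(tk$text[i], substring(txt, cursor), fixed = TRUE)
    if (hit == -1L) {
      stop_cid("parse/text misalignment: token '%s' (index %d) not found in '%s'",
               tk$text[i], tk$index[i], txt)
    }
    at <- cursor + as.integer(hit) - 1L
    gap <- substring(txt, cursor, at - 1L)
    if (!grepl("^[[:space:][:punct:]]*$", gap)) {
      stop_cid("parse/text misalignment: unexpected text '%s' before token '%s'",
               gap, tk$text[i])
    }
    starts[i] <- at - 1L
    ends[i] <- starts[i] + nchar(tk$text[i])
    cursor <- ends[i] + 1L
  }
  tokens <- data.frame(
    index = tk$index,
    start = starts + sentence$start,
    end = ends + sentence$start,
    text = tk$text, lemma = tk$lemma, pos = tk$pos,
    stringsAsFactors = FALSE
  )
  keep <- tk$head >= 0L
  deps <- data.frame(head = tk$head[keep], dep = tk$index[keep],
                     label = tk$label[keep], stringsAsFactors = FALSE)
  if (any(deps$head == deps$dep)) stop_cid("dependency self-loop in parse record")
  n <- nrow(tokens)
  if (nrow(deps) && (any(deps$head >= n) || any(deps$dep >= n))) {
    stop_cid("dependency edge references token index out of range")
  }
  sentence$tokens <- tokens
  sentence$deps <- deps
  sentence$extra_edges <- parse_record$extra_edges
  sentence
}

#' Attach sidecar parses to every sentence of a document
#'
#' @param doc a document with sentences (see [split_sentences()]).
#' @param records sidecar records from [read_parse_sidecar()].
#' @return the document with parsed sentences; sentences without a record
#'   are left unparsed.
#' @export
attach_parses <- function(doc, records) {
  recs <- records[[doc$doc_id]]
  if (is.null(recs)) return(doc)
  for (i in seq_along(doc$sentences)) {
    if (i <= length(recs) && !is.null(recs[[i]])) {
      doc$sentences[[i]] <- attach_parse(doc$sentences[[i]], recs[[i]])
    }
  }
  doc
}

# Mention rows overlapping a sentence span.
#' @noRd
mentions_in_sentence <- function(doc, sentence) {
  m <- doc$mentions
  m[m$start >= sentence$start & m$end <= sentence$end, , drop = FALSE]
}
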