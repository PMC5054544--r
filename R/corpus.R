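#' Construct a document
#'
#' The document is the unit of classification: a PMID-like identifier, a
#' title, an abstract, offset-anchored entity mentions and a set of
#' document-level \code{<chemical ID, disease ID>} relations. Offsets are
#' 0-based half-open character positions into \code{title + " " + abstract}
#' (the PubTator convention: abstract offsets start at \code{nchar(title) + 1}).
#'
#' @param doc_id document identifier (PMID-like string).
#' @param title,abstract document text fields.
#' @param mentions a mention data frame as built by [mention_frame()].
#' @param relations a data frame with columns \code{chemical_id},
#'   \code{disease_id}; duplicates collapse.
#' @return an object of class \code{cid_document}.
#' @seealso [read_pubtator()], [split_sentences()]
#' @export
cid_document <- function(doc_id, title, abstract = "",
                         mentions = mention_frame(),
                         relations = relation_frame()) {
  doc <- structure(
    list(
      doc_id = as.character(doc_id),
      title = title,
      abstract = abstract,
      mentions = mentions,
      relations = canonical_relations(relations),
      sentences = list()
    ),
    class = "cid_document"
  )
  validate_document(doc)
  doc
}

#' @export
print.cid_document <- function(x, ...) {
  cat(sprintf(
    "<cid_document %s: %d mention(s), %d relation(s), %d sentence(s)>\n",
    x$doc_id, nrow(x$mentions), nrow(x$relations), length(x$sentences)
  ))
  invisible(x)
}

#' Full text of a document
#'
#' Title and abstract joined by a single space, the string all mention
#' offsets index into.
#' @param doc a \code{cid_document}.
#' @return a string.
#' @export
doc_text <- function(doc) {
  if (nzchar(doc$abstract)) paste(doc$title, doc$abstract) else doc$title
}

#' Empty mention frame
#'
#' Mentions are kept in a data frame with one row per mention:
#' \code{start}/\code{end} (0-based half-open offsets), \code{text},
#' \code{type} (\code{"chemical"} or \code{"disease"}) and a list-column
#' \code{concept_ids} holding one or more concept identifiers. Composite
#' annotations (IDs joined by \code{|} in PubTator) keep all their IDs; the
#' sentinel ID \code{"-1"} marks a mention that failed normalization and is
#' excluded from candidate-pair generation.
#'
#' @param start,end integer offsets.
#' @param text,type character vectors.
#' @param concept_ids list of character vectors (one per mention).
#' @return a data frame of class \code{data.frame}.
#' @export
mention_frame <- function(start = integer(0), end = integer(0),
                          text = character(0), type = character(0),
                          concept_ids = list()) {
  stopifnot(length(start) == length(end), length(start) == length(text),
            length(start) == length(type), length(start) == length(concept_ids))
  data.frame(
    start = as.integer(start), end = as.integer(end),
    text = as.character(text), type = as.character(type),
    concept_ids = I(concept_ids),
    stringsAsFactors = FALSE
  )
}

#' @rdname mention_frame
#' @param chemical_id,disease_id concept-ID character vectors.
#' @export
relation_frame <- function(chemical_id = character(0),
                           disease_id = character(0)) {
  data.frame(chemical_id = as.character(chemical_id),
             disease_id = as.character(disease_id),
             stringsAsFactors = FALSE)
}

# Deduplicate and sort relations lexicographically (chemical, then disease).
#' @noRd
canonical_relations <- function(relations) {
  if (nrow(relations) == 0L) return(relation_frame())
  relations <- unique(relations[, c("chemical_id", "disease_id")])
  relations <- relations[order(relations$chemical_id, relations$disease_id), ,
                         drop = FALSE]
  rownames(relations) <- NULL
  relations
}

#' @noRd
validate_document <- function(doc) {
  txt <- doc_text(doc)
  m <- doc$mentions
  if (nrow(m)) {
    if (any(m$end <= m$start)) {
      stop_cid("document %s: mention with end <= start", doc$doc_id)
    }
    if (any(m$end > nchar(txt))) {
      stop_cid("document %s: mention span outside document text", doc$doc_id)
    }
    sub <- substring(txt, m$start + 1L, m$end)
    bad <- which(sub != m$text)
    if (length(bad)) {
      stop_cid("document %s: mention text %s does not match span [%d,%d) ('%s')",
               doc$doc_id, dQuote(m$text[bad[1]]), m$start[bad[1]],
               m$end[bad[1]], sub[bad[1]])
    }
    if (!all(m$type %in% c("chemical", "disease"))) {
      stop_cid("document %s: mention type must be 'chemical' or 'disease'",
               doc$doc_id)
    }
    if (any(vapply(m$concept_ids, length, 1L) == 0L)) {
      stop_cid("document %s: mention with empty concept-ID list", doc$doc_id)
    }
  }
  invisible(doc)
}

#' Concept IDs of a document's mentions, by entity type
#'
#' Unnormalizable mentions (sentinel ID \code{"-1"}) are dropped.
#' @param doc a \code{cid_document}.
#' @param type \code{"chemical"} or \code{"disease"}.
#' @return character vector of unique concept IDs.
#' @export
doc_concept_ids <- function(doc, type) {
  m <- doc$mentions[doc$mentions$type == type, , drop = FALSE]
  ids <- unique(unlist(m$concept_ids))
  setdiff(ids, "-1")
}

#' Read a PubTator-format corpus
#'
#' Parses blank-line-separated document blocks of the BioCreative V CDR
#' dialect: \code{id|t|title} and \code{id|a|abstract} header lines, then
#' tab-separated mention lines
#' \code{id start end text type conceptID} and relation lines
#' \code{id CID chemicalID diseaseID}.
#'
#' Composite concept IDs (\code{"D001|D002"}) are kept as multi-ID mentions.
#' An empty or missing concept-ID field becomes the sentinel \code{"-1"}.
#' A mention whose text does not match its span is a hard error naming the
#' document and line; a relation line whose tag is not \code{CID} is skipped
#' with a warning.
#'
#' @param stream a file path or connection (UTF-8).
#' @return a list of [cid_document] objects.
#' @export
read_pubtator <- function(stream) {
  lines <- read_lines_utf8(stream)
  docs <- list()
  block <- character(0)
  flush_block <- function(block) {
    if (length(block)) docs[[length(docs) + 1L]] <<- parse_pubtator_block(block)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      flush_block(block)
      block <- character(0)
    } else {
      block <- c(block, ln)
    }
  }
  flush_block(block)
  docs
}

#' @noRd
parse_pubtator_block <- function(block) {
  title <- NULL; abstract <- ""; doc_id <- NULL
  starts <- integer(0); ends <- integer(0); texts <- character(0)
  types <- character(0); cids <- list()
  chem <- character(0); dis <- character(0)
  for (ln in block) {
    ht <- regmatches(ln, regexec("^([^|\t]+)\\|t\\|(.*)$", ln))[[1]]
    ha <- regmatches(ln, regexec("^([^|\t]+)\\|a\\|(.*)$", ln))[[1]]
    if (length(ht) == 3L) {
      doc_id <- ht[2]; title <- ht[3]
      next
    }
    if (length(ha) == 3L) {
      doc_id <- doc_id %||% ha[2]; abstract <- ha[3]
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 4L) {
      if (fields[2] != "CID") {
        warn_cid("document %s: unknown relation tag '%s', line skipped",
                 fields[1], fields[2])
        next
      }
      chem <- c(chem, fields[3]); dis <- c(dis, fields[4])
    } else if (length(fields) >= 5L) {
      id_field <- if (length(fields) >= 6L) fields[6] else ""
      ids <- strsplit(id_field, "|", fixed = TRUE)[[1]]
      ids <- ids[nzchar(ids)]
      if (length(ids) == 0L) ids <- "-1"
      starts <- c(starts, as.integer(fields[2]))
      ends <- c(ends, as.integer(fields[3]))
      texts <- c(texts, fields[4])
      types <- c(types, tolower(fields[5]))
      cids <- c(cids, list(ids))
    } else {
      stop_cid("unparseable PubTator line: '%s'", ln)
    }
  }
  if (is.null(doc_id) || is.null(title)) {
    stop_cid("PubTator block without a title line: '%s'", block[1])
  }
  cid_document(doc_id, title, abstract,
               mentions = mention_frame(starts, ends, texts, types, cids),
               relations = relation_frame(chem, dis))
}

#' Write documents in PubTator format
#'
#' Canonical serialization: mentions sorted by start offset (then end),
#' relations sorted lexicographically, entity types capitalized, composite
#' concept IDs joined by \code{|}. \code{write_pubtator(read_pubtator(f))}
#' reproduces a canonical file byte-for-byte.
#'
#' @param docs list of [cid_document] objects.
#' @param stream file path or connection.
#' @export
write_pubtator <- function(docs, stream) {
  out <- character(0)
  for (doc in docs) {
    validate_document(doc)
    out <- c(out, sprintf("%s|t|%s", doc$doc_id, doc$title))
    out <- c(out, sprintf("%s|a|%s", doc$doc_id, doc$abstract))
    m <- doc$mentions
    if (nrow(m)) {
      m <- m[order(m$start, m$end), , drop = FALSE]
      type_out <- ifelse(m$type == "chemical", "Chemical", "Disease")
      ids_out <- vapply(m$concept_ids, paste, "", collapse = "|")
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                            doc$doc_id, m$start, m$end, m$text, type_out,
                            ids_out))
    }
    r <- canonical_relations(doc$relations)
    if (nrow(r)) {
      out <- c(out, sprintf("%s\tCID\t%s\t%s",
                            doc$doc_id, r$chemical_id, r$disease_id))
    }
    out <- c(out, "")
  }
  write_lines_utf8(out, stream)
  invisible(NULL)
}

#' Load a concept dictionary
#'
#' Reads a MeSH-style controlled vocabulary from tab-separated rows
#' \code{conceptID TAB type TAB name1|name2|...}. All synonyms are indexed
#' lowercase; lookup is case-insensitive. A concept ID appearing twice with
#' conflicting entity types is a hard error (synonym lists merge otherwise).
#'
#' @param stream file path or connection.
#' @return an object of class \code{cid_dictionary} with elements
#'   \code{concepts} (ID -> list(type, names)) and \code{index}
#'   (lowercase name -> character vector of IDs).
#' @export
load_dictionary <- function(stream) {
  lines <- read_lines_utf8(stream)
  lines <- lines[nzchar(trimws(lines))]
  concepts <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_cid("malformed dictionary row: '%s'", ln)
    id <- f[1]; type <- tolower(f[2])
    names_ <- strsplit(f[3], "|", fixed = TRUE)[[1]]
    names_ <- names_[nzchar(names_)]
    if (length(names_) == 0L) stop_cid("dictionary row for %s has no names", id)
    if (!type %in% c("chemical", "disease")) {
      stop_cid("dictionary row for %s: unknown type '%s'", id, f[2])
    }
    if (!is.null(concepts[[id]])) {
      if (concepts[[id]]$type != type) {
        stop_cid("dictionary: concept %s declared both '%s' and '%s'",
                 id, concepts[[id]]$type, type)
      }
      names_ <- union(concepts[[id]]$names, names_)
    }
    concepts[[id]] <- list(type = type, names = names_)
  }
  index <- list()
  for (id in names(concepts)) {
    for (nm in tolower(concepts[[id]]$names)) {
      index[[nm]] <- union(index[[nm]] %||% character(0), id)
    }
  }
  structure(list(concepts = concepts, index = index), class = "cid_dictionary")
}

#' @export
print.cid_dictionary <- function(x, ...) {
  cat(sprintf("<cid_dictionary: %d concept(s), %d indexed name(s)>\n",
              length(x$concepts), length(x$index)))
  invisible(x)
}

#' Case-insensitive dictionary lookup
#'
#' @param dict a \code{cid_dictionary}.
#' @param name surface string.
#' @return character vector of concept IDs (empty on a miss).
#' @export
dict_lookup <- function(dict, name) {
  dict$index[[tolower(name)]] %||% character(0)
}
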