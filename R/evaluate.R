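# Micro-averaged precision / recall / F1 over normalized concept pairs.

#' Precision/recall/F1 record
#'
#' Conventions: precision = tp/(tp+fp) and recall = tp/(tp+fn), reported as
#' 0 (with \code{undefined = TRUE}) when the denominator is 0; F1 is the
#' harmonic mean, 0 when P + R = 0.
#'
#' @param tp,fp,fn counts.
#' @return a list of class \code{cid_prf}.
#' @export
prf <- function(tp, fp, fn) {
  undefined <- FALSE
  p <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- TRUE; 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- TRUE; 0 }
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f1 = f, undefined = undefined),
            class = "cid_prf")
}

#' @export
print.cid_prf <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (tp %d, fp %d, fn %d)%s\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn,
              if (x$undefined) "  [degenerate denominator]" else ""))
  invisible(x)
}

# normalize a per-doc prediction map to unique pair keys
#' @noRd
pair_keys <- function(rel) {
  if (is.null(rel) || nrow(rel) == 0L) return(character(0))
  unique(paste(rel$chemical_id, rel$disease_id, sep = "\r"))
}

#' Document-level pair precision/recall/F1
#'
#' Micro-averaged counts over documents; pairs match by exact
#' \code{(chemical_id, disease_id)} equality. A predicted document absent
#' from the gold map is a corpus mismatch and a hard error. Gold documents
#' without predictions contribute their pairs as false negatives.
#'
#' @param gold_by_doc,pred_by_doc named lists (doc_id -> relation frame).
#' @return a [prf()] record.
#' @export
pair_prf <- function(gold_by_doc, pred_by_doc) {
  extra <- setdiff(names(pred_by_doc), names(gold_by_doc))
  if (length(extra)) {
    stop_cid("predictions for document(s) absent from gold: %s",
             paste(utils::head(extra, 3), collapse = ", "))
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (di in names(gold_by_doc)) {
    g <- pair_keys(gold_by_doc[[di]])
    p <- pair_keys(pred_by_doc[[di]])
    tp <- tp + length(intersect(g, p))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  prf(tp, fp, fn)
}

#' Normalized concept recognition precision/recall/F1 per entity type
#'
#' Per-document sets of concept IDs per type are compared (ID level,
#' offset-agnostic) and micro-averaged.
#'
#' @param gold_docs,pred_docs lists of documents over the same corpus;
#'   predicted documents must be a subset of gold document IDs.
#' @return named list of [prf()] records, one per entity type.
#' @export
concept_prf <- function(gold_docs, pred_docs) {
  gid <- vapply(gold_docs, function(d) d$doc_id, "")
  pid <- vapply(pred_docs, function(d) d$doc_id, "")
  extra <- setdiff(pid, gid)
  if (length(extra)) {
    stop_cid("predicted document(s) absent from gold: %s",
             paste(utils::head(extra, 3), collapse = ", "))
  }
  out <- list()
  for (type in c("chemical", "disease")) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (k in seq_along(gold_docs)) {
      g <- doc_concept_ids(gold_docs[[k]], type)
      idx <- match(gid[k], pid)
      p <- if (!is.na(idx)) doc_concept_ids(pred_docs[[idx]], type) else character(0)
      tp <- tp + length(intersect(g, p))
      fp <- fp + length(setdiff(p, g))
      fn <- fn + length(setdiff(g, p))
    }
    out[[type]] <- prf(tp, fp, fn)
  }
  out
}

#' Co-occurrence baseline
#'
#' Predicts a CID relation for every \code{(chemical ID, disease ID)} pair
#' co-mentioned in a document — the maximal-recall baseline any
#' same-document classifier's predictions are a subset of.
#'
#' @param documents list of documents with mentions.
#' @return named list (doc_id -> relation frame).
#' @export
cooccurrence_baseline <- function(documents) {
  out <- list()
  for (doc in documents) {
    chem <- doc_concept_ids(doc, "chemical")
    dis <- doc_concept_ids(doc, "disease")
    if (length(chem) && length(dis)) {
      grid <- expand.grid(chemical_id = sort(chem), disease_id = sort(dis),
                          stringsAsFactors = FALSE)
      out[[doc$doc_id]] <- canonical_relations(grid)
    } else {
      out[[doc$doc_id]] <- relation_frame()
    }
  }
  out
}

#' Gold relation map of a corpus
#'
#' @param documents list of documents.
#' @return named list (doc_id -> relation frame) for [pair_prf()].
#' @export
gold_relations <- function(documents) {
  out <- lapply(documents, function(d) canonical_relations(d$relations))
  names(out) <- vapply(documents, function(d) d$doc_id, "")
  out
}

#' Write a PRF report
#'
#' Tab-separated metrics plus a human-readable rendering.
#'
#' @param prfs named list of [prf()] records.
#' @param path output TSV path (a sibling .txt is written alongside).
#' @export
write_prf_report <- function(prfs, path) {
  rows <- vapply(names(prfs), function(nm) {
    x <- prfs[[nm]]
    sprintf("%s\t%d\t%d\t%d\t%.4f\t%.4f\t%.4f", nm, x$tp, x$fp, x$fn,
            x$precision, x$recall, x$f1)
  }, "")
  write_lines_utf8(c("metric\ttp\tfp\tfn\tprecision\trecall\tf1", rows), path)
  invisible(path)
}
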