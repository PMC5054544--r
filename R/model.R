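# Candidate-pair construction, vectorization and the SVM classifier.

#' Feature-family toggles
#'
#' Mirrors the ablation protocol: each family can be disabled
#' independently; disabling all of them is rejected.
#'
#' @param bow,bon,pattern,path,statistical logical switches.
#' @return a named logical vector of class \code{feature_toggles}.
#' @export
feature_toggles <- function(bow = TRUE, bon = TRUE, pattern = TRUE,
                            path = TRUE, statistical = TRUE) {
  out <- c(bow = bow, bon = bon, pattern = pattern, path = path,
           statistical = statistical)
  if (!any(out)) stop_cid("all feature families disabled")
  structure(out, class = "feature_toggles")
}

#' Build candidate pair instances for one document
#'
#' One instance per member of the cross product of the document's chemical
#' and disease concept IDs (sentinel \code{"-1"} excluded). Features:
#' mention-level bag-of-ngram and trigger-pattern vectors for every
#' same-sentence mention pair of the two IDs, merged with the ID-level
#' bag-of-words, shortest-path walk and statistical vectors. When
#' \code{labeled} is TRUE the instance label is whether the pair is in the
#' document's relation set.
#'
#' @param doc a document with parsed sentences.
#' @param labeled attach labels from \code{doc$relations}?
#' @param kb a knowledge base ([kb_null()] by default).
#' @param config a [path_feature_config()].
#' @param toggles a [feature_toggles()].
#' @param keywords a [stat_keyword_config()].
#' @param edg_cfg an [edg_config()].
#' @param weak flag instances as weakly labeled (carried through to
#'   training for optional down-weighting).
#' @return a data-frame-free list of \code{PairInstance} lists with fields
#'   \code{doc_id}, \code{chemical_id}, \code{disease_id},
#'   \code{features}, \code{label} (NA when unlabeled), \code{weak}.
#' @export
build_instances <- function(doc, labeled = TRUE, kb = kb_null(),
                            config = path_feature_config(),
                            toggles = feature_toggles(),
                            keywords = stat_keyword_config(),
                            edg_cfg = edg_config(),
                            weak = FALSE) {
  chem_ids <- doc_concept_ids(doc, "chemical")
  dis_ids <- doc_concept_ids(doc, "disease")
  if (length(chem_ids) == 0L || length(dis_ids) == 0L) return(list())
  edgs <- if (toggles[["pattern"]] || toggles[["path"]]) {
    document_edgs(doc, edg_cfg)
  } else NULL

  gold_key <- character(0)
  if (labeled && nrow(doc$relations)) {
    gold_key <- paste(doc$relations$chemical_id, doc$relations$disease_id)
  }

  instances <- list()
  for (cid in sort(chem_ids)) {
    bow_c <- if (toggles[["bow"]]) bow_features(doc, cid, config) else empty_fv()
    for (did in sort(dis_ids)) {
      id_vec <- empty_fv()
      if (toggles[["bow"]]) {
        id_vec <- fv_add(bow_c, bow_features(doc, did, config))
      }
      if (toggles[["path"]]) {
        id_vec <- fv_add(id_vec, path_features(edgs, cid, did, config))
      }
      if (toggles[["statistical"]]) {
        id_vec <- c(id_vec, statistical_features(doc, cid, did, kb,
                                                 keywords, config))
      }
      mention_vecs <- list()
      if (toggles[["bon"]] || toggles[["pattern"]]) {
        mention_vecs <- pair_mention_vectors(doc, edgs, cid, did, config,
                                             toggles)
      }
      feats <- merge_to_pair_vector(mention_vecs, id_vec)
      instances[[length(instances) + 1L]] <- list(
        doc_id = doc$doc_id, chemical_id = cid, disease_id = did,
        features = feats,
        label = if (labeled) paste(cid, did) %in% gold_key else NA,
        weak = weak
      )
    }
  }
  instances
}

# mention-level vectors (BON + pattern) for all same-sentence mention pairs
#' @noRd
pair_mention_vectors <- function(doc, edgs, chem_id, dis_id, config, toggles) {
  vecs <- list()
  m <- doc$mentions
  has_id <- function(ids, id) id %in% ids
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    if (is.null(s$tokens)) next
    ms <- mentions_in_sentence(doc, s)
    if (nrow(ms) == 0L) next
    chems <- which(ms$type == "chemical" &
                     vapply(ms$concept_ids, has_id, TRUE, id = chem_id))
    diss <- which(ms$type == "disease" &
                    vapply(ms$concept_ids, has_id, TRUE, id = dis_id))
    for (ci in chems) for (di in diss) {
      v <- empty_fv()
      cm <- ms[ci, , drop = FALSE]
      dm <- ms[di, , drop = FALSE]
      # BON renders the pair's own IDs, not composite alternatives
      cm$concept_ids <- list(chem_id)
      dm$concept_ids <- list(dis_id)
      if (toggles[["bon"]]) v <- fv_add(v, bon_features(s, cm, dm, config))
      if (toggles[["pattern"]] && !is.null(edgs[[si]])) {
        v <- fv_add(v, pattern_features(edgs[[si]], cm, dm))
      }
      vecs[[length(vecs) + 1L]] <- v
    }
  }
  vecs
}

#' Build a feature index from training instances
#'
#' The explicit name-to-column map frozen at training time; features unseen
#' in training are dropped at prediction time.
#'
#' @param instances list of pair instances.
#' @return character vector of feature names in deterministic (sorted)
#'   order.
#' @export
build_feature_index <- function(instances) {
  sort(unique(unlist(lapply(instances, function(x) names(x$features)))))
}

#' Vectorize instances against a frozen feature index
#'
#' @param instances list of pair instances.
#' @param index feature index from [build_feature_index()].
#' @return a list with \code{X} (sparse dgCMatrix, one row per instance),
#'   \code{y} (logical labels, NA when unlabeled) and \code{weak}.
#' @export
vectorize <- function(instances, index) {
  n <- length(instances)
  if (n == 0L) {
    return(list(X = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(0L, length(index)),
                                         dimnames = list(NULL, index)),
                y = logical(0), weak = logical(0)))
  }
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_len(n)) {
    f <- instances[[k]]$features
    cols <- match(names(f), index)
    keep <- !is.na(cols) & f != 0
    ii[[k]] <- rep.int(k, sum(keep))
    jj[[k]] <- cols[keep]
    xx[[k]] <- unname(f[keep])
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, length(index)),
                            dimnames = list(NULL, index))
  y <- vapply(instances, function(x) as.logical(x$label), TRUE)
  weak <- vapply(instances, function(x) isTRUE(x$weak), TRUE)
  list(X = X, y = y, weak = weak)
}

#' Train the pair classifier
#'
#' A linear-kernel support vector machine (libsvm via e1071) over the
#' vectorized instances. Class weights default to balanced (inverse class
#' frequency) because document-level relation data are label-imbalanced.
#' Training is deterministic for fixed inputs and seed.
#'
#' @param instances labeled pair instances (at least one positive and one
#'   negative).
#' @param cost regularization constant C.
#' @param class_weights \code{"balanced"}, NULL (uniform) or a named
#'   numeric vector over \code{c("FALSE","TRUE")}.
#' @param kernel libsvm kernel name; default \code{"linear"}.
#' @param seed RNG seed recorded in the config snapshot.
#' @param scale min-max scale numeric features? Default off.
#' @return an object of class \code{cid_model}: feature index, fitted SVM,
#'   config snapshot.
#' @export
train_cid_model <- function(instances, cost = 1, class_weights = "balanced",
                            kernel = "linear", seed = 1L, scale = FALSE) {
  labs <- vapply(instances, function(x) as.logical(x$label), TRUE)
  if (any(is.na(labs))) stop_cid("train_cid_model: unlabeled instance")
  if (length(unique(labs)) < 2L) {
    stop_cid("train_cid_model: training data contain a single class")
  }
  index <- build_feature_index(instances)
  vz <- vectorize(instances, index)
  y <- factor(vz$y, levels = c(FALSE, TRUE))
  cw <- NULL
  if (identical(class_weights, "balanced")) {
    tab <- table(y)
    cw <- as.numeric(length(y) / (2 * tab))
    names(cw) <- names(tab)
  } else if (is.numeric(class_weights)) {
    cw <- class_weights
  }
  fit <- with_seed(seed, e1071::svm(
    x = as.matrix(vz$X), y = y, kernel = kernel, cost = cost,
    class.weights = cw, scale = scale, probability = FALSE
  ))
  # libsvm decision values are signed w.r.t. the first label it encountered
  flip <- if (fit$labels[1] == 2L) 1 else -1
  structure(list(index = index, fit = fit, flip = flip,
                 config = list(kernel = kernel, cost = cost,
                               class_weights = class_weights, seed = seed,
                               scale = scale)),
            class = "cid_model")
}

#' @export
print.cid_model <- function(x, ...) {
  cat(sprintf("<cid_model: %s SVM, C = %g, %d features, %d support vectors>\n",
              x$config$kernel, x$config$cost, length(x$index), x$fit$tot.nSV))
  invisible(x)
}

#' Decision values for instances
#'
#' @param model a trained [train_cid_model()] model.
#' @param instances pair instances.
#' @return numeric vector; positive values favor a CID relation.
#' @export
decision_values <- function(model, instances) {
  if (length(instances) == 0L) return(numeric(0))
  vz <- vectorize(instances, model$index)
  pr <- stats::predict(model$fit, as.matrix(vz$X), decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1]
  unname(dv) * model$flip
}

#' Predict document-level relations
#'
#' Instances whose decision value exceeds the threshold become predicted
#' \code{<chemical ID, disease ID>} relations of their document. The
#' predicted set shrinks monotonically as the threshold grows.
#'
#' @param model a \code{cid_model}.
#' @param instances pair instances (typically from [build_instances()] over
#'   a corpus).
#' @param threshold decision threshold, default 0.
#' @return named list: per doc_id a relation data frame
#'   (\code{chemical_id}, \code{disease_id}).
#' @export
predict_relations <- function(model, instances, threshold = 0) {
  out <- list()
  if (length(instances) == 0L) return(out)
  dv <- decision_values(model, instances)
  for (k in seq_along(instances)) {
    inst <- instances[[k]]
    if (is.null(out[[inst$doc_id]])) out[[inst$doc_id]] <- relation_frame()
    if (dv[k] > threshold) {
      out[[inst$doc_id]] <- rbind(out[[inst$doc_id]],
                                  relation_frame(inst$chemical_id,
                                                 inst$disease_id))
    }
  }
  lapply(out, canonical_relations)
}

#' Save / load a trained model
#'
#' The archive holds the config snapshot, frozen feature index and fitted
#' weights; reloading gives bit-identical predictions.
#'
#' @param model a \code{cid_model}.
#' @param path file path.
#' @export
save_cid_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cid_model
#' @return \code{load_cid_model}: the restored \code{cid_model}.
#' @export
load_cid_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cid_model")) stop_cid("not a cid_model archive: %s", path)
  model
}
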