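#' Assemble GO training instances for a set of proteins
#'
#' Resolves each protein's accession keys for the chosen input mode, builds
#' one GO vector per key on the given subspace, and returns the training
#' matrix with one label set per row. In the homolog modes each key's vector
#' is by default a separate training instance carrying the protein's full
#' label set; with `train_fused = TRUE` the key vectors are fused into a
#' single instance per protein instead.
#'
#' @param ds A `loc_dataset` (or any list with `accessions`, `labels`,
#'   `annotations`, `homologs`).
#' @param subspace A `go_subspace`.
#' @param mode Input mode: `"ac"`, `"seq"` or `"ac+seq"`.
#' @param n Homologs per protein for the `"seq"` modes.
#' @param vector_mode `"tf"` or `"binary"`.
#' @param train_fused Fuse each protein's key vectors into one instance.
#' @param which Indices of the proteins to include (default all).
#' @return List with `x` (instance matrix), `labels` (list of label sets,
#'   parallel to rows), `protein` (row -> protein index).
#' @export
training_instances <- function(ds, subspace, mode = "ac", n = 1L,
                               vector_mode = "tf", train_fused = FALSE,
                               which = seq_along(ds$accessions)) {
  rows <- list(); labs <- list(); prot <- integer(0)
  for (i in which) {
    keys <- resolve_keys(ds$accessions[i], ds$homologs[[ds$accessions[i]]],
                         mode = mode, n = n)
    qs <- query_set(keys, ds$annotations, subspace, mode = vector_mode)
    if (train_fused) {
      rows[[length(rows) + 1L]] <- fuse(qs)
      labs[[length(labs) + 1L]] <- ds$labels[[i]]
      prot <- c(prot, i)
    } else {
      for (r in seq_len(nrow(qs$vectors))) {
        rows[[length(rows) + 1L]] <- qs$vectors[r, ]
        labs[[length(labs) + 1L]] <- ds$labels[[i]]
        prot <- c(prot, i)
      }
    }
  }
  list(x = do.call(rbind, rows), labels = labs, protein = prot)
}

# union of the GO terms retrievable for each protein under a mode
retrieval_vocabulary <- function(ds, mode, n) {
  lapply(seq_along(ds$accessions), function(i) {
    keys <- resolve_keys(ds$accessions[i], ds$homologs[[ds$accessions[i]]],
                         mode = mode, n = n)
    unique(unlist(lapply(keys, function(k) names(go_terms(ds$annotations, k)))))
  })
}

#' Train the full localization model on a dataset
#'
#' Builds the GO subspace from the training proteins' retrieval results,
#' assembles the training instances and fits the multi-label one-vs-rest
#' SVMs.
#'
#' @inheritParams training_instances
#' @param kernel A [kernel_spec()].
#' @param C Soft-margin penalty (default 0.1).
#' @return A `goloc_model`: list with the fitted `mlsvm`, the `subspace`,
#'   and the configuration (`mode`, `n`, `vector_mode`, `kernel`, `C`).
#' @export
train_goloc <- function(ds, mode = "ac", n = 1L, vector_mode = "tf",
                        kernel = kernel_spec("linear"), C = 0.1,
                        train_fused = FALSE) {
  vocab <- retrieval_vocabulary(ds, mode, n)
  subspace <- build_subspace(vocab)
  ti <- training_instances(ds, subspace, mode = mode, n = n,
                           vector_mode = vector_mode,
                           train_fused = train_fused)
  model <- mlsvm(ti$x, ti$labels, M = length(ds$classes), kernel = kernel,
                 C = C, classes = ds$classes)
  structure(list(model = model, subspace = subspace, mode = mode,
                 n = as.integer(n), vector_mode = vector_mode,
                 kernel = kernel, C = C, classes = ds$classes),
            class = "goloc_model")
}

#' @export
print.goloc_model <- function(x, ...) {
  cat(sprintf("goloc model: mode = %s, n = %d homolog(s), %s vectors\n",
              x$mode, x$n, x$vector_mode))
  print(x$subspace)
  print(x$model)
  invisible(x)
}

#' Predict localizations for query proteins
#'
#' @param object A `goloc_model`.
#' @param ds Query dataset (a `loc_dataset`, or a list with `accessions`,
#'   `annotations`, `homologs`).
#' @param homolog_cascade When `TRUE` and a protein's resolved keys carry no
#'   GO term at all in `"seq"` mode, fall back to the highest-ranked
#'   annotated homolog beyond the top `n` (the novel-protein cascade).
#' @param ... Unused.
#' @return Prediction data frame as in [predict.mlsvm()].
#' @export
predict.goloc_model <- function(object, ds, homolog_cascade = FALSE, ...) {
  qss <- lapply(seq_along(ds$accessions), function(i) {
    acc <- ds$accessions[i]
    keys <- resolve_keys(acc, ds$homologs[[acc]], mode = object$mode,
                         n = object$n)
    qs <- query_set(keys, ds$annotations, object$subspace,
                    mode = object$vector_mode)
    if (homolog_cascade && qs$zero_vector && object$mode != "ac") {
      alt <- first_annotated_key(ds$homologs[[acc]], ds$annotations)
      if (!is.null(alt)) {
        qs <- query_set(alt, ds$annotations, object$subspace,
                        mode = object$vector_mode)
      }
    }
    qs
  })
  names(qss) <- ds$accessions
  predict(object$model, qss)
}

#' Leave-one-out cross validation of the localization pipeline
#'
#' Folds iterate over actual proteins: each protein in turn is held out,
#' the model is trained on the remaining N - 1 (by default rebuilding the
#' GO subspace from the training proteins only, so no term identity leaks
#' from the held-out protein), and the held-out protein is scored and
#' decided.
#'
#' @inheritParams train_goloc
#' @param rebuild_subspace Rebuild the GO subspace inside every fold
#'   (default). `FALSE` freezes the subspace built once from the whole
#'   dataset — cheaper, and the variant whose global distinct-term count is
#'   a single number.
#' @param verbose Print fold progress.
#' @return List with `predicted` (list of predicted sets), `details`
#'   (per-protein data frame), and `report` (an `eval_report`).
#' @export
loocv <- function(ds, mode = "ac", n = 1L, vector_mode = "tf",
                  kernel = kernel_spec("linear"), C = 0.1,
                  train_fused = FALSE, rebuild_subspace = TRUE,
                  verbose = FALSE) {
  N <- length(ds$accessions)
  if (N < 3L) stop("leave-one-out cross validation needs at least 3 proteins")
  M <- length(ds$classes)
  vocab <- retrieval_vocabulary(ds, mode, n)
  # term -> number of proteins whose retrieval result contains it
  vocab_tab <- table(unlist(vocab))
  global_terms <- sort(names(vocab_tab))
  predicted <- vector("list", N)
  fallback <- logical(N)
  zero_vec <- logical(N)
  frozen <- if (!rebuild_subspace) build_subspace(list(global_terms)) else NULL
  for (i in seq_len(N)) {
    subspace <- if (rebuild_subspace) {
      mine <- vocab[[i]]
      drop <- mine[vocab_tab[mine] == 1L]  # terms seen only in the held-out protein
      terms <- setdiff(global_terms, drop)
      if (length(terms) == 0L) stop("empty subspace in fold ", i)
      structure(terms, class = "go_subspace")
    } else frozen
    ti <- training_instances(ds, subspace, mode = mode, n = n,
                             vector_mode = vector_mode,
                             train_fused = train_fused,
                             which = setdiff(seq_len(N), i))
    model <- suppressWarnings(
      mlsvm(ti$x, ti$labels, M = M, kernel = kernel, C = C))
    keys <- resolve_keys(ds$accessions[i], ds$homologs[[ds$accessions[i]]],
                         mode = mode, n = n)
    qs <- query_set(keys, ds$annotations, subspace, mode = vector_mode)
    dec <- decide(svm_scores(model, qs))
    predicted[[i]] <- dec$set
    fallback[i] <- dec$fallback
    zero_vec[i] <- qs$zero_vector
    if (verbose && i %% 25L == 0L) {
      message(sprintf("loocv: fold %d/%d", i, N))
    }
  }
  details <- data.frame(
    id = ds$accessions,
    true = vapply(ds$labels, paste, "", collapse = ";"),
    predicted = vapply(predicted, paste, "", collapse = ";"),
    fallback = fallback, zero_vector = zero_vec,
    stringsAsFactors = FALSE)
  list(predicted = predicted, details = details,
       report = evaluate_predictions(ds$labels, predicted, M = M,
                                     classes = ds$classes))
}
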