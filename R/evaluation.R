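#' Actual and locative protein counts
#'
#' A protein residing in k locations counts as k locative proteins but one
#' actual protein. With `n_act(m)` the number of actual proteins carrying m
#' labels, `N_act = sum_m n_act(m)` and `N_loc = sum_m m * n_act(m)`.
#'
#' @param truth List of non-empty true label sets.
#' @param M Number of classes (bounds the multiplicity histogram); defaults
#'   to the largest label present.
#' @return List with `n_act`, `n_loc`, and `n_act_by_multiplicity` (length-M
#'   integer vector, entry m = number of proteins with exactly m labels).
#' @export
count_proteins <- function(truth, M = NULL) {
  stopifnot(is.list(truth), length(truth) > 0L)
  sizes <- lengths(truth)
  if (any(sizes == 0L)) stop("empty true label set")
  if (is.null(M)) M <- max(unlist(truth))
  stopifnot(max(sizes) <= M)
  n_by_mult <- vapply(seq_len(M), function(m) sum(sizes == m), integer(1))
  list(n_act = length(truth),
       n_loc = as.integer(sum(seq_len(M) * n_by_mult)),
       n_act_by_multiplicity = n_by_mult)
}

check_pair <- function(truth, predicted) {
  stopifnot(is.list(truth), is.list(predicted),
            length(truth) == length(predicted))
  if (any(lengths(truth) == 0L)) stop("empty true label set")
}

pred_size <- function(p) if (is.null(p)) 0L else length(p)

#' Overall locative accuracy
#'
#' The number of correctly predicted locative proteins,
#' `sum_i |M(p_i) intersect L(p_i)|`, divided by `N_loc`. A locative protein
#' counts as correct when its location appears anywhere in the predicted
#' set, so a predictor that always emits every class scores 100% here —
#' which is why the actual accuracy is the stricter, more objective
#' companion metric.
#'
#' @param truth,predicted Equal-length lists of label sets. Predicted sets
#'   may be `NULL`/empty (e.g. an unpredictable protein under the lookup
#'   baseline); they contribute no hits.
#' @return Fraction in `[0, 1]`.
#' @export
locative_accuracy <- function(truth, predicted) {
  check_pair(truth, predicted)
  hits <- sum(mapply(function(l, m) length(intersect(l, m)), truth, predicted))
  n_loc <- sum(lengths(truth))
  hits / n_loc
}

#' Overall actual accuracy
#'
#' The fraction of proteins whose predicted label set equals the true set
#' exactly — no over- and no under-prediction.
#'
#' @inheritParams locative_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
actual_accuracy <- function(truth, predicted) {
  check_pair(truth, predicted)
  mean(mapply(exact_match, truth, predicted))
}

exact_match <- function(l, m) {
  pred_size(m) == length(l) && setequal(l, m)
}

#' Over/equal/under-prediction distribution
#'
#' Buckets each protein by the difference between the sizes of its predicted
#' and true label sets: over-predicted when `|M| > |L|`, equal when sizes
#' match, under-predicted when `|M| < |L|` (an empty prediction is maximal
#' under-prediction). `k = ||M| - |L||` is the number of extra or missing
#' labels.
#'
#' @inheritParams locative_accuracy
#' @return List with `counts` (3 x (M+1) matrix, rows `over`/`equal`/`under`,
#'   column k+1 = proteins at difference k) and `totals` (named vector
#'   `over`/`equal`/`under`).
#' @export
prediction_distribution <- function(truth, predicted) {
  check_pair(truth, predicted)
  M <- max(unlist(c(truth, predicted)), 0L)
  diffs <- mapply(function(l, m) pred_size(m) - length(l), truth, predicted)
  counts <- matrix(0L, nrow = 3L, ncol = M + 1L,
                   dimnames = list(c("over", "equal", "under"),
                                   paste0("k=", 0:M)))
  for (d in diffs) {
    row <- if (d > 0) "over" else if (d == 0) "equal" else "under"
    k <- abs(d)
    counts[row, k + 1L] <- counts[row, k + 1L] + 1L
  }
  totals <- rowSums(counts)
  storage.mode(totals) <- "integer"
  list(counts = counts, totals = totals)
}

#' Actual accuracy stratified by label multiplicity
#'
#' Exact-match fraction among the proteins with exactly l true labels, for
#' each observed l. Multi-location strata are the hard ones: the size of the
#' set and all its members must be right.
#'
#' @inheritParams locative_accuracy
#' @return `data.frame` with columns `l`, `n` (proteins in the stratum),
#'   `hits`, `accuracy`; strata with no proteins are absent.
#' @export
per_multiplicity_accuracy <- function(truth, predicted) {
  check_pair(truth, predicted)
  sizes <- lengths(truth)
  ok <- mapply(exact_match, truth, predicted)
  ls <- sort(unique(sizes))
  data.frame(l = ls,
             n = vapply(ls, function(l) sum(sizes == l), integer(1)),
             hits = vapply(ls, function(l) sum(ok[sizes == l]), integer(1)),
             accuracy = vapply(ls, function(l) mean(ok[sizes == l]), numeric(1)))
}

#' Per-class locative accuracy
#'
#' For each class m: among the locative proteins of class m (proteins whose
#' true set contains m), the fraction whose predicted set also contains m.
#'
#' @inheritParams locative_accuracy
#' @param M Number of classes.
#' @return `data.frame` with columns `class`, `n` (locative proteins),
#'   `hits`, `accuracy` (NA when the class has no locative protein).
#' @export
per_class_locative_accuracy <- function(truth, predicted, M) {
  check_pair(truth, predicted)
  res <- lapply(seq_len(M), function(m) {
    in_class <- vapply(truth, function(l) m %in% l, TRUE)
    hit <- vapply(seq_along(truth), function(i) {
      in_class[i] && m %in% predicted[[i]]
    }, TRUE)
    c(n = sum(in_class), hits = sum(hit))
  })
  n <- vapply(res, `[[`, 0, "n")
  hits <- vapply(res, `[[`, 0, "hits")
  data.frame(class = seq_len(M), n = as.integer(n), hits = as.integer(hits),
             accuracy = ifelse(n > 0, hits / n, NA_real_))
}

#' Full multi-label evaluation report
#'
#' Bundles the protein counts, overall locative and actual accuracies,
#' per-class locative accuracies, the over/equal/under-prediction
#' distribution, and the per-multiplicity actual accuracies.
#'
#' @inheritParams locative_accuracy
#' @param M Number of classes; defaults to the largest label observed.
#' @param classes Optional class names (length M).
#' @return An `eval_report` list.
#' @export
evaluate_predictions <- function(truth, predicted, M = NULL, classes = NULL) {
  check_pair(truth, predicted)
  if (is.null(M)) M <- max(unlist(c(truth, predicted)))
  cp <- count_proteins(truth, M = M)
  loc_hits <- sum(mapply(function(l, m) length(intersect(l, m)),
                         truth, predicted))
  act_hits <- sum(mapply(exact_match, truth, predicted))
  structure(list(
    M = M, classes = classes,
    n_act = cp$n_act, n_loc = cp$n_loc,
    n_act_by_multiplicity = cp$n_act_by_multiplicity,
    locative_hits = loc_hits,
    locative_accuracy = loc_hits / cp$n_loc,
    actual_hits = act_hits,
    actual_accuracy = act_hits / cp$n_act,
    per_class = per_class_locative_accuracy(truth, predicted, M),
    distribution = prediction_distribution(truth, predicted),
    per_multiplicity = per_multiplicity_accuracy(truth, predicted)),
    class = "eval_report")
}

ratio_cell <- function(hits, total) {
  sprintf("%d/%d = %.1f%%", hits, total, 100 * hits / total)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Multi-label evaluation over %d actual / %d locative proteins (M = %d)\n",
              x$n_act, x$n_loc, x$M))
  cat("  Overall locative accuracy:", ratio_cell(x$locative_hits, x$n_loc), "\n")
  cat("  Overall actual accuracy:  ", ratio_cell(x$actual_hits, x$n_act), "\n")
  cat("  Per-class locative accuracy:\n")
  for (i in seq_len(nrow(x$per_class))) {
    row <- x$per_class[i, ]
    nm <- if (!is.null(x$classes)) x$classes[row$class] else sprintf("class %d", row$class)
    cell <- if (row$n > 0) ratio_cell(row$hits, row$n) else "-"
    cat(sprintf("    %-28s %s\n", nm, cell))
  }
  tot <- x$distribution$totals
  cat(sprintf("  Over / equal / under-predicted: %d / %d / %d\n",
              tot["over"], tot["equal"], tot["under"]))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report An `eval_report`.
#' @param file Output path; format chosen by extension (`.json` or `.tsv`).
#' @export
write_eval_report <- function(report, file) {
  stopifnot(inherits(report, "eval_report"))
  if (grepl("\\.json$", file)) {
    out <- report
    out$distribution <- list(
      counts = as.data.frame(report$distribution$counts),
      totals = as.list(report$distribution$totals))
    class(out) <- NULL
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    lines <- c(
      sprintf("n_act\t%d", report$n_act),
      sprintf("n_loc\t%d", report$n_loc),
      sprintf("locative_accuracy\t%d/%d\t%.10g", report$locative_hits,
              report$n_loc, report$locative_accuracy),
      sprintf("actual_accuracy\t%d/%d\t%.10g", report$actual_hits,
              report$n_act, report$actual_accuracy),
      sprintf("over\t%d", report$distribution$totals["over"]),
      sprintf("equal\t%d", report$distribution$totals["equal"]),
      sprintf("under\t%d", report$distribution$totals["under"]))
    writeLines(lines, file)
  }
  invisible(file)
}
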