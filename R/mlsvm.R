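#' Kernel specification for the one-vs-rest SVMs
#'
#' @param family `"linear"`, `"rbf"` or `"polynomial"`. Linear kernels are
#'   the default: GO vectors typically have more dimensions than there are
#'   training proteins, and highly non-linear kernels overfit badly in that
#'   regime.
#' @param sigma RBF width, `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`;
#'   must be positive.
#' @param degree Polynomial degree (>= 2), `K(x, y) = (<x, y> + 1)^d`.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(family = c("linear", "rbf", "polynomial"),
                        sigma = 1, degree = 3L) {
  family <- match.arg(family)
  if (family == "rbf") stopifnot(sigma > 0)
  if (family == "polynomial") stopifnot(degree >= 2L, degree == as.integer(degree))
  structure(list(family = family, sigma = as.numeric(sigma),
                 degree = as.integer(degree)),
            class = "kernel_spec")
}

#' Kernel matrix between two sets of row vectors
#'
#' @param spec A `kernel_spec`.
#' @param x,y Matrices with vectors in rows (same column count).
#' @return The `nrow(x)` x `nrow(y)` matrix of kernel values.
#' @export
kernel_matrix <- function(spec, x, y) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  stopifnot(inherits(spec, "kernel_spec"), ncol(x) == ncol(y))
  switch(spec$family,
         linear = x %*% t(y),
         rbf = {
           d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
           d2[d2 < 0] <- 0
           exp(-d2 / (2 * spec$sigma^2))
         },
         polynomial = (x %*% t(y) + 1)^spec$degree)
}

#' Transformed one-vs-rest labels of a label set
#'
#' Class m's binary SVM sees a protein as +1 exactly when m belongs to the
#' protein's label set; a multi-location protein therefore has several
#' positive transformed labels but is still a single training instance.
#'
#' @param labels Non-empty set of class indices, subset of `1..M`.
#' @param M Number of classes.
#' @return Numeric vector of length M with entries in `{-1, +1}`.
#' @export
transform_labels <- function(labels, M) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label set")
  if (any(labels < 1L | labels > M)) stop("label outside 1..M")
  ifelse(seq_len(M) %in% labels, 1, -1)
}

#' Train the multi-label one-vs-rest SVM classifier
#'
#' Fits M independent binary soft-margin SVMs, one per subcellular location,
#' on GO training vectors. Class m's SVM is trained with the transformed
#' labels of [transform_labels()]; raw (unscaled) coordinates are used, as
#' term counts are already on a common scale. A class with no positive (or
#' no negative) training instance cannot be fitted and becomes a stub whose
#' score is `-Inf`: it can never be predicted by the positive-score rule and
#' never wins the argmax fallback unless every class is a stub (an error).
#'
#' @param x Training matrix, one GO vector per row. When homolog-derived
#'   vectors are used for training, each key's vector is a separate row
#'   carrying the protein's full label set.
#' @param labels List of label sets (integer vectors), one per row of `x`.
#' @param M Number of classes; defaults to the largest label present.
#' @param kernel A [kernel_spec()].
#' @param C Soft-margin penalty; default 0.1.
#' @param classes Optional character vector of class names (length M).
#' @return An `mlsvm` model: per-class support vectors, dual coefficients
#'   `alpha_r * y_r`, bias `b_m`, plus (linear kernel) the equivalent primal
#'   weight vector.
#' @export
mlsvm <- function(x, labels, M = NULL, kernel = kernel_spec("linear"),
                  C = 0.1, classes = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  stopifnot(is.list(labels), length(labels) == nrow(x), C > 0)
  if (is.null(M)) M <- max(unlist(labels))
  Y <- t(vapply(labels, transform_labels, numeric(M), M = M))
  if (M == 1L) Y <- matrix(Y, ncol = 1L)
  args <- switch(kernel$family,
                 linear = list(kernel = "linear"),
                 rbf = list(kernel = "radial", gamma = 1 / (2 * kernel$sigma^2)),
                 polynomial = list(kernel = "polynomial",
                                   degree = kernel$degree, gamma = 1,
                                   coef0 = 1))
  svms <- vector("list", M)
  for (m in seq_len(M)) {
    ym <- Y[, m]
    if (all(ym > 0) || all(ym < 0)) {
      warning(sprintf("class %d has no %s training instance; using constant stub",
                      m, if (all(ym > 0)) "negative" else "positive"))
      svms[[m]] <- list(stub = TRUE)
      next
    }
    yf <- factor(ifelse(ym > 0, "pos", "neg"), levels = c("neg", "pos"))
    fit <- do.call(e1071::svm,
                   c(list(x = x, y = yf, type = "C-classification",
                          cost = C, scale = FALSE), args))
    # libsvm orients decision values toward the first label seen in y
    flip <- if (fit$levels[fit$labels[1L]] == "pos") 1 else -1
    coef <- as.numeric(fit$coefs) * flip   # alpha_r * y_r
    b <- -fit$rho * flip
    cls <- list(stub = FALSE, sv = fit$SV, coef = coef, b = b,
                index = fit$index, n_pos = sum(ym > 0))
    if (kernel$family == "linear") {
      cls$w <- as.numeric(crossprod(fit$SV, coef))
    }
    svms[[m]] <- cls
  }
  if (all(vapply(svms, function(s) isTRUE(s$stub), TRUE))) {
    stop("every class is a stub: no class has both positive and negative instances")
  }
  structure(list(M = M, classes = classes, kernel = kernel, C = C,
                 T = ncol(x), svms = svms),
            class = "mlsvm")
}

#' @export
print.mlsvm <- function(x, ...) {
  cat(sprintf("Multi-label one-vs-rest SVM: M = %d classes, T = %d, %s kernel, C = %g\n",
              x$M, x$T, x$kernel$family, x$C))
  nsv <- vapply(x$svms, function(s) if (isTRUE(s$stub)) NA_integer_ else length(s$coef),
                integer(1))
  cat("  support vectors per class:", paste(nsv, collapse = ", "), "\n")
  invisible(x)
}

#' Per-class SVM scores of a query-vector set
#'
#' The fused score of class m is the weighted sum over the query vectors
#' `q_0..q_n` of their dual-form SVM outputs,
#' `s_m = sum_j w_j [ sum_r alpha_r y_r K(p_r, q_j) + b_m ]`.
#' The bias sits inside the weighted sum; since the fusion weights sum to 1
#' it contributes exactly `b_m` once. For a linear kernel this equals the
#' score of the single fused vector.
#'
#' @param model An `mlsvm` model.
#' @param qs A `go_query_set` (or a bare numeric vector, treated as a
#'   single-vector set with weight 1).
#' @param form `"dual"` scores through the support-vector expansion;
#'   `"weight"` (linear kernel only) through the primal weight vector. The
#'   two agree to numerical precision.
#' @return Numeric vector `s_1..s_M` (stub classes score `-Inf`).
#' @export
svm_scores <- function(model, qs, form = c("dual", "weight")) {
  form <- match.arg(form)
  stopifnot(inherits(model, "mlsvm"))
  if (!inherits(qs, "go_query_set")) qs <- new_query_set(qs, weights = 1)
  if (ncol(qs$vectors) != model$T) {
    stop(sprintf("dimension mismatch: query has %d coordinates, model expects %d",
                 ncol(qs$vectors), model$T))
  }
  if (form == "weight" && model$kernel$family != "linear") {
    stop("weight-form scoring requires a linear kernel")
  }
  vapply(model$svms, function(cls) {
    if (isTRUE(cls$stub)) return(-Inf)
    per_vec <- if (form == "dual") {
      as.numeric(kernel_matrix(model$kernel, qs$vectors, cls$sv) %*% cls$coef) + cls$b
    } else {
      as.numeric(qs$vectors %*% cls$w) + cls$b
    }
    sum(qs$weights * per_vec)
  }, numeric(1))
}

#' Multi-label decision rule
#'
#' Predicts every class whose score is strictly positive. When no score is
#' positive the number of locations is set to one and the top-scoring class
#' is returned (ties broken by the smallest class index), so the predicted
#' set is never empty.
#'
#' @param scores Numeric vector `s_1..s_M`, M >= 2.
#' @return List with `set` (sorted integer vector of predicted classes) and
#'   `fallback` (`TRUE` iff the argmax branch was taken).
#' @export
decide <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 2L)
  pos <- which(scores > 0)
  if (length(pos) > 0L) {
    return(list(set = as.integer(sort(pos)), fallback = FALSE))
  }
  if (all(scores == -Inf)) stop("all classes are stubs; no decision possible")
  list(set = which.max(scores), fallback = TRUE)  # which.max takes first tie
}

#' Predict label sets for query-vector sets
#'
#' @param object An `mlsvm` model.
#' @param query_sets A `go_query_set` or a list of them; names are used as
#'   protein ids.
#' @param ... Unused.
#' @return A `data.frame` with one row per query: `id`, `labels`
#'   (semicolon-joined class indices), one `score_<m>` column per class,
#'   `fallback` and `zero_vector` flags. The raw predicted sets are attached
#'   as attribute `sets` (list of integer vectors).
#' @export
predict.mlsvm <- function(object, query_sets, ...) {
  if (inherits(query_sets, "go_query_set")) query_sets <- list(query_sets)
  ids <- names(query_sets)
  if (is.null(ids)) ids <- sprintf("query_%d", seq_along(query_sets))
  scores <- t(vapply(query_sets, function(qs) svm_scores(object, qs),
                     numeric(object$M)))
  decisions <- apply(scores, 1L, decide)
  sets <- lapply(decisions, `[[`, "set")
  out <- data.frame(
    id = ids,
    labels = vapply(sets, function(s) paste(s, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  colnames(scores) <- sprintf("score_%d", seq_len(object$M))
  out <- cbind(out, as.data.frame(scores))
  out$fallback <- vapply(decisions, `[[`, TRUE, "fallback")
  out$zero_vector <- vapply(query_sets, function(qs) isTRUE(qs$zero_vector), TRUE)
  rownames(out) <- NULL
  attr(out, "sets") <- sets
  out
}
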