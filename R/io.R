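#' Read and write multi-label files
#'
#' Label files are TSV with one row per protein, `id <TAB>
#' label;label;...`, preceded by a header line `#classes<TAB>name;name;...`
#' naming the class catalog (which defines M and the index of every class).
#' Labels in the rows may be class names or 1-based indices.
#'
#' @param file Path or connection.
#' @return `read_labels`: list with `ids`, `labels` (list of integer label
#'   sets) and `classes`.
#' @export
read_labels <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#classes\t")) {
    stop("labels file must start with a '#classes<TAB>name;name;...' header")
  }
  classes <- strsplit(sub("^#classes\t", "", lines[[1L]]), ";", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  labels <- lapply(fields, function(f) {
    if (length(f) < 2L || !nzchar(f[[2L]])) return(integer(0))
    toks <- strsplit(f[[2L]], ";", fixed = TRUE)[[1L]]
    idx <- match(toks, classes)
    numeric_toks <- suppressWarnings(as.integer(toks))
    idx[is.na(idx)] <- numeric_toks[is.na(idx)]
    if (any(is.na(idx)) || any(idx < 1L | idx > length(classes))) {
      stop("unknown label token(s): ", paste(toks, collapse = ";"))
    }
    sort(unique(idx))
  })
  names(labels) <- ids
  list(ids = ids, labels = labels, classes = classes)
}

#' @rdname read_labels
#' @param ids Protein ids.
#' @param labels List of integer label sets, parallel to `ids`.
#' @param classes Class catalog (character vector).
#' @export
write_labels <- function(ids, labels, classes, file) {
  stopifnot(length(ids) == length(labels))
  rows <- vapply(labels, function(l) paste(classes[l], collapse = ";"), "")
  writeLines(c(paste0("#classes\t", paste(classes, collapse = ";")),
               paste(ids, rows, sep = "\t")), file)
  invisible(file)
}

#' Write a prediction table as TSV
#'
#' @param predictions Data frame from [predict.mlsvm()] /
#'   [predict.goloc_model()].
#' @param file Output path.
#' @export
write_predictions <- function(predictions, file) {
  utils::write.table(predictions, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Serialize a trained localization model to versioned JSON
#'
#' The JSON records the format version, the GO subspace, the kernel
#' specification (including the RBF convention
#' `K(x,y) = exp(-||x-y||^2 / (2 sigma^2))`), the penalty C, and per class
#' either the support vectors with their dual coefficients and bias or a
#' stub marker.
#'
#' @param model A `goloc_model`.
#' @param file Output path.
#' @export
write_model <- function(model, file) {
  stopifnot(inherits(model, "goloc_model"))
  per_class <- lapply(model$model$svms, function(cls) {
    if (isTRUE(cls$stub)) return(list(stub = TRUE))
    list(stub = FALSE, b = cls$b, coef = as.numeric(cls$coef),
         sv = apply(unname(cls$sv), 1L, as.numeric, simplify = FALSE))
  })
  obj <- list(format = "goloc-model", version = 1L,
              mode = model$mode, n = model$n,
              vector_mode = model$vector_mode,
              kernel = list(family = model$kernel$family,
                            sigma = model$kernel$sigma,
                            degree = model$kernel$degree,
                            rbf_convention = "exp(-||x-y||^2/(2*sigma^2))"),
              C = model$C, classes = model$classes,
              subspace = as.character(model$subspace),
              svms = per_class)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_model
#' @return `read_model` returns the reconstructed `goloc_model`.
#' @export
read_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (!identical(obj$format, "goloc-model") || obj$version != 1L) {
    stop("not a version-1 goloc model file")
  }
  kernel <- kernel_spec(obj$kernel$family, sigma = obj$kernel$sigma,
                        degree = obj$kernel$degree)
  subspace <- build_subspace(list(unlist(obj$subspace)))
  svms <- lapply(obj$svms, function(cls) {
    if (isTRUE(cls$stub)) return(list(stub = TRUE))
    sv <- do.call(rbind, lapply(cls$sv, unlist))
    out <- list(stub = FALSE, sv = sv, coef = unlist(cls$coef), b = cls$b)
    if (kernel$family == "linear") {
      out$w <- as.numeric(crossprod(sv, out$coef))
    }
    out
  })
  classes <- unlist(obj$classes)
  inner <- structure(list(M = length(svms), classes = classes,
                          kernel = kernel, C = obj$C,
                          T = length(subspace), svms = svms),
                     class = "mlsvm")
  structure(list(model = inner, subspace = subspace, mode = obj$mode,
                 n = as.integer(obj$n), vector_mode = obj$vector_mode,
                 kernel = kernel, C = obj$C, classes = classes),
            class = "goloc_model")
}
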