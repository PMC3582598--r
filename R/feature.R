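#' Build the GO subspace spanned by a set of training proteins
#'
#' The feature space is not the full ontology but the set of T distinct GO
#' terms observed in the GO-term search results of the training proteins.
#' Query terms outside this subspace are later dropped, which is what keeps
#' the vectors low-dimensional without losing the terms that can carry class
#' signal.
#'
#' @param termsets List of GO-term multisets (named integer vectors or
#'   character vectors), one per training retrieval result.
#' @return A `go_subspace`: a character vector of the T distinct term ids in
#'   strict lexicographic order (the ordering fixes the coordinate system so
#'   that models are reproducible).
#' @export
build_subspace <- function(termsets) {
  stopifnot(is.list(termsets))
  all_terms <- unlist(lapply(termsets, function(ts) {
    if (is.character(ts)) ts else names(ts)
  }), use.names = FALSE)
  terms <- sort(unique(all_terms))
  if (length(terms) == 0L) stop("empty subspace: no GO terms in any training multiset")
  bad <- !is_go_id(terms)
  if (any(bad)) stop("invalid GO id(s): ", paste(terms[bad], collapse = ", "))
  structure(terms, class = "go_subspace")
}

#' @export
print.go_subspace <- function(x, ...) {
  cat(sprintf("GO subspace: T = %d distinct terms\n", length(x)))
  invisible(x)
}

#' Serialize / deserialize a GO subspace
#'
#' Plain-text format: a header line `T=<int>` followed by one GO id per
#' line.
#'
#' @param subspace A `go_subspace`.
#' @param file Path or connection.
#' @return `read_subspace` returns a `go_subspace`.
#' @export
write_subspace <- function(subspace, file) {
  stopifnot(inherits(subspace, "go_subspace"))
  writeLines(c(sprintf("T=%d", length(subspace)), unclass(subspace)), file)
  invisible(file)
}

#' @rdname write_subspace
#' @export
read_subspace <- function(file) {
  lines <- read_text_lines(file)
  stopifnot(length(lines) >= 1L, grepl("^T=[0-9]+$", lines[[1L]]))
  t_decl <- as.integer(sub("^T=", "", lines[[1L]]))
  terms <- lines[-1L]
  terms <- terms[nzchar(terms)]
  if (length(terms) != t_decl) stop("subspace header T does not match term count")
  build_subspace(list(terms))
}

#' Construct a GO vector from a term multiset
#'
#' Maps a protein's GO-term multiset onto the subspace coordinate system. In
#' `"tf"` (term-frequency) mode coordinate j is the number of occurrences of
#' subspace term j; in `"binary"` (1-0) mode it is 1 when the term occurs at
#' all. Terms outside the subspace are dropped (their count is reported via
#' attribute `dropped`); an empty multiset gives the all-zero vector.
#'
#' @param terms GO-term multiset (named integer vector, or character vector
#'   counting one occurrence per element).
#' @param subspace A `go_subspace`.
#' @param mode `"tf"` or `"binary"`.
#' @return Numeric vector of length T with attributes `mode` and `dropped`
#'   (number of out-of-subspace occurrences).
#' @export
vectorize <- function(terms, subspace, mode = c("tf", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(subspace, "go_subspace"))
  terms <- as_term_multiset(terms)
  v <- numeric(length(subspace))
  pos <- match(names(terms), unclass(subspace))
  inside <- !is.na(pos)
  v[pos[inside]] <- as.numeric(terms[inside])
  dropped <- sum(terms[!inside])
  if (mode == "binary") v <- as.numeric(v > 0)
  structure(v, mode = mode, dropped = as.integer(dropped))
}

#' Quantize a term-frequency vector to the 1-0 representation
#'
#' @param v Numeric GO vector.
#' @return Vector with each positive coordinate replaced by 1.
#' @export
binarize <- function(v) {
  out <- as.numeric(v > 0)
  attributes(out) <- attributes(v)
  attr(out, "mode") <- "binary"
  out
}

#' Build the query-vector set of a protein
#'
#' A protein queried through its own accession and/or the accessions of its
#' n homologs yields up to n+1 GO vectors, fused at scoring time with equal
#' weights: case 1 (accession only) has a single vector with weight 1,
#' case 2 (sequence only) the n homolog vectors with weights 1/n, case 3
#' (both) the true-accession vector followed by the homolog vectors with
#' weights 1/(n+1). When no key resolves at all (e.g. no homolog found) the
#' set degenerates to one all-zero vector with weight 1.
#'
#' @param keys Ordered character vector of accession keys (see
#'   [resolve_keys()]).
#' @param table A `go_annotation` object.
#' @param subspace A `go_subspace`.
#' @param mode Vector mode, `"tf"` or `"binary"`.
#' @param case Optional consistency check: 1 requires exactly one key, 2 and
#'   3 place no count constraint beyond non-degeneracy of the weights.
#' @return A `go_query_set`: list with `vectors` (k x T matrix, one row per
#'   key), `weights` (length k, summing to 1), `keys`, and `zero_vector`
#'   flag (`TRUE` when every coordinate of every vector is zero).
#' @export
query_set <- function(keys, table, subspace, mode = c("tf", "binary"),
                      case = NULL) {
  mode <- match.arg(mode)
  if (!is.null(case)) {
    stopifnot(case %in% 1:3)
    if (case == 1L && length(keys) != 1L) stop("case 1 requires exactly one key")
  }
  t_dim <- length(subspace)
  if (length(keys) == 0L) {
    vectors <- matrix(0, nrow = 1L, ncol = t_dim)
    weights <- 1
    keys <- NA_character_
  } else {
    vectors <- t(vapply(keys, function(k) {
      as.numeric(vectorize(go_terms(table, k), subspace, mode))
    }, numeric(t_dim)))
    if (t_dim == 0L) vectors <- matrix(0, nrow = length(keys), ncol = 0L)
    weights <- rep(1 / length(keys), length(keys))
  }
  structure(list(vectors = vectors, weights = weights, keys = keys,
                 zero_vector = all(vectors == 0)),
            class = "go_query_set")
}

#' Construct a query set from explicit vectors and weights
#'
#' Lower-level companion of [query_set()] for callers that already hold the
#' GO vectors.
#'
#' @param vectors Matrix (k x T) or single numeric vector.
#' @param weights Non-negative fusion weights summing to 1; default equal.
#' @return A `go_query_set`.
#' @export
new_query_set <- function(vectors, weights = NULL) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1L)
  k <- nrow(vectors)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k, all(weights >= 0),
            abs(sum(weights) - 1) <= 1e-12)
  structure(list(vectors = vectors, weights = as.numeric(weights),
                 keys = rep(NA_character_, k),
                 zero_vector = all(vectors == 0)),
            class = "go_query_set")
}

#' Fuse a query-vector set into its weighted mean vector
#'
#' Computes the convex combination sum_j w_j q_j. For a linear kernel,
#' scoring this single fused vector is exactly equivalent to fusing the
#' per-vector scores, which is a useful shortcut and a strong internal
#' consistency check.
#'
#' @param qs A `go_query_set`.
#' @return Numeric vector of length T.
#' @export
fuse <- function(qs) {
  stopifnot(inherits(qs, "go_query_set"))
  as.numeric(crossprod(qs$vectors, qs$weights))
}
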