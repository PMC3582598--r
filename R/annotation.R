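#' Read a GAF 2.x annotation file into an annotation table
#'
#' Parses a Gene Ontology Annotation (GAF 2.x) file and builds a table mapping
#' each accession (column 2) to the multiset of GO term ids (column 5)
#' annotated to it. A GO term annotated to the same accession in several rows
#' accumulates an occurrence count of several: these counts are the raw
#' term frequencies behind TF GO vectors, so no de-duplication by evidence
#' code or reference is performed.
#'
#' @param file Path to a GAF file (plain or gzip-compressed) or a connection.
#' @param exclude_not If `TRUE`, rows whose qualifier column (column 4)
#'   contains a `NOT` token are dropped. Default `FALSE`: every row counts.
#' @return An object of class `go_annotation`: a list with elements
#'   `terms` (named list, accession -> named integer vector of GO-term
#'   occurrence counts) and `n_skipped` (rows dropped as malformed).
#' @details Comment lines start with `!`. A data row is skipped, with a
#'   warning reporting the total skipped, when it has fewer than 15 columns
#'   or its column 5 does not match `GO:` followed by exactly 7 digits.
#'   An empty table is legal.
#' @seealso [go_terms()], [annotation_table()]
#' @export
read_gaf <- function(file, exclude_not = FALSE) {
  lines <- read_text_lines(file)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(annotation_table(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  acc <- vapply(fields, function(f) if (length(f) >= 5L) f[[2L]] else "", "")
  go <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "", "")
  qual <- vapply(fields, function(f) if (length(f) >= 5L) f[[4L]] else "", "")
  ok <- nf >= 15L & is_go_id(go) & nzchar(acc)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(sprintf("read_gaf: skipped %d malformed row(s)", n_skipped))
  }
  keep <- ok
  if (exclude_not) {
    keep <- keep & !grepl("(^|\\|)NOT($|\\|)", qual)
  }
  acc <- acc[keep]
  go <- go[keep]
  terms <- lapply(split(go, factor(acc, levels = unique(acc))), function(g) {
    tab <- table(g)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts
  })
  annotation_table(terms, n_skipped = n_skipped)
}

#' Construct an annotation table from term multisets
#'
#' @param terms Named list: accession -> GO-term multiset, given either as a
#'   named integer vector (term -> count) or a character vector in which each
#'   element counts one occurrence.
#' @param n_skipped Number of malformed source rows, if any.
#' @return A `go_annotation` object.
#' @export
annotation_table <- function(terms = list(), n_skipped = 0L) {
  terms <- lapply(terms, as_term_multiset)
  structure(list(terms = terms, n_skipped = as.integer(n_skipped)),
            class = "go_annotation")
}

as_term_multiset <- function(x) {
  if (is.character(x)) {
    tab <- table(x)
    x <- structure(as.integer(tab), names = names(tab))
  }
  if (length(x) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  bad <- !is_go_id(names(x))
  if (any(bad)) {
    stop("invalid GO id(s): ", paste(names(x)[bad], collapse = ", "))
  }
  if (any(x < 1)) stop("occurrence counts must be >= 1")
  counts <- as.integer(x)
  names(counts) <- names(x)
  counts[order(names(counts))]
}

is_go_id <- function(x) grepl("^GO:[0-9]{7}$", x)

#' Look up the GO-term multiset of an accession
#'
#' An absent accession yields the empty multiset, not an error: a protein
#' with no GOA entry simply has no GO terms (its GO vector will be all
#' zeros).
#'
#' @param table A `go_annotation` object.
#' @param accession Accession string.
#' @return Named integer vector of GO-term occurrence counts (possibly
#'   empty).
#' @export
go_terms <- function(table, accession) {
  stopifnot(inherits(table, "go_annotation"), is.character(accession),
            length(accession) == 1L)
  ts <- table$terms[[accession]]
  if (is.null(ts)) structure(integer(0), names = character(0)) else ts
}

#' @export
print.go_annotation <- function(x, ...) {
  n_occ <- sum(vapply(x$terms, sum, 0L))
  cat(sprintf("GO annotation table: %d accession(s), %d term occurrence(s)",
              length(x$terms), n_occ), "\n")
  if (x$n_skipped > 0L) {
    cat(sprintf("  (%d malformed source row(s) skipped)\n", x$n_skipped))
  }
  invisible(x)
}

#' Parse BLAST tabular (outfmt 6) output into a ranked homolog list
#'
#' Reads 12-column tab-separated BLAST output (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), keeps the rows
#' of one query, removes the query's own accession, de-duplicates subjects
#' keeping the best bit-score, and ranks by descending bit-score (ties:
#' ascending e-value, then lexicographic subject accession).
#'
#' @param file Path (plain or gzipped) or connection.
#' @param query_id Query sequence id whose rows to keep; `NULL` keeps all
#'   rows (single-query file).
#' @param self Accession to drop as a self-hit (exact string match).
#' @return A `homolog_hits` data frame with columns `subject`, `evalue`,
#'   `bitscore`, carrying the query id as attribute `query`.
#' @export
read_blast_tab <- function(file, query_id = NULL, self = NULL) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(homolog_hits(character(0), numeric(0), numeric(0),
                        query = query_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 12L
  if (any(!ok)) {
    warning(sprintf("read_blast_tab: skipped %d short row(s)", sum(!ok)))
  }
  fields <- fields[ok]
  qid <- vapply(fields, `[[`, "", 1L)
  sid <- vapply(fields, `[[`, "", 2L)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  num_ok <- !is.na(ev) & !is.na(bs)
  if (any(!num_ok)) {
    warning(sprintf("read_blast_tab: skipped %d row(s) with non-numeric evalue/bitscore",
                    sum(!num_ok)))
  }
  keep <- num_ok
  if (!is.null(query_id)) keep <- keep & qid == query_id
  homolog_hits(sid[keep], ev[keep], bs[keep], query = query_id, self = self)
}

#' Construct a ranked homolog list
#'
#' @param subject Character vector of subject accessions.
#' @param evalue,bitscore Numeric vectors, parallel to `subject`.
#' @param query Query id (attribute only).
#' @param self Optional self accession to remove.
#' @return A `homolog_hits` data frame sorted by descending bit-score
#'   (ties: ascending e-value, then subject accession), one row per subject.
#' @export
homolog_hits <- function(subject, evalue, bitscore, query = NULL,
                         self = NULL) {
  df <- data.frame(subject = as.character(subject),
                   evalue = as.numeric(evalue),
                   bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  if (!is.null(self)) df <- df[df$subject != self, , drop = FALSE]
  if (nrow(df) > 0L) {
    # de-duplicate by subject keeping best bit-score (then best e-value)
    df <- df[order(-df$bitscore, df$evalue, df$subject), , drop = FALSE]
    df <- df[!duplicated(df$subject), , drop = FALSE]
    df <- df[order(-df$bitscore, df$evalue, df$subject), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, query = query, class = c("homolog_hits", "data.frame"))
}

#' Write a homolog list as BLAST outfmt-6 rows
#'
#' Emits 12-column rows reconstructible by [read_blast_tab()]; the columns
#' not represented in a `homolog_hits` object are written as zeros.
#'
#' @param hits A `homolog_hits` object.
#' @param file Path or connection; opened in append mode when `append=TRUE`.
#' @param query Query id for column 1 (defaults to the stored attribute).
#' @param append Append to `file` instead of overwriting.
#' @export
write_blast_tab <- function(hits, file, query = attr(hits, "query"),
                            append = FALSE) {
  stopifnot(inherits(hits, "homolog_hits"))
  if (is.null(query)) query <- "query"
  rows <- sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t%s\t%s",
                  query, hits$subject,
                  format(hits$evalue, scientific = TRUE, trim = TRUE),
                  format(hits$bitscore, trim = TRUE))
  cat(rows, file = file, sep = "\n", append = append)
  invisible(file)
}

#' Read a precomputed homolog map
#'
#' A homolog map is a TSV with columns `query`, `rank`, `subject`, `evalue`,
#' `bitscore` (header optional), an alternative to raw BLAST output when the
#' search was run elsewhere.
#'
#' @param file Path (plain or gzipped) or connection.
#' @return Named list of `homolog_hits`, one per query.
#' @export
read_homolog_map <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^query\t", lines[[1L]])) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(fields) >= 5L))
  qid <- vapply(fields, `[[`, "", 1L)
  sid <- vapply(fields, `[[`, "", 3L)
  ev <- as.numeric(vapply(fields, `[[`, "", 4L))
  bs <- as.numeric(vapply(fields, `[[`, "", 5L))
  idx <- split(seq_along(qid), factor(qid, levels = unique(qid)))
  lapply(idx, function(i) homolog_hits(sid[i], ev[i], bs[i],
                                       query = qid[i[1L]]))
}

#' Resolve a protein's search keys for GO-term retrieval
#'
#' Maps a protein to the ordered accession keys used to query the annotation
#' table, according to the available input: accession only (`"ac"`), sequence
#' only (`"seq"`, top-n homolog accessions), or both (`"ac+seq"`, the true
#' accession followed by the top-n homologs). When fewer than `n` homologs
#' exist the list is simply shorter; with no homologs at all in `"seq"` mode
#' the key list is empty and the downstream GO vector is all zeros.
#'
#' @param accession The protein's own accession (may be `NA` in `"seq"`
#'   mode).
#' @param homologs A `homolog_hits` object (may be empty or `NULL`).
#' @param mode One of `"ac"`, `"seq"`, `"ac+seq"`.
#' @param n Number of homologs to use (`n >= 0`).
#' @return Character vector of accession keys (possibly empty).
#' @export
resolve_keys <- function(accession, homologs = NULL,
                         mode = c("ac", "seq", "ac+seq"), n = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 0L)
  homolog_keys <- character(0)
  if (mode != "ac") {
    if (!is.null(homologs) && nrow(homologs) > 0L) {
      homolog_keys <- utils::head(homologs$subject, n)
    }
  }
  switch(mode,
         "ac" = {
           stopifnot(is.character(accession), !is.na(accession))
           accession
         },
         "seq" = homolog_keys,
         "ac+seq" = {
           stopifnot(is.character(accession), !is.na(accession))
           c(accession, homolog_keys)
         })
}

#' Find the highest-ranked annotated homolog
#'
#' Walks the homolog ranking and returns the first accession whose GO-term
#' multiset in `table` is non-empty. This is the cascade used for novel
#' proteins whose top homologs carry no GO annotation: the second-top
#' homolog is consulted when the top one is unannotated, and so on.
#'
#' @param homologs A `homolog_hits` object.
#' @param table A `go_annotation` object.
#' @return The first annotated accession, or `NULL` when every homolog is
#'   unannotated (the caller decides the fallback).
#' @export
first_annotated_key <- function(homologs, table) {
  if (is.null(homologs) || nrow(homologs) == 0L) return(NULL)
  for (acc in homologs$subject) {
    if (length(go_terms(table, acc)) > 0L) return(acc)
  }
  NULL
}

#' Read homology evidence, sniffing the format
#'
#' Accepts either raw BLAST outfmt-6 output (12 columns, possibly several
#' queries) or a precomputed homolog-map TSV (`query rank subject evalue
#' bitscore`), and returns per-query ranked homolog lists either way.
#'
#' @param file Path (plain or gzipped) or connection.
#' @param self_hits Remove rows whose subject equals their query.
#' @return Named list of `homolog_hits`, one per query.
#' @export
read_homologs <- function(file, self_hits = TRUE) {
  lines <- read_text_lines(file)
  data <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(data) == 0L) return(list())
  ncols <- length(strsplit(data[[1L]], "\t", fixed = TRUE)[[1L]])
  maps <- if (ncols >= 12L) {
    fields <- strsplit(data, "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 12L]
    qid <- vapply(fields, `[[`, "", 1L)
    sid <- vapply(fields, `[[`, "", 2L)
    ev <- as.numeric(vapply(fields, `[[`, "", 11L))
    bs <- as.numeric(vapply(fields, `[[`, "", 12L))
    idx <- split(seq_along(qid), factor(qid, levels = unique(qid)))
    lapply(idx, function(i) {
      homolog_hits(sid[i], ev[i], bs[i], query = qid[i[1L]],
                   self = if (self_hits) qid[i[1L]] else NULL)
    })
  } else {
    read_homolog_map(file)
  }
  maps
}

# Read all lines from a path (plain or gzip; sniffed by magic bytes) or an
# open connection.
read_text_lines <- function(file) {
  if (inherits(file, "connection")) {
    return(readLines(file, warn = FALSE))
  }
  stopifnot(is.character(file), length(file) == 1L)
  con <- gzfile(file, "rt")  # gzfile reads plain text transparently
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
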