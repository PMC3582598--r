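#' Read an essential/child GO-term lookup table
#'
#' The table-lookup baseline predicts locations directly from cellular
#' component GO terms: each class lists *essential* GO terms (the term
#' denoting the compartment itself) and *child* terms (direct `is_a` /
#' `part_of` descendants, which also carry direct localization information;
#' `occurs_in` descendants are biological-process terms and are excluded).
#'
#' @param file TSV with columns `class`, `go_id`, `role`
#'   (`essential`/`child`), `relationship` (`is_a`/`part_of`, or `-` for
#'   essential terms); `#` comment lines and an optional header row are
#'   skipped. Class indices follow first appearance order.
#' @return A `go_lookup`: data frame `class_index`, `class`, `go_id`,
#'   `role`, `relationship`, with attribute `classes`.
#' @export
read_lookup_table <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^class\t", lines[[1L]])) lines <- lines[-1L]
  if (length(lines) == 0L) stop("empty lookup table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L) stop(sprintf("lookup table line %d: expected 4 columns", i))
    if (!f[[3L]] %in% c("essential", "child")) {
      stop(sprintf("lookup table line %d: unknown role '%s'", i, f[[3L]]))
    }
    if (!f[[4L]] %in% c("is_a", "part_of", "-")) {
      stop(sprintf("lookup table line %d: unknown relationship '%s'", i, f[[4L]]))
    }
    if (!is_go_id(f[[2L]])) {
      stop(sprintf("lookup table line %d: malformed GO id '%s'", i, f[[2L]]))
    }
  }
  df <- data.frame(
    class = vapply(fields, `[[`, "", 1L),
    go_id = vapply(fields, `[[`, "", 2L),
    role = vapply(fields, `[[`, "", 3L),
    relationship = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  dup <- duplicated(df[c("class", "go_id")])
  if (any(dup)) {
    warning(sprintf("lookup table: %d duplicate (class, go_id) row(s) dropped",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  classes <- unique(df$class)
  df$class_index <- match(df$class, classes)
  df <- df[c("class_index", "class", "go_id", "role", "relationship")]
  rownames(df) <- NULL
  structure(df, classes = classes, class = c("go_lookup", "data.frame"))
}

#' The packaged viral-protein lookup table
#'
#' Essential and child cellular component GO terms for the six viral
#' localization classes (viral capsid, host cell membrane, host endoplasmic
#' reticulum, host cytoplasm, host nucleus, secreted): 7 + 20 + 5 + 2 + 2 +
#' 3 explicit terms.
#'
#' @return A `go_lookup` object.
#' @export
virus_lookup_table <- function() {
  read_lookup_table(system.file("extdata", "virus_lookup_table.tsv",
                                package = "goloc", mustWork = TRUE))
}

#' Direct table-lookup localization prediction
#'
#' Matches a protein's GO-term set against the lookup table in two strict
#' tiers: all classes whose *essential* terms are hit are returned; only
#' when no essential term matches are the *child* terms consulted, again
#' returning every matching class. Essential matches therefore pre-empt
#' child matches and the two tiers are never mixed.
#'
#' @param terms Character vector (or named multiset) of GO term ids.
#' @param table A `go_lookup`.
#' @return Sorted integer vector of matched class indices, or `NULL` when
#'   neither tier matches (an *unpredictable* protein — distinct from an
#'   empty prediction, so the evaluator can count these separately).
#' @export
predict_lookup <- function(terms, table) {
  stopifnot(inherits(table, "go_lookup"))
  if (!is.character(terms)) terms <- names(as_term_multiset(terms))
  ess <- table[table$role == "essential" & table$go_id %in% terms, ]
  if (nrow(ess) > 0L) return(sort(unique(ess$class_index)))
  chl <- table[table$role == "child" & table$go_id %in% terms, ]
  if (nrow(chl) > 0L) return(sort(unique(chl$class_index)))
  NULL
}

#' Table-lookup predictions for many proteins
#'
#' @param termsets Named list of GO-term sets.
#' @param table A `go_lookup`.
#' @return Named list: each element a sorted integer vector of class
#'   indices, or `NULL` for unpredictable proteins.
#' @export
predict_lookup_all <- function(termsets, table) {
  lapply(termsets, predict_lookup, table = table)
}
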