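#' Configuration of the synthetic multi-label GO dataset generator
#'
#' The generator emulates the statistical structure the classifier relies
#' on — proteins of the same subcellular localization tend to be annotated
#' with similar sets of GO terms, with occurrence counts that repeat across
#' GOA entries — without emulating the real GO DAG or real sequences.
#' Each class owns a block of signature GO terms; a protein is annotated
#' with the signature terms of all its locations at a Poisson-like
#' annotation depth, degraded by a noise dial, and each of its synthetic
#' homologs carries a fidelity-degraded copy of that annotation.
#'
#' @param M Number of classes (>= 2).
#' @param N Number of actual proteins.
#' @param multiplicity Label-multiplicity distribution over l = 1..L. Given
#'   as integer counts summing to `N` the histogram is reproduced exactly
#'   (default the 165/39/3 single/double/triple split of the 207-protein
#'   viral benchmark shape); otherwise entries are normalized to sampling
#'   probabilities.
#' @param n_signature Signature GO terms per class (default 8, a typical
#'   count of localization-relevant annotations per compartment).
#' @param signature_overlap Number of the `n_signature` terms per class that
#'   are drawn from a block shared by *all* classes (same term ids, so only
#'   occurrence depth can distinguish classes there); the remaining terms
#'   are class-unique. 0 gives fully disjoint, separable signatures;
#'   `n_signature` makes term identity completely uninformative.
#' @param depth Mean occurrence count per annotated signature term (default
#'   3; GOA commonly repeats a term over a handful of entries). Counts are
#'   `1 + Poisson(depth - 1)`, so every annotated term occurs at least once.
#' @param depth_by_class Optional length-M vector of per-class depths (lets
#'   occurrence counts, not just term identity, carry class signal).
#' @param noise_pool Size of the noise-term pool, disjoint from every
#'   signature (default 40).
#' @param noise_rate Probability that a signature-term annotation is dropped
#'   and, independently, that each noise-pool term is annotated
#'   (default 0.1).
#' @param n_homologs Synthetic homologs per protein (default 1).
#' @param fidelity Probability a homolog retains each of its protein's
#'   annotated terms (default 0.9).
#' @param seed Integer master seed; per-protein substreams are derived from
#'   it so generation is deterministic and independent of insertion order.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(M = 6L, N = 207L,
                             multiplicity = c(165L, 39L, 3L),
                             n_signature = 8L, signature_overlap = 0L,
                             depth = 3, depth_by_class = NULL,
                             noise_pool = 40L, noise_rate = 0.1,
                             n_homologs = 1L, fidelity = 0.9,
                             seed = 1L) {
  stopifnot(M >= 2L, N >= 1L, n_signature >= 1L,
            signature_overlap >= 0L, signature_overlap <= n_signature,
            depth >= 1, noise_pool >= 0L,
            noise_rate >= 0, noise_rate <= 1,
            n_homologs >= 0L, fidelity >= 0, fidelity <= 1)
  if (length(multiplicity) > M) {
    stop("multiplicity distribution allows more labels than classes")
  }
  if (any(multiplicity < 0) || sum(multiplicity) <= 0) {
    stop("multiplicity entries must be non-negative and not all zero")
  }
  if (!is.null(depth_by_class)) {
    stopifnot(length(depth_by_class) == M, all(depth_by_class >= 1))
  }
  structure(list(M = as.integer(M), N = as.integer(N),
                 multiplicity = multiplicity,
                 n_signature = as.integer(n_signature),
                 signature_overlap = as.integer(signature_overlap),
                 depth = depth, depth_by_class = depth_by_class,
                 noise_pool = as.integer(noise_pool),
                 noise_rate = noise_rate,
                 n_homologs = as.integer(n_homologs),
                 fidelity = fidelity, seed = as.integer(seed)),
            class = "synthetic_config")
}

# stable per-protein substream seed below 2^31
substream_seed <- function(seed, i, salt = 0) {
  as.integer((abs(seed) * 69069 + i * 7919 + salt * 104729) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

signature_terms <- function(config) {
  n_unique <- config$n_signature - config$signature_overlap
  shared <- if (config$signature_overlap > 0L) {
    sprintf("GO:%07d", 2000000L + seq_len(config$signature_overlap))
  } else character(0)
  lapply(seq_len(config$M), function(m) {
    own <- if (n_unique > 0L) {
      sprintf("GO:%07d", 1000000L + (m - 1L) * n_unique + seq_len(n_unique))
    } else character(0)
    c(own, shared)
  })
}

noise_terms <- function(config) {
  if (config$noise_pool == 0L) return(character(0))
  sprintf("GO:%07d", 9000000L + seq_len(config$noise_pool))
}

draw_counts <- function(terms, depth) {
  if (length(terms) == 0L) return(structure(integer(0), names = character(0)))
  structure(1L + stats::rpois(length(terms), depth - 1), names = terms)
}

merge_multisets <- function(a, b) {
  all_terms <- union(names(a), names(b))
  out <- structure(integer(length(all_terms)), names = all_terms)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + as.integer(b)
  out[order(names(out))]
}

#' Generate a synthetic multi-label localization dataset
#'
#' Draws label sets from the configured multiplicity distribution, annotates
#' each protein's accession with its classes' signature terms (occurrence
#' counts at the configured annotation depth, degraded by the noise rate,
#' plus noise-pool terms), and emits `n_homologs` synthetic homolog
#' accessions per protein carrying fidelity-degraded copies. Everything is
#' deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return A `loc_dataset`: list with `accessions`, `labels` (list of
#'   integer label sets), `classes`, `annotations` (a `go_annotation`
#'   covering protein and homolog accessions), `homologs` (named list of
#'   `homolog_hits`), `sequences` (placeholder amino-acid strings),
#'   `signatures`, and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  M <- config$M
  N <- config$N
  sigs <- signature_terms(config)
  pool <- noise_terms(config)
  mult <- config$multiplicity
  exact <- all(mult == round(mult)) && sum(mult) == N
  ls <- if (exact) {
    with_seed(substream_seed(config$seed, 0L, 1L),
              sample(rep(seq_along(mult), times = mult)))
  } else {
    p <- mult / sum(mult)
    with_seed(substream_seed(config$seed, 0L, 1L),
              sample(seq_along(mult), N, replace = TRUE, prob = p))
  }
  accessions <- sprintf("P%05d", seq_len(N))
  labels <- vector("list", N)
  terms <- list()
  homologs <- vector("list", N)
  sequences <- character(N)
  depth_of <- function(m) {
    if (is.null(config$depth_by_class)) config$depth else config$depth_by_class[m]
  }
  for (i in seq_len(N)) {
    with_seed(substream_seed(config$seed, i), {
      lab <- sort(sample.int(M, ls[i]))
      labels[[i]] <- lab
      ann <- structure(integer(0), names = character(0))
      for (m in lab) {
        keep <- stats::runif(length(sigs[[m]])) >= config$noise_rate
        ann <- merge_multisets(ann, draw_counts(sigs[[m]][keep], depth_of(m)))
      }
      if (length(pool) > 0L && config$noise_rate > 0) {
        on_terms <- pool[stats::runif(length(pool)) < config$noise_rate]
        ann <- merge_multisets(ann, draw_counts(on_terms, config$depth))
      }
      terms[[accessions[i]]] <- ann
      # homologs: degraded copies under distinct synthetic accessions
      if (config$n_homologs > 0L) {
        hacc <- sprintf("H%05d.%d", i, seq_len(config$n_homologs))
        for (k in seq_len(config$n_homologs)) {
          keep <- stats::runif(length(ann)) < config$fidelity
          hann <- ann[keep]
          if (length(pool) > 0L && config$noise_rate > 0) {
            on_terms <- pool[stats::runif(length(pool)) < config$noise_rate]
            hann <- merge_multisets(hann, draw_counts(on_terms, config$depth))
          }
          terms[[hacc[k]]] <- hann
        }
        homologs[[i]] <- homolog_hits(
          subject = hacc,
          evalue = 10^-(60 - 12 * (seq_len(config$n_homologs) - 1L)),
          bitscore = 250 - 25 * (seq_len(config$n_homologs) - 1L),
          query = accessions[i])
      } else {
        homologs[[i]] <- homolog_hits(character(0), numeric(0), numeric(0),
                                      query = accessions[i])
      }
      sequences[i] <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                                   80, replace = TRUE), collapse = "")
    })
  }
  names(homologs) <- accessions
  structure(list(accessions = accessions, labels = labels,
                 classes = sprintf("class_%d", seq_len(M)),
                 annotations = annotation_table(terms),
                 homologs = homologs, sequences = sequences,
                 signatures = sigs, config = config),
            class = "loc_dataset")
}

#' @export
print.loc_dataset <- function(x, ...) {
  cp <- count_proteins(x$labels, M = x$config$M)
  cat(sprintf("Multi-label localization dataset: %d actual / %d locative proteins, M = %d\n",
              cp$n_act, cp$n_loc, x$config$M))
  mult <- cp$n_act_by_multiplicity
  shown <- which(mult > 0)
  cat("  multiplicity:", paste(sprintf("l=%d: %d", shown, mult[shown]),
                               collapse = ", "), "\n")
  invisible(x)
}

#' The packaged virus-shaped synthetic benchmark
#'
#' A deterministic dataset with the shape of the 6-class viral benchmark —
#' 207 actual proteins of which 165 carry one label, 39 two and 3 three
#' (252 locative proteins) — generated with disjoint class signatures, no
#' noise and perfect-fidelity homologs, so the classes are separable by
#' construction. Contents are synthetic; only the shape mirrors the
#' benchmark.
#'
#' @param seed Master seed (default 1001).
#' @return A `loc_dataset`.
#' @export
virus_fixture <- function(seed = 1001L) {
  generate_dataset(synthetic_config(
    M = 6L, N = 207L, multiplicity = c(165L, 39L, 3L),
    n_signature = 8L, signature_overlap = 0L, depth = 3,
    noise_pool = 40L, noise_rate = 0, n_homologs = 1L, fidelity = 1,
    seed = seed))
}

#' Write a dataset to disk in standard interchange formats
#'
#' Emits a GAF 2.1 annotation file (one row per term occurrence, so term
#' frequencies survive the round trip), a labels TSV with a class-catalog
#' header, the homolog map in BLAST outfmt-6 form (so the real parser is
#' exercised end-to-end), a placeholder FASTA, and a JSON manifest echoing
#' the generator configuration.
#'
#' @param ds A `loc_dataset`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "loc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gaf = file.path(dir, "annotations.gaf"),
             labels = file.path(dir, "labels.tsv"),
             homologs = file.path(dir, "homologs.tsv"),
             fasta = file.path(dir, "proteins.fasta"),
             manifest = file.path(dir, "manifest.json"))
  write_gaf(ds$annotations, paths["gaf"])
  write_labels(ds$accessions, ds$labels, ds$classes, paths["labels"])
  lines <- character(0)
  con <- file(paths["homologs"], "w")
  for (acc in ds$accessions) {
    hits <- ds$homologs[[acc]]
    if (nrow(hits) > 0L) write_blast_tab(hits, con, query = acc)
    if (nrow(hits) > 0L) cat("\n", file = con)
  }
  close(con)
  writeLines(as.vector(rbind(paste0(">", ds$accessions), ds$sequences)),
             paths["fasta"])
  cfg <- unclass(ds$config)
  cfg$depth_by_class <- if (is.null(cfg$depth_by_class)) NULL else cfg$depth_by_class
  jsonlite::write_json(cfg, paths["manifest"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Write an annotation table as a GAF 2.1 file
#'
#' One data row per term occurrence; repeated annotations of the same term
#' to the same accession become repeated rows, which is exactly how term
#' frequencies arise in a real association file.
#'
#' @param table A `go_annotation`.
#' @param file Output path.
#' @export
write_gaf <- function(table, file) {
  stopifnot(inherits(table, "go_annotation"))
  rows <- character(0)
  for (acc in names(table$terms)) {
    ts <- table$terms[[acc]]
    go <- rep(names(ts), times = as.integer(ts))
    if (length(go) == 0L) next
    rows <- c(rows, sprintf(
      "UniProtKB\t%s\t%s\t\t%s\tGO_REF:0000000\tIEA\t\tC\t\t\tprotein\ttaxon:0000\t20110308\tGOA\t\t",
      acc, acc, go))
  }
  writeLines(c("!gaf-version: 2.1", rows), file)
  invisible(file)
}
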