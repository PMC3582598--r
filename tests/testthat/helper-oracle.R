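# Independent oracles and fixture builders for the test suite.

# Brute-force soft-margin linear SVM via direct minimization of the primal
# objective 0.5*||w||^2 + C * sum(hinge). Independent of the package's
# dual-form path (and of libsvm): plain Nelder-Mead from several starts.
primal_svm_oracle <- function(x, y, C) {
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  obj <- function(par) {
    w <- par[-length(par)]
    b <- par[length(par)]
    f <- as.numeric(x %*% w) + b
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * f))
  }
  starts <- rbind(rep(0, ncol(x) + 1L),
                  c(as.numeric(colMeans(x[y > 0, , drop = FALSE]) -
                                 colMeans(x[y < 0, , drop = FALSE])), 0),
                  rep(0.1, ncol(x) + 1L))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(w = best$par[-length(best$par)], b = best$par[length(best$par)],
       value = best$value)
}

# Tiny GAF text fixture: one row per (accession, go) occurrence, 17 columns.
gaf_text <- function(pairs, extra_lines = character(0)) {
  rows <- vapply(pairs, function(p) {
    sprintf("UniProtKB\t%s\t%s\t\t%s\tGO_REF:0000000\tIEA\t\tC\t\t\tprotein\ttaxon:0000\t20110308\tGOA\t\t",
            p[[1L]], p[[1L]], p[[2L]])
  }, "")
  c("!gaf-version: 2.1", extra_lines, rows)
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# BLAST outfmt-6 row
blast_row <- function(q, s, evalue, bitscore) {
  sprintf("%s\t%s\t90\t100\t5\t1\t1\t100\t1\t100\t%s\t%s",
          q, s, format(evalue, scientific = TRUE), format(bitscore))
}

# Random GO-term multiset over a small vocabulary
random_multiset <- function(vocab, max_count = 4L) {
  k <- sample.int(length(vocab), sample.int(length(vocab), 1L))
  structure(sample.int(max_count, length(k), replace = TRUE),
            names = vocab[k])
}

# Random small mlsvm training problem (separated class means, multi-label)
random_toy_problem <- function(n = 12L, t_dim = 5L, M = 3L) {
  centers <- matrix(stats::rpois(M * t_dim, 2) + 3 * diag(M)[, rep(1:M, length.out = t_dim)],
                    nrow = M)
  labs <- lapply(seq_len(n), function(i) {
    l <- sample.int(2L, 1L)
    sort(sample.int(M, l))
  })
  x <- t(vapply(labs, function(l) {
    base <- colMeans(centers[l, , drop = FALSE])
    pmax(0, base + stats::rnorm(t_dim, sd = 0.5))
  }, numeric(t_dim)))
  list(x = x, labels = labs, M = M)
}
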