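test_that("transformed labels are +1 exactly on the label set", {
  expect_equal(transform_labels(2, 3), c(-1, 1, -1))
  expect_equal(transform_labels(c(1, 3), 3), c(1, -1, 1))
  expect_equal(transform_labels(1:3, 3), c(1, 1, 1))
  expect_error(transform_labels(integer(0), 3), "empty")
  expect_error(transform_labels(4, 3), "outside")
})

test_that("training agrees with a brute-force primal oracle on a 2-D toy", {
  x <- rbind(c(3, 0), c(4, 1), c(0, 3), c(1, 4))
  labels <- list(1L, 1L, 2L, 2L)
  model <- mlsvm(x, labels, M = 2, kernel = kernel_spec("linear"), C = 0.1)
  scores <- t(apply(x, 1, function(v) svm_scores(model, v)))
  # every training vector classified with the correct sign for its class
  expect_true(all(scores[1:2, 1] > 0), info = "class-1 positives")
  expect_true(all(scores[3:4, 1] < 0))
  expect_true(all(scores[3:4, 2] > 0))
  expect_true(all(scores[1:2, 2] < 0))
  # independent check: direct primal minimization yields the same signs
  for (m in 1:2) {
    y <- vapply(labels, function(l) if (m %in% l) 1 else -1, 0)
    oracle <- primal_svm_oracle(x, y, C = 0.1)
    f_oracle <- as.numeric(x %*% oracle$w) + oracle$b
    expect_equal(sign(f_oracle), sign(scores[, m]))
    # and the oracle's primal objective matches the dual solution's
    w_dual <- model$svms[[m]]$w
    b_dual <- model$svms[[m]]$b
    primal_of <- function(w, b) {
      0.5 * sum(w^2) + 0.1 * sum(pmax(0, 1 - y * (as.numeric(x %*% w) + b)))
    }
    expect_equal(primal_of(w_dual, b_dual), oracle$value, tolerance = 1e-4)
  }
})

test_that("dual coefficients satisfy the KKT box and balance conditions", {
  set.seed(21)
  for (i in 1:10) {
    prob <- random_toy_problem()
    model <- suppressWarnings(mlsvm(prob$x, prob$labels, M = prob$M, C = 0.1))
    for (cls in model$svms) {
      if (isTRUE(cls$stub)) next
      expect_lte(max(abs(cls$coef)), 0.1 + 1e-8)     # |alpha y| <= C
      expect_lt(abs(sum(cls$coef)), 1e-8)            # sum alpha y = 0
    }
  }
})

test_that("a multi-label protein is positive for all its classes' SVMs", {
  x <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(4, 4, 0))
  labels <- list(1L, 2L, 3L, c(1L, 2L))
  model <- mlsvm(x, labels, M = 3, C = 0.1)
  s <- svm_scores(model, x[4, ])
  expect_gt(s[1], 0)
  expect_gt(s[2], 0)
  expect_lt(s[3], 0)
})

test_that("a class with no members becomes a stub that can never win", {
  x <- rbind(c(3, 0), c(4, 1), c(0, 3), c(1, 4))
  labels <- list(1L, 1L, 2L, 2L)
  expect_warning(model <- mlsvm(x, labels, M = 3, C = 0.1), "stub")
  s <- svm_scores(model, c(2, 2))
  expect_identical(s[3], -Inf)
  expect_false(3L %in% decide(s)$set)
  # all-stub models are refused outright
  expect_error(suppressWarnings(mlsvm(x, list(1L, 1L, 1L, 1L), M = 1, C = 0.1)),
               "stub")
})

test_that("single-vector scoring reduces to the single-key score form", {
  set.seed(22)
  prob <- random_toy_problem()
  model <- suppressWarnings(mlsvm(prob$x, prob$labels, M = prob$M, C = 0.1))
  q <- prob$x[1, ] + 0.25
  qs <- new_query_set(q, weights = 1)
  expect_equal(svm_scores(model, qs), svm_scores(model, q))
})

test_that("linear-kernel fusion equivalence: score(qs) == score(fuse(qs))", {
  set.seed(23)
  for (i in 1:20) {
    prob <- random_toy_problem()
    model <- suppressWarnings(mlsvm(prob$x, prob$labels, M = prob$M, C = 0.1))
    k <- sample(2:4, 1)
    vecs <- matrix(stats::rpois(k * ncol(prob$x), 2), nrow = k)
    w <- stats::runif(k); w <- w / sum(w)
    qs <- new_query_set(vecs, w)
    expect_equal(svm_scores(model, qs), svm_scores(model, fuse(qs)),
                 tolerance = 1e-9)
  }
})

test_that("dual-form and weight-form scores agree for linear kernels", {
  set.seed(24)
  for (i in 1:100) {
    prob <- random_toy_problem(n = 10L, t_dim = 4L, M = 2L)
    model <- suppressWarnings(mlsvm(prob$x, prob$labels, M = prob$M, C = 0.1))
    q <- new_query_set(matrix(stats::rpois(8, 2), nrow = 2))
    d <- svm_scores(model, q, form = "dual")
    w <- svm_scores(model, q, form = "weight")
    finite <- is.finite(d)
    expect_equal(d[finite], w[finite], tolerance = 1e-9)
  }
})

test_that("a zero query vector scores the per-class biases", {
  x <- rbind(c(3, 0), c(4, 1), c(0, 3), c(1, 4))
  model <- mlsvm(x, list(1L, 1L, 2L, 2L), M = 2, C = 0.1)
  s <- svm_scores(model, c(0, 0))
  expect_equal(s, vapply(model$svms, `[[`, 0, "b"))
})

test_that("non-linear kernels score through the stored dual expansion", {
  set.seed(25)
  prob <- random_toy_problem(n = 14L, t_dim = 4L, M = 2L)
  for (kern in list(kernel_spec("rbf", sigma = 4),
                    kernel_spec("polynomial", degree = 2))) {
    model <- suppressWarnings(
      mlsvm(prob$x, prob$labels, M = prob$M, kernel = kern, C = 0.1))
    q <- stats::rpois(4, 2)
    s <- svm_scores(model, q)
    expect_true(all(is.finite(s)))
    # manual expansion for class 1
    cls <- model$svms[[1]]
    if (!isTRUE(cls$stub)) {
      kvec <- kernel_matrix(kern, matrix(q, 1), cls$sv)
      expect_equal(s[1], as.numeric(kvec %*% cls$coef) + cls$b)
    }
  }
})

test_that("the decision rule takes positive scores, else the argmax", {
  expect_equal(decide(c(0.5, -0.2, 0.1)), list(set = c(1L, 3L), fallback = FALSE))
  expect_equal(decide(c(-0.3, -0.1, -0.5)), list(set = 2L, fallback = TRUE))
  expect_equal(decide(c(-0.1, -0.1))$set, 1L)  # tie -> smallest index
  # never empty over random score vectors
  set.seed(26)
  for (i in 1:200) {
    s <- stats::rnorm(sample(2:6, 1))
    d <- decide(s)
    expect_gt(length(d$set), 0L)
    expect_identical(d$fallback, all(s <= 0))
  }
})

test_that("score dimension mismatches are refused", {
  x <- rbind(c(3, 0), c(0, 3), c(4, 1), c(1, 4))
  model <- mlsvm(x, list(1L, 2L, 1L, 2L), M = 2, C = 0.1)
  expect_error(svm_scores(model, c(1, 2, 3)), "dimension mismatch")
})

test_that("duplicating a positive-margin point never flips its own sign", {
  set.seed(27)
  for (i in 1:10) {
    prob <- random_toy_problem(n = 10L, t_dim = 4L, M = 2L)
    model <- suppressWarnings(mlsvm(prob$x, prob$labels, M = prob$M, C = 0.1))
    for (r in seq_len(nrow(prob$x))) {
      m <- prob$labels[[r]][1L]
      s <- svm_scores(model, prob$x[r, ])[m]
      if (!is.finite(s) || s <= 1e-6) next
      x2 <- rbind(prob$x, prob$x[r, ])
      labs2 <- c(prob$labels, prob$labels[r])
      model2 <- suppressWarnings(mlsvm(x2, labs2, M = prob$M, C = 0.1))
      expect_gt(svm_scores(model2, prob$x[r, ])[m], 0)
      break
    }
  }
})

test_that("LOOCV is exact on a separable set and order-independent", {
  cfg <- synthetic_config(M = 4, N = 24, multiplicity = c(18, 5, 1),
                          noise_rate = 0, fidelity = 1, n_homologs = 1,
                          seed = 5)
  ds <- generate_dataset(cfg)
  res <- loocv(ds, mode = "ac")
  expect_equal(res$report$actual_accuracy, 1.0)
  # brute-force check of each fold: nearest class-signature by cosine
  sigs <- ds$signatures
  for (i in seq_along(ds$accessions)) {
    ts <- go_terms(ds$annotations, ds$accessions[i])
    hit <- vapply(sigs, function(sg) any(names(ts) %in% sg), TRUE)
    expect_identical(which(hit), sort(ds$labels[[i]]),
                     ignore_attr = TRUE)
  }
  # permuting the dataset leaves the multiset of predictions unchanged
  perm <- sample(length(ds$accessions))
  ds_perm <- ds
  ds_perm$accessions <- ds$accessions[perm]
  ds_perm$labels <- ds$labels[perm]
  ds_perm$homologs <- ds$homologs[perm]
  res_perm <- loocv(ds_perm, mode = "ac")
  expect_identical(sort(res_perm$details$predicted),
                   sort(res$details$predicted))
})

test_that("LOOCV refuses fewer than three proteins", {
  cfg <- synthetic_config(M = 2, N = 2, multiplicity = c(2),
                          noise_rate = 0, seed = 1)
  ds <- generate_dataset(cfg)
  expect_error(loocv(ds), "at least 3")
})

test_that("conflicting identical vectors keep accuracies within bounds", {
  tab <- annotation_table(list(P1 = c("GO:0000001" = 2L),
                               P2 = c("GO:0000001" = 2L),
                               P3 = c("GO:0000001" = 2L),
                               P4 = c("GO:0000001" = 2L)))
  ds <- list(accessions = sprintf("P%d", 1:4),
             labels = list(1L, 2L, 1L, 2L),
             classes = c("a", "b"),
             annotations = tab,
             homologs = stats::setNames(replicate(4,
               homolog_hits(character(0), numeric(0), numeric(0)),
               simplify = FALSE), sprintf("P%d", 1:4)))
  res <- suppressWarnings(loocv(ds, mode = "ac"))
  expect_gte(res$report$actual_accuracy, 0)
  expect_lte(res$report$actual_accuracy, 1)
})

test_that("models round-trip through versioned JSON serialization", {
  cfg <- synthetic_config(M = 3, N = 15, multiplicity = c(12, 3),
                          noise_rate = 0, seed = 9)
  ds <- generate_dataset(cfg)
  model <- train_goloc(ds, mode = "ac")
  f <- tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  q <- query_set(ds$accessions[1], ds$annotations, model$subspace)
  expect_equal(svm_scores(back$model, q), svm_scores(model$model, q),
               tolerance = 1e-12)
  expect_identical(as.character(back$subspace), as.character(model$subspace))
})
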