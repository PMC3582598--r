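make_sets <- function(mult) {
  # label sets with a given multiplicity histogram (classes cycle)
  unlist(lapply(seq_along(mult), function(l) {
    replicate(mult[l], seq_len(l), simplify = FALSE)
  }), recursive = FALSE)
}

test_that("actual/locative counts follow the multiplicity histogram", {
  virus <- make_sets(c(165, 39, 3))
  cp <- count_proteins(virus, M = 6)
  expect_identical(cp$n_act, 207L)
  expect_identical(cp$n_loc, 252L)
  plant <- make_sets(c(904, 71, 3))
  cp2 <- count_proteins(plant, M = 12)
  expect_identical(cp2$n_act, 978L)
  expect_identical(cp2$n_loc, 1055L)
  cp3 <- count_proteins(list(c(1L, 2L, 3L)), M = 3)
  expect_identical(cp3$n_act, 1L)
  expect_identical(cp3$n_loc, 3L)
  expect_error(count_proteins(list(integer(0))), "empty")
  # invariants: N_act = sum n_act(m), N_loc = sum m * n_act(m)
  expect_identical(sum(cp$n_act_by_multiplicity), cp$n_act)
  expect_equal(sum(seq_len(6) * cp$n_act_by_multiplicity), cp$n_loc)
})

test_that("locative accuracy counts intersection hits over N_loc", {
  expect_equal(locative_accuracy(list(1L, c(1L, 2L)), list(1L, 1L)), 2 / 3)
  truth <- make_sets(c(4, 2, 1))
  expect_equal(locative_accuracy(truth, truth), 1)
  all6 <- lapply(truth, function(x) 1:6)
  expect_equal(locative_accuracy(truth, all6), 1)
})

test_that("actual accuracy is the exact-set-match fraction", {
  expect_equal(actual_accuracy(list(1L, c(1L, 2L)), list(1L, 1L)), 0.5)
  truth <- make_sets(c(4, 2, 1))
  expect_equal(actual_accuracy(truth, truth), 1)
  # order within a set is irrelevant
  expect_equal(actual_accuracy(list(c(1L, 2L)), list(c(2L, 1L))), 1)
})

test_that("the all-labels degenerate predictor separates the two metrics", {
  truth <- make_sets(c(165, 39, 3))          # no true set has 6 labels
  all6 <- lapply(truth, function(x) 1:6)
  expect_equal(locative_accuracy(truth, all6), 1)
  expect_equal(actual_accuracy(truth, all6), 0)
  # and exactly reproduces the extreme-case argument in general:
  # actual accuracy = fraction of proteins whose true set is the full set
  truth2 <- c(truth, list(1:6))
  expect_equal(actual_accuracy(truth2, lapply(truth2, function(x) 1:6)),
               1 / length(truth2))
})

test_that("exact multi-label agreement implies locative perfection", {
  set.seed(41)
  for (i in 1:20) {
    truth <- replicate(15, sort(sample.int(5, sample.int(3, 1))),
                       simplify = FALSE)
    pred <- truth
    if (actual_accuracy(truth, pred) == 1) {
      expect_equal(locative_accuracy(truth, pred), 1)
    }
  }
})

test_that("single-label problems collapse the two accuracies", {
  set.seed(42)
  truth <- replicate(30, sample.int(4, 1), simplify = FALSE)
  pred <- replicate(30, sample.int(4, 1), simplify = FALSE)
  expect_equal(locative_accuracy(truth, pred), actual_accuracy(truth, pred))
  cp <- count_proteins(truth, M = 4)
  expect_equal(cp$n_loc, cp$n_act)
})

test_that("over/equal/under distribution buckets by size difference", {
  d <- prediction_distribution(list(1L, c(1L, 2L)),
                               list(c(1L, 2L), c(1L, 2L)))
  expect_identical(d$counts["over", "k=1"], 1L)
  expect_identical(d$counts["equal", "k=0"], 1L)
  expect_identical(unname(d$totals["under"]), 0L)
  d2 <- prediction_distribution(list(c(1L, 2L, 3L)), list(1L))
  expect_identical(d2$counts["under", "k=2"], 1L)
  truth <- make_sets(c(5, 3))
  d3 <- prediction_distribution(truth, truth)
  expect_identical(unname(d3$totals["equal"]), length(truth))
})

test_that("distribution buckets partition the actual proteins", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    truth <- replicate(n, sort(sample.int(6, sample.int(3, 1))),
                       simplify = FALSE)
    pred <- replicate(n, sort(sample.int(6, sample.int(4, 1))),
                      simplify = FALSE)
    d <- prediction_distribution(truth, pred)
    expect_identical(sum(d$counts), n)
    expect_identical(unname(sum(d$totals)), n)
  }
})

test_that("per-multiplicity accuracy stratifies by |true set|", {
  truth <- list(1L, 2L, c(1L, 2L))
  pred <- list(1L, 1L, c(1L, 2L))
  pm <- per_multiplicity_accuracy(truth, pred)
  expect_equal(pm$accuracy[pm$l == 1], 0.5)
  expect_equal(pm$accuracy[pm$l == 2], 1)
  # absent strata are absent, not 0/0
  expect_identical(pm$l, c(1L, 2L))
  pm2 <- per_multiplicity_accuracy(truth, truth)
  expect_true(all(pm2$accuracy == 1))
})

test_that("empty predicted sets are tolerated as under-prediction", {
  truth <- list(1L, c(1L, 2L))
  pred <- list(NULL, c(1L, 2L))
  expect_equal(actual_accuracy(truth, pred), 0.5)
  expect_equal(locative_accuracy(truth, pred), 2 / 3)
  d <- prediction_distribution(truth, pred)
  expect_identical(unname(d$totals["under"]), 1L)
})

test_that("the full report is internally consistent and printable", {
  set.seed(44)
  truth <- replicate(20, sort(sample.int(4, sample.int(2, 1))),
                     simplify = FALSE)
  pred <- replicate(20, sort(sample.int(4, sample.int(2, 1))),
                    simplify = FALSE)
  rep <- evaluate_predictions(truth, pred, M = 4)
  expect_equal(rep$locative_accuracy, locative_accuracy(truth, pred))
  expect_equal(rep$actual_accuracy, actual_accuracy(truth, pred))
  expect_identical(unname(sum(rep$distribution$totals)), rep$n_act)
  expect_output(print(rep), "Overall locative accuracy")
  # per-class hits sum to the overall locative hits
  expect_equal(sum(rep$per_class$hits), rep$locative_hits)
  # serialization smoke: both formats
  fj <- tempfile(fileext = ".json"); ft <- tempfile(fileext = ".tsv")
  write_eval_report(rep, fj)
  write_eval_report(rep, ft)
  expect_true(file.exists(fj) && file.exists(ft))
  expect_equal(jsonlite::read_json(fj)$actual_accuracy, rep$actual_accuracy)
})
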