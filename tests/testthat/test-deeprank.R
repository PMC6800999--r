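# Small shared dataset for ensemble tests (10 targets keeps folds legal
# while staying fast).
qa_train_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeQADataset(10, 10, toy_qa_noise(oracle = TRUE), seed = 42)
    cache
  }
})

test_that("target-wise folds partition targets evenly and deterministically", {
  ds <- data.frame(target_id = rep(sprintf("T%02d", 1:20), each = 3))
  folds <- targetWiseFolds(ds, 10, seed = 1)
  expect_equal(length(folds), 10L)
  expect_true(all(lengths(folds) == 2L))
  expect_setequal(unlist(folds), unique(ds$target_id))
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  expect_identical(folds, targetWiseFolds(ds, 10, seed = 1))
  ds9 <- data.frame(target_id = sprintf("T%02d", 1:9))
  expect_error(targetWiseFolds(ds9, 10), "at least 10")
  # sizes differ by at most one for non-divisible counts
  ds23 <- data.frame(target_id = sprintf("T%02d", 1:23))
  expect_lte(diff(range(lengths(targetWiseFolds(ds23, 10, 2)))), 1L)
})

test_that("the trained ensemble recovers an oracle feature", {
  ds <- qa_train_small()
  ens <- trainEnsemble(ds, arch_grid = list(8), seed = 7)
  expect_s4_class(ens, "QAEnsemble")
  expect_equal(length(ens@level1), 10L)
  test <- makeQADataset(5, 10, toy_qa_noise(oracle = TRUE), seed = 901)
  loss <- datasetSelectionLoss(test, function(df) predictDeepRank(ens, df))
  expect_lt(loss, 0.02)
  expect_gt(cor(predictDeepRank(ens, test), test$gdt), 0.9)
})

test_that("training is deterministic and honours a single-candidate grid", {
  ds <- qa_train_small()
  e1 <- trainEnsemble(ds, arch_grid = list(6), seed = 3)
  e2 <- trainEnsemble(ds, arch_grid = list(6), seed = 3)
  expect_identical(predictDeepRank(e1, ds), predictDeepRank(e2, ds))
  for (m in e1@level1) expect_equal(m$arch, 6)
})

test_that("predictions are clipped, schema-checked and per-model", {
  ds <- qa_train_small()
  ens <- trainEnsemble(ds, arch_grid = list(6), seed = 3)
  p <- predictDeepRank(ens, ds)
  expect_true(all(p >= 0 & p <= 1))
  pa <- predictDeepRankAvg(ens, ds)
  expect_true(all(pa >= 0 & pa <= 1))
  # avg equals the hand-computed mean of the 10 member outputs
  X <- as.matrix(ds[, ens@featureNames])
  s1 <- vapply(ens@level1, function(m)
    ContactFold:::mlpPredict(m$net,
      ContactFold:::.standardize_apply(X, m$norm)), numeric(nrow(X)))
  expect_equal(unname(pa), unname(pmin(pmax(rowMeans(s1), 0), 1)))
  expect_true(all(pa >= apply(s1, 1, min) - 1e-9 &
                    pa <= apply(s1, 1, max) + 1e-9))
  # permuting rows permutes scores identically (per-model function)
  idx <- sample(nrow(ds))
  expect_equal(unname(predictDeepRank(ens, ds[idx, ])), unname(p[idx]))
  bad <- ds[, setdiff(names(ds), "f_ss")]
  expect_error(predictDeepRank(ens, bad), "f_ss")
})

test_that("ranking orders by score with lexicographic ties", {
  rk <- rankModels(c(A = 0.9, B = 0.7))
  expect_equal(rk$model_id, c("A", "B"))
  expect_equal(rankModels(c(B = 0.5, A = 0.5))$model_id, c("A", "B"))
  sc <- c(m3 = 0.2, m1 = 0.9, m2 = 0.5)
  expect_equal(rankModels(sc)$model_id, rev(rankModels(-sc)$model_id))
})

test_that("selection loss is the gap to the best model", {
  truth <- c(a = 0.8, b = 0.7, c = 0.3)
  expect_equal(selectionLoss(rankModels(c(a = 1, b = 0.5, c = 0.1)), truth), 0)
  expect_equal(selectionLoss(rankModels(c(a = 0.1, b = 1, c = 0.5)), truth),
               0.1, tolerance = 1e-12)
  # invariant to the ranking below position 1
  expect_equal(selectionLoss(c("b", "a", "c"), truth),
               selectionLoss(c("b", "c", "a"), truth))
  expect_error(selectionLoss(c("z"), truth), "missing")
  # a degenerate pool where the top pick is the best model scores 0 loss
  expect_equal(selectionLoss(rankModels(c(a = 0.6)), truth["a"]), 0)
})

test_that("constant labels train with a zero-variance warning", {
  ds <- qa_train_small()
  ds$gdt <- 0.5
  expect_warning(trainEnsemble(ds, arch_grid = list(4), seed = 1),
                 "zero-variance")
})

test_that("ensembles serialise to text and reload exactly", {
  ds <- qa_train_small()
  ens <- trainEnsemble(ds, arch_grid = list(6), seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  saveEnsemble(ens, path)
  back <- loadEnsemble(path)
  expect_equal(predictDeepRank(back, ds), predictDeepRank(ens, ds))
  expect_error(loadEnsemble(withr::local_tempfile(fileext = ".txt",
                                                  lines = "list()")),
               "archive")
})
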