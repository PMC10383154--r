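test_that("degenerate single-group labels give a perfect 1x1 report", {
  fx <- separable_scores(n_per = 20, centers = 0)
  rep <- trainEval(fx$scores, fx$labels, classifierSpec("knn", seed = 1), 2)
  expect_equal(meanAccuracy(rep), 100)
  expect_identical(dim(confusionMatrix(rep)), c(1L, 1L))
  expect_length(misclassifiedIds(rep), 0)
})

test_that("all three classifiers are perfect on separable clusters", {
  fx <- separable_scores(n_per = 25, centers = c(-5, 5), seed = 61)
  for (m in c("knn", "random_forest", "svm")) {
    rep <- trainEval(fx$scores, fx$labels,
                     classifierSpec(m, nSearchDraws = 3L, seed = 7), 2)
    expect_equal(meanAccuracy(rep), 100, info = m)
    expect_equal(sdAccuracy(rep), 0, info = m)
  }
})

test_that("label permutation drops accuracy to chance (no leakage)", {
  fx <- separable_scores(n_per = 50, centers = c(-9, -3, 3, 9), seed = 62)
  set.seed(63)
  shuffled <- setNames(sample(unname(fx$labels)), names(fx$labels))
  rep <- trainEval(fx$scores, shuffled,
                   classifierSpec("knn", nSearchDraws = 5L, seed = 8), 4)
  se <- 100 * sqrt(0.25 * 0.75 / 200)
  expect_lt(abs(meanAccuracy(rep) - 25), 3 * se)
})

test_that("reports are internally consistent and deterministic per seed", {
  fx <- separable_scores(n_per = 15, centers = c(-4, 0, 4), sd = 1.5,
                         seed = 64)
  spec <- classifierSpec("random_forest", nSearchDraws = 2L, seed = 3)
  rep <- trainEval(fx$scores, fx$labels, spec, 3)
  cm <- confusionMatrix(rep)
  expect_equal(sum(cm), length(fx$labels))
  expect_equal(unname(rowSums(cm)),
               as.integer(table(fx$labels)[rownames(cm)]))
  pct <- sweep(cm, 1, rowSums(cm), "/") * 100
  expect_equal(unname(rowSums(pct)), rep(100, nrow(cm)), tolerance = 1e-9)
  expect_equal(length(misclassifiedIds(rep)), sum(cm) - sum(diag(cm)))

  rep2 <- trainEval(fx$scores, fx$labels, spec, 3)
  expect_equal(foldAccuracy(rep), foldAccuracy(rep2))
  expect_identical(misclassifiedIds(rep), misclassifiedIds(rep2))

  expect_error(trainEval(fx$scores, fx$labels, spec, 99), "exceeds")
  few <- fx$labels
  few[1:43] <- "A"  # group C left with 2 members < 5 folds
  expect_error(trainEval(fx$scores, few, spec, 2), "smaller than cvFolds")
})

test_that("stratified folds balance group proportions within one sample", {
  y <- rep(c("a", "b", "c"), times = c(40, 25, 11))
  set.seed(5)
  folds <- pgxStrat:::.stratified_folds(y, 5L)
  for (cl in unique(y)) {
    per_fold <- table(factor(folds[y == cl], levels = 1:5))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("PC sweep finds the plateau and breaks ties by smallest count", {
  fx <- separable_scores(n_per = 20, centers = c(-5, 5), n_pcs = 6, seed = 65)
  sw <- sweepPCs(fx$scores, fx$labels,
                 classifierSpec("knn", nSearchDraws = 2L, seed = 2), 2:4)
  expect_equal(nrow(sw$summary), 3L)
  expect_true(all(sw$summary$mean_accuracy == 100))
  expect_equal(sw$bestNPCs, 2L)  # tie -> smallest PC count

  single <- sweepPCs(fx$scores, fx$labels,
                     classifierSpec("knn", nSearchDraws = 2L, seed = 2), 2:2)
  expect_length(single$reports, 1L)
  expect_error(sweepPCs(fx$scores, fx$labels,
                        classifierSpec("knn"), integer(0)), "empty")
})

test_that("confusion analysis recovers per-group accuracy and destinations", {
  cm <- matrix(c(90, 20, 10, 80), 2, 2,
               dimnames = list(c("g1", "g2"), c("g1", "g2")))
  rep <- new("ClassificationReport", method = "knn", nPCs = 2L,
             foldAccuracy = rep(85, 5), bestParams = list(),
             confusion = cm, misclassified = character(0))
  ca <- confusionAnalysis(rep)
  expect_equal(ca$perGroup$accuracy, c(90, 80))
  expect_equal(ca$destinations["g2", "g1"], 20)

  diag_only <- new("ClassificationReport", method = "knn", nPCs = 2L,
                   foldAccuracy = rep(100, 5), bestParams = list(),
                   confusion = diag(c(5, 7, 9)) |>
                     (\(m) {dimnames(m) <- list(letters[1:3], letters[1:3]); m})(),
                   misclassified = character(0))
  expect_true(all(confusionAnalysis(diag_only)$perGroup$accuracy == 100))
})

test_that("majority down-sampling retains the requested group size", {
  labels <- setNames(rep(c("big", "small"), c(100, 10)),
                     sprintf("s%03d", 1:110))
  keep <- downsampleMajority(labels, "big", 30, seed = 4)
  expect_equal(sum(labels[keep] == "big"), 30)
  expect_equal(sum(labels[keep] == "small"), 10)
  expect_identical(downsampleMajority(labels, "small", 50), names(labels))
})
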