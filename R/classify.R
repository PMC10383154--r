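# Group-label prediction from PC-score features: k-NN, random forest and
# RBF-kernel SVM, with randomized hyperparameter search nested inside
# stratified cross-validation (search sees training folds only).

#' @importFrom randomForest randomForest
#' @importFrom class knn
#' @importFrom e1071 svm
NULL

.default_search_space <- function(method) {
  switch(method,
    knn = list(k = c(3L, 50L)),
    random_forest = list(ntree = c(100L, 800L), nodesize = c(1L, 8L),
                         mtry_max = 8L),
    svm = list(log10_cost = c(0, 5), log10_gamma = c(-3, 2)))
}

#' Specify a classifier and its randomized search
#'
#' Default search spaces cover neighbourhoods of typical optima for
#' population-assignment problems: k-NN neighbours in \[3, 50\]; random
#' forest trees in \[100, 800\], minimum node size in \[1, 8\], `mtry` up
#' to 8; SVM with an RBF kernel, cost log-uniform on \[1, 1e5\] and gamma
#' log-uniform on \[1e-3, 1e2\].
#'
#' @param method "knn", "random_forest" or "svm".
#' @param searchSpace named list overriding the default space.
#' @param nSearchDraws randomized-search draws per training fold.
#' @param cvFolds outer stratified cross-validation folds.
#' @param innerFolds folds used by the nested search inside each training
#'   fold.
#' @param seed integer seed.
#' @return A [ClassifierSpec].
#' @export
classifierSpec <- function(method = c("random_forest", "knn", "svm"),
                           searchSpace = NULL, nSearchDraws = 10L,
                           cvFolds = 5L, innerFolds = 3L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(searchSpace)) searchSpace <- .default_search_space(method)
  new("ClassifierSpec", method = method, searchSpace = searchSpace,
      nSearchDraws = as.integer(nSearchDraws), cvFolds = as.integer(cvFolds),
      innerFolds = as.integer(innerFolds), seed = as.integer(seed))
}

# stratified fold ids: within each class, shuffled round-robin assignment,
# so per-fold class proportions deviate by at most one sample
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.draw_params <- function(method, space, n_features) {
  switch(method,
    knn = list(k = sample(space$k[1]:space$k[2], 1L)),
    random_forest = list(
      ntree = sample(space$ntree[1]:space$ntree[2], 1L),
      nodesize = sample(space$nodesize[1]:space$nodesize[2], 1L),
      mtry = sample(seq_len(min(space$mtry_max, n_features)), 1L)),
    svm = list(
      cost = 10^stats::runif(1, space$log10_cost[1], space$log10_cost[2]),
      gamma = 10^stats::runif(1, space$log10_gamma[1], space$log10_gamma[2])))
}

.fit_predict <- function(method, params, xtr, ytr, xte) {
  ytr <- factor(ytr)
  if (nlevels(ytr) == 1L)
    return(factor(rep(levels(ytr), nrow(xte)), levels = levels(ytr)))
  switch(method,
    knn = {
      # cap k at the smallest training class so no class can be outvoted
      # by construction
      k_eff <- max(1L, min(params$k, min(table(ytr))))
      class::knn(xtr, xte, ytr, k = k_eff)
    },
    random_forest = {
      fit <- randomForest::randomForest(
        x = xtr, y = ytr, ntree = params$ntree, nodesize = params$nodesize,
        mtry = min(params$mtry, ncol(xtr)))
      stats::predict(fit, xte)
    },
    svm = {
      fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                        cost = params$cost, gamma = params$gamma)
      stats::predict(fit, xte)
    })
}

# mean inner-CV accuracy of one hyperparameter draw on the training fold
.inner_cv_accuracy <- function(method, params, x, y, inner_folds) {
  k <- min(inner_folds, min(table(y)))
  if (k < 2L) k <- 2L
  folds <- .stratified_folds(y, k)
  accs <- vapply(seq_len(k), function(f) {
    te <- folds == f
    if (!any(te) || all(te)) return(NA_real_)
    pred <- .fit_predict(method, params, x[!te, , drop = FALSE], y[!te],
                         x[te, , drop = FALSE])
    mean(pred == y[te])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Cross-validated group prediction from PC scores
#'
#' Outer stratified `cvFolds`-fold cross-validation; within each training
#' fold a randomized hyperparameter search (`nSearchDraws` draws, each
#' evaluated by nested `innerFolds`-fold CV on the training fold only)
#' picks the hyperparameters, the model is refit on the whole training
#' fold, and accuracy is measured on the held-out test fold. Test folds are
#' never seen by the search. Deterministic for a fixed spec seed.
#'
#' @param scores a [PGxPCA] or a samples x PCs numeric matrix with sample
#'   ids as rownames.
#' @param labels named character vector or factor of group labels.
#' @param spec a [ClassifierSpec].
#' @param nPCs number of leading PCs used as features.
#' @return A [ClassificationReport].
#' @export
trainEval <- function(scores, labels, spec, nPCs = ncol(pcScores(scores))) {
  if (is(scores, "PGxPCA")) scores <- pcScores(scores)
  nPCs <- as.integer(nPCs)
  if (nPCs > ncol(scores))
    stop("nPCs exceeds the number of fitted PCs (", ncol(scores), ")")
  x <- scores[, seq_len(nPCs), drop = FALSE]
  if (!is.null(names(labels))) labels <- labels[rownames(x)]
  y <- factor(as.character(labels))
  tab <- table(y)
  small <- names(tab)[tab < spec@cvFolds]
  if (length(small) && nlevels(y) > 1L)
    stop("group(s) smaller than cvFolds: ", paste(small, collapse = ", "))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))

  .with_seed(.derive_seed(spec@seed, paste0("traineval", nPCs)), {
    k <- spec@cvFolds
    folds <- if (nlevels(y) == 1L) rep_len(seq_len(k), length(y))
             else .stratified_folds(as.character(y), k)
    fold_acc <- numeric(k)
    best_params <- vector("list", k)
    pred_all <- factor(rep(NA, length(y)), levels = levels(y))
    for (f in seq_len(k)) {
      te <- folds == f
      xtr <- x[!te, , drop = FALSE]
      ytr <- as.character(y[!te])
      if (nlevels(y) == 1L) {
        params <- list()
      } else {
        draws <- replicate(spec@nSearchDraws,
                           .draw_params(spec@method, spec@searchSpace, nPCs),
                           simplify = FALSE)
        inner <- vapply(draws, function(p)
          .inner_cv_accuracy(spec@method, p, xtr, ytr, spec@innerFolds),
          numeric(1))
        params <- draws[[which.max(inner)]]
      }
      best_params[[f]] <- params
      pred <- .fit_predict(spec@method, params, xtr, ytr,
                           x[te, , drop = FALSE])
      pred <- factor(as.character(pred), levels = levels(y))
      pred_all[te] <- pred
      fold_acc[f] <- 100 * mean(pred == y[te])
    }
    tb <- table(true = y, predicted = pred_all)
    cm <- matrix(as.integer(tb), nrow = nrow(tb), dimnames = dimnames(tb))
    new("ClassificationReport", method = spec@method, nPCs = nPCs,
        foldAccuracy = fold_acc, bestParams = best_params,
        confusion = cm, misclassified = ids[pred_all != y])
  })
}

#' Sweep classification accuracy over PC counts
#'
#' Runs [trainEval()] for each PC count in a contiguous range and
#' identifies the best mean accuracy; ties go to the smallest PC count.
#'
#' @inheritParams trainEval
#' @param pcRange contiguous integer range of PC counts (within 2..25 by
#'   convention; upper bound at most the fitted PCs).
#' @return A list with `reports` (one [ClassificationReport] per count),
#'   `summary` (data.frame of n_pcs, mean and sd accuracy) and `bestNPCs`.
#' @export
sweepPCs <- function(scores, labels, spec, pcRange = 2:25) {
  if (!length(pcRange)) stop("empty PC range")
  pcRange <- sort(as.integer(pcRange))
  reports <- lapply(pcRange, function(np) trainEval(scores, labels, spec, np))
  names(reports) <- paste0("PC", pcRange)
  summary <- data.frame(
    n_pcs = pcRange,
    mean_accuracy = vapply(reports, meanAccuracy, numeric(1)),
    sd_accuracy = vapply(reports, sdAccuracy, numeric(1)))
  best <- pcRange[which.max(summary$mean_accuracy)]  # ties -> smallest count
  list(reports = reports, summary = summary, bestNPCs = best)
}

#' Per-group accuracy and misclassification destinations
#'
#' Row-normalizes the report's confusion matrix: per-group accuracy is the
#' diagonal percentage, and each off-diagonal percentage is the share of a
#' true group's samples predicted as another group.
#'
#' @param report a [ClassificationReport].
#' @return A list with `perGroup` (data.frame: group, n, accuracy),
#'   `destinations` (row-percentage matrix) and `misclassified` ids.
#' @export
confusionAnalysis <- function(report) {
  cm <- confusionMatrix(report)
  n <- rowSums(cm)
  pct <- sweep(cm, 1L, pmax(n, 1L), "/") * 100
  list(
    perGroup = data.frame(group = rownames(cm), n = as.integer(n),
                          accuracy = diag(pct), row.names = NULL),
    destinations = pct,
    misclassified = misclassifiedIds(report))
}

#' Down-sample a majority group
#'
#' Optional preprocessing to balance group sizes before classification:
#' randomly retains at most `n` samples of `group`, all others untouched.
#'
#' @param labels named character vector of group labels.
#' @param group the group to down-sample.
#' @param n maximum retained size for that group.
#' @param seed integer seed.
#' @return The names (sample ids) of the retained samples.
#' @export
downsampleMajority <- function(labels, group, n, seed = 1L) {
  idx <- which(labels == group)
  if (length(idx) <= n) return(names(labels))
  keep_group <- .with_seed(.derive_seed(seed, "downsample"),
                           sample(idx, n))
  names(labels)[sort(c(setdiff(seq_along(labels), idx), keep_group))]
}
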