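#' Target-wise k-fold split of a QA dataset
#'
#' Partitions the targets (not the model rows) into k subsets whose sizes
#' differ by at most one, so that all models of a target fall into one
#' subset. Deterministic given `seed`.
#'
#' @param dataset QA data.frame with a `target_id` column (one row per
#'   model; feature columns plus a `gdt` label column).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list of k character vectors of target ids.
#' @export
targetWiseFolds <- function(dataset, k = 10, seed = 1) {
  targets <- unique(dataset$target_id)
  if (length(targets) < k)
    stop("need at least ", k, " targets, got ", length(targets))
  set.seed(seed)
  targets <- sample(targets)
  split(targets, rep(seq_len(k), length.out = length(targets)))
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2, stats::sd)
  sig[sig < 1e-9] <- 1
  list(mu = mu, sigma = sig)
}

.standardize_apply <- function(X, st) {
  sweep(sweep(as.matrix(X), 2, st$mu, "-"), 2, st$sigma, "/")
}

.mean_selection_loss <- function(scores, dataset) {
  tapply(seq_len(nrow(dataset)), dataset$target_id, function(idx) {
    g <- dataset$gdt[idx]
    max(g) - g[which.max(scores[idx])]
  }) |> mean()
}

#' Train the two-level DeepRank ensemble
#'
#' Level 1: the targets are split into 10 folds ([targetWiseFolds()]); for
#' each fold, every candidate architecture in `arch_grid` is trained on the
#' other nine folds (with early stopping on the fold's validation MSE) and
#' the candidate with the lowest mean selection loss on the held-out fold
#' becomes that fold's ensemble member. Level 2: the ten level-1 scores
#' concatenated with the original features are used to train a combiner
#' network on a random 9:1 model-level split, selected across the grid by
#' validation MSE. All inputs are z-scored per column with statistics from
#' the respective training data, stored in the ensemble. Deterministic given
#' `seed`.
#'
#' @param dataset QA data.frame: target_id, model_id, feature columns,
#'   `gdt` label in [0, 1] (e.g. from [makeQADataset()]).
#' @param arch_grid list of hidden-layer configurations, each an integer
#'   vector (e.g. `list(8, 16, c(16, 8))`).
#' @param seed integer seed.
#' @param epochs,patience training-schedule knobs passed to the optimiser.
#' @return a [QAEnsemble-class].
#' @export
trainEnsemble <- function(dataset, arch_grid = list(8, 16, c(16, 8)),
                          seed = 1, epochs = 300, patience = 20) {
  fn <- featureColumns(dataset)
  X_all <- as.matrix(dataset[, fn, drop = FALSE])
  y_all <- dataset$gdt
  if (stats::sd(y_all) < 1e-12)
    warning("zero-variance labels: ensemble will be uninformative")
  folds <- targetWiseFolds(dataset, 10, seed)
  level1 <- vector("list", 10L)
  for (f in seq_len(10L)) {
    val_rows <- dataset$target_id %in% folds[[f]]
    Xtr <- X_all[!val_rows, , drop = FALSE]
    ytr <- y_all[!val_rows]
    st <- .standardize_fit(Xtr)
    Xtr_z <- .standardize_apply(Xtr, st)
    Xval_z <- .standardize_apply(X_all[val_rows, , drop = FALSE], st)
    val_ds <- dataset[val_rows, , drop = FALSE]
    best <- NULL
    for (ai in seq_along(arch_grid)) {
      net <- mlpTrain(Xtr_z, ytr, hidden = arch_grid[[ai]],
                      Xval = Xval_z, yval = y_all[val_rows],
                      epochs = epochs, patience = patience,
                      seed = seed + 31L * f + ai)
      loss <- .mean_selection_loss(mlpPredict(net, Xval_z), val_ds)
      if (is.null(best) || loss < best$loss - 1e-12)
        best <- list(net = net, loss = loss, arch = arch_grid[[ai]])
    }
    level1[[f]] <- list(net = best$net, norm = st, arch = best$arch,
                        val_loss = best$loss)
  }
  s1 <- vapply(level1, function(m)
    mlpPredict(m$net, .standardize_apply(X_all, m$norm)), numeric(nrow(X_all)))
  X2 <- cbind(s1, X_all)
  colnames(X2) <- c(paste0("l1_", seq_len(10L)), fn)
  st2 <- .standardize_fit(X2)
  X2_z <- .standardize_apply(X2, st2)
  set.seed(seed + 997L)
  n <- nrow(X2)
  val_idx <- sample(n, max(1L, round(n / 10)))
  best2 <- NULL
  # the combiner grid adds a linear candidate (no hidden layer): with ten
  # already-calibrated level-1 scores a low-variance weighting is often best
  arch_grid2 <- c(list(integer(0)), arch_grid)
  for (ai in seq_along(arch_grid2)) {
    net <- mlpTrain(X2_z[-val_idx, , drop = FALSE], y_all[-val_idx],
                    hidden = arch_grid2[[ai]],
                    Xval = X2_z[val_idx, , drop = FALSE],
                    yval = y_all[val_idx],
                    epochs = epochs, patience = patience,
                    seed = seed + 631L + ai)
    mse <- mean((mlpPredict(net, X2_z[val_idx, , drop = FALSE]) -
                   y_all[val_idx])^2)
    if (is.null(best2) || mse < best2$mse - 1e-12)
      best2 <- list(net = net, mse = mse, arch = arch_grid2[[ai]])
  }
  new("QAEnsemble",
      level1 = level1,
      level2 = list(net = best2$net, norm = st2, arch = best2$arch),
      featureNames = fn,
      config = list(arch_grid = arch_grid, seed = seed, epochs = epochs,
                    patience = patience))
}

.check_schema <- function(ensemble, features) {
  missing <- setdiff(ensemble@featureNames, names(features))
  if (length(missing))
    stop("feature columns missing: ", paste(missing, collapse = ", "))
  as.matrix(features[, ensemble@featureNames, drop = FALSE])
}

.level1_scores <- function(ensemble, X) {
  vapply(ensemble@level1, function(m)
    mlpPredict(m$net, .standardize_apply(X, m$norm)), numeric(nrow(X)))
}

#' Predict model quality with the full two-level ensemble
#'
#' @param ensemble a trained [QAEnsemble-class].
#' @param features data.frame containing the ensemble's feature columns
#'   (and optionally model_id, used to name the result).
#' @return numeric scores in [0, 1], one per row.
#' @export
predictDeepRank <- function(ensemble, features) {
  X <- .check_schema(ensemble, features)
  s1 <- matrix(.level1_scores(ensemble, X), nrow = nrow(X))
  X2 <- cbind(s1, X)
  colnames(X2) <- c(paste0("l1_", seq_len(10L)), ensemble@featureNames)
  out <- mlpPredict(ensemble@level2$net,
                    .standardize_apply(X2, ensemble@level2$norm))
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(features$model_id)) names(out) <- features$model_id
  out
}

#' Predict model quality by averaging the ten level-1 networks
#'
#' The simplified ensemble variant: the arithmetic mean of the ten level-1
#' outputs, clipped to [0, 1].
#'
#' @inheritParams predictDeepRank
#' @return numeric scores in [0, 1], one per row.
#' @export
predictDeepRankAvg <- function(ensemble, features) {
  X <- .check_schema(ensemble, features)
  s1 <- matrix(.level1_scores(ensemble, X), nrow = nrow(X))
  out <- pmin(pmax(rowMeans(s1), 0), 1)
  if (!is.null(features$model_id)) names(out) <- features$model_id
  out
}

#' Rank models by predicted quality score
#'
#' @param scores named numeric vector (names are model ids).
#' @return data.frame (model_id, score) in descending score order, ties
#'   broken by model_id lexicographic order.
#' @export
rankModels <- function(scores) {
  if (!length(scores)) stop("no scored models")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  out <- data.frame(model_id = ids, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GDT-TS selection loss of a ranking
#'
#' The difference between the true GDT-TS of the best model in the pool and
#' the true GDT-TS of the model ranked first (1-point scale).
#'
#' @param ranking output of [rankModels()] (or a character vector of model
#'   ids in rank order).
#' @param true_gdts named numeric vector of true GDT-TS scores.
#' @return loss >= 0.
#' @export
selectionLoss <- function(ranking, true_gdts) {
  ids <- if (is.data.frame(ranking)) ranking$model_id else as.character(ranking)
  if (!length(ids)) stop("empty ranking")
  if (any(!ids %in% names(true_gdts)))
    stop("true score missing for: ",
         paste(setdiff(ids, names(true_gdts)), collapse = ", "))
  max(true_gdts[ids]) - unname(true_gdts[ids[1]])
}

#' Mean selection loss of a scoring method over a QA dataset
#'
#' @param dataset QA data.frame (target_id, model_id, features, gdt).
#' @param scorer function(features_df) returning one score per row, or a
#'   character scalar naming a single feature column to rank by.
#' @return mean over targets of the selection loss.
#' @export
datasetSelectionLoss <- function(dataset, scorer) {
  if (is.character(scorer)) {
    col <- scorer
    scorer <- function(df) df[[col]]
  }
  losses <- tapply(seq_len(nrow(dataset)), dataset$target_id, function(idx) {
    sub <- dataset[idx, , drop = FALSE]
    sc <- setNames(scorer(sub), sub$model_id)
    selectionLoss(rankModels(sc), setNames(sub$gdt, sub$model_id))
  })
  mean(losses)
}

#' Serialize a QAEnsemble to a structured text archive
#'
#' Writes weights, normalisation statistics and configuration as a single
#' versioned plain-text file (dput-based), readable by [loadEnsemble()].
#'
#' @param ensemble a [QAEnsemble-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
saveEnsemble <- function(ensemble, path) {
  obj <- list(format = "ContactFold-QAEnsemble-v1",
              level1 = ensemble@level1, level2 = ensemble@level2,
              featureNames = ensemble@featureNames,
              config = ensemble@config)
  dput(obj, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) {
  obj <- dget(path)
  if (!identical(obj$format, "ContactFold-QAEnsemble-v1"))
    stop("not a ContactFold ensemble archive: ", path)
  new("QAEnsemble", level1 = obj$level1, level2 = obj$level2,
      featureNames = obj$featureNames, config = obj$config)
}
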