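# Classical classifier baselines evaluated on the same splits as the CNN.
#
# The CNN's two-level scheme (3-class training, head swap, 2-class
# fine-tune) has no direct analogue for these models, so the closest fair
# comparison is used: each baseline is fit once on the union of the
# non-bio training genes restricted to the evaluation's label space (the
# up-/down-regulated genes of T1) and the fine-tune genes F1, then
# evaluated on the binary test set.

BASELINE_IDS <- c("decision-tree", "k-nearest-neighbors", "random-forest",
                  "support-vector", "gradient-boosted-trees")

#' Run the five classical classifier baselines
#'
#' Fits decision tree, k-nearest neighbors, random forest, support vector
#' machine and gradient-boosted trees on the byte-identical splits used by
#' the network and evaluates them with the same metric suite, so the
#' reports are schema-identical to the network's.
#'
#' @param labels A `labeled_gene_set`.
#' @param split Its [make_split()] result; training rows are the
#'   up-/down-regulated genes of `T1` plus all of `F1`, the test rows are
#'   `T3`.
#' @param ids Baseline identifiers, a subset of
#'   `c("decision-tree", "k-nearest-neighbors", "random-forest",
#'   "support-vector", "gradient-boosted-trees")`.
#' @param seed Integer seed (each baseline draws a derived stream).
#' @param knn_k Neighborhood size for k-nearest neighbors. Default 5.
#' @param xgb_nrounds Boosting rounds for gradient-boosted trees. Default
#'   50.
#' @return Named list of `metrics_report`s, one per baseline.
#' @export
run_baselines <- function(labels, split, ids = BASELINE_IDS, seed = 1L,
                          knn_k = 5L, xgb_nrounds = 50L) {
  stopifnot(inherits(labels, "labeled_gene_set"), inherits(split, "data_split"))
  unknown <- setdiff(ids, BASELINE_IDS)
  if (length(unknown) > 0L)
    stop2("unknown baseline id: '", unknown[[1L]], "' (known: ",
          paste(BASELINE_IDS, collapse = ", "), ")")

  t1_binary <- split$T1[labels$label[split$T1] %in% c(0L, 1L)]
  train_idx <- c(t1_binary, split$F1)
  xtr <- labels$features[train_idx, , drop = FALSE]
  ytr <- labels$label[train_idx]
  xte <- labels$features[split$T3, , drop = FALSE]
  yte <- labels$label[split$T3]
  colnames(xtr) <- colnames(xte) <- paste0("f", seq_len(ncol(xtr)))

  reports <- list()
  for (id in ids) {
    fit <- with_seed(derive_seed(seed, paste0("baseline_", id)),
                     fit_baseline(id, xtr, ytr, xte, knn_k, xgb_nrounds))
    metrics <- compute_metrics(yte, fit$class, scores = fit$score)
    reports[[id]] <- metrics_report(folds = list(metrics), model = id,
                                    dataset = labels$dataset_name,
                                    split = "T3", seed = seed)
  }
  reports
}

require_pkg <- function(pkg, id) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop2("baseline '", id, "' needs the '", pkg, "' package")
}

# returns list(class = predicted 0/1 labels, score = probability of class 1)
fit_baseline <- function(id, xtr, ytr, xte, knn_k, xgb_nrounds) {
  switch(id,
    "decision-tree" = {
      require_pkg("rpart", id)
      df <- data.frame(.y = factor(ytr, levels = c(0L, 1L)), xtr)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      p <- predict(fit, newdata = data.frame(xte), type = "prob")[, "1"]
      list(class = as.integer(p >= 0.5), score = p)
    },
    "k-nearest-neighbors" = {
      require_pkg("class", id)
      pred <- class::knn(train = xtr, test = xte,
                         cl = factor(ytr, levels = c(0L, 1L)),
                         k = knn_k, prob = TRUE)
      win <- attr(pred, "prob")
      p <- ifelse(pred == "1", win, 1 - win)
      list(class = as.integer(as.character(pred)), score = p)
    },
    "random-forest" = {
      require_pkg("randomForest", id)
      fit <- randomForest::randomForest(x = xtr,
                                        y = factor(ytr, levels = c(0L, 1L)))
      p <- predict(fit, newdata = xte, type = "prob")[, "1"]
      list(class = as.integer(p >= 0.5), score = p)
    },
    "support-vector" = {
      require_pkg("e1071", id)
      fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(0L, 1L)),
                        probability = TRUE)
      pred <- predict(fit, newdata = xte, probability = TRUE)
      p <- attr(pred, "probabilities")[, "1"]
      list(class = as.integer(p >= 0.5), score = p)
    },
    "gradient-boosted-trees" = {
      require_pkg("xgboost", id)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L),
        data = xgboost::xgb.DMatrix(xtr, label = ytr),
        nrounds = xgb_nrounds, verbose = 0)
      p <- predict(fit, xgboost::xgb.DMatrix(xte))
      list(class = as.integer(p >= 0.5), score = p)
    },
    stop2("unknown baseline id: ", id))
}
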