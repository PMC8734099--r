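#' Training configuration for the two-level scheme
#'
#' Defaults follow the published hyperparameter table: first-level
#' (3-class) training runs 50 epochs at batch size 256 with a multiclass
#' cross-entropy loss; fine-tuning runs 31 epochs at batch size 64 with a
#' sigmoid cross-entropy on raw scores; both use an adaptive-moment
#' optimizer with learning rate 1e-4, betas (0.9, 0.999), eps 1e-8 and no
#' weight decay; cross-validation uses 5 folds.
#'
#' @param level1,finetune Named lists overriding individual fields
#'   (`epochs`, `batch`, `lr`, `beta1`, `beta2`, `eps`, `weight_decay`).
#' @param folds Number of cross-validation folds. Default 5.
#' @return A `train_config` list.
#' @export
train_config <- function(level1 = list(), finetune = list(), folds = 5L) {
  l1 <- utils::modifyList(list(epochs = 50L, batch = 256L, loss = "ce",
                               lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, weight_decay = 0), level1)
  ft <- utils::modifyList(list(epochs = 31L, batch = 64L, loss = "bce",
                               lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, weight_decay = 0), finetune)
  for (cfg in list(l1, ft))
    if (cfg$epochs < 0L || cfg$batch < 1L || cfg$lr <= 0)
      stop2("epochs must be >= 0, batch >= 1 and lr > 0")
  structure(list(level1 = l1, finetune = ft, folds = as.integer(folds)),
            class = "train_config")
}

# shared gradient-descent driver; stage picks the level1/finetune block
run_training <- function(model, x, y, stage_cfg, seed, salt) {
  x <- as_feature_matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  epochs <- stage_cfg$epochs
  if (epochs == 0L)
    return(list(model = model, loss_trace = numeric(0L)))
  perms <- with_seed(derive_seed(seed, salt), {
    t(vapply(seq_len(epochs), function(e) sample.int(nrow(x)),
             integer(nrow(x))))
  })
  res <- .cnn_train_cpp(model$params, list(), x, y, stage_cfg$loss, perms,
                        stage_cfg$batch, stage_cfg$lr, stage_cfg$beta1,
                        stage_cfg$beta2, stage_cfg$eps, stage_cfg$weight_decay)
  model$params <- res$params
  list(model = model, loss_trace = as.numeric(res$loss_trace))
}

#' First-level (3-class) training
#'
#' Trains the 3-class head on down-regulated / up-regulated / neutral
#' labels with a multiclass cross-entropy loss at the configured settings.
#' Batches are reshuffled every epoch under the derived seed; the run is
#' fully deterministic given (data, config, seed). With `epochs = 0` the
#' model is returned unchanged.
#'
#' @param model A `degnet_model` with a 3-class head.
#' @param x Feature matrix (genes in rows) or `labeled_gene_set`.
#' @param y Integer labels in \{0, 1, 2\} (ignored when `x` is a
#'   `labeled_gene_set`, whose labels are used).
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @param dataset_name Optional name appended to the model's training
#'   provenance.
#' @return List with `model` (trained) and `loss_trace` (per-epoch mean
#'   training loss).
#' @export
train_level1 <- function(model, x, y = NULL, config = train_config(), seed = 1L,
                         dataset_name = NULL) {
  stopifnot(inherits(model, "degnet_model"), inherits(config, "train_config"))
  if (head_arity(model) != 3L)
    stop2("first-level training needs a 3-class head; call swap_head(model, 3) first")
  if (inherits(x, "labeled_gene_set")) {
    y <- y %||% x$label
    dataset_name <- dataset_name %||% x$dataset_name
  }
  if (!all(y %in% 0:2)) stop2("level-1 labels must lie in {0, 1, 2}")
  missing_cls <- setdiff(0:2, unique(y))
  if (length(missing_cls) > 0L)
    warning("label class(es) absent from the training data: ",
            paste(missing_cls, collapse = ", "), call. = FALSE)
  out <- run_training(model, x, y, config$level1, seed, "train_level1")
  if (!is.null(dataset_name))
    out$model$provenance$trained_on <-
      c(out$model$provenance$trained_on, paste0(dataset_name, ":level1"))
  out
}

#' Second-level (2-class) fine-tuning
#'
#' Fine-tunes a head-swapped model on biologically validated
#' down-/up-regulated genes with a sigmoid cross-entropy on raw scores
#' (labels one-hot encoded as two real targets). The whole network is
#' updated; no layers are frozen.
#'
#' @param model A `degnet_model` whose head has been swapped to arity 2.
#' @param x Feature matrix or `labeled_gene_set`.
#' @param y Integer labels in \{0, 1\}; a label 2 is an error.
#' @inheritParams train_level1
#' @return List with `model` and `loss_trace`.
#' @export
finetune_model <- function(model, x, y = NULL, config = train_config(),
                           seed = 1L, dataset_name = NULL) {
  stopifnot(inherits(model, "degnet_model"), inherits(config, "train_config"))
  if (head_arity(model) != 2L)
    stop2("fine-tuning needs a 2-class head; call swap_head(model, 2) first")
  if (inherits(x, "labeled_gene_set")) {
    y <- y %||% x$label
    dataset_name <- dataset_name %||% x$dataset_name
  }
  if (any(y == 2L)) stop2("fine-tune data must contain only labels 0 and 1")
  if (!all(y %in% 0:1)) stop2("fine-tune labels must lie in {0, 1}")
  out <- run_training(model, x, y, config$finetune, seed, "finetune")
  if (!is.null(dataset_name))
    out$model$provenance$trained_on <-
      c(out$model$provenance$trained_on, paste0(dataset_name, ":finetune"))
  out
}

# subset helper: features and labels at the given gene indices
subset_genes <- function(labels, idx) {
  list(x = labels$features[idx, , drop = FALSE], y = labels$label[idx])
}

#' Five-fold cross-validated first-level training with best-fold selection
#'
#' Trains one freshly initialized model per fold on the remaining folds and
#' validates on the held-out fold with the full metric suite. The best fold
#' is the one with the highest validation Matthews correlation coefficient
#' (the headline quality metric); ties break toward the lower fold index.
#'
#' @param labels A `labeled_gene_set`.
#' @param folds Fold assignments from [make_cv_folds()].
#' @param model_cfg A [model_config()] with a 3-class head.
#' @param train_cfg A [train_config()].
#' @param seed Integer seed; fold models are initialized and trained under
#'   derived streams.
#' @return List with `fold_results` (per fold: index, validation metrics,
#'   trained model, loss trace), `best_index` and `best_model`.
#' @export
cross_validate_level1 <- function(labels, folds, model_cfg = model_config(),
                                  train_cfg = train_config(), seed = 1L) {
  stopifnot(inherits(labels, "labeled_gene_set"), length(folds) >= 2L)
  all_idx <- sort(unlist(folds))
  fold_results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    val_idx <- folds[[f]]
    tr_idx <- setdiff(all_idx, val_idx)
    model <- init_model(model_cfg, seed = derive_seed(seed, paste0("fold_init", f)))
    tr <- subset_genes(labels, tr_idx)
    fit <- train_level1(model, tr$x, tr$y, train_cfg,
                        seed = derive_seed(seed, paste0("fold_train", f)))
    va <- subset_genes(labels, val_idx)
    metrics <- compute_metrics(va$y, predict_classes(fit$model, va$x),
                               scores = model_forward(fit$model, va$x))
    fold_results[[f]] <- list(fold_index = f, metrics = metrics,
                              model = fit$model, loss_trace = fit$loss_trace)
  }
  mccs <- vapply(fold_results, function(r) r$metrics$mcc, numeric(1L))
  best <- which.max(mccs)  # which.max takes the first maximum: lower index wins ties
  list(fold_results = fold_results, best_index = best,
       best_model = fold_results[[best]]$model)
}

#' General learning: cross-validated training, fine-tuning and bio-testing
#'
#' The full first-experiment pipeline on one dataset: five-fold
#' cross-validated 3-class training on the non-bio training genes T1, head
#' swap to two classes, fine-tuning on the bio fine-tune genes F1, and
#' binary evaluation on the held-out bio-test genes T3. Every fold's model
#' is fine-tuned and tested, so the report carries per-fold metrics and
#' their mean; the returned model is the fine-tuned best fold (highest
#' validation MCC).
#'
#' @param labels A `labeled_gene_set`.
#' @param split A [make_split()] result on the same genes.
#' @param model_cfg A [model_config()] (3-class head).
#' @param train_cfg A [train_config()].
#' @param seed Master seed; initialization, fold training, head
#'   initialization and fine-tuning draw from derived streams.
#' @return List with `report` (a `metrics_report` over T3, one entry per
#'   fold plus their mean), `model` (best fold, fine-tuned),
#'   `best_metrics` (the pipeline's headline result: T3 metrics of the
#'   best-validation-MCC fold), `cv` (the [cross_validate_level1()]
#'   result) and `provenance`.
#' @export
run_general_learning <- function(labels, split, model_cfg = model_config(),
                                 train_cfg = train_config(), seed = 1L) {
  stopifnot(inherits(labels, "labeled_gene_set"), inherits(split, "data_split"))
  folds <- make_cv_folds(labels, split, k = train_cfg$folds, seed = seed)
  cv <- cross_validate_level1(labels, folds, model_cfg, train_cfg, seed)

  f1 <- subset_genes(labels, split$F1)
  t3 <- subset_genes(labels, split$T3)
  fold_metrics <- vector("list", length(folds))
  best_finetuned <- NULL
  for (f in seq_along(cv$fold_results)) {
    m2 <- swap_head(cv$fold_results[[f]]$model, 2L,
                    seed = derive_seed(seed, paste0("head", f)))
    ft <- finetune_model(m2, f1$x, f1$y, train_cfg,
                         seed = derive_seed(seed, paste0("finetune", f)))
    fold_metrics[[f]] <- compute_metrics(
      t3$y, predict_classes(ft$model, t3$x),
      scores = model_forward(ft$model, t3$x)[, 2L])
    if (f == cv$best_index) best_finetuned <- ft$model
  }

  report <- metrics_report(folds = fold_metrics, model = "degnet",
                           dataset = labels$dataset_name, split = "T3",
                           seed = seed)
  list(report = report, model = best_finetuned, cv = cv,
       best_metrics = fold_metrics[[cv$best_index]],
       provenance = list(seed = as.integer(seed),
                         best_fold = cv$best_index,
                         split_sizes = vapply(split[c("T1", "T2", "F1", "T3")],
                                              length, integer(1L))))
}

#' Transfer learning: sequential training, then frozen prediction
#'
#' Phase A trains the 3-class model sequentially on every training
#' dataset's T1 genes, carrying the weights forward. Phase B swaps the head
#' once and fine-tunes sequentially on every training dataset's F1 genes.
#' Phase C evaluates the frozen model on each test dataset's bio-validated
#' genes with binary metrics — no gradient updates occur, which is verified
#' by comparing a digest of the weights before and after evaluation.
#' Datasets may have different sample counts; the adaptive pooling makes
#' the same weights applicable to all of them.
#'
#' @param train_sets List of lists, each with elements `labels` (a
#'   `labeled_gene_set`) and `split` (its `data_split`).
#' @param test_sets List of `labeled_gene_set`s containing only labels 0
#'   and 1 (100\% bio-validated genes); a neutral label is an error.
#' @param model_cfg,train_cfg,seed As in [run_general_learning()].
#' @return List with `reports` (one `metrics_report` per test dataset),
#'   `model` (the frozen transfer model) and `provenance` (dataset order
#'   and the weight digest).
#' @export
run_transfer_learning <- function(train_sets, test_sets,
                                  model_cfg = model_config(),
                                  train_cfg = train_config(), seed = 1L) {
  stopifnot(length(train_sets) >= 1L, length(test_sets) >= 1L)
  for (ts in test_sets)
    if (any(ts$label == 2L))
      stop2("transfer test datasets must contain only labels 0 and 1 (dataset '",
            ts$dataset_name, "' has neutral genes)")

  model <- init_model(model_cfg, seed = derive_seed(seed, "transfer_init"))
  for (i in seq_along(train_sets)) {
    s <- train_sets[[i]]
    t1 <- subset_genes(s$labels, s$split$T1)
    model <- train_level1(model, t1$x, t1$y, train_cfg,
                          seed = derive_seed(seed, paste0("transferA", i)),
                          dataset_name = s$labels$dataset_name)$model
  }
  model <- swap_head(model, 2L, seed = derive_seed(seed, "transfer_head"))
  for (i in seq_along(train_sets)) {
    s <- train_sets[[i]]
    f1 <- subset_genes(s$labels, s$split$F1)
    model <- finetune_model(model, f1$x, f1$y, train_cfg,
                            seed = derive_seed(seed, paste0("transferB", i)),
                            dataset_name = s$labels$dataset_name)$model
  }

  digest_before <- object_digest(model$params)
  reports <- lapply(test_sets, function(ts) {
    metrics <- compute_metrics(ts$label, predict_classes(model, ts$features),
                               scores = model_forward(model, ts$features)[, 2L])
    metrics_report(folds = list(metrics), model = "degnet-transfer",
                   dataset = ts$dataset_name, split = "Q", seed = seed)
  })
  names(reports) <- make.unique(vapply(test_sets, function(ts)
    ts$dataset_name, character(1L)))
  digest_after <- object_digest(model$params)
  stopifnot(identical(digest_before, digest_after))

  list(reports = reports, model = model,
       provenance = list(
         seed = as.integer(seed),
         train_order = vapply(train_sets, function(s) s$labels$dataset_name,
                              character(1L)),
         test_order = vapply(test_sets, function(ts) ts$dataset_name,
                             character(1L)),
         weights_digest = digest_before))
}
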