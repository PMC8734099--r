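test_that("training configuration defaults match the two-level scheme", {
  cfg <- train_config()
  expect_identical(cfg$level1$epochs, 50L)
  expect_identical(cfg$level1$batch, 256L)
  expect_identical(cfg$finetune$epochs, 31L)
  expect_identical(cfg$finetune$batch, 64L)
  expect_equal(cfg$level1$lr, 1e-4)
  expect_equal(cfg$finetune$lr, 1e-4)
  expect_equal(cfg$level1$beta1, 0.9)
  expect_equal(cfg$level1$beta2, 0.999)
  expect_equal(cfg$level1$eps, 1e-8)
  expect_identical(cfg$level1$weight_decay, 0)
  expect_identical(cfg$folds, 5L)
  expect_error(train_config(level1 = list(lr = 0)), "lr > 0")
})

test_that("level-1 training descends on separable data, deterministically", {
  sep <- make_separable(n_per_class = 50L, seed = 21L)
  model <- init_model(tiny_model_config(), seed = 21L)
  cfg <- tiny_train_config(epochs1 = 8L)
  fit <- train_level1(model, sep$x, sep$y, cfg, seed = 21L)
  expect_length(fit$loss_trace, 8L)
  expect_lt(fit$loss_trace[[8L]], fit$loss_trace[[1L]])

  fit2 <- train_level1(model, sep$x, sep$y, cfg, seed = 21L)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_identical(fit$model$params, fit2$model$params)

  # epochs = 0 is a no-op
  fit0 <- train_level1(model, sep$x, sep$y,
                       train_config(level1 = list(epochs = 0L)), seed = 1L)
  expect_identical(fit0$model$params, model$params)
  expect_length(fit0$loss_trace, 0L)

  # label sanity
  expect_error(train_level1(model, sep$x, sep$y + 5L), "0, 1, 2")
  expect_warning(train_level1(model, sep$x[sep$y != 2, ],
                              sep$y[sep$y != 2],
                              train_config(level1 = list(epochs = 1L)),
                              seed = 1L),
                 "absent")
})

test_that("fine-tuning requires a swapped head and binary labels", {
  sep <- make_separable(classes = 0:1, n_per_class = 40L, seed = 22L)
  model3 <- init_model(tiny_model_config(), seed = 22L)
  expect_error(finetune_model(model3, sep$x, sep$y), "swap_head")

  model2 <- swap_head(model3, 2L, seed = 1L)
  expect_error(finetune_model(model2, sep$x, c(sep$y[-1L], 2L)),
               "only labels 0 and 1")

  fit <- finetune_model(model2, sep$x, sep$y, tiny_train_config(epochs2 = 8L),
                        seed = 22L)
  expect_lt(tail(fit$loss_trace, 1L), fit$loss_trace[[1L]])
  expect_identical(head_arity(fit$model), 2L)
})

test_that("cross-validation trains one model per fold and picks the top MCC", {
  lab <- make_labeled_set(n_dr = 25L, n_ur = 25L, n_neutral = 55L,
                          n_samples = 16L, seed = 23L)
  sep <- make_separable(n_per_class = 35L, seed = 23L)
  lab$features[lab$label == 0L, ] <- sep$x[sep$y == 0, ][seq_len(25), ]
  lab$features[lab$label == 1L, ] <- sep$x[sep$y == 1, ][seq_len(25), ]
  lab$features[lab$label == 2L, ] <- 0
  split <- make_split(lab, seed = 23L)
  folds <- make_cv_folds(lab, split, k = 5L, seed = 23L)
  cv <- cross_validate_level1(lab, folds, tiny_model_config(),
                              tiny_train_config(), seed = 23L)
  expect_length(cv$fold_results, 5L)
  mccs <- vapply(cv$fold_results, function(r) r$metrics$mcc, numeric(1L))
  expect_identical(cv$best_index, which.max(mccs))
  expect_identical(cv$best_model$params,
                   cv$fold_results[[cv$best_index]]$model$params)
})

test_that("the general-learning pipeline reports six metrics per fold", {
  sim <- simulate_dataset(synthetic_spec(n_genes = 400L, n_normal = 10L,
                                         n_tumor = 10L, seed = 24L))
  lab <- label_genes(sim$dataset, compute_de_standin(sim$dataset), sim$bio)
  split <- make_split(lab, seed = 24L)
  res <- run_general_learning(lab, split, tiny_model_config(),
                              tiny_train_config(), seed = 24L)
  expect_s3_class(res$report, "metrics_report")
  expect_length(res$report$folds, 5L)
  for (f in res$report$folds)
    expect_true(all(c("accuracy", "recall", "precision", "f_measure",
                      "mcc", "roc_auc") %in% names(f)))
  expect_identical(head_arity(res$model), 2L)
  expect_identical(unclass(res$best_metrics),
                   res$report$folds[[res$provenance$best_fold]])

  # bit-for-bit reproducibility of the whole pipeline
  res2 <- run_general_learning(lab, split, tiny_model_config(),
                               tiny_train_config(), seed = 24L)
  expect_identical(res$report$mean, res2$report$mean)
  expect_identical(res$model$params, res2$model$params)
})

test_that("transfer learning carries weights, then predicts frozen", {
  base <- synthetic_spec(n_genes = 300L, n_normal = 10L, n_tumor = 10L)
  fam <- simulate_family(base, 3L, seeds = c(31L, 32L, 33L),
                         n_normal = c(10L, 10L, 4L), n_tumor = c(10L, 10L, 4L))
  train_sets <- lapply(fam[1:2], function(d) {
    lab <- suppressWarnings(label_genes(d$dataset, compute_de_standin(d$dataset),
                                        d$bio))
    list(labels = lab, split = make_split(lab, seed = 31L))
  })
  # test member: bio-validated genes only (planted DEGs)
  truth <- fam[[3L]]$truth
  keep <- truth$label != 2L
  test_set <- degnet:::new_labeled_gene_set(
    truth$gene_ids[keep], truth$features[keep, ], truth$label[keep],
    rep(TRUE, sum(keep)), dataset_name = "family-test")

  res <- run_transfer_learning(train_sets, list(test_set),
                               tiny_model_config(), tiny_train_config(),
                               seed = 31L)
  expect_length(res$reports, 1L)
  expect_identical(res$provenance$train_order,
                   vapply(train_sets, function(s) s$labels$dataset_name,
                          character(1L)))
  # evaluation left the weights untouched (digest recorded and re-checked
  # inside the runner); re-predicting now must match the report
  m <- res$reports[[1L]]$folds[[1L]]
  again <- compute_metrics(test_set$label,
                           predict_classes(res$model, test_set$features),
                           scores = model_forward(res$model, test_set$features)[, 2L])
  expect_equal(again$accuracy, m$accuracy)
  expect_equal(again$mcc, m$mcc)
  # training order is stamped into the model provenance
  expect_length(res$model$provenance$trained_on, 4L)

  # a neutral gene in a test set is an error
  bad <- test_set; bad$label[1L] <- 2L; bad$bio_flag[1L] <- FALSE
  expect_error(run_transfer_learning(train_sets, list(bad),
                                     tiny_model_config(), tiny_train_config()),
               "labels 0 and 1")
})

test_that("with zero epochs the pipeline sits at chance on balanced data", {
  sim <- simulate_dataset(synthetic_spec(n_genes = 300L, n_normal = 8L,
                                         n_tumor = 8L, seed = 25L))
  lab <- suppressWarnings(
    label_genes(sim$dataset, compute_de_standin(sim$dataset), sim$bio))
  split <- make_split(lab, seed = 25L)
  cfg0 <- train_config(level1 = list(epochs = 0L), finetune = list(epochs = 0L))
  mccs <- vapply(1:5, function(s) {
    res <- run_general_learning(lab, split, tiny_model_config(), cfg0, seed = s)
    res$best_metrics$mcc
  }, numeric(1L))
  expect_true(all(abs(mccs) <= 0.35))
  expect_lt(abs(mean(mccs)), 0.2)
})
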