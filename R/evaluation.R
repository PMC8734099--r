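#' Six-metric evaluation of class predictions
#'
#' Computes accuracy, recall, precision (as percentages), F-measure,
#' Matthews correlation coefficient and ROC-AUC. Per-class precision,
#' recall and F are combined by support-weighted averaging (class weights
#' proportional to their frequency in the truth), under which weighted
#' recall equals accuracy exactly — an identity asserted on every call.
#' MCC uses the generalized multiclass correlation over the confusion
#' matrix, which reduces to the standard binary formula for two classes.
#' ROC-AUC is computed from the score-ranked ROC curve by trapezoidal
#' integration: binary for two classes, support-weighted one-vs-rest for
#' three.
#'
#' @param y_true,y_pred Equal-length integer label vectors.
#' @param scores Optional scores for ROC: for binary labels a vector of
#'   scores for class 1 (a two-column matrix is reduced to its second
#'   column); for multiclass a matrix with one column per class in label
#'   order. Without scores `roc_auc` is `NA`.
#' @return A `fold_metrics` list: `accuracy`, `recall`, `precision`
#'   (percentages), `f_measure`, `mcc`, `roc_auc` (unit scale),
#'   `n_classes`, `averaging`, `support`.
#' @details A single-class truth leaves the ROC undefined; `roc_auc` is
#'   then `NA` with a warning, not an error. An all-one-class prediction
#'   degenerates the MCC denominator to zero; the conventional value 0 is
#'   returned.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stop2("y_true and y_pred must be nonempty and of equal length")
  n <- length(y_true)
  classes <- sort(union(unique(y_true), unique(y_pred)))
  k <- length(classes)

  tp <- fp <- fn <- support <- numeric(k)
  for (i in seq_len(k)) {
    cls <- classes[[i]]
    tp[i] <- sum(y_true == cls & y_pred == cls)
    fp[i] <- sum(y_true != cls & y_pred == cls)
    fn[i] <- sum(y_true == cls & y_pred != cls)
    support[i] <- sum(y_true == cls)
  }
  prec_k <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_k <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  w <- support / sum(support)

  accuracy <- mean(y_true == y_pred)
  recall <- sum(w * rec_k)
  precision <- sum(w * prec_k)
  f_measure <- sum(w * f_k)
  stopifnot(abs(accuracy - recall) < 1e-12)  # identity of weighted recall

  # generalized multiclass MCC over the confusion matrix
  t_k <- support
  p_k <- vapply(classes, function(cls) sum(y_pred == cls), numeric(1L))
  c_corr <- sum(y_true == y_pred)
  num <- c_corr * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den

  roc_auc <- compute_roc_auc(y_true, scores, classes, w)

  structure(list(accuracy = 100 * accuracy, recall = 100 * recall,
                 precision = 100 * precision, f_measure = f_measure,
                 mcc = mcc, roc_auc = roc_auc, n_classes = k,
                 averaging = "weighted",
                 support = stats::setNames(as.integer(support),
                                           as.character(classes))),
            class = "fold_metrics")
}

compute_roc_auc <- function(y_true, scores, classes, w) {
  if (is.null(scores)) return(NA_real_)
  present <- classes[w > 0]
  if (length(present) < 2L) {
    warning("ROC undefined: a single class in the truth labels", call. = FALSE)
    return(NA_real_)
  }
  if (is.matrix(scores) && ncol(scores) == 2L && length(classes) <= 2L)
    scores <- scores[, 2L]
  if (!is.matrix(scores)) {
    if (length(classes) > 2L)
      stop2("multiclass ROC needs a score matrix with one column per class")
    return(auc_trapezoid(y_true == classes[[2L]], scores))
  }
  if (ncol(scores) < length(classes))
    stop2("score matrix needs one column per class")
  # support-weighted one-vs-rest
  aucs <- weights <- numeric(0L)
  for (i in seq_along(classes)) {
    is_pos <- y_true == classes[[i]]
    if (!any(is_pos) || all(is_pos)) next
    aucs <- c(aucs, auc_trapezoid(is_pos, scores[, i]))
    weights <- c(weights, sum(is_pos))
  }
  sum(aucs * weights) / sum(weights)
}

# ROC curve at every distinct score threshold (descending), with the
# conventional (0,0) anchor; ties grouped so the curve is a step/diagonal.
roc_points <- function(is_pos, scores) {
  stopifnot(length(is_pos) == length(scores))
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop2("ROC needs both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  # cumulative counts at each distinct threshold
  idx <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(p)[idx]
  cum_fp <- cumsum(!p)[idx]
  data.frame(threshold = c(Inf, s[idx]),
             fpr = c(0, cum_fp / n_neg),
             tpr = c(0, cum_tp / n_pos))
}

auc_trapezoid <- function(is_pos, scores) {
  pts <- roc_points(is_pos, scores)
  sum(diff(pts$fpr) * (head(pts$tpr, -1L) + pts$tpr[-1L]) / 2)
}

#' Assemble per-fold metrics into a report with their mean
#'
#' @param folds List of `fold_metrics` from [compute_metrics()].
#' @param model,dataset,split Identifying strings recorded in the report.
#' @param seed The seed that produced the run.
#' @return A `metrics_report`: `model`, `dataset`, `split`, `folds`,
#'   `mean` (fieldwise mean of the six metrics), `averaging`, `n_classes`,
#'   `seed`, `schema_version`.
#' @export
metrics_report <- function(folds, model = "degnet", dataset = "", split = "",
                           seed = NA_integer_) {
  stopifnot(length(folds) >= 1L)
  fields <- c("accuracy", "recall", "precision", "f_measure", "mcc", "roc_auc")
  mean_metrics <- lapply(fields, function(f)
    mean(vapply(folds, function(x) as.numeric(x[[f]] %||% NA_real_), numeric(1L))))
  names(mean_metrics) <- fields
  structure(list(model = model, dataset = dataset, split = split,
                 folds = lapply(folds, unclass), mean = mean_metrics,
                 averaging = "weighted",
                 n_classes = folds[[1L]]$n_classes,
                 seed = as.integer(seed), schema_version = 1L),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report %s/%s on %s: %d fold(s)>\n",
              x$model, x$dataset, x$split, length(x$folds)))
  m <- x$mean
  cat(sprintf("  mean: accuracy %.2f  recall %.2f  precision %.2f  F %.3f  MCC %.3f  ROC-AUC %s\n",
              m$accuracy, m$recall, m$precision, m$f_measure, m$mcc,
              ifelse(is.na(m$roc_auc), "NA", sprintf("%.3f", m$roc_auc))))
  invisible(x)
}

#' Write or read metrics reports as JSON
#'
#' @param reports A `metrics_report` or a (possibly empty) list of them.
#' @param path File path.
#' @return `write_metrics_report` returns `path` invisibly;
#'   `read_metrics_report` a list of `metrics_report`s.
#' @export
write_metrics_report <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  payload <- list(schema_version = 1L,
                  reports = lapply(reports, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload$reports, function(r) {
    r$folds <- lapply(r$folds, function(f) {
      f$support <- unlist(f$support)
      f$roc_auc <- as.numeric(f$roc_auc %||% NA_real_)
      structure(f, class = "fold_metrics")
    })
    r$mean <- lapply(r$mean, function(v) as.numeric(v %||% NA_real_))
    structure(r, class = "metrics_report")
  })
}

#' Export ROC curve points for external plotting
#'
#' Writes a tab-separated file of `(model, threshold, fpr, tpr)` rows, one
#' curve per named score set, each anchored at (0,0) and ending at (1,1).
#'
#' @param y_true Binary truth labels (the larger label is the positive
#'   class).
#' @param scores_by_model Named list of score vectors for the positive
#'   class.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_roc_points <- function(y_true, scores_by_model, path) {
  stopifnot(is.list(scores_by_model), !is.null(names(scores_by_model)))
  classes <- sort(unique(as.integer(y_true)))
  if (length(classes) != 2L) stop2("ROC export needs binary truth labels")
  rows <- lapply(names(scores_by_model), function(nm) {
    pts <- roc_points(y_true == classes[[2L]], scores_by_model[[nm]])
    cbind(model = nm, pts)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Noise specification for the robustness benchmark
#'
#' @param levels Noise levels as percentages of the per-feature reference
#'   standard deviation. Default `c(1, 10, 50, 100, 500, 1000, 1500)`.
#' @param seed Integer seed for the noise draws.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(levels = c(1, 10, 50, 100, 500, 1000, 1500), seed = 1L) {
  if (any(levels <= 0)) stop2("noise levels must be positive")
  structure(list(levels = as.numeric(levels), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Per-feature reference standard deviation
#'
#' The scale against which noise levels are expressed, computed from the
#' training portion of the data only.
#'
#' @param x Feature matrix (genes in rows) or `labeled_gene_set`.
#' @return Numeric vector, one standard deviation per feature (sample
#'   position).
#' @export
reference_sd <- function(x) {
  x <- as_feature_matrix(x)
  apply(x, 2L, stats::sd)
}

#' Inject independent Gaussian noise into a batch of gene vectors
#'
#' Each feature j receives zero-mean Gaussian noise with standard
#' deviation `(level / 100) * ref_sd[j]`; a constant feature
#' (`ref_sd = 0`) is left unchanged. Deterministic under the seed.
#'
#' @param x Feature matrix (genes in rows).
#' @param level Positive noise level in percent.
#' @param ref_sd Per-feature reference standard deviations (from
#'   [reference_sd()] on the training portion).
#' @param seed Integer seed.
#' @return The corrupted feature matrix.
#' @export
add_gaussian_noise <- function(x, level, ref_sd, seed = 1L) {
  x <- as_feature_matrix(x)
  if (!is.numeric(level) || length(level) != 1L || level <= 0)
    stop2("noise level must be a single positive percentage")
  if (length(ref_sd) != ncol(x))
    stop2("ref_sd must have one entry per feature")
  noise <- with_seed(derive_seed(seed, paste0("noise", level)), {
    matrix(rnorm(length(x)), nrow = nrow(x))
  })
  x + sweep(noise, 2L, (level / 100) * ref_sd, `*`)
}

#' Accuracy degradation under increasing Gaussian noise
#'
#' Evaluates an unmodified trained model on noise-corrupted copies of the
#' test inputs at each level of the noise specification, plus the clean
#' baseline (level 0). Noise is applied at test time only.
#'
#' @param model A trained `degnet_model`.
#' @param x Test feature matrix or `labeled_gene_set`.
#' @param y Test labels (taken from `x` when it is a `labeled_gene_set`).
#' @param ref_sd Per-feature reference standard deviations from the
#'   training portion.
#' @param spec A [noise_spec()].
#' @return A data frame with one row per level (0 first) and the six
#'   metric columns.
#' @export
robustness_curve <- function(model, x, y = NULL, ref_sd, spec = noise_spec()) {
  stopifnot(inherits(model, "degnet_model"), inherits(spec, "noise_spec"))
  if (inherits(x, "labeled_gene_set")) {
    y <- y %||% x$label
    x <- x$features
  }
  x <- as_feature_matrix(x)
  binary <- head_arity(model) == 2L
  eval_at <- function(xx) {
    sc <- model_forward(model, xx)
    if (binary) sc <- sc[, 2L]
    compute_metrics(y, predict_classes(model, xx), scores = sc)
  }
  levels <- c(0, spec$levels)
  rows <- lapply(levels, function(lv) {
    xx <- if (lv == 0) x else add_gaussian_noise(x, lv, ref_sd, seed = spec$seed)
    m <- eval_at(xx)
    data.frame(level = lv, accuracy = m$accuracy, recall = m$recall,
               precision = m$precision, f_measure = m$f_measure,
               mcc = m$mcc, roc_auc = m$roc_auc)
  })
  do.call(rbind, rows)
}
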