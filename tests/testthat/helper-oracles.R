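# brute-force metric oracles, written independently of compute_metrics
oracle_metrics <- function(y_true, y_pred) {
  classes <- sort(union(y_true, y_pred))
  n <- length(y_true)
  per <- lapply(classes, function(cls) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (y_pred[i] == cls && y_true[i] == cls) tp <- tp + 1
      if (y_pred[i] == cls && y_true[i] != cls) fp <- fp + 1
      if (y_pred[i] != cls && y_true[i] == cls) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f = f, support = sum(y_true == cls))
  })
  w <- vapply(per, function(p) p[["support"]], numeric(1L)) / n
  # generalized MCC straight from its covariance definition
  K <- length(classes)
  C <- matrix(0, K, K)
  for (i in seq_len(n))
    C[match(y_true[i], classes), match(y_pred[i], classes)] <-
      C[match(y_true[i], classes), match(y_pred[i], classes)] + 1
  num <- sum(diag(C)) * n - sum(rowSums(C) * colSums(C))
  den <- sqrt(n^2 - sum(colSums(C)^2)) * sqrt(n^2 - sum(rowSums(C)^2))
  list(accuracy = 100 * mean(y_true == y_pred),
       precision = 100 * sum(w * vapply(per, `[[`, numeric(1L), "prec")),
       recall = 100 * sum(w * vapply(per, `[[`, numeric(1L), "rec")),
       f_measure = sum(w * vapply(per, `[[`, numeric(1L), "f")),
       mcc = if (den == 0) 0 else num / den)
}

# Mann-Whitney U normalization as the independent ROC-AUC oracle
oracle_auc <- function(is_pos, scores) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

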