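#' Simple differential-expression stand-in (Welch t-test on log2 counts)
#'
#' Computes, for each gene, the log2 fold change of tumor over normal mean
#' expression (with a pseudocount) and a p-value from a two-sample
#' unequal-variance t-test on `log2(x + pseudocount)` values, adjusted by
#' Benjamini-Hochberg across all genes. This is a documented, self-contained
#' stand-in for a full count-model DE analysis: when an externally produced
#' DE table (e.g. from edgeR or DESeq2) is available, reading it with
#' [read_de_table()] is the recommended path.
#'
#' @param data An `expression_dataset` with at least two samples per
#'   condition.
#' @param pseudocount Positive value added before log transformation and to
#'   the group means in the fold-change ratio. Default 1.
#' @return A `differential_table` with columns `gene`, `logfc`, `fdr`.
#' @export
compute_de_standin <- function(data, pseudocount = 1) {
  stopifnot(inherits(data, "expression_dataset"), pseudocount > 0)
  is_t <- data$condition == "tumor"
  n_t <- sum(is_t); n_n <- sum(!is_t)
  if (n_t < 2L || n_n < 2L)
    stop2("each condition needs at least 2 samples (variance undefined); got ",
          n_n, " normal, ", n_t, " tumor")

  x <- data$matrix
  logfc <- log2((rowMeans(x[, is_t, drop = FALSE]) + pseudocount) /
                (rowMeans(x[, !is_t, drop = FALSE]) + pseudocount))

  lx <- log2(x + pseudocount)
  m_t <- rowMeans(lx[, is_t, drop = FALSE])
  m_n <- rowMeans(lx[, !is_t, drop = FALSE])
  v_t <- apply(lx[, is_t, drop = FALSE], 1L, stats::var)
  v_n <- apply(lx[, !is_t, drop = FALSE], 1L, stats::var)
  se2 <- v_t / n_t + v_n / n_n
  tstat <- (m_t - m_n) / sqrt(se2)
  df <- se2^2 / ((v_t / n_t)^2 / (n_t - 1L) + (v_n / n_n)^2 / (n_n - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate genes: zero variance in both groups
  flat <- se2 == 0
  p[flat] <- ifelse(m_t[flat] == m_n[flat], 1, 0)
  p[is.na(p)] <- 1

  validate_de_table(data.frame(gene = data$gene_ids, logfc = unname(logfc),
                               fdr = stats::p.adjust(p, method = "BH"),
                               stringsAsFactors = FALSE))
}

#' Label genes as down-regulated, up-regulated or neutral
#'
#' Genes significant at the FDR cutoff are labeled by the sign of their log2
#' fold change: label 0 (down-regulated) below the threshold, label 1
#' (up-regulated) above it; non-significant genes get label 2 (neutral).
#' A gene whose log fold change equals the threshold exactly is assigned
#' neutral and the boundary event is reported. A gene is flagged as
#' biologically validated when it appears in `bio` *and* carries label 0 or
#' 1; bio-listed genes that are not significant keep `bio_flag = FALSE` with
#' a warning.
#'
#' @param data An `expression_dataset`.
#' @param de A `differential_table` covering the dataset's genes; genes
#'   absent from the table are dropped with a warning.
#' @param bio Character vector of biologically validated gene identifiers
#'   (or `NULL` for none).
#' @param fdr_cutoff Significance cutoff on the adjusted p-value. Default
#'   0.01.
#' @param logfc_threshold Sign threshold on the log2 fold change. Default 0.
#' @param feature_transform Transformation applied to the expression values
#'   when building per-gene feature vectors. `"log2_centered_scaled"`
#'   (default) is `(log2(x + 1) - rowmean) * feature_scale`: on the log
#'   scale a fold change acts as an additive shift of the same size for
#'   every gene regardless of its baseline; per-gene centering makes zero
#'   the neutral value, so the zero padding of the 2D reshape reads as
#'   average expression whatever the sample count (which is what lets one
#'   model transfer across cohorts of different sizes); and the scale
#'   constant places inputs on a numeric range that conditions gradient
#'   magnitudes for the fixed learning-rate schedule. `"log2_scaled"`
#'   omits the centering, `"log2"` is plain `log2(x + 1)`, `"none"` passes
#'   the matrix values through.
#' @param feature_scale Multiplier used by the scaled transforms. Default
#'   100.
#' @return A `labeled_gene_set`: `gene_ids`, `features` (genes x samples),
#'   `label` (integer 0/1/2), `bio_flag` (logical), plus the sample
#'   conditions and dataset name of the source.
#' @export
label_genes <- function(data, de, bio = NULL, fdr_cutoff = 0.01,
                        logfc_threshold = 0,
                        feature_transform = c("log2_centered_scaled",
                                              "log2_scaled", "log2", "none"),
                        feature_scale = 100) {
  stopifnot(inherits(data, "expression_dataset"),
            fdr_cutoff > 0, fdr_cutoff < 1)
  feature_transform <- match.arg(feature_transform)
  de <- validate_de_table(as.data.frame(de))

  keep <- data$gene_ids %in% de$gene
  if (!any(keep)) stop2("no genes shared between the dataset and the DE table")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    warning(n_drop, " gene(s) absent from the DE table were dropped",
            call. = FALSE)

  gene_ids <- data$gene_ids[keep]
  de <- de[match(gene_ids, de$gene), ]
  sig <- de$fdr < fdr_cutoff
  label <- ifelse(!sig, 2L,
                  ifelse(de$logfc < logfc_threshold, 0L,
                         ifelse(de$logfc > logfc_threshold, 1L, 2L)))
  n_boundary <- sum(sig & de$logfc == logfc_threshold)
  if (n_boundary > 0L)
    message(n_boundary, " significant gene(s) at the exact logfc threshold ",
            "were assigned neutral")

  bio <- unique(trimws(bio %||% character(0L)))
  in_bio <- gene_ids %in% bio
  bio_flag <- in_bio & label %in% c(0L, 1L)
  n_nonsig_bio <- sum(in_bio & label == 2L)
  if (n_nonsig_bio > 0L)
    warning(n_nonsig_bio, " bio-listed gene(s) are not significant and were ",
            "not flagged as biologically validated", call. = FALSE)

  features <- data$matrix[keep, , drop = FALSE]
  features <- switch(feature_transform,
                     log2_centered_scaled = {
                       lg <- log2(features + 1)
                       (lg - rowMeans(lg)) * feature_scale
                     },
                     log2_scaled = log2(features + 1) * feature_scale,
                     log2 = log2(features + 1),
                     none = features)

  new_labeled_gene_set(gene_ids, features, as.integer(label), bio_flag,
                       condition = data$condition,
                       dataset_name = data$dataset_name)
}

new_labeled_gene_set <- function(gene_ids, features, label, bio_flag,
                                 condition = NULL, dataset_name = "") {
  stopifnot(length(gene_ids) == nrow(features),
            length(label) == length(gene_ids),
            length(bio_flag) == length(gene_ids),
            all(label %in% 0:2))
  if (any(bio_flag & label == 2L))
    stop2("neutral genes can never be biologically validated")
  structure(list(gene_ids = gene_ids, features = features,
                 label = as.integer(label), bio_flag = bio_flag,
                 condition = condition, dataset_name = dataset_name),
            class = "labeled_gene_set")
}

#' @export
print.labeled_gene_set <- function(x, ...) {
  cat(sprintf("<labeled_gene_set '%s': %d genes (%d DR, %d UR, %d neutral; %d bio-validated), %d samples>\n",
              x$dataset_name, length(x$gene_ids), sum(x$label == 0L),
              sum(x$label == 1L), sum(x$label == 2L), sum(x$bio_flag),
              ncol(x$features)))
  invisible(x)
}

# stratified two-way allocation: returns indices for the "large" part so that
# its total equals round(frac * n) and every class is within one gene of its
# proportional share (largest-remainder rounding)
stratified_take <- function(idx, strata, frac) {
  n <- length(idx)
  target <- round(frac * n)
  classes <- sort(unique(strata))
  share <- vapply(classes, function(k) frac * sum(strata == k), numeric(1L))
  base <- floor(share)
  rem <- share - base
  extra <- target - sum(base)
  if (extra > 0L) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  taken <- integer(0L)
  for (i in seq_along(classes)) {
    members <- idx[strata == classes[[i]]]
    members <- members[sample.int(length(members))]
    taken <- c(taken, members[seq_len(base[[i]])])
  }
  sort(taken)
}

#' Split labeled genes into train/test and fine-tune/bio-test partitions
#'
#' The non-bio genes P (neutral genes plus significant genes without
#' biological validation) are split 80:20 into T1 (train) and T2 (test); the
#' bio-validated genes Q are split 80:20 into F1 (fine-tune) and T3
#' (bio-test). Both splits are random, stratified by label, and fully
#' determined by the seed.
#'
#' @param labels A `labeled_gene_set`.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param ratios Two ratios summing to 1; default `c(0.8, 0.2)`.
#' @return A `data_split`: integer index vectors `T1`, `T2`, `F1`, `T3`
#'   (indices into `labels`), with the seed and ratios recorded.
#' @export
make_split <- function(labels, seed, ratios = c(0.8, 0.2)) {
  stopifnot(inherits(labels, "labeled_gene_set"),
            length(ratios) == 2L, abs(sum(ratios) - 1) < 1e-8,
            all(ratios > 0))
  P <- which(!labels$bio_flag)
  Q <- which(labels$bio_flag)
  if (length(P) == 0L) stop2("no non-bio genes to split")
  if (length(Q) < 5L)
    stop2("need at least 5 bio-validated genes for a meaningful 80:20 split; got ",
          length(Q))
  with_seed(derive_seed(seed, "split"), {
    T1 <- stratified_take(P, labels$label[P], ratios[[1L]])
    F1 <- stratified_take(Q, labels$label[Q], ratios[[1L]])
  })
  structure(list(T1 = T1, T2 = sort(setdiff(P, T1)),
                 F1 = F1, T3 = sort(setdiff(Q, F1)),
                 seed = as.integer(seed), ratios = ratios,
                 n_genes = length(labels$gene_ids)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split: |T1|=%d |T2|=%d |F1|=%d |T3|=%d (seed %d)>\n",
              length(x$T1), length(x$T2), length(x$F1), length(x$T3), x$seed))
  invisible(x)
}

#' Persist or restore a data split as JSON
#'
#' @param split A `data_split`.
#' @param path File path.
#' @return `write_split` returns `path` invisibly; `read_split` the
#'   `data_split`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "data_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (f in c("T1", "T2", "F1", "T3")) x[[f]] <- as.integer(x[[f]])
  structure(x, class = "data_split")
}

#' Stratified k-fold assignments over the level-1 training indices
#'
#' Partitions the `T1` indices of a split into `k` disjoint, label-stratified
#' folds, deterministically under the seed.
#'
#' @param labels The `labeled_gene_set` the split refers to.
#' @param split A `data_split`.
#' @param k Number of folds; default 5.
#' @param seed Integer seed.
#' @return List of `k` integer vectors whose union is `split$T1`.
#' @export
make_cv_folds <- function(labels, split, k = 5L, seed) {
  stopifnot(inherits(labels, "labeled_gene_set"), inherits(split, "data_split"),
            k >= 2L)
  idx <- split$T1
  strata <- labels$label[idx]
  counts <- table(strata)
  if (any(counts < k))
    stop2("class ", names(counts)[which(counts < k)[[1L]]],
          " has fewer than k = ", k, " members in T1")
  folds <- vector("list", k)
  with_seed(derive_seed(seed, "cv_folds"), {
    for (cls in sort(unique(strata))) {
      members <- idx[strata == cls]
      members <- members[sample.int(length(members))]
      assign_to <- rep_len(seq_len(k), length(members))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], members[assign_to == f])
    }
  })
  lapply(folds, sort)
}

#' Filter genes by mean expression quantile
#'
#' Retains genes whose mean expression strictly exceeds the `q`-quantile
#' (linear interpolation) of all per-gene means. Off by default in the
#' pipeline; provided as an optional convenience stage.
#'
#' @param data An `expression_dataset`.
#' @param q Quantile in (0, 1); default 0.25.
#' @return The filtered `expression_dataset`.
#' @export
quantile_filter <- function(data, q = 0.25) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop2("q must lie strictly inside (0, 1)")
  means <- rowMeans(data$matrix)
  thr <- stats::quantile(means, q, names = FALSE)
  keep <- means > thr
  if (!any(keep))
    stop2("quantile filter would remove every gene (all means tie at the quantile)")
  new_expression_dataset(data$matrix[keep, , drop = FALSE], data$condition,
                         data$dataset_name, provenance = data$provenance)
}
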