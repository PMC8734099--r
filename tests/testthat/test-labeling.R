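make_count_dataset <- function(mat, n_normal, n_tumor, name = "toy") {
  dimnames(mat) <- list(sprintf("G%03d", seq_len(nrow(mat))),
                        c(sprintf("N%d", seq_len(n_normal)),
                          sprintf("T%d", seq_len(n_tumor))))
  degnet:::new_expression_dataset(mat, rep(c("normal", "tumor"),
                                           c(n_normal, n_tumor)), name)
}

test_that("the DE stand-in reproduces forced fold changes and t-test p-values", {
  # equal group means give logfc 0; tumor mean 31 vs normal 7 with
  # pseudocount 1 gives log2(32/8) = 2
  mat <- rbind(c(5, 9, 5, 9), c(7, 7, 31, 31))
  ds <- make_count_dataset(mat, 2L, 2L)
  de <- compute_de_standin(ds, pseudocount = 1)
  expect_equal(de$logfc[[1L]], 0)
  expect_equal(de$logfc[[2L]], 2)

  # oracle: per-gene Welch t-test on log2(x+1), BH across genes
  set.seed(42)
  mat2 <- matrix(rnbinom(50 * 12, mu = 60, size = 5), nrow = 50)
  ds2 <- make_count_dataset(mat2, 6L, 6L)
  de2 <- compute_de_standin(ds2)
  p_oracle <- apply(log2(mat2 + 1), 1L, function(r)
    stats::t.test(r[7:12], r[1:6])$p.value)
  expect_equal(de2$fdr, unname(stats::p.adjust(p_oracle, "BH")),
               tolerance = 1e-12)

  expect_error(compute_de_standin(make_count_dataset(mat[, -1], 1L, 2L)),
               "at least 2 samples")
})

test_that("genes are labeled by significance and fold-change sign", {
  mat <- matrix(10, nrow = 5, ncol = 4)
  ds <- make_count_dataset(mat, 2L, 2L)
  de <- data.frame(gene = sprintf("G%03d", 1:5),
                   logfc = c(-1.2, 0.8, 2.1, -0.5, 0),
                   fdr = c(0.001, 0.5, 0.004, 0.009, 0.002))
  labels <- suppressWarnings(suppressMessages(
    label_genes(ds, de, bio = c("G003", "G002"))))
  # (-1.2, .001) -> DR; (0.8, .5) -> neutral; (2.1, .004, bio) -> UR + flag;
  # (-0.5, .009) -> DR; significant logfc == 0 -> neutral (boundary rule)
  expect_identical(labels$label, c(0L, 2L, 1L, 0L, 2L))
  expect_identical(labels$bio_flag, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # label conservation
  expect_identical(sum(labels$label == 0L) + sum(labels$label == 1L) +
                   sum(labels$label == 2L), length(labels$gene_ids))

  # bio-listed but not significant -> warning, flag stays FALSE
  expect_warning(label_genes(ds, de, bio = c("G002")), "not significant")

  # genes missing from the DE table are dropped with a warning
  expect_warning(l2 <- label_genes(ds, de[-1, ], bio = NULL), "dropped")
  expect_identical(length(l2$gene_ids), 4L)

  expect_error(label_genes(ds, data.frame(gene = "ZZZ", logfc = 1, fdr = 0.1)),
               "no genes shared")
})

test_that("splits are stratified 80:20 partitions, deterministic under seed", {
  for (case_seed in 1:20) {
    set.seed(case_seed)
    lab <- make_labeled_set(n_dr = sample(20:40, 1), n_ur = sample(20:40, 1),
                            n_neutral = sample(40:90, 1),
                            n_bio_dr = sample(5:15, 1), n_bio_ur = sample(5:15, 1),
                            seed = case_seed)
    split <- make_split(lab, seed = case_seed)
    P <- which(!lab$bio_flag); Q <- which(lab$bio_flag)
    # partition properties
    expect_length(intersect(split$T1, split$T2), 0L)
    expect_length(intersect(split$F1, split$T3), 0L)
    expect_setequal(c(split$T1, split$T2), P)
    expect_setequal(c(split$F1, split$T3), Q)
    expect_length(intersect(c(split$T1, split$T2), c(split$F1, split$T3)), 0L)
    # 80:20 within one gene
    expect_lte(abs(length(split$T1) - 0.8 * length(P)), 1)
    expect_lte(abs(length(split$F1) - 0.8 * length(Q)), 1)
    # stratification within one gene per class
    for (cls in 0:2) {
      in_t1 <- sum(lab$label[split$T1] == cls)
      expect_lte(abs(in_t1 - 0.8 * sum(lab$label[P] == cls)), 1)
    }
    for (cls in 0:1) {
      in_f1 <- sum(lab$label[split$F1] == cls)
      expect_lte(abs(in_f1 - 0.8 * sum(lab$label[Q] == cls)), 1)
    }
    # determinism
    split2 <- make_split(lab, seed = case_seed)
    expect_identical(split, split2)
  }
})

test_that("split sizes follow the ratio arithmetic and stratified allocation", {
  lab <- make_labeled_set(n_dr = 35L, n_ur = 35L, n_neutral = 30L,
                          n_bio_dr = 20L, n_bio_ur = 30L)
  # P = (35-20) + (35-30) + 30 = 50; Q = 20 + 30 = 50
  split <- make_split(lab, seed = 5L)
  expect_length(split$F1, 40L)
  expect_length(split$T3, 10L)
  # Q holds 30 UR and 20 DR -> F1 gets 24 UR + 16 DR (largest remainder)
  expect_identical(sum(lab$label[split$F1] == 1L), 24L)
  expect_identical(sum(lab$label[split$F1] == 0L), 16L)

  tiny <- make_labeled_set(n_bio_dr = 2L, n_bio_ur = 2L)
  expect_error(make_split(tiny, seed = 1L), "at least 5")
})

test_that("cross-validation folds partition T1 with stratified sizes", {
  lab <- make_labeled_set(n_dr = 30L, n_ur = 30L, n_neutral = 65L)
  split <- make_split(lab, seed = 2L)
  folds <- make_cv_folds(lab, split, k = 5L, seed = 2L)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), split$T1)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(folds[[i]], folds[[j]]), 0L)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 3L)  # one per class at most
  # deterministic under seed; different seed reshuffles but keeps sizes
  expect_identical(folds, make_cv_folds(lab, split, k = 5L, seed = 2L))
  folds3 <- make_cv_folds(lab, split, k = 5L, seed = 3L)
  expect_false(identical(folds, folds3))
  expect_identical(lengths(folds3), sizes)

  small <- make_labeled_set(n_dr = 6L, n_ur = 30L, n_neutral = 65L,
                            n_bio_dr = 3L, n_bio_ur = 5L)
  ssplit <- make_split(small, seed = 1L)
  expect_error(make_cv_folds(small, ssplit, k = 5L, seed = 1L), "fewer than k")
})

test_that("quantile filter keeps genes above the mean-expression quantile", {
  mat <- matrix(rep(c(1, 2, 3, 4), 4), nrow = 4)
  ds <- make_count_dataset(mat, 2L, 2L)
  # means (1,2,3,4), q = .25 -> threshold 1.75 by linear interpolation
  kept <- quantile_filter(ds, q = 0.25)
  expect_identical(nrow(kept$matrix), 3L)
  expect_identical(rownames(kept$matrix), c("G002", "G003", "G004"))
  # q near 0: the interpolated threshold sits just above the minimum, so
  # every gene strictly above the minimum survives
  expect_identical(nrow(quantile_filter(ds, q = 1e-9)$matrix), 3L)
  # all means tied: refuse to return an empty dataset
  flat <- make_count_dataset(matrix(5, 4, 4), 2L, 2L)
  expect_error(quantile_filter(flat, q = 0.25), "every gene")
  expect_error(quantile_filter(ds, q = 0), "inside")
  expect_error(quantile_filter(ds, q = 1), "inside")
})

test_that("splits persist to JSON and restore identically", {
  lab <- make_labeled_set()
  split <- make_split(lab, seed = 9L)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(split, path)
  back <- read_split(path)
  expect_identical(back$T1, split$T1)
  expect_identical(back$T3, split$T3)
  expect_identical(back$seed, split$seed)
})
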