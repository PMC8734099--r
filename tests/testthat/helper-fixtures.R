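# fixtures built in code; nothing is read from disk except what a test writes

write_fixture_expression <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                     genes = c("TP53", "BRCA1", "EGFR"),
                                     n_normal = 2L, n_tumor = 2L,
                                     values = NULL, sep = "\t") {
  samples <- c(sprintf("N%d", seq_len(n_normal)), sprintf("T%d", seq_len(n_tumor)))
  n <- length(samples)
  if (is.null(values))
    values <- matrix(seq_len(length(genes) * n), nrow = length(genes))
  mat_path <- file.path(dir, "expr.tsv")
  df <- data.frame(gene = genes, values, check.names = FALSE)
  colnames(df) <- c("gene", samples)
  utils::write.table(df, mat_path, sep = sep, quote = FALSE, row.names = FALSE)
  map_path <- file.path(dir, "map.tsv")
  utils::write.table(data.frame(samples, rep(c("normal", "tumor"),
                                             c(n_normal, n_tumor))),
                     map_path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(matrix = mat_path, map = map_path, samples = samples)
}

# small labeled gene set with controllable class sizes
make_labeled_set <- function(n_dr = 20L, n_ur = 20L, n_neutral = 60L,
                             n_bio_dr = 5L, n_bio_ur = 5L, n_samples = 10L,
                             seed = 1L) {
  n <- n_dr + n_ur + n_neutral
  set.seed(seed)
  label <- c(rep(0L, n_dr), rep(1L, n_ur), rep(2L, n_neutral))
  bio <- c(rep(c(TRUE, FALSE), c(n_bio_dr, n_dr - n_bio_dr)),
           rep(c(TRUE, FALSE), c(n_bio_ur, n_ur - n_bio_ur)),
           rep(FALSE, n_neutral))
  feats <- matrix(rnorm(n * n_samples), n, n_samples)
  degnet:::new_labeled_gene_set(sprintf("G%04d", seq_len(n)), feats, label, bio,
                                condition = rep(c("normal", "tumor"),
                                                length.out = n_samples),
                                dataset_name = "fixture")
}

# tiny architecture for fast structural/training tests
tiny_model_config <- function(head_arity = 3L) {
  model_config(conv_channels = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 4L),
               linear_widths = c(8L, 8L, 8L, 4L, head_arity),
               head_arity = head_arity)
}

tiny_train_config <- function(epochs1 = 5L, epochs2 = 5L) {
  train_config(level1 = list(epochs = epochs1),
               finetune = list(epochs = epochs2))
}

# well-separated 2-condition feature matrix: class 0 low-then-high is
# reversed etc.; returns features + labels for direct training tests
make_separable <- function(n_per_class = 60L, n_samples = 16L, classes = 0:2,
                           seed = 1L, scale = 100) {
  set.seed(seed)
  half <- n_samples %/% 2L
  rows <- lapply(classes, function(cls) {
    base <- switch(as.character(cls),
                   "0" = c(rep(1, half), rep(-1, n_samples - half)),
                   "1" = c(rep(-1, half), rep(1, n_samples - half)),
                   "2" = rep(0, n_samples))
    t(replicate(n_per_class, base * scale + rnorm(n_samples, sd = scale / 10)))
  })
  list(x = do.call(rbind, rows),
       y = rep(classes, each = n_per_class))
}
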