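#' Specification for a synthetic two-condition count dataset
#'
#' Describes a negative-binomial gene-by-sample count matrix with planted
#' up- and down-regulated genes of known sign and a designated biologically
#' validated subset. Per-gene baseline means are drawn log-uniformly;
#' planted up-regulated genes have tumor mean `2^effect_logfc` times the
#' normal mean, down-regulated genes the reciprocal, neutral genes equal
#' means. Counts follow a negative binomial with variance
#' `mu + dispersion * mu^2` (the standard RNA-seq count model).
#'
#' @param n_genes Number of genes. Default 2000.
#' @param n_normal,n_tumor Samples per condition. Default 20 each.
#' @param frac_ur,frac_dr Fractions of planted up-/down-regulated genes.
#'   Default 0.2 each.
#' @param effect_logfc Planted absolute log2 fold change (> 0). Default 2.
#' @param base_mean_log_range Range (low, high) of baseline means on the
#'   log2 scale. Default `c(3, 10)` (means between 8 and 1024 counts).
#' @param dispersion Negative-binomial overdispersion (> 0). Default 0.2.
#' @param bio_frac Fraction of planted DEGs marked biologically validated.
#'   Default 0.25.
#' @param seed Integer seed making the draw fully deterministic.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_normal = 20L, n_tumor = 20L,
                           frac_ur = 0.2, frac_dr = 0.2, effect_logfc = 2,
                           base_mean_log_range = c(3, 10), dispersion = 0.2,
                           bio_frac = 0.25, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
               n_tumor = as.integer(n_tumor), frac_ur = frac_ur,
               frac_dr = frac_dr, effect_logfc = effect_logfc,
               base_mean_log_range = as.numeric(base_mean_log_range),
               dispersion = dispersion, bio_frac = bio_frac,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_genes < 1L || n_normal < 1L || n_tumor < 1L)
      stop2("n_genes, n_normal and n_tumor must all be at least 1")
    if (frac_ur < 0 || frac_dr < 0 || frac_ur + frac_dr > 1)
      stop2("frac_ur and frac_dr must be non-negative with frac_ur + frac_dr <= 1")
    if (effect_logfc <= 0) stop2("effect_logfc must be positive")
    if (dispersion <= 0) stop2("dispersion must be positive")
    if (bio_frac < 0 || bio_frac > 1) stop2("bio_frac must lie in [0, 1]")
    if (length(base_mean_log_range) != 2L ||
        base_mean_log_range[[2L]] < base_mean_log_range[[1L]])
      stop2("base_mean_log_range must be an increasing (low, high) pair")
  })
  invisible(spec)
}

#' Simulate a two-condition expression dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param dataset_name Name recorded in the outputs.
#' @return A list with `dataset` (`expression_dataset` of counts), `truth`
#'   (`labeled_gene_set` holding the planted labels and bio flags, with
#'   features on the default `log2_scaled` scale of [label_genes()]) and
#'   `bio` (character vector: the designated
#'   biologically validated subset of the planted DEGs).
#' @export
simulate_dataset <- function(spec, dataset_name = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  g <- spec$n_genes
  n_ur <- round(spec$frac_ur * g)
  n_dr <- round(spec$frac_dr * g)

  with_seed(derive_seed(spec$seed, "simulate"), {
    truth_label <- rep(2L, g)
    planted <- sample.int(g, n_ur + n_dr)
    truth_label[planted[seq_len(n_ur)]] <- 1L
    if (n_dr > 0L) truth_label[planted[n_ur + seq_len(n_dr)]] <- 0L

    base_mean <- 2^runif(g, spec$base_mean_log_range[[1L]],
                         spec$base_mean_log_range[[2L]])
    fold <- 2^(spec$effect_logfc * (truth_label == 1L) -
               spec$effect_logfc * (truth_label == 0L))
    size <- 1 / spec$dispersion
    normal <- matrix(rnbinom(g * spec$n_normal, mu = rep(base_mean, spec$n_normal),
                             size = size), nrow = g)
    tumor <- matrix(rnbinom(g * spec$n_tumor, mu = rep(base_mean * fold, spec$n_tumor),
                            size = size), nrow = g)
    n_bio <- round(spec$bio_frac * length(planted))
    bio_idx <- if (n_bio > 0L) sort(sample(planted, n_bio)) else integer(0L)
  })

  counts <- cbind(normal, tumor)
  gene_ids <- sprintf("G%05d", seq_len(g))
  dimnames(counts) <- list(gene_ids,
                           c(sprintf("N%03d", seq_len(spec$n_normal)),
                             sprintf("T%03d", seq_len(spec$n_tumor))))
  condition <- rep(c("normal", "tumor"), c(spec$n_normal, spec$n_tumor))
  dataset <- new_expression_dataset(counts, condition, dataset_name,
                                    provenance = list(spec = unclass(spec)))
  bio <- gene_ids[bio_idx]
  lg <- log2(counts + 1)
  truth <- new_labeled_gene_set(gene_ids, (lg - rowMeans(lg)) * 100, truth_label,
                                bio_flag = gene_ids %in% bio & truth_label != 2L,
                                condition = condition,
                                dataset_name = dataset_name)
  list(dataset = dataset, truth = truth, bio = bio)
}

#' Simulate a family of related datasets for transfer experiments
#'
#' All family members share the generative parameters (effect size,
#' dispersion, fractions of planted genes) but have independent genes and
#' samples, and may differ in sample count — emulating transfer from large
#' training cohorts to small unseen ones.
#'
#' @param base_spec A [synthetic_spec()] providing the shared parameters.
#' @param n_datasets Number of datasets (at least 2).
#' @param seeds Integer vector with one seed per dataset.
#' @param n_normal,n_tumor Optional integer vectors (recycled) overriding
#'   the per-dataset sample counts.
#' @param bio_frac Optional numeric vector (recycled) overriding the
#'   per-dataset bio-validated fraction.
#' @return List of [simulate_dataset()] results, one per dataset, each with
#'   the shared family parameters recorded in the dataset's provenance.
#' @export
simulate_family <- function(base_spec, n_datasets, seeds,
                            n_normal = NULL, n_tumor = NULL, bio_frac = NULL) {
  stopifnot(inherits(base_spec, "synthetic_spec"))
  if (n_datasets < 2L) stop2("a dataset family needs at least 2 members")
  if (length(seeds) < n_datasets)
    stop2("need at least one seed per dataset: got ", length(seeds),
          " seeds for ", n_datasets, " datasets")
  n_normal <- rep_len(n_normal %||% base_spec$n_normal, n_datasets)
  n_tumor <- rep_len(n_tumor %||% base_spec$n_tumor, n_datasets)
  bio_frac <- rep_len(bio_frac %||% base_spec$bio_frac, n_datasets)
  family_id <- paste0("family-", derive_seed(seeds[[1L]], "family"))
  lapply(seq_len(n_datasets), function(i) {
    spec <- base_spec
    spec$n_normal <- as.integer(n_normal[[i]])
    spec$n_tumor <- as.integer(n_tumor[[i]])
    spec$bio_frac <- bio_frac[[i]]
    spec$seed <- as.integer(seeds[[i]])
    out <- simulate_dataset(spec, dataset_name = sprintf("%s-%d", family_id, i))
    out$dataset$provenance$family <- list(
      id = family_id, member = i,
      effect_logfc = base_spec$effect_logfc,
      dispersion = base_spec$dispersion,
      frac_ur = base_spec$frac_ur, frac_dr = base_spec$frac_dr)
    out
  })
}
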