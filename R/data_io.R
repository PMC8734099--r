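#' Read a gene-by-sample expression matrix with its condition map
#'
#' The expression file is delimited text with a header row of sample
#' identifiers and gene identifiers in the first column. Tab is the canonical
#' delimiter; comma is accepted and detected by sniffing the header line. The
#' condition map is two-column delimited text (sample identifier, condition)
#' without a header; conditions must be `"normal"` or `"tumor"`.
#'
#' @param path Path to the expression matrix file.
#' @param condition_map Path to the sample-to-condition map file.
#' @param dataset_name Name recorded in the returned object; defaults to the
#'   file name without extension.
#' @return An `expression_dataset` object: a list with `matrix` (numeric,
#'   genes x samples, dimnames set), `gene_ids`, `sample_ids`, `condition`
#'   (character vector aligned with samples) and `dataset_name`.
#' @details Every sample present in the matrix must appear in the map;
#'   duplicate gene identifiers, non-numeric cells, unknown condition tags
#'   and an empty map are errors. Matrix entries must be finite and
#'   non-negative.
#' @export
read_expression <- function(path, condition_map,
                            dataset_name = tools::file_path_sans_ext(basename(path))) {
  sep <- sniff_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop2("expression file has no data rows or no sample columns: ", path)
  gene_ids <- trimws(raw[[1L]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L)
    stop2("duplicate gene id in expression matrix: ", dup[[1L]])
  sample_ids <- trimws(colnames(raw)[-1L])
  if (anyDuplicated(sample_ids))
    stop2("duplicate sample id in expression matrix header")

  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop2(sprintf("non-numeric expression value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
                  cells[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                  bad[1L, 1L], sample_ids[bad[1L, 2L]], bad[1L, 2L]))
  if (anyNA(num) || any(!is.finite(num)))
    stop2("expression matrix contains missing or non-finite values")
  if (any(num < 0))
    stop2("expression matrix contains negative values")
  dimnames(num) <- list(gene_ids, sample_ids)

  cmap <- read_condition_map(condition_map)
  missing <- setdiff(sample_ids, names(cmap))
  if (length(missing) > 0L)
    stop2("samples missing from condition map: ", paste(head(missing, 5L), collapse = ", "))
  condition <- unname(cmap[sample_ids])

  new_expression_dataset(num, condition, dataset_name)
}

read_condition_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop2("no samples mapped: condition map is empty")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]])) "," else "[[:space:]]+"
  parts <- strsplit(lines, sep)
  # tolerate an optional header line
  if (tolower(trimws(parts[[1L]][2L] %||% "")) %in% c("condition", "group", "status"))
    parts <- parts[-1L]
  if (length(parts) == 0L) stop2("no samples mapped: condition map is empty")
  ids <- vapply(parts, function(p) trimws(p[[1L]]), character(1L))
  cond <- vapply(parts, function(p) trimws(p[2L] %||% NA_character_), character(1L))
  if (anyNA(cond)) stop2("condition map rows must have two columns")
  unknown <- setdiff(unique(cond), c("normal", "tumor"))
  if (length(unknown) > 0L)
    stop2("unknown condition tag: '", unknown[[1L]], "' (expected 'normal' or 'tumor')")
  if (anyDuplicated(ids)) stop2("duplicate sample id in condition map: ",
                                ids[duplicated(ids)][[1L]])
  stats::setNames(cond, ids)
}

new_expression_dataset <- function(matrix, condition, dataset_name,
                                   provenance = list()) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (length(condition) != ncol(matrix))
    stop2("condition vector length must equal the number of samples")
  structure(list(matrix = matrix,
                 gene_ids = rownames(matrix),
                 sample_ids = colnames(matrix),
                 condition = condition,
                 dataset_name = dataset_name,
                 provenance = provenance),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d genes x %d samples (%d normal, %d tumor)>\n",
              x$dataset_name, nrow(x$matrix), ncol(x$matrix),
              sum(x$condition == "normal"), sum(x$condition == "tumor")))
  invisible(x)
}

#' Write an expression dataset and its condition map to disk
#'
#' @param data An `expression_dataset`.
#' @param path Output path for the matrix (tab-separated).
#' @param condition_map Output path for the two-column condition map.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(data, path, condition_map) {
  stopifnot(inherits(data, "expression_dataset"))
  df <- data.frame(gene = data$gene_ids, data$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = data$sample_ids, condition = data$condition),
                     condition_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects delimited text with a header naming the columns `gene`, `logfc`
#' and `fdr` (case-insensitive, any order, extra columns ignored).
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns `gene`, `logfc`, `fdr`, one row per
#'   gene, of class `differential_table`.
#' @export
read_de_table <- function(path) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  names(df) <- tolower(trimws(names(df)))
  for (col in c("gene", "logfc", "fdr"))
    if (!col %in% names(df)) stop2("DE table is missing column '", col, "'")
  if (nrow(df) == 0L) stop2("empty table: DE table has a header but no rows")
  out <- data.frame(gene = trimws(as.character(df$gene)),
                    logfc = as.numeric(df$logfc),
                    fdr = as.numeric(df$fdr),
                    stringsAsFactors = FALSE)
  validate_de_table(out)
}

validate_de_table <- function(out) {
  if (anyDuplicated(out$gene))
    stop2("duplicate gene in DE table: ", out$gene[duplicated(out$gene)][[1L]])
  bad <- which(!is.finite(out$logfc))
  if (length(bad) > 0L)
    stop2("non-finite logfc for gene '", out$gene[bad[[1L]]], "'")
  bad <- which(is.na(out$fdr) | out$fdr < 0 | out$fdr > 1)
  if (length(bad) > 0L)
    stop2("fdr outside [0,1] for gene '", out$gene[bad[[1L]]], "'")
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Write a differential-expression table
#' @param de A `differential_table` (or data frame with gene/logfc/fdr).
#' @param path Output path (tab-separated, with header).
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene", "logfc", "fdr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a biologically validated gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored;
#' duplicates are removed. Matching against other inputs is by exact string
#' after whitespace stripping (gene symbols are case-sensitive).
#'
#' @param path Path to the list.
#' @return Character vector of unique gene identifiers.
#' @export
read_bio_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop2("bio gene list is empty: ", path)
  unique(lines)
}

#' Write a biologically validated gene list
#' @param genes Character vector of gene identifiers.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bio_list <- function(genes, path) {
  writeLines(unique(trimws(genes)), path)
  invisible(path)
}

sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop2("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

CHECKPOINT_FORMAT <- "degnet_checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save or load a model checkpoint
#'
#' A checkpoint stores the full architecture configuration alongside the
#' weights, the head arity and the provenance record, so loading never
#' depends on external configuration. A loaded checkpoint reproduces
#' bit-identical predictions to the saved model.
#'
#' @param model A `degnet_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `degnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "degnet_model"))
  payload <- list(format = CHECKPOINT_FORMAT,
                  version = CHECKPOINT_VERSION,
                  package_version = as.character(utils::packageVersion("degnet")),
                  model = model)
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop2("corrupted or unreadable checkpoint file: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(payload) || !identical(payload$format, CHECKPOINT_FORMAT))
    stop2("not a degnet checkpoint: ", path)
  if (!identical(payload$version, CHECKPOINT_VERSION))
    stop2("checkpoint version mismatch: file has ", payload$version,
          ", this package reads ", CHECKPOINT_VERSION)
  model <- payload$model
  if (!inherits(model, "degnet_model")) stop2("checkpoint payload is damaged: ", path)
  model
}
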