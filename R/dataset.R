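#' Construct an expression dataset
#'
#' The basic container used throughout the package: a genes-by-samples
#' numeric matrix with unique gene identifiers as rownames and one class
#' label per sample (column).  This mirrors the layout of multi-class
#' tumour panels such as the Global Cancer Map: many features, few samples
#' per class, possible class imbalance.
#'
#' @param matrix Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(matrix)`.
#' @param labels Vector of per-sample class labels (coerced to character),
#'   one per column.
#' @param require_labels If `FALSE`, allow an unlabeled matrix (used while
#'   loading, before a label file is attached).
#' @return An object of class `expression_dataset` with fields `matrix`,
#'   `gene_ids`, `labels`.
#' @examples
#' m <- matrix(rnorm(20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' ds <- expression_dataset(m, labels = c("A", "A", "B", "B"))
#' n_genes(ds)
#' @export
expression_dataset <- function(matrix, gene_ids = rownames(matrix),
                               labels = NULL, require_labels = TRUE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (genes x samples)")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("expression matrix contains missing or non-finite values; ",
         "no imputation is performed")
  if (is.null(gene_ids))
    gene_ids <- paste0("gene_", seq_len(nrow(matrix)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(matrix))
    stop("need one gene id per matrix row: ", length(gene_ids),
         " ids vs ", nrow(matrix), " rows")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene ids are not allowed (chromosomes index genes ",
         "positionally): ", paste(unique(dup), collapse = ", "))
  rownames(matrix) <- gene_ids
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(matrix))
      stop("label count (", length(labels), ") does not match sample count (",
           ncol(matrix), ")")
  } else if (require_labels) {
    stop("`labels` is required (one class label per sample)")
  }
  if (!is.null(labels)) {
    tab <- table(labels)
    if (length(tab) < 2L)
      stop("need at least 2 distinct classes, got ", length(tab))
    small <- names(tab)[tab < 2L]
    if (length(small))
      stop("every class needs >= 2 samples; offending class(es): ",
           paste(small, collapse = ", "))
  }
  structure(list(matrix = matrix, gene_ids = gene_ids, labels = labels),
            class = "expression_dataset")
}

#' @rdname expression_dataset
#' @param x An `expression_dataset`.
#' @export
n_genes <- function(x) nrow(x$matrix)

#' @rdname expression_dataset
#' @export
n_samples <- function(x) ncol(x$matrix)

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", n_genes(x), " genes x ", n_samples(x),
      " samples", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("; ", length(tab), " classes (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Attach labels to an unlabeled dataset
#'
#' @param dataset An `expression_dataset` loaded without labels.
#' @param labels Per-sample class labels.
#' @return A labeled `expression_dataset`.
#' @export
set_labels <- function(dataset, labels) {
  stopifnot(inherits(dataset, "expression_dataset"))
  expression_dataset(dataset$matrix, dataset$gene_ids, labels)
}
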