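#' Labeled expression dataset
#'
#' The universal pipeline input: a cells x genes matrix of nonnegative,
#' finite expression values (by convention log1p-transformed counts, though
#' all downstream stages treat the scale as arbitrary), together with unique
#' cell and gene identifiers and a per-cell class label (cell type).
#'
#' @param matrix numeric cells x genes matrix, nonnegative and finite.
#' @param labels per-cell class labels; character or factor of length
#'   `nrow(matrix)`.
#' @param gene_ids unique gene identifiers; defaults to `colnames(matrix)`.
#' @param cell_ids unique cell identifiers; defaults to `rownames(matrix)`.
#' @param class_order optional explicit class set/order; defaults to the
#'   sorted unique labels (or the factor levels of `labels`).
#'
#' @return an object of class `labeled_dataset`: a list with elements
#'   `matrix` (with `cell_ids`/`gene_ids` as dimnames), `gene_ids`,
#'   `cell_ids`, `labels` (factor) and `class_order`.
#' @export
labeled_dataset <- function(matrix, labels, gene_ids = colnames(matrix),
                            cell_ids = rownames(matrix), class_order = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(gene_ids)) stopf("'gene_ids' missing and matrix has no colnames")
  if (is.null(cell_ids)) stopf("'cell_ids' missing and matrix has no rownames")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (ncol(matrix) != length(gene_ids)) {
    stopf("matrix has %d columns but %d gene_ids", ncol(matrix), length(gene_ids))
  }
  if (nrow(matrix) != length(cell_ids)) {
    stopf("matrix has %d rows but %d cell_ids", nrow(matrix), length(cell_ids))
  }
  if (length(labels) != nrow(matrix)) {
    stopf("%d labels for %d cells", length(labels), nrow(matrix))
  }
  if (anyDuplicated(gene_ids)) stopf("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stopf("duplicate cell_ids")
  if (any(!is.finite(matrix))) stopf("matrix contains non-finite values")
  if (any(matrix < 0)) stopf("matrix contains negative values")
  if (is.null(class_order)) {
    class_order <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  }
  labels <- as.character(labels)
  if (!all(labels %in% class_order)) {
    bad <- setdiff(unique(labels), class_order)
    stopf("labels outside the declared class set: %s", paste(bad, collapse = ", "))
  }
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(
    list(matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = factor(labels, levels = class_order), class_order = class_order),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d cells x %d genes, %d classes\n",
              nrow(x$matrix), ncol(x$matrix), length(x$class_order)))
  tab <- table(x$labels)
  cat(sprintf("  class sizes: min %d, median %s, max %d\n",
              min(tab), format(stats::median(tab)), max(tab)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$matrix)

# restrict to a gene subset (keeps labels); internal
restrict_genes <- function(dataset, genes) {
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing)) {
    stopf("genes not in dataset: %s", paste(utils::head(missing, 5), collapse = ", "))
  }
  labeled_dataset(dataset$matrix[, genes, drop = FALSE], dataset$labels,
                  gene_ids = genes, cell_ids = dataset$cell_ids,
                  class_order = dataset$class_order)
}
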