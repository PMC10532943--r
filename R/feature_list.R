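#' Ranked feature list
#'
#' One ranker's ordered genes with scores. For score-based rankers the
#' order is by score descending with ties broken by gene id ascending;
#' for greedy selection (mRMR) the order is the selection order and the
#' scores are the selection-round criterion values, with unselected genes
#' appended by gene id with `NA` scores.
#'
#' @param method ranker name, one of `"lasso"`, `"gbt"`, `"mcfs"`,
#'   `"mrmr"`, `"rf"` (or any label for externally produced lists).
#' @param genes character vector of unique gene ids.
#' @param scores numeric vector parallel to `genes` (`NA` allowed only for
#'   an appended unscored tail).
#' @param reorder if `TRUE` (default) sort by score descending, ties by
#'   gene id ascending; if `FALSE` keep the given order (selection-order
#'   lists).
#' @return object of class `feature_list`: list with `method`, `genes`,
#'   `scores`.
#' @export
feature_list <- function(method, genes, scores, reorder = TRUE) {
  genes <- as.character(genes)
  scores <- as.numeric(scores)
  if (length(genes) != length(scores)) {
    stopf("%d genes but %d scores", length(genes), length(scores))
  }
  if (anyDuplicated(genes)) stopf("duplicate gene ids in feature list")
  if (reorder) {
    ord <- order(-scores, genes)
    genes <- genes[ord]
    scores <- scores[ord]
  } else {
    scored <- !is.na(scores)
    if (any(scored) && any(!scored) && max(which(scored)) > min(which(!scored))) {
      stopf("NA scores must form a contiguous tail of the list")
    }
  }
  structure(list(method = as.character(method), genes = genes, scores = scores),
            class = "feature_list")
}

#' @export
print.feature_list <- function(x, ...) {
  cat(sprintf("feature_list '%s': %d genes (top: %s)\n", x$method,
              length(x$genes), paste(utils::head(x$genes, 5), collapse = ", ")))
  invisible(x)
}

#' @export
length.feature_list <- function(x) length(x$genes)

#' @export
as.data.frame.feature_list <- function(x, ...) {
  data.frame(rank = seq_along(x$genes), gene_id = x$genes, score = x$scores,
             stringsAsFactors = FALSE)
}
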