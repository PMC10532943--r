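#' SMOTE oversampling to the largest class size
#'
#' Synthetic minority oversampling: every class smaller than the largest
#' class is topped up with synthetic cells until all class counts equal
#' the original maximum. Each synthetic sample is `x + lambda * (x_nn - x)`
#' for a real sample `x` of the class, one of its `k` nearest same-class
#' neighbors `x_nn` (Euclidean distance in the dataset's current gene
#' space) and `lambda` uniform in \[0, 1) — i.e. a point on the segment
#' between two real same-class cells. Original cells are preserved
#' verbatim (in their original order, synthetic rows appended); synthetic
#' cell ids carry a `synthetic:` prefix.
#'
#' The effective neighbor count for a class of size `n_c` is
#' `min(k_neighbors, n_c - 1)`, so every class needs at least 2 samples.
#'
#' By default the cross-validation engine applies this only to the
#' training portion of each fold (see [ifs_config()]); balancing the full
#' dataset before splitting leaks interpolated copies of test cells into
#' the training data and inflates measured performance.
#'
#' @param dataset a [labeled_dataset()].
#' @param k_neighbors neighbor pool size (default 5).
#' @param seed integer seed; output is deterministic in (dataset, seed).
#' @param on_singleton what to do with a class holding a single sample,
#'   which has no neighbor to interpolate with: `"error"` (default;
#'   callers should drop or duplicate such classes deliberately) or
#'   `"duplicate"` (top the class up with verbatim copies — the
#'   degenerate segment from the sample to itself). The cross-validation
#'   engine uses `"duplicate"`, since fold splitting routinely strands a
#'   single training cell of a rare class.
#' @return a [labeled_dataset()] with `L x max(class size)` cells. If the
#'   input is already balanced it is returned unchanged.
#' @export
smote <- function(dataset, k_neighbors = 5, seed = 1,
                  on_singleton = c("error", "duplicate")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  on_singleton <- match.arg(on_singleton)
  k_neighbors <- check_count(k_neighbors, "k_neighbors")
  if (nrow(dataset$matrix) == 0L) stopf("empty dataset")
  tab <- table(dataset$labels)
  tab <- tab[tab > 0]
  if (any(tab == 1L) && on_singleton == "error") {
    stopf("class(es) with a single sample cannot be oversampled (no neighbor): %s; drop or duplicate them first",
          paste(names(tab)[tab == 1L], collapse = ", "))
  }
  n_max <- max(tab)
  if (all(tab == n_max)) return(dataset)

  synth_rows <- list()
  synth_labels <- character(0)
  synth_ids <- character(0)
  with_seed(seed, {
    for (cls in names(tab)) {
      n_c <- as.integer(tab[[cls]])
      n_new <- n_max - n_c
      if (n_new == 0L) next
      rows <- which(as.character(dataset$labels) == cls)
      X <- dataset$matrix[rows, , drop = FALSE]
      if (n_c == 1L) {  # on_singleton == "duplicate"
        synth_rows[[cls]] <- X[rep(1L, n_new), , drop = FALSE]
        synth_labels <- c(synth_labels, rep(cls, n_new))
        synth_ids <- c(synth_ids, sprintf("synthetic:%s:%04d", cls, seq_len(n_new)))
        next
      }
      k_eff <- min(k_neighbors, n_c - 1L)
      d <- as.matrix(stats::dist(X))
      diag(d) <- Inf
      # k_eff nearest same-class neighbors of each sample (ties by index)
      nn <- vapply(seq_len(n_c),
                   function(i) order(d[i, ])[seq_len(k_eff)],
                   integer(k_eff))
      nn <- matrix(nn, nrow = k_eff)
      base <- sample.int(n_c, n_new, replace = TRUE)
      pick <- sample.int(k_eff, n_new, replace = TRUE)
      lambda <- stats::runif(n_new)
      neigh <- nn[cbind(pick, base)]
      new_rows <- X[base, , drop = FALSE] +
        lambda * (X[neigh, , drop = FALSE] - X[base, , drop = FALSE])
      synth_rows[[cls]] <- new_rows
      synth_labels <- c(synth_labels, rep(cls, n_new))
      synth_ids <- c(synth_ids, sprintf("synthetic:%s:%04d", cls, seq_len(n_new)))
    }
  })
  new_matrix <- rbind(dataset$matrix, do.call(rbind, synth_rows))
  labeled_dataset(new_matrix,
                  c(as.character(dataset$labels), synth_labels),
                  gene_ids = dataset$gene_ids,
                  cell_ids = c(dataset$cell_ids, synth_ids),
                  class_order = dataset$class_order)
}
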