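#' Specification of a synthetic labeled expression dataset
#'
#' Describes a cells x genes dataset with class-specific planted marker
#' genes, severe class imbalance and a noisy uninformative background —
#' the statistical structure the marker-discovery pipeline assumes.
#' Counts are drawn per entry from a negative binomial with mean
#' `baseline_mean` and shape `dispersion`; each class owns
#' `markers_per_class` disjoint marker genes whose mean is multiplied by
#' `exp(effect_size)` in cells of that class; entries are then zeroed
#' independently with probability `dropout_rate` (dropout), and stored as
#' `log(1 + count)`.
#'
#' @param n_classes number of cell types (>= 2).
#' @param n_genes total number of genes.
#' @param markers_per_class planted marker genes per class;
#'   `markers_per_class * n_classes <= n_genes`.
#' @param class_sizes either an integer vector of per-class cell counts
#'   (all >= 2), or the profile name `"colon-immune"`, which rescales the
#'   published 25-subtype colon immune proportions (max/min ratio 1252) to
#'   `total_cells` cells, flooring at 2 cells per class.
#' @param total_cells total cell count used when `class_sizes` is a profile
#'   name (default 3000).
#' @param effect_size mean log-expression shift of a marker in its own
#'   class (>= 0; default 2, i.e. a `exp(2) ~ 7.4`-fold mean increase).
#' @param baseline_mean negative-binomial mean of background expression
#'   counts (default 1).
#' @param dispersion negative-binomial shape parameter (default 1; smaller
#'   is more overdispersed).
#' @param dropout_rate probability that an entry is zeroed (default 0.2).
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#'
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [planted_markers()]
#' @export
synthetic_spec <- function(n_classes = 25, n_genes = 2000, markers_per_class = 5,
                           class_sizes = "colon-immune", total_cells = 3000,
                           effect_size = 2, baseline_mean = 1, dispersion = 1,
                           dropout_rate = 0.2, seed = 1) {
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  markers_per_class <- check_count(markers_per_class, "markers_per_class", min = 0L)
  if (markers_per_class * n_classes > n_genes) {
    stopf("'markers_per_class' x 'n_classes' (%d) exceeds 'n_genes' (%d)",
          markers_per_class * n_classes, n_genes)
  }
  if (is.character(class_sizes)) {
    if (!identical(class_sizes, "colon-immune")) {
      stopf("unknown 'class_sizes' profile '%s' (known: \"colon-immune\")", class_sizes)
    }
    profile <- colon_immune_class_sizes()
    if (n_classes != length(profile)) {
      stopf("'class_sizes' profile \"colon-immune\" requires n_classes = %d", length(profile))
    }
    class_sizes <- scale_class_sizes(total_cells, profile)
  } else {
    nm <- names(class_sizes)
    class_sizes <- vapply(seq_along(class_sizes), function(i) {
      check_count(class_sizes[[i]], sprintf("class_sizes[%d]", i), min = 2L)
    }, integer(1))
    names(class_sizes) <- nm
    if (length(class_sizes) != n_classes) {
      stopf("'class_sizes' has length %d but n_classes = %d",
            length(class_sizes), n_classes)
    }
    if (is.null(names(class_sizes)) || anyDuplicated(names(class_sizes))) {
      names(class_sizes) <- sprintf("class%02d", seq_len(n_classes))
    }
  }
  if (length(effect_size) != 1L || !is.numeric(effect_size) || effect_size < 0) {
    stopf("'effect_size' must be a single number >= 0")
  }
  structure(
    list(n_classes = n_classes, n_genes = n_genes,
         markers_per_class = markers_per_class,
         class_sizes = class_sizes,
         effect_size = as.numeric(effect_size),
         baseline_mean = check_positive(baseline_mean, "baseline_mean"),
         dispersion = check_positive(dispersion, "dispersion"),
         dropout_rate = check_prob(dropout_rate, "dropout_rate"),
         seed = check_count(seed, "seed", min = 0L)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_spec: %d classes, %d genes, %d markers/class, ",
                     "%d cells (class sizes %d..%d)\n"),
              x$n_classes, x$n_genes, x$markers_per_class, sum(x$class_sizes),
              min(x$class_sizes), max(x$class_sizes)))
  cat(sprintf("  effect_size %.3g, baseline_mean %.3g, dispersion %.3g, dropout %.3g, seed %d\n",
              x$effect_size, x$baseline_mean, x$dispersion, x$dropout_rate, x$seed))
  invisible(x)
}

spec_gene_ids <- function(spec) sprintf("g%05d", seq_len(spec$n_genes))

#' Ground-truth planted marker genes of a synthetic spec
#'
#' Returns the class -> marker-gene assignment that [generate_dataset()]
#' uses for the same spec (markers are sampled from the gene pool with the
#' spec's seed, so the two functions always agree). The sets are pairwise
#' disjoint with exactly `markers_per_class` genes each.
#'
#' @param spec a [synthetic_spec()].
#' @return named list (one element per class) of character vectors of gene ids.
#' @export
planted_markers <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- spec_gene_ids(spec)
  idx <- with_seed(spec$seed, sample.int(spec$n_genes, spec$n_classes * spec$markers_per_class))
  split(genes[idx], rep(names(spec$class_sizes), each = spec$markers_per_class))[
    names(spec$class_sizes)]
}

#' Generate a synthetic labeled expression dataset
#'
#' Draws counts per entry from NB(`baseline_mean`, `dispersion`); for each
#' class, its planted marker genes get their mean multiplied by
#' `exp(effect_size)` in cells of that class; dropout zeroes each entry
#' independently with probability `dropout_rate`; values are stored as
#' `log(1 + count)`. Identical spec + seed give bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return a [labeled_dataset()] whose per-class cell counts equal
#'   `spec$class_sizes` exactly.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- spec_gene_ids(spec)
  classes <- names(spec$class_sizes)
  n_cells <- sum(spec$class_sizes)
  labels <- rep(classes, times = spec$class_sizes)
  with_seed(spec$seed, {
    # marker sampling first: replays the same stream prefix as planted_markers()
    midx <- sample.int(spec$n_genes, spec$n_classes * spec$markers_per_class)
    marker_of_class <- split(midx, rep(seq_len(spec$n_classes), each = spec$markers_per_class))
    mu <- matrix(spec$baseline_mean, nrow = n_cells, ncol = spec$n_genes)
    fold <- exp(spec$effect_size)
    if (spec$markers_per_class > 0) {
      for (ci in seq_len(spec$n_classes)) {
        rows <- which(labels == classes[ci])
        mu[rows, marker_of_class[[ci]]] <- spec$baseline_mean * fold
      }
    }
    counts <- matrix(stats::rnbinom(n_cells * spec$n_genes, size = spec$dispersion,
                                    mu = as.vector(mu)),
                     nrow = n_cells, ncol = spec$n_genes)
    if (spec$dropout_rate > 0) {
      counts[stats::runif(length(counts)) < spec$dropout_rate] <- 0L
    }
    labeled_dataset(log1p(counts), labels,
                    gene_ids = genes,
                    cell_ids = sprintf("cell%06d", seq_len(n_cells)),
                    class_order = classes)
  })
}
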