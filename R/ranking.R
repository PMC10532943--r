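#' Rank genes by one-vs-rest lasso coefficients
#'
#' Fits, for each class, an L1-penalized linear model of the 0/1 class
#' indicator on all genes (one-vs-rest) and scores each gene by the
#' maximum absolute coefficient across classes, read at the penalty
#' `lambda_frac * lambda_max` (per class). Reading the coefficients high
#' on the path, while each one-vs-rest model is still sparse, keeps the
#' score focused on each class's strongest predictors instead of the
#' noisy near-unpenalized fit; the default fraction was calibrated by
#' planted-marker recovery on synthetic data. Genes with all-zero
#' coefficients rank after every nonzero gene, ties broken by gene id.
#'
#' @param dataset a [labeled_dataset()] with at least 2 classes.
#' @param lambda_frac fraction of each class's lambda_max at which
#'   coefficients are read (default 0.3).
#' @param lambda_min_ratio endpoint of the glmnet lambda path relative to
#'   lambda_max (default 0.01).
#' @param nlambda path length (default 100).
#' @return a [feature_list()] with `method = "lasso"` covering all genes.
#' @export
rank_lasso <- function(dataset, lambda_frac = 0.3, lambda_min_ratio = 0.01,
                       nlambda = 100) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset$class_order) < 2L) stopf("need at least 2 classes")
  x <- dataset$matrix
  keep <- which(matrixStats_colSds(x) > 0)
  scores <- stats::setNames(numeric(ncol(x)), dataset$gene_ids)
  if (length(keep) >= 2L) {
    xk <- x[, keep, drop = FALSE]
    for (cls in dataset$class_order) {
      y <- as.numeric(dataset$labels == cls)
      if (stats::var(y) == 0) next
      fit <- glmnet::glmnet(xk, y, family = "gaussian", alpha = 1,
                            nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
                            standardize = TRUE)
      at <- which.min(abs(fit$lambda - lambda_frac * max(fit$lambda)))
      beta <- abs(fit$beta[, at])
      scores[keep] <- pmax(scores[keep], beta)
    }
  }
  feature_list("lasso", dataset$gene_ids, as.numeric(scores))
}

# column standard deviations without an extra dependency
matrixStats_colSds <- function(x) {
  m <- colMeans(x)
  sqrt(pmax(0, colMeans(x^2) - m^2))
}

#' Rank genes by split counts of a gradient-boosted tree ensemble
#'
#' Trains a multiclass gradient-boosted tree ensemble (softmax objective,
#' one tree per class per round) on the full dataset with a fixed seed and
#' scores each gene by the number of times it is used as a split across
#' all trees ("used times in constructed trees"). Scores are nonnegative
#' integers summing to the total split count of the ensemble.
#'
#' @param dataset a [labeled_dataset()].
#' @param nrounds boosting rounds (default 100).
#' @param eta learning rate (default 0.1).
#' @param max_depth tree depth limit (default 6).
#' @param seed integer seed.
#' @return a [feature_list()] with `method = "gbt"` covering all genes.
#' @export
rank_gbt <- function(dataset, nrounds = 100, eta = 0.1, max_depth = 6, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  L <- length(dataset$class_order)
  if (L < 2L) stopf("need at least 2 classes")
  y <- as.integer(dataset$labels) - 1L
  x <- dataset$matrix
  colnames(x) <- paste0("V", seq_len(ncol(x)))  # ids may be non-syntactic
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  bst <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = L,
                  eta = eta, max_depth = max_depth,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  tree_tab <- xgboost::xgb.model.dt.tree(model = bst)
  used <- table(tree_tab$Feature[tree_tab$Feature != "Leaf"])
  scores <- stats::setNames(numeric(ncol(x)), colnames(x))
  scores[names(used)] <- as.numeric(used)
  feature_list("gbt", dataset$gene_ids, as.numeric(scores))
}

#' Monte Carlo feature selection parameters
#'
#' @param n_subsets number of random gene subsets `s` (default 100).
#' @param trees_per_subset trees (random train/test splits) per subset `t`
#'   (default 5); `s * t` trees in total.
#' @param subset_size genes per random subset `m`; default
#'   `ceiling(0.1 * n_genes)` resolved at ranking time.
#' @param u exponent on the tree's weighted accuracy (default 1).
#' @param v exponent on the node sample fraction (default 1).
#' @param train_fraction fraction of cells used to train each tree
#'   (default 2/3); the remainder is the held-out split scoring the tree.
#' @param seed integer seed.
#' @return object of class `mcfs_params`.
#' @export
mcfs_params <- function(n_subsets = 100, trees_per_subset = 5, subset_size = NULL,
                        u = 1, v = 1, train_fraction = 2 / 3, seed = 1) {
  n_subsets <- check_count(n_subsets, "n_subsets")
  trees_per_subset <- check_count(trees_per_subset, "trees_per_subset")
  if (!is.null(subset_size)) subset_size <- check_count(subset_size, "subset_size")
  if (u < 0 || v < 0) stopf("'u' and 'v' must be >= 0")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("'train_fraction' must be in (0, 1)")
  }
  structure(list(n_subsets = n_subsets, trees_per_subset = trees_per_subset,
                 subset_size = subset_size, u = as.numeric(u), v = as.numeric(v),
                 train_fraction = as.numeric(train_fraction),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "mcfs_params")
}

#' Rank genes by Monte Carlo feature selection
#'
#' Trains `s * t` decision trees, each on a random `m`-gene subset and a
#' random `train_fraction` sample split, and scores each gene by its
#' relative importance
#' `RI(g) = sum over trees of wAcc^u * sum over nodes splitting on g of
#' IG(node) * (node sample fraction)^v`,
#' where `wAcc` is the tree's mean per-class recall on its held-out split
#' and `IG` the information gain (entropy decrease) of the split. Genes
#' never sampled into any subset score 0.
#'
#' @param dataset a [labeled_dataset()].
#' @param params an [mcfs_params()] object.
#' @return a [feature_list()] with `method = "mcfs"` covering all genes.
#' @export
rank_mcfs <- function(dataset, params = mcfs_params()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(params, "mcfs_params"))
  p <- ncol(dataset$matrix)
  n <- nrow(dataset$matrix)
  m <- if (is.null(params$subset_size)) ceiling(0.1 * p) else params$subset_size
  if (m > p) stopf("'subset_size' (%d) exceeds the number of genes (%d)", m, p)
  labels <- dataset$labels
  classes <- dataset$class_order
  ri <- stats::setNames(numeric(p), dataset$gene_ids)
  n_train <- max(2L, round(params$train_fraction * n))
  if (n_train >= n) n_train <- n - 1L
  with_seed(params$seed, {
    for (si in seq_len(params$n_subsets)) {
      gene_idx <- sort(sample.int(p, m))
      genes <- dataset$gene_ids[gene_idx]
      sf <- safe_gene_frame(dataset$matrix, genes)
      for (ti in seq_len(params$trees_per_subset)) {
        train <- sample.int(n, n_train)
        df <- sf$frame
        df$.class <- labels
        fit <- rpart::rpart(.class ~ ., data = df[train, , drop = FALSE],
                            method = "class",
                            control = rpart::rpart.control(
                              minsplit = 5, minbucket = 2, cp = 0, xval = 0,
                              maxsurrogate = 0, maxcompete = 0, maxdepth = 30))
        pred <- predict(fit, newdata = df[-train, , drop = FALSE], type = "class")
        truth <- labels[-train]
        present <- classes[classes %in% as.character(truth)]
        recalls <- vapply(present, function(cl) {
          mean(pred[truth == cl] == cl)
        }, numeric(1))
        w_acc <- mean(recalls)
        contrib <- tree_gain_contributions(fit, length(classes), v = params$v)
        if (length(contrib)) {
          gene_names <- sf$genes[match(names(contrib), sf$safe)]
          add <- (w_acc^params$u) * contrib
          agg <- tapply(add, gene_names, sum)
          ri[names(agg)] <- ri[names(agg)] + as.numeric(agg)
        }
      }
    }
  })
  feature_list("mcfs", dataset$gene_ids, as.numeric(ri))
}

# Per-split-gene sum of IG(node) * (node fraction)^v over a fitted rpart
# tree; one entry per internal node, named by the (safe) split variable.
tree_gain_contributions <- function(fit, n_classes, v = 1) {
  frame <- fit$frame
  internal <- which(frame$var != "<leaf>")
  if (!length(internal)) return(numeric(0))
  nodes <- as.integer(rownames(frame))
  counts <- frame$yval2[, 1L + seq_len(n_classes), drop = FALSE]
  entropy <- function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) return(0)
    pr <- cnt[cnt > 0] / tot
    -sum(pr * log(pr))
  }
  root_n <- frame$n[1]
  out <- numeric(length(internal))
  vars <- as.character(frame$var[internal])
  for (k in seq_along(internal)) {
    i <- internal[k]
    node <- nodes[i]
    il <- match(node * 2L, nodes)
    ir <- match(node * 2L + 1L, nodes)
    cp <- counts[i, ]; cl <- counts[il, ]; cr <- counts[ir, ]
    np <- sum(cp)
    ig <- entropy(cp) - sum(cl) / np * entropy(cl) - sum(cr) / np * entropy(cr)
    out[k] <- ig * (frame$n[i] / root_n)^v
  }
  stats::setNames(out, vars)
}

#' Minimum-redundancy maximum-relevance parameters
#'
#' @param n_select number of genes to select greedily; default
#'   `min(n_genes, 2000)` resolved at ranking time.
#' @param discretization `"mean_std"` (3 states at mean +/- alpha sd, the
#'   canonical default) or `"equal_frequency"`.
#' @param alpha cut width for `mean_std` (default 1).
#' @param bins states for `equal_frequency` (default 3).
#' @param criterion `"difference"` (relevance minus mean redundancy, MID)
#'   or `"quotient"` (MIQ).
#' @param max_prefilter redundancy is only computed among the top
#'   `max_prefilter` genes by relevance (default 5000); the quadratic
#'   redundancy term makes an unrestricted run impractical on
#'   genome-scale inputs.
#' @return object of class `mrmr_params`.
#' @export
mrmr_params <- function(n_select = NULL, discretization = c("mean_std", "equal_frequency"),
                        alpha = 1, bins = 3, criterion = c("difference", "quotient"),
                        max_prefilter = 5000) {
  if (!is.null(n_select)) n_select <- check_count(n_select, "n_select")
  structure(list(n_select = n_select,
                 discretization = match.arg(discretization),
                 alpha = check_positive(alpha, "alpha"),
                 bins = check_count(bins, "bins", min = 2L),
                 criterion = match.arg(criterion),
                 max_prefilter = check_count(max_prefilter, "max_prefilter")),
            class = "mrmr_params")
}

#' Rank genes by minimum-redundancy maximum-relevance selection
#'
#' Discretizes expression per gene, then greedily selects genes one by
#' one: the first gene maximizes the mutual information `I(g; class)`;
#' each subsequent gene maximizes `I(g; class) - mean(I(g; s))` over the
#' already-selected genes `s` (difference criterion) or the quotient
#' variant. The returned order is the selection order, with scores equal
#' to the criterion value in the selection round; genes beyond `n_select`
#' (or outside the relevance prefilter) are appended by gene id with `NA`
#' scores.
#'
#' @param dataset a [labeled_dataset()].
#' @param params an [mrmr_params()] object.
#' @return a [feature_list()] with `method = "mrmr"` covering all genes.
#' @export
rank_mrmr <- function(dataset, params = mrmr_params()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(params, "mrmr_params"))
  p <- ncol(dataset$matrix)
  n_select <- if (is.null(params$n_select)) min(p, 2000L) else params$n_select
  if (n_select > p) stopf("'n_select' (%d) exceeds the number of genes (%d)", n_select, p)
  k <- if (params$discretization == "mean_std") 3L else params$bins
  disc <- discretize_expression(dataset$matrix, params$discretization,
                                alpha = params$alpha, bins = params$bins)
  G <- one_hot_states(disc, k)
  L <- length(dataset$class_order)
  n <- nrow(disc)
  Lh <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(dataset$labels),
                             x = 1, dims = c(n, L))
  relevance <- mi_from_joint(Matrix::crossprod(Lh, G), k)
  names(relevance) <- dataset$gene_ids

  pool <- order(-relevance, dataset$gene_ids)[seq_len(min(p, params$max_prefilter))]
  n_select <- min(n_select, length(pool))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)
  candidates <- pool
  for (round in seq_len(n_select)) {
    crit <- if (round == 1L) {
      relevance[candidates]
    } else {
      mean_red <- red_sum[candidates] / (round - 1L)
      if (params$criterion == "difference") {
        relevance[candidates] - mean_red
      } else {
        relevance[candidates] / pmax(mean_red, .Machine$double.eps)
      }
    }
    best <- candidates[order(-crit, dataset$gene_ids[candidates])[1L]]
    selected <- c(selected, best)
    scores <- c(scores, crit[match(best, candidates)])
    candidates <- candidates[candidates != best]
    if (length(candidates) && round < n_select) {
      Sb <- G[, k * (best - 1L) + seq_len(k), drop = FALSE]
      red_sum <- red_sum + mi_from_joint(Matrix::crossprod(Sb, G), k)
    }
  }
  rest <- setdiff(seq_len(p), selected)
  rest <- rest[order(dataset$gene_ids[rest])]
  feature_list("mrmr",
               dataset$gene_ids[c(selected, rest)],
               c(as.numeric(scores), rep(NA_real_, length(rest))),
               reorder = FALSE)
}

#' Rank genes by random-forest importance
#'
#' Trains a seeded random forest on the full dataset. The default score is
#' the impurity-decrease (Gini) importance, normalized to sum to 1 when
#' any split occurred; `importance = "permutation"` instead scores each
#' gene by the out-of-bag accuracy drop when its values are permuted.
#'
#' @param dataset a [labeled_dataset()].
#' @param num_trees forest size (default 500).
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @param seed integer seed.
#' @return a [feature_list()] with `method = "rf"` covering all genes.
#' @export
rank_rf <- function(dataset, num_trees = 500,
                    importance = c("impurity", "permutation"), seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  importance <- match.arg(importance)
  x <- dataset$matrix
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  fit <- ranger::ranger(x = x, y = dataset$labels,
                        num.trees = num_trees, importance = importance,
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance[colnames(x)]
  imp[is.na(imp)] <- 0
  if (importance == "impurity" && sum(imp) > 0) imp <- imp / sum(imp)
  feature_list("rf", dataset$gene_ids, as.numeric(imp))
}

#' Run all five gene rankers
#'
#' Convenience wrapper producing the five ranked lists (`lasso`, `gbt`,
#' `mcfs`, `mrmr`, `rf`) from one dataset with per-method parameters.
#'
#' @param dataset a [labeled_dataset()].
#' @param seed integer seed shared by the stochastic rankers.
#' @param mcfs,mrmr parameter objects ([mcfs_params()], [mrmr_params()]).
#' @param gbt_nrounds,rf_num_trees sizes of the boosted and bagged
#'   ensembles.
#' @return named list of five [feature_list()] objects.
#' @export
rank_all <- function(dataset, seed = 1,
                     mcfs = mcfs_params(seed = derive_seed(seed, 3)),
                     mrmr = mrmr_params(),
                     gbt_nrounds = 100, rf_num_trees = 500) {
  list(
    lasso = rank_lasso(dataset),
    gbt = rank_gbt(dataset, nrounds = gbt_nrounds, seed = derive_seed(seed, 2)),
    mcfs = rank_mcfs(dataset, mcfs),
    mrmr = rank_mrmr(dataset, mrmr),
    rf = rank_rf(dataset, num_trees = rf_num_trees, seed = derive_seed(seed, 5))
  )
}
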