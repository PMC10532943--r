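#' Incremental feature selection configuration
#'
#' @param interval subset-size step `s`: subsets are the list prefixes of
#'   sizes `s, 2s, ...` (default 10).
#' @param cap only the top `cap` genes of a list are considered
#'   (default 2000).
#' @param cv_folds stratified cross-validation folds (default 10).
#' @param classifier `"random_forest"` or `"decision_tree"`.
#' @param num_trees forest size for the random-forest classifier
#'   (default 100).
#' @param smote_enabled apply SMOTE oversampling to the training cells of
#'   each fold (default TRUE).
#' @param smote_k_neighbors SMOTE neighbor pool (default 5).
#' @param smote_before_cv compatibility mode: balance the whole dataset
#'   once, before splitting into folds. This leaks interpolated copies of
#'   test cells into training and inflates measured performance; off by
#'   default.
#' @param feasible_delta tolerance for the feasible classifier: the
#'   smallest subset whose weighted F1 is within `feasible_delta` of the
#'   optimum (default 0.04).
#' @param seed integer seed driving fold assignment, per-fold SMOTE and
#'   the classifier.
#' @return object of class `ifs_config`.
#' @export
ifs_config <- function(interval = 10, cap = 2000, cv_folds = 10,
                       classifier = c("random_forest", "decision_tree"),
                       num_trees = 100, smote_enabled = TRUE,
                       smote_k_neighbors = 5, smote_before_cv = FALSE,
                       feasible_delta = 0.04, seed = 1) {
  interval <- check_count(interval, "interval")
  cap <- check_count(cap, "cap", min = interval)
  cv_folds <- check_count(cv_folds, "cv_folds", min = 2L)
  if (feasible_delta < 0) stopf("'feasible_delta' must be >= 0")
  structure(list(interval = interval, cap = cap, cv_folds = cv_folds,
                 classifier = match.arg(classifier),
                 num_trees = check_count(num_trees, "num_trees"),
                 smote_enabled = isTRUE(smote_enabled),
                 smote_k_neighbors = check_count(smote_k_neighbors, "smote_k_neighbors"),
                 smote_before_cv = isTRUE(smote_before_cv),
                 feasible_delta = as.numeric(feasible_delta),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "ifs_config")
}

#' Build the nested prefix subsets of a ranked list
#'
#' Prefixes of sizes `s, 2s, ...` up to `m = min(length(list), cap)`, with
#' a final partial subset of size `m` when `m` is not a multiple of `s`
#' (so the subset count is `ceiling(m / s)`). Each prefix extends the
#' previous one.
#'
#' @param flist a [feature_list()].
#' @param interval step size `s`.
#' @param cap maximum prefix size.
#' @return list of character vectors of gene ids.
#' @export
build_subsets <- function(flist, interval = 10, cap = 2000) {
  stopifnot(inherits(flist, "feature_list"))
  interval <- check_count(interval, "interval")
  cap <- check_count(cap, "cap")
  m <- min(length(flist$genes), cap)
  if (m == 0L) stopf("empty feature list")
  sizes <- unique(c(seq(interval, m, by = interval), m))
  lapply(sizes, function(k) flist$genes[seq_len(k)])
}

# Stratified fold assignment: within each class, cells are shuffled and
# dealt round-robin, so every fold gets floor or ceiling n_c/k per class.
make_folds <- function(labels, cv_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
  })
  fold
}

fit_classifier <- function(kind, x, y, num_trees, seed) {
  if (kind == "random_forest") {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
    ranger::ranger(x = x, y = y, num.trees = num_trees, seed = seed,
                   num.threads = 1)
  } else {
    df <- as.data.frame(x)
    colnames(df) <- paste0("V", seq_len(ncol(x)))
    df$.class <- y
    rpart::rpart(.class ~ ., data = df, method = "class",
                 control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                cp = 0, xval = 0,
                                                maxsurrogate = 0, maxcompete = 0,
                                                maxdepth = 30))
  }
}

predict_classifier <- function(model, x, seed = 1L) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (inherits(model, "ranger")) {
    # fixed prediction seed: ranger breaks vote ties with its own RNG
    predict(model, data = x, num.threads = 1, seed = seed)$predictions
  } else {
    predict(model, newdata = as.data.frame(x), type = "class")
  }
}

#' Cross-validated evaluation of one gene subset
#'
#' Stratified `cv_folds`-fold cross-validation of the configured
#' classifier on the dataset restricted to `genes`. In each fold the
#' training cells are SMOTE-balanced (in the subset's gene space) and the
#' untouched test cells predicted; out-of-fold predictions are pooled and
#' summarized into accuracy, multiclass MCC, macro/weighted F1 and
#' per-class metrics, with per-fold accuracies recorded. In the
#' `smote_before_cv` compatibility mode the whole dataset is balanced
#' first and the folds stratify the augmented data.
#'
#' Classes with fewer cells than `cv_folds` are kept (some folds then see
#' none of their cells); a warning notes them once.
#'
#' @param dataset a [labeled_dataset()].
#' @param genes subset of the dataset's gene ids.
#' @param config an [ifs_config()].
#' @param folds optional precomputed fold vector (as produced internally);
#'   used by [run_ifs()] to share folds across subset sizes.
#' @return an `evaluation_summary` (see [summarize_confusion()]).
#' @export
evaluate_subset <- function(dataset, genes, config = ifs_config(), folds = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(config, "ifs_config"))
  if (length(genes) == 0L) stopf("empty gene subset")
  sub <- restrict_genes(dataset, genes)
  if (config$smote_enabled && config$smote_before_cv) {
    sub <- smote(sub, config$smote_k_neighbors, seed = derive_seed(config$seed, length(genes)))
    folds <- NULL
  }
  small <- table(sub$labels) < config$cv_folds
  if (any(small)) {
    warning(sprintf("class(es) smaller than cv_folds are unevenly stratified: %s",
                    paste(names(small)[small], collapse = ", ")), call. = FALSE)
  }
  if (is.null(folds)) folds <- make_folds(sub$labels, config$cv_folds, config$seed)
  k <- length(genes)
  pred <- factor(rep(NA_character_, nrow(sub$matrix)), levels = sub$class_order)
  per_fold_acc <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    train <- labeled_dataset(sub$matrix[train_idx, , drop = FALSE],
                             sub$labels[train_idx],
                             class_order = sub$class_order)
    if (config$smote_enabled && !config$smote_before_cv) {
      train <- smote(train, config$smote_k_neighbors,
                     seed = derive_seed(config$seed, k * 100L + f),
                     on_singleton = "duplicate")
    }
    fold_seed <- derive_seed(config$seed, k * 100L + f)
    model <- fit_classifier(config$classifier, train$matrix, train$labels,
                            config$num_trees, fold_seed)
    fold_pred <- predict_classifier(model, sub$matrix[test_idx, , drop = FALSE],
                                    seed = fold_seed)
    pred[test_idx] <- as.character(fold_pred)
    per_fold_acc[f] <- mean(as.character(fold_pred) == as.character(sub$labels[test_idx]))
  }
  truth <- as.character(sub$labels)
  cc <- confusion(truth, as.character(pred), sub$class_order)
  summarize_confusion(cc, per_fold_acc = per_fold_acc,
                      mcc = mcc_multiclass(truth, as.character(pred), sub$class_order))
}

#' Run incremental feature selection over one ranked list
#'
#' Evaluates every prefix subset of the ranked list (see
#' [build_subsets()]) with [evaluate_subset()], sharing one stratified
#' fold assignment across subset sizes, and selects:
#' * the optimal subset size: the `k` attaining the maximum weighted F1
#'   (ties broken toward the smallest `k`), and
#' * the feasible subset size: the smallest `k` whose weighted F1 is
#'   within `feasible_delta` of that maximum.
#'
#' @param dataset a [labeled_dataset()].
#' @param flist a [feature_list()].
#' @param config an [ifs_config()].
#' @param verbose print one progress line per subset (default FALSE).
#' @return object of class `ifs_result`: list with `method`, `classifier`,
#'   `records` (list of `list(k, summary)` ordered by `k`), `optimal_k`,
#'   `feasible_k`, `config`.
#' @export
run_ifs <- function(dataset, flist, config = ifs_config(), verbose = FALSE) {
  stopifnot(inherits(flist, "feature_list"))
  subsets <- build_subsets(flist, config$interval, config$cap)
  folds <- if (config$smote_enabled && config$smote_before_cv) NULL else {
    make_folds(dataset$labels, config$cv_folds, config$seed)
  }
  records <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    genes <- subsets[[i]]
    summary <- evaluate_subset(dataset, genes, config, folds = folds)
    records[[i]] <- list(k = length(genes), summary = summary)
    if (verbose) {
      message(sprintf("[ifs %s/%s] k = %d: weighted F1 %.4f, ACC %.4f",
                      flist$method, config$classifier, length(genes),
                      summary$weighted_f1, summary$acc))
    }
  }
  ks <- vapply(records, `[[`, numeric(1), "k")
  wf1 <- vapply(records, function(r) r$summary$weighted_f1, numeric(1))
  best <- max(wf1)
  optimal_k <- ks[which(wf1 == best)[1L]]
  feasible_k <- ks[which(wf1 >= best - config$feasible_delta)[1L]]
  structure(list(method = flist$method, classifier = config$classifier,
                 records = records, optimal_k = optimal_k,
                 feasible_k = feasible_k, config = config),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("ifs_result (%s list, %s): %d subsets, optimal k = %d, feasible k = %d\n",
              x$method, x$classifier, length(x$records), x$optimal_k, x$feasible_k))
  invisible(x)
}

#' Flatten an IFS result into its curve table
#'
#' One row per evaluated subset size with accuracy, MCC, macro and
#' weighted F1 and the per-fold accuracies (`fold_1 ... fold_K`).
#'
#' @param x an `ifs_result`.
#' @param ... unused.
#' @return a data.frame ordered by `k`.
#' @export
as.data.frame.ifs_result <- function(x, ...) {
  rows <- lapply(x$records, function(r) {
    s <- r$summary
    folds <- as.list(s$per_fold_acc)
    names(folds) <- paste0("fold_", seq_along(folds))
    c(list(k = r$k, acc = s$acc, mcc = s$mcc, macro_f1 = s$macro_f1,
           weighted_f1 = s$weighted_f1), folds)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
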