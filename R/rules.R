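#' Train a decision tree for rule extraction
#'
#' Fits a single fully grown decision tree on all cells, restricted to the
#' given genes (typically the optimal subset of a ranked list). By default
#' the tree sees the real, unbalanced cells so that the extracted rules
#' describe real expression patterns; `oversample = TRUE` SMOTE-balances
#' the cells (in the subset's gene space) first.
#'
#' @param dataset a [labeled_dataset()].
#' @param genes nonempty subset of the dataset's gene ids.
#' @param seed integer seed (used by the optional oversampling; the tree
#'   fit itself is deterministic).
#' @param oversample balance classes before fitting (default FALSE).
#' @param control optional [rpart::rpart.control()]; the default grows the
#'   tree fully (no complexity pruning, minimum node size 1).
#' @return object of class `rule_tree`: list with the fitted `tree`, the
#'   `genes`/safe-name mapping and the `class_order`.
#' @export
train_rule_tree <- function(dataset, genes, seed = 1, oversample = FALSE,
                            control = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(genes) == 0L) stopf("empty gene subset")
  sub <- restrict_genes(dataset, genes)
  if (oversample) sub <- smote(sub, seed = seed)
  if (is.null(control)) {
    control <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                    xval = 0, maxsurrogate = 0, maxcompete = 0,
                                    maxdepth = 30)
  }
  sf <- safe_gene_frame(sub$matrix, genes)
  df <- sf$frame
  df$.class <- sub$labels
  fit <- rpart::rpart(.class ~ ., data = df, method = "class", control = control)
  structure(list(tree = fit, genes = sf$genes, safe = sf$safe,
                 class_order = sub$class_order),
            class = "rule_tree")
}

#' Extract one classification rule per leaf of a decision tree
#'
#' Each rule is the root-to-leaf path of one leaf: an ordered conjunction
#' of gene-expression threshold predicates (`gene <= t` or `gene > t`, at
#' the tree's native split values) predicting the leaf's majority class,
#' with the leaf's training-sample `support` and class `purity`. The rules
#' of one tree partition the feature space: every input satisfies exactly
#' one rule. Repeated predicates on one gene along a path are kept, so the
#' literal path is preserved.
#'
#' Thresholds are midpoints between observed training values, so on
#' continuous expression data the boundary case `x == t` (where the `<=`
#' convention and the tree's strict `<` comparison could differ) does not
#' arise on training cells and has probability zero on continuous inputs.
#'
#' @param rtree a [train_rule_tree()] object.
#' @return object of class `rule_group`: list with `method` (label,
#'   settable), `class_order` and `rules`, each rule a list with `id`,
#'   `predicates` (data.frame gene/op/threshold in root-to-leaf order),
#'   `class`, `support`, `purity`.
#' @export
extract_rules <- function(rtree) {
  stopifnot(inherits(rtree, "rule_tree"))
  fit <- rtree$tree
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  L <- length(rtree$class_order)
  counts <- frame$yval2[, 1L + seq_len(L), drop = FALSE]
  ylevels <- attr(fit, "ylevels")

  # per internal node (frame order), its primary split row of fit$splits
  internal <- which(frame$var != "<leaf>")
  splits <- fit$splits
  split_of_node <- stats::setNames(seq_along(internal), nodes[internal])

  predicate_for <- function(parent_idx, go_left) {
    srow <- splits[split_of_node[[as.character(nodes[parent_idx])]], , drop = TRUE]
    gene <- rtree$genes[match(as.character(frame$var[parent_idx]), rtree$safe)]
    thr <- unname(srow["index"])
    ncat <- unname(srow["ncat"])
    # ncat < 0: left child takes x < threshold; ncat > 0: left takes x >= threshold
    left_is_low <- ncat < 0
    if (go_left == left_is_low) {
      list(gene = gene, op = "le", threshold = thr)
    } else {
      list(gene = gene, op = "gt", threshold = thr)
    }
  }

  leaves <- which(frame$var == "<leaf>")
  rules <- lapply(seq_along(leaves), function(ri) {
    i <- leaves[ri]
    node <- nodes[i]
    path <- list()
    child <- node
    while (child > 1L) {
      parent <- child %/% 2L
      parent_idx <- match(parent, nodes)
      path <- c(list(predicate_for(parent_idx, go_left = child %% 2L == 0L)), path)
      child <- parent
    }
    preds <- if (length(path)) {
      data.frame(gene = vapply(path, `[[`, character(1), "gene"),
                 op = vapply(path, `[[`, character(1), "op"),
                 threshold = vapply(path, `[[`, numeric(1), "threshold"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(0), op = character(0), threshold = numeric(0),
                 stringsAsFactors = FALSE)
    }
    cnt <- counts[i, ]
    list(id = sprintf("rule_%04d", ri),
         predicates = preds,
         class = ylevels[frame$yval[i]],
         support = as.integer(frame$n[i]),
         purity = max(cnt) / sum(cnt))
  })
  structure(list(method = "tree", class_order = rtree$class_order, rules = rules),
            class = "rule_group")
}

#' @export
print.rule_group <- function(x, ...) {
  cat(sprintf("rule_group '%s': %d rules over %d classes\n",
              x$method, length(x$rules), length(x$class_order)))
  invisible(x)
}

#' Classify samples with a rule group
#'
#' Applies every rule's conjunction to each sample (a named vector or a
#' samples x genes matrix providing every referenced gene) and returns the
#' class of the single matching rule. Because the rules of one tree
#' partition the feature space, zero or multiple matches indicate a
#' corrupted rule group and raise an error.
#'
#' @param group a [extract_rules()] rule group.
#' @param samples named numeric vector (one sample) or matrix with gene
#'   ids as column names.
#' @return character vector of predicted classes.
#' @export
apply_rules <- function(group, samples) {
  stopifnot(inherits(group, "rule_group"))
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1,
                                               dimnames = list(NULL, names(samples)))
  needed <- unique(unlist(lapply(group$rules, function(r) r$predicates$gene)))
  missing <- setdiff(needed, colnames(samples))
  if (length(missing)) {
    stopf("samples are missing gene(s) referenced by the rules: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  n <- nrow(samples)
  match_count <- integer(n)
  pred <- character(n)
  for (r in group$rules) {
    ok <- rep(TRUE, n)
    pr <- r$predicates
    for (j in seq_len(nrow(pr))) {
      v <- samples[, pr$gene[j]]
      ok <- ok & if (pr$op[j] == "le") v <= pr$threshold[j] else v > pr$threshold[j]
    }
    match_count <- match_count + ok
    pred[ok] <- r$class
  }
  if (any(match_count != 1L)) {
    stopf("rule group is not a partition: %d sample(s) matched %s rules",
          sum(match_count != 1L),
          paste(unique(match_count[match_count != 1L]), collapse = "/"))
  }
  pred
}

#' Number of rules per predicted cell type
#'
#' @param group a rule group.
#' @return named integer vector over `class_order`; sums to the number of
#'   rules.
#' @export
rules_per_class <- function(group) {
  stopifnot(inherits(group, "rule_group"))
  cls <- factor(vapply(group$rules, `[[`, character(1), "class"),
                levels = group$class_order)
  stats::setNames(as.integer(table(cls)), group$class_order)
}

#' Binary class x gene matrix of rule-associated genes
#'
#' Entry (c, g) is 1 iff some rule predicting class c references gene g in
#' one of its predicates. Only genes referenced by at least one rule
#' appear as columns.
#'
#' @param group a rule group.
#' @return binary integer matrix, rows = `class_order`, columns = genes.
#' @export
rule_gene_matrix <- function(group) {
  stopifnot(inherits(group, "rule_group"))
  genes <- sort(unique(unlist(lapply(group$rules, function(r) r$predicates$gene))))
  m <- matrix(0L, nrow = length(group$class_order), ncol = length(genes),
              dimnames = list(group$class_order, genes))
  for (r in group$rules) {
    g <- unique(r$predicates$gene)
    if (length(g)) m[r$class, g] <- 1L
  }
  m
}

#' Cluster cell types on their rule-associated gene patterns
#'
#' Hierarchical clustering (average linkage) of the classes on the
#' Jaccard distance between their binary gene-presence rows (1 minus
#' shared genes over pooled genes; two classes with identical rows sit at
#' distance 0, classes sharing no genes at distance 1). Rows are ordered
#' by class name before clustering so ties resolve deterministically.
#'
#' @param m a binary class x gene matrix ([rule_gene_matrix()]).
#' @return an [stats::hclust] object (linkage table + leaf order).
#' @export
cluster_cell_types <- function(m) {
  if (nrow(m) < 2L) stopf("need at least 2 classes to cluster")
  m <- m[order(rownames(m)), , drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- sum(m[i, ] & m[j, ])
      uni <- sum(m[i, ] | m[j, ])
      d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
    }
  }
  stats::hclust(stats::as.dist(d), method = "average")
}
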