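# Small synthetic fixtures shared across tests; all built in code.

# A clean, well-separated instance: few classes, strong markers, no dropout.
toy_dataset <- function(seed = 42, n_classes = 3, n_genes = 30,
                        markers_per_class = 2,
                        class_sizes = c(a = 40, b = 25, c = 12),
                        effect_size = 3, dropout_rate = 0) {
  spec <- synthetic_spec(n_classes = n_classes, n_genes = n_genes,
                         markers_per_class = markers_per_class,
                         class_sizes = class_sizes,
                         effect_size = effect_size,
                         dropout_rate = dropout_rate, seed = seed)
  list(spec = spec, dataset = generate_dataset(spec),
       markers = planted_markers(spec))
}

# A dataset with one perfectly separating gene and pure-noise background.
separator_dataset <- function(seed = 7, n = 60, p = 50) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * p)), n, p,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("g%03d", 1:p)))
  labels <- rep(c("A", "B"), length.out = n)
  m[, 1] <- ifelse(labels == "A", 10, 0)
  labeled_dataset(m, labels)
}

# Independent recomputation of per-gene information-gain contributions of
# an rpart tree by re-partitioning the raw data along path.rpart()
# conditions (oracle for the MCFS aggregation).
tree_gain_oracle <- function(fit, df, class_col = ".class") {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  internal <- nodes[frame$var != "<leaf>"]
  entropy <- function(labels) {
    p <- table(labels)
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  }
  node_mask <- function(node) {
    conds <- rpart::path.rpart(fit, node, print.it = FALSE)[[1]]
    mask <- rep(TRUE, nrow(df))
    for (cond in conds[-1]) {  # first entry is "root"
      m <- regmatches(cond, regexec("^([^<>=]+)(>=|<=|<|>)(.*)$", cond))[[1]]
      v <- df[[m[2]]]
      thr <- as.numeric(m[4])
      mask <- mask & switch(m[3],
                            "<" = v < thr, ">=" = v >= thr,
                            ">" = v > thr, "<=" = v <= thr)
    }
    mask
  }
  out <- numeric(0)
  for (node in internal) {
    par <- node_mask(node)
    left <- node_mask(node * 2L)
    right <- node_mask(node * 2L + 1L)
    y <- df[[class_col]]
    ig <- entropy(y[par]) -
      sum(left) / sum(par) * entropy(y[left]) -
      sum(right) / sum(par) * entropy(y[right])
    var <- as.character(frame$var[match(node, nodes)])
    out[var] <- if (var %in% names(out)) out[[var]] + ig else ig
  }
  out
}

# Brute-force discrete mutual information (nats) between two vectors.
mi_brute <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j] / n
    if (p > 0) mi <- mi + p * log(p / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  mi
}

# Multiclass correlation coefficient from the confusion matrix (the
# closed form over totals; independent of the one-hot implementation).
mcc_oracle <- function(true, pred, classes) {
  C <- table(factor(true, classes), factor(pred, classes))
  n <- sum(C)
  c_ok <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- c_ok * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

expect_feature_list_valid <- function(fl, gene_ids) {
  expect_s3_class(fl, "feature_list")
  expect_setequal(fl$genes, gene_ids)
  expect_length(fl$scores, length(gene_ids))
}
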