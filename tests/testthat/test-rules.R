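stump_fixture <- function() {
  m <- matrix(c(0, 0.2, 0.4, 5, 6, 7), ncol = 1,
              dimnames = list(paste0("c", 1:6), "GENE1"))
  labeled_dataset(m, c("lo", "lo", "lo", "hi", "hi", "hi"))
}

test_that("a perfectly separated one-gene dataset yields a depth-one stump", {
  ds <- stump_fixture()
  rt <- train_rule_tree(ds, "GENE1")
  rg <- extract_rules(rt)
  expect_length(rg$rules, 2)
  preds <- do.call(rbind, lapply(rg$rules, `[[`, "predicates"))
  expect_equal(nrow(preds), 2)
  expect_equal(unique(preds$gene), "GENE1")
  expect_setequal(preds$op, c("le", "gt"))
  expect_equal(preds$threshold[1], preds$threshold[2])
  expect_setequal(vapply(rg$rules, `[[`, character(1), "class"), c("lo", "hi"))
  # both classes flag the single split gene in the rule-gene matrix
  m <- rule_gene_matrix(rg)
  expect_equal(dim(m), c(2, 1))
  expect_true(all(m == 1))
  # per-class counts: one rule each, conserving the rule total
  expect_equal(unname(rules_per_class(rg)), c(1, 1))
})

test_that("extracted rules reproduce the tree's predictions exactly", {
  fx <- toy_dataset(seed = 71, class_sizes = c(a = 50, b = 30, c = 15),
                    n_genes = 12, effect_size = 2, dropout_rate = 0.2)
  ds <- fx$dataset
  rt <- train_rule_tree(ds, ds$gene_ids)
  rg <- extract_rules(rt)
  expect_length(rg$rules, sum(rt$tree$frame$var == "<leaf>"))

  set.seed(99)
  random <- matrix(runif(2000 * 12, 0, 4), ncol = 12,
                   dimnames = list(NULL, ds$gene_ids))
  mine <- apply_rules(rg, random)
  df <- as.data.frame(random)
  colnames(df) <- rt$safe
  oracle <- as.character(predict(rt$tree, newdata = df, type = "class"))
  expect_identical(mine, oracle)
  # and on the training data itself
  expect_identical(apply_rules(rg, ds$matrix),
                   as.character(predict(rt$tree, type = "class")))
})

test_that("rule supports, purities and class counts are internally consistent", {
  fx <- toy_dataset(seed = 61, n_genes = 10)
  ds <- fx$dataset
  rt <- train_rule_tree(ds, ds$gene_ids[1:8])
  rg <- extract_rules(rt)
  supports <- vapply(rg$rules, `[[`, integer(1), "support")
  purities <- vapply(rg$rules, `[[`, numeric(1), "purity")
  expect_equal(sum(supports), nrow(ds$matrix))
  expect_true(all(purities > 0 & purities <= 1))
  expect_equal(sum(rules_per_class(rg)), length(rg$rules))
  # training accuracy is at least any single rule's purity-weighted share
  acc <- mean(apply_rules(rg, ds$matrix[, ds$gene_ids[1:8]]) ==
                as.character(ds$labels))
  expect_gte(acc, max(purities * supports) / nrow(ds$matrix))
})

test_that("rule trees are deterministic and respect the oversample flag", {
  fx <- toy_dataset(seed = 37, class_sizes = c(a = 30, b = 10, c = 4), n_genes = 8)
  r1 <- train_rule_tree(fx$dataset, fx$dataset$gene_ids, seed = 5)
  r2 <- train_rule_tree(fx$dataset, fx$dataset$gene_ids, seed = 5)
  expect_identical(extract_rules(r1)$rules, extract_rules(r2)$rules)
  ro <- train_rule_tree(fx$dataset, fx$dataset$gene_ids, seed = 5, oversample = TRUE)
  expect_equal(sum(vapply(extract_rules(ro)$rules, `[[`, integer(1), "support")),
               3 * 30)
})

test_that("apply_rules validates its inputs", {
  ds <- stump_fixture()
  rg <- extract_rules(train_rule_tree(ds, "GENE1"))
  expect_error(apply_rules(rg, c(OTHER = 1)), "GENE1")
  expect_equal(apply_rules(rg, c(GENE1 = 100)), "hi")
  # unsplittable (constant) gene: a single-leaf tree whose one
  # empty-predicate rule matches everything and predicts the majority
  const <- labeled_dataset(matrix(1, 4, 1, dimnames = list(paste0("c", 1:4), "G")),
                           c("A", "A", "A", "B"))
  rg1 <- extract_rules(train_rule_tree(const, "G"))
  expect_length(rg1$rules, 1)
  expect_equal(nrow(rg1$rules[[1]]$predicates), 0)
  expect_equal(apply_rules(rg1, c(G = 0.5)), "A")
})

test_that("cell-type clustering on rule-gene patterns behaves as documented", {
  m <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0), C = c(0, 0, 1, 1),
             D = c(1, 0, 1, 0))
  colnames(m) <- paste0("g", 1:4)
  hc <- cluster_cell_types(m)
  # identical rows merge first at height 0
  expect_equal(hc$height[1], 0)
  first_pair <- rownames(m)[sort(-hc$merge[1, ])]
  expect_setequal(first_pair, c("A", "B"))
  # a class sharing no genes with another sits at Jaccard distance 1
  expect_setequal(hc$labels[hc$order], rownames(m))
  # full-distance check against a brute-force Jaccard matrix
  jac <- function(a, b) 1 - sum(a & b) / sum(a | b)
  expect_equal(jac(m["A", ], m["C", ]), 1)
  expect_error(cluster_cell_types(m[1, , drop = FALSE]), "2 classes")
})

test_that("rule groups serialize to JSON and back without loss", {
  fx <- toy_dataset(seed = 83, n_genes = 8)
  rg <- extract_rules(train_rule_tree(fx$dataset, fx$dataset$gene_ids[1:6]))
  rg$method <- "rf"
  path <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_rules(rg, path, txt)
  back <- read_rules(path)
  expect_equal(back$method, rg$method)
  expect_equal(back$class_order, rg$class_order)
  expect_equal(back$rules, rg$rules)
  expect_gt(length(readLines(txt)), 0)
})
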