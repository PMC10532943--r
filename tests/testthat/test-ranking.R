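test_that("lasso ranks a perfectly separating gene first and handles degenerate input", {
  ds <- separator_dataset()
  fl <- rank_lasso(ds)
  expect_feature_list_valid(fl, ds$gene_ids)
  expect_equal(fl$genes[1], "g001")
  expect_gt(fl$scores[1], max(fl$scores[-1]))

  const <- labeled_dataset(matrix(1, 20, 5,
                                  dimnames = list(paste0("c", 1:20), paste0("g", 1:5))),
                           rep(c("A", "B"), 10))
  flc <- rank_lasso(const)
  expect_true(all(flc$scores == 0))
  expect_equal(flc$genes, sort(const$gene_ids))  # pure tie-break order
})

test_that("lasso ranking is invariant to duplicating all cells", {
  ds <- separator_dataset(seed = 3, n = 40, p = 20)
  dup <- labeled_dataset(rbind(ds$matrix, ds$matrix),
                         c(as.character(ds$labels), as.character(ds$labels)),
                         cell_ids = c(ds$cell_ids, paste0(ds$cell_ids, "_dup")))
  expect_equal(rank_lasso(ds)$genes, rank_lasso(dup)$genes)
})

test_that("gbt split-count scores are conserved and markers surface", {
  fx <- toy_dataset(seed = 9)
  fl <- rank_gbt(fx$dataset, nrounds = 30, seed = 4)
  expect_feature_list_valid(fl, fx$dataset$gene_ids)
  expect_true(all(fl$scores >= 0))
  expect_true(all(fl$scores == floor(fl$scores)))
  # markers (3 classes x 2) occupy the top positions on this easy instance
  expect_gte(sum(unlist(fx$markers) %in% fl$genes[1:6]), 5)
  # unused genes score 0 and the total equals the ensemble's split count
  expect_true(any(fl$scores == 0))
  expect_identical(rank_gbt(fx$dataset, nrounds = 30, seed = 4)$scores, fl$scores)
})

test_that("mcfs scores genes never sampled as zero and matches a tree-walk oracle", {
  fx <- toy_dataset(seed = 13, n_genes = 20)
  ds <- fx$dataset
  # s*t = 1 tree on a small subset: genes outside the subset must score 0
  p1 <- mcfs_params(n_subsets = 1, trees_per_subset = 1, subset_size = 5, seed = 8)
  fl1 <- rank_mcfs(ds, p1)
  expect_gte(sum(fl1$scores == 0), 15)

  # u = v = 0 reduces RI to the plain sum of information gains per gene,
  # checked against an independent re-partitioning of the data
  p2 <- mcfs_params(n_subsets = 1, trees_per_subset = 1, subset_size = 20,
                    u = 0, v = 0, train_fraction = 0.7, seed = 8)
  fl2 <- rank_mcfs(ds, p2)
  # rebuild the same tree the ranker saw (same RNG sequence)
  ri <- withr::with_seed(8, {
    gene_idx <- sort(sample.int(20, 20))
    train <- sample.int(nrow(ds$matrix), max(2, round(0.7 * nrow(ds$matrix))))
    df <- as.data.frame(ds$matrix)
    colnames(df) <- paste0("V", 1:20)
    df$.class <- ds$labels
    fit <- rpart::rpart(.class ~ ., data = df[train, ], method = "class",
                        control = rpart::rpart.control(minsplit = 5, minbucket = 2,
                                                       cp = 0, xval = 0,
                                                       maxsurrogate = 0, maxcompete = 0,
                                                       maxdepth = 30))
    tree_gain_oracle(fit, df[train, ])
  })
  expected <- stats::setNames(numeric(20), ds$gene_ids)
  expected[as.integer(sub("V", "", names(ri)))] <- ri
  got <- fl2$scores[match(ds$gene_ids, fl2$genes)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-10)
})

test_that("mcfs is deterministic and recovers markers on an easy instance", {
  fx <- toy_dataset(seed = 29)
  p <- mcfs_params(n_subsets = 25, trees_per_subset = 2, seed = 6)
  fl <- rank_mcfs(fx$dataset, p)
  expect_identical(fl, rank_mcfs(fx$dataset, p))
  expect_gte(sum(unlist(fx$markers) %in% fl$genes[1:6]), 5)
})

test_that("mrmr picks the max-MI gene first and avoids duplicated genes", {
  fx <- toy_dataset(seed = 19, n_genes = 6, markers_per_class = 1,
                    class_sizes = c(a = 30, b = 30, c = 30))
  ds <- fx$dataset
  fl <- rank_mrmr(ds, mrmr_params())
  # brute-force MI of each discretized gene with the labels
  disc <- markerIFS:::discretize_expression(ds$matrix, "mean_std")
  mis <- apply(disc, 2, function(col) mi_brute(col, ds$labels))
  expect_equal(fl$genes[1], ds$gene_ids[which.max(mis)])

  # an exact copy of the first selected gene is deferred to the very end
  # of the scored selection while informative genes remain
  m2 <- cbind(ds$matrix, dup_of_first = ds$matrix[, fl$genes[1]])
  colnames(m2)[ncol(m2)] <- "zzz_dup"
  ds2 <- labeled_dataset(m2, ds$labels)
  fl2 <- rank_mrmr(ds2, mrmr_params())
  pos_dup <- match("zzz_dup", fl2$genes)
  expect_gt(pos_dup, 2)
  informative <- names(sort(mis, decreasing = TRUE))[1:3]
  expect_true(all(match(informative, fl2$genes) < pos_dup))
})

test_that("mrmr handles constant genes and appends an unscored tail", {
  m <- cbind(separator_dataset(seed = 2, n = 40, p = 5)$matrix,
             flat = rep(1, 40))
  ds <- labeled_dataset(m, rep(c("A", "B"), 20))
  fl <- rank_mrmr(ds, mrmr_params(n_select = 3))
  expect_length(fl$genes, 6)
  expect_equal(sum(is.na(fl$scores)), 3)
  expect_equal(fl$genes[1], "g001")
  # the constant gene has zero relevance, so it can never rank first and
  # any score it receives in a later round is <= 0
  flat_score <- fl$scores[match("flat", fl$genes)]
  if (!is.na(flat_score)) expect_lte(flat_score, 1e-12)
})

test_that("rf impurity importances normalize and permutation nulls unused genes", {
  fx <- toy_dataset(seed = 23)
  fl <- rank_rf(fx$dataset, num_trees = 200, seed = 3)
  expect_feature_list_valid(fl, fx$dataset$gene_ids)
  expect_true(all(fl$scores >= 0))
  expect_equal(sum(fl$scores), 1)
  expect_gte(sum(unlist(fx$markers) %in% fl$genes[1:6]), 5)
  expect_identical(rank_rf(fx$dataset, num_trees = 200, seed = 3)$scores, fl$scores)

  # a constant gene can never be split on: permutation importance exactly 0
  m <- cbind(fx$dataset$matrix, flat = rep(2, nrow(fx$dataset$matrix)))
  dsf <- labeled_dataset(m, fx$dataset$labels)
  flp <- rank_rf(dsf, num_trees = 100, importance = "permutation", seed = 3)
  expect_identical(flp$scores[match("flat", flp$genes)], 0)
})

test_that("every ranker returns a permutation of the gene set with the shared tie-break", {
  fx <- toy_dataset(seed = 31, n_genes = 15)
  ds <- fx$dataset
  lists <- list(rank_lasso(ds),
                rank_gbt(ds, nrounds = 10, seed = 1),
                rank_mcfs(ds, mcfs_params(n_subsets = 5, trees_per_subset = 1, seed = 1)),
                rank_mrmr(ds),
                rank_rf(ds, num_trees = 50, seed = 1))
  for (fl in lists) {
    expect_feature_list_valid(fl, ds$gene_ids)
    if (fl$method != "mrmr") {  # mrmr is selection-ordered, not score-ordered
      sc <- fl$scores[!is.na(fl$scores)]
      expect_false(is.unsorted(rev(sc)))
    }
  }
})
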