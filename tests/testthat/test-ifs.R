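make_list <- function(n, method = "toy") {
  feature_list(method, sprintf("g%04d", seq_len(n)), rev(seq_len(n)), reorder = FALSE)
}

test_that("prefix subsets follow the interval grid with a partial tail", {
  expect_equal(lengths(build_subsets(make_list(25), interval = 10, cap = 2000)),
               c(10, 20, 25))
  expect_equal(lengths(build_subsets(make_list(40), interval = 1, cap = 5)), 1:5)
  subs <- build_subsets(make_list(40), interval = 15, cap = 40)
  expect_equal(lengths(subs), c(15, 30, 40))
  # each prefix extends the previous
  for (i in 2:length(subs)) {
    expect_identical(subs[[i]][seq_along(subs[[i - 1]])], subs[[i - 1]])
  }
  expect_error(build_subsets(feature_list("x", character(0), numeric(0)), 10, 10),
               "empty")
})

test_that("cross-validated evaluation separates planted markers from noise", {
  fx <- toy_dataset(seed = 77, class_sizes = c(a = 200, b = 200, c = 200),
                    n_genes = 40, effect_size = 3)
  cfg <- ifs_config(cv_folds = 5, classifier = "random_forest", num_trees = 60,
                    seed = 11)
  s <- evaluate_subset(fx$dataset, unlist(fx$markers), cfg)
  expect_gte(s$weighted_f1, 0.95)
  expect_length(s$per_fold_acc, 5)

  # pure-noise genes on balanced 2-class data: chance-level accuracy
  spec <- synthetic_spec(n_classes = 2, n_genes = 20, markers_per_class = 0,
                         class_sizes = c(60, 60), effect_size = 0, seed = 5)
  noise <- generate_dataset(spec)
  s0 <- evaluate_subset(noise, noise$gene_ids[1:10],
                        ifs_config(cv_folds = 5, classifier = "decision_tree",
                                   seed = 2))
  expect_lt(abs(s0$acc - 0.5), 0.17)
})

test_that("run_ifs selects optimal and feasible subset sizes as defined", {
  fx <- toy_dataset(seed = 41, n_genes = 24)
  fl <- rank_rf(fx$dataset, num_trees = 100, seed = 1)
  cfg <- ifs_config(interval = 6, cap = 18, cv_folds = 3,
                    classifier = "decision_tree", seed = 7)
  res <- suppressWarnings(run_ifs(fx$dataset, fl, cfg))
  expect_length(res$records, 3)          # ceil(18 / 6)
  ks <- vapply(res$records, `[[`, numeric(1), "k")
  wf1 <- vapply(res$records, function(r) r$summary$weighted_f1, numeric(1))
  expect_equal(ks, c(6, 12, 18))
  expect_equal(res$optimal_k, ks[which.max(wf1)])
  expect_true(res$feasible_k <= res$optimal_k)
  expect_gte(wf1[ks == res$feasible_k], max(wf1) - cfg$feasible_delta)

  cfg0 <- ifs_config(interval = 6, cap = 18, cv_folds = 3,
                     classifier = "decision_tree", feasible_delta = 0, seed = 7)
  res0 <- suppressWarnings(run_ifs(fx$dataset, fl, cfg0))
  expect_equal(res0$feasible_k, res0$optimal_k)
})

test_that("records are prefix-independent of the cap and fully deterministic", {
  fx <- toy_dataset(seed = 55, n_genes = 20, class_sizes = c(a = 25, b = 15, c = 8))
  fl <- rank_mrmr(fx$dataset)
  cfg_small <- ifs_config(interval = 5, cap = 10, cv_folds = 3,
                          classifier = "decision_tree", seed = 13)
  cfg_big <- ifs_config(interval = 5, cap = 20, cv_folds = 3,
                        classifier = "decision_tree", seed = 13)
  r_small <- suppressWarnings(run_ifs(fx$dataset, fl, cfg_small))
  r_big <- suppressWarnings(run_ifs(fx$dataset, fl, cfg_big))
  expect_identical(r_small$records, r_big$records[1:2])
  expect_identical(r_big, suppressWarnings(run_ifs(fx$dataset, fl, cfg_big)))
})

test_that("balancing before splitting inflates measured performance", {
  spec <- synthetic_spec(n_classes = 3, n_genes = 25, markers_per_class = 2,
                         class_sizes = c(60, 15, 6), effect_size = 1,
                         dropout_rate = 0.3, seed = 21)
  ds <- generate_dataset(spec)
  genes <- ds$gene_ids[1:25]
  base <- ifs_config(cv_folds = 5, classifier = "decision_tree", seed = 3)
  leaky <- ifs_config(cv_folds = 5, classifier = "decision_tree",
                      smote_before_cv = TRUE, seed = 3)
  s_def <- suppressWarnings(evaluate_subset(ds, genes, base))
  s_leak <- suppressWarnings(evaluate_subset(ds, genes, leaky))
  # coarse tolerance: leakage of interpolated test copies should not hurt
  expect_gte(s_leak$weighted_f1, s_def$weighted_f1 - 0.02)
})

test_that("degenerate inputs are rejected or warned about", {
  fx <- toy_dataset(seed = 2, class_sizes = c(a = 12, b = 6, c = 3), n_genes = 8)
  expect_error(evaluate_subset(fx$dataset, character(0), ifs_config(cv_folds = 3)),
               "empty")
  expect_warning(evaluate_subset(fx$dataset, fx$dataset$gene_ids[1:4],
                                 ifs_config(cv_folds = 5, classifier = "decision_tree",
                                            seed = 1)),
                 "stratified")
  expect_error(ifs_config(cv_folds = 1), "cv_folds")
  expect_error(ifs_config(interval = 0), "interval")
})
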