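test_that("generated datasets have the spec's exact shape and class sizes", {
  spec <- synthetic_spec(n_classes = 3, n_genes = 50, markers_per_class = 2,
                         class_sizes = c(10, 5, 3), seed = 1)
  ds <- generate_dataset(spec)
  expect_equal(dim(ds$matrix), c(18, 50))
  expect_equal(as.integer(table(ds$labels)), c(10, 5, 3))
  expect_true(all(is.finite(ds$matrix)) && all(ds$matrix >= 0))
  expect_equal(length(ds$gene_ids), 50)
  expect_false(anyDuplicated(ds$cell_ids) > 0)
})

test_that("generation is a pure function of spec and seed", {
  spec <- synthetic_spec(n_classes = 3, n_genes = 40, markers_per_class = 2,
                         class_sizes = c(6, 5, 4), seed = 99)
  expect_identical(generate_dataset(spec), generate_dataset(spec))
  spec2 <- synthetic_spec(n_classes = 3, n_genes = 40, markers_per_class = 2,
                          class_sizes = c(6, 5, 4), seed = 100)
  expect_false(identical(generate_dataset(spec)$matrix, generate_dataset(spec2)$matrix))
})

test_that("invariant violations name the offending field", {
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_error(synthetic_spec(n_classes = 5, n_genes = 8, markers_per_class = 2),
               "markers_per_class")
  expect_error(synthetic_spec(n_classes = 2, class_sizes = c(5, 1)), "class_sizes")
  expect_error(synthetic_spec(effect_size = -1), "effect_size")
  expect_error(synthetic_spec(dropout_rate = 1.5), "dropout_rate")
})

test_that("planted markers are disjoint, complete and match generation", {
  spec <- synthetic_spec(n_classes = 3, n_genes = 60, markers_per_class = 2,
                         class_sizes = c(5, 5, 5), seed = 3)
  pm <- planted_markers(spec)
  expect_length(pm, 3)
  expect_true(all(lengths(pm) == 2))
  expect_equal(length(unique(unlist(pm))), 3 * 2)
  expect_identical(pm, planted_markers(spec))
})

test_that("markers are elevated in their own class (Monte Carlo check)", {
  spec <- synthetic_spec(n_classes = 3, n_genes = 40, markers_per_class = 2,
                         class_sizes = c(500, 500, 500), effect_size = 2,
                         dropout_rate = 0, seed = 17)
  ds <- generate_dataset(spec)
  pm <- planted_markers(spec)
  for (cls in names(pm)) {
    inside <- ds$labels == cls
    for (g in pm[[cls]]) {
      expect_gt(mean(ds$matrix[inside, g]), mean(ds$matrix[!inside, g]))
    }
  }
})

test_that("a planted marker separates its class better than background (AUC)", {
  fx <- toy_dataset(seed = 5, class_sizes = c(a = 60, b = 60, c = 60))
  ds <- fx$dataset
  auc <- function(score, positive) {
    r <- rank(score)
    n1 <- sum(positive); n0 <- sum(!positive)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pm <- fx$markers
  background <- setdiff(ds$gene_ids, unlist(pm))
  for (cls in names(pm)) {
    pos <- ds$labels == cls
    marker_auc <- auc(ds$matrix[, pm[[cls]][1]], pos)
    bg_auc <- vapply(background, function(g) auc(ds$matrix[, g], pos), numeric(1))
    expect_gt(marker_auc, max(abs(bg_auc - 0.5)) + 0.5)
  }
})

test_that("with zero effect size, 'markers' look like background genes", {
  pvals <- vapply(1:30, function(s) {
    spec <- synthetic_spec(n_classes = 2, n_genes = 10, markers_per_class = 1,
                           class_sizes = c(40, 40), effect_size = 0, seed = s)
    ds <- generate_dataset(spec)
    g <- planted_markers(spec)[[1]][1]
    suppressWarnings(stats::wilcox.test(ds$matrix[ds$labels == levels(ds$labels)[1], g],
                                        ds$matrix[ds$labels == levels(ds$labels)[2], g]))$p.value
  }, numeric(1))
  # p-values should be roughly uniform: coarse checks on mean and extremes
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.75)
  expect_lt(mean(pvals < 0.05), 0.34)
})

test_that("the colon-immune imbalance profile matches its published source", {
  sizes <- colon_immune_class_sizes()
  expect_length(sizes, 25)
  scaled <- scale_class_sizes(3000)
  expect_length(scaled, 25)
  expect_true(all(scaled >= 2))
  expect_equal(names(scaled), names(sizes))
  # proportions approximately preserved for the large classes
  expect_equal(as.numeric(scaled["B cell (IgA Plasma)"] / sum(scaled)),
               12522 / 41650, tolerance = 0.05)
  spec <- synthetic_spec(class_sizes = "colon-immune", total_cells = 3000)
  expect_equal(sum(spec$class_sizes), sum(scaled))
})
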