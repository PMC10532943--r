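#' Venn-region table of top-k feature sets
#'
#' For the top `ks[i]` genes of each ranked list, computes, for every
#' nonempty combination of methods (2^m - 1 regions), the genes exclusive
#' to exactly that combination. Region counts sum to the size of the union
#' of the top-k sets and every union gene falls in exactly one region.
#'
#' @param lists named list of [feature_list()] objects (distinct names).
#' @param ks integer vector (recycled if length 1) of top-k cutoffs, one
#'   per list, each at most the list length.
#' @return data.frame with columns `region` (e.g. `"lasso+rf"`), one
#'   logical membership column per method, `count` and `genes`
#'   (semicolon-separated ids), ordered by number of methods then region
#'   name.
#' @export
intersect_top_features <- function(lists, ks) {
  if (is.null(names(lists)) || anyDuplicated(names(lists)) || any(names(lists) == "")) {
    stopf("'lists' must have unique non-empty names")
  }
  if (length(ks) == 1L) ks <- rep(ks, length(lists))
  if (length(ks) != length(lists)) {
    stopf("%d cutoffs for %d lists", length(ks), length(lists))
  }
  methods <- names(lists)
  tops <- lapply(seq_along(lists), function(i) {
    fl <- lists[[i]]
    stopifnot(inherits(fl, "feature_list"))
    if (ks[i] > length(fl$genes)) {
      stopf("k = %d exceeds length of list '%s' (%d)", ks[i], methods[i],
            length(fl$genes))
    }
    fl$genes[seq_len(ks[i])]
  })
  names(tops) <- methods
  union_genes <- sort(unique(unlist(tops)))
  membership <- vapply(tops, function(g) union_genes %in% g,
                       logical(length(union_genes)))
  membership <- matrix(membership, ncol = length(methods),
                       dimnames = list(union_genes, methods))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(methods)))
  colnames(combos) <- methods
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- as.logical(combos[i, ])
    in_region <- apply(membership, 1, function(r) all(r == sel))
    genes <- union_genes[in_region]
    cbind(data.frame(region = paste(methods[sel], collapse = "+"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(sel, methods))),
          data.frame(count = length(genes),
                     genes = paste(genes, collapse = ";"),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out[order(rowSums(out[methods]), out$region), , drop = FALSE]
}

#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()]: the synthetic data
#' spec (ignored when a dataset is passed directly), the five ranker
#' parameter sets, the incremental-feature-selection settings shared by
#' the decision-tree and random-forest runs, and the rule stage.
#'
#' @param spec a [synthetic_spec()] describing the data to generate.
#' @param seed master seed; stage seeds are derived from it.
#' @param interval,cap,cv_folds,num_trees,feasible_delta,smote_enabled
#'   IFS settings (see [ifs_config()]).
#' @param mcfs,mrmr ranker parameter objects.
#' @param gbt_nrounds,rf_num_trees ranker ensemble sizes.
#' @param rules_oversample balance classes before fitting rule trees
#'   (default FALSE: rules describe real cells).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = synthetic_spec(), seed = 1,
                            interval = 10, cap = 2000, cv_folds = 10,
                            num_trees = 100, feasible_delta = 0.04,
                            smote_enabled = TRUE,
                            mcfs = mcfs_params(seed = derive_seed(seed, 3)),
                            mrmr = mrmr_params(),
                            gbt_nrounds = 100, rf_num_trees = 500,
                            rules_oversample = FALSE) {
  structure(list(spec = spec, seed = check_count(seed, "seed", min = 0L),
                 interval = interval, cap = cap, cv_folds = cv_folds,
                 num_trees = num_trees, feasible_delta = feasible_delta,
                 smote_enabled = isTRUE(smote_enabled),
                 mcfs = mcfs, mrmr = mrmr,
                 gbt_nrounds = gbt_nrounds, rf_num_trees = rf_num_trees,
                 rules_oversample = isTRUE(rules_oversample)),
            class = "pipeline_config")
}

#' Run the whole marker-discovery pipeline
#'
#' Orchestrates all stages on one dataset and writes a deterministic
#' artifact directory: the five ranked feature lists; decision-tree and
#' random-forest IFS curve tables per list; a summary table of the
#' optimal decision-tree, optimal random-forest and feasible
#' random-forest classifiers (5 methods x 3 rows); one rule group per
#' list (a tree on all cells over the decision-tree-optimal genes), with
#' per-class rule counts, rule-gene matrices and cell-type dendrograms;
#' a Venn-region table of the feasible random-forest gene sets; and a
#' JSON manifest of all parameters, seeds and versions. Two runs with the
#' same config and dataset produce byte-identical tables.
#'
#' A stage failure aborts with the stage name; outputs written so far
#' stay on disk and the manifest flags the run incomplete.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created; existing files overwritten).
#' @param dataset optional [labeled_dataset()]; by default generated from
#'   `config$spec`.
#' @param verbose log stage progress via [message()] (default TRUE).
#' @return invisibly, a list with the datasets, feature lists, IFS
#'   results, rule groups, the Venn table and the summary data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, dataset = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("feature_lists", "ifs", "rules")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(
    package = as.character(utils::packageVersion("markerIFS")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("spec", "mcfs", "mrmr"))],
    mcfs = unclass(config$mcfs), mrmr = unclass(config$mrmr),
    complete = FALSE
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_manifest()
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("[data] preparing dataset")
  dataset <- run_stage("data", {
    if (is.null(dataset)) generate_dataset(config$spec) else dataset
  })
  run_stage("data", write_labels(dataset, file.path(out_dir, "labels.tsv")))

  say("[ranking] computing the five feature lists")
  lists <- run_stage("ranking", rank_all(
    dataset, seed = config$seed, mcfs = config$mcfs, mrmr = config$mrmr,
    gbt_nrounds = config$gbt_nrounds, rf_num_trees = config$rf_num_trees))
  manifest$methods <- names(lists)
  run_stage("ranking", for (m in names(lists)) {
    write_feature_list(lists[[m]], file.path(out_dir, "feature_lists",
                                             paste0(m, ".tsv")))
  })

  ifs_results <- list()
  for (clf in c("decision_tree", "random_forest")) {
    cfg <- ifs_config(interval = config$interval, cap = config$cap,
                      cv_folds = config$cv_folds, classifier = clf,
                      num_trees = config$num_trees,
                      smote_enabled = config$smote_enabled,
                      feasible_delta = config$feasible_delta,
                      seed = config$seed)
    for (m in names(lists)) {
      say("[ifs] %s list, %s classifier", m, clf)
      res <- run_stage("ifs", suppressWarnings(run_ifs(dataset, lists[[m]], cfg)))
      ifs_results[[paste(m, clf, sep = "_")]] <- res
      run_stage("ifs", write_ifs_table(
        res, file.path(out_dir, "ifs", paste0(m, "_", clf, ".csv"))))
    }
  }

  say("[report] summary table")
  summary_df <- run_stage("report", {
    rows <- list()
    for (m in names(lists)) {
      dt_res <- ifs_results[[paste0(m, "_decision_tree")]]
      rf_res <- ifs_results[[paste0(m, "_random_forest")]]
      pick <- function(res, k, role) {
        rec <- Filter(function(r) r$k == k, res$records)[[1]]
        data.frame(method = m, classifier = res$classifier, role = role,
                   k = k, acc = rec$summary$acc, mcc = rec$summary$mcc,
                   macro_f1 = rec$summary$macro_f1,
                   weighted_f1 = rec$summary$weighted_f1,
                   stringsAsFactors = FALSE)
      }
      rows <- c(rows, list(pick(dt_res, dt_res$optimal_k, "optimal"),
                           pick(rf_res, rf_res$optimal_k, "optimal"),
                           pick(rf_res, rf_res$feasible_k, "feasible")))
    }
    do.call(rbind, rows)
  })
  run_stage("report", data.table::fwrite(summary_df,
                                         file.path(out_dir, "summary.csv")))

  say("[rules] rule groups from decision-tree-optimal gene sets")
  rule_groups <- list()
  rpc <- list()
  run_stage("rules", for (m in names(lists)) {
    k <- ifs_results[[paste0(m, "_decision_tree")]]$optimal_k
    genes <- lists[[m]]$genes[seq_len(k)]
    rtree <- train_rule_tree(dataset, genes, seed = derive_seed(config$seed, 7),
                             oversample = config$rules_oversample)
    group <- extract_rules(rtree)
    group$method <- m
    rule_groups[[m]] <- group
    write_rules(group, file.path(out_dir, "rules", paste0(m, ".json")),
                file.path(out_dir, "rules", paste0(m, ".txt")))
    rpc[[m]] <- rules_per_class(group)
    rgm <- rule_gene_matrix(group)
    data.table::fwrite(
      data.table::data.table(class = rownames(rgm), as.data.frame(rgm)),
      file.path(out_dir, "rules", paste0(m, "_rule_genes.csv")))
    if (nrow(rgm) >= 2L) {
      hc <- cluster_cell_types(rgm)
      dend <- data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                         height = hc$height)
      data.table::fwrite(dend, file.path(out_dir, "rules",
                                         paste0(m, "_dendrogram.csv")))
      writeLines(hc$labels[hc$order],
                 file.path(out_dir, "rules", paste0(m, "_leaf_order.txt")))
    }
  })
  run_stage("rules", {
    rpc_df <- data.frame(class = dataset$class_order,
                         do.call(cbind, lapply(rpc, as.integer)))
    data.table::fwrite(rpc_df, file.path(out_dir, "rules", "rules_per_class.csv"))
  })

  say("[report] Venn regions of feasible random-forest gene sets")
  venn <- run_stage("report", {
    ks <- vapply(names(lists), function(m) {
      ifs_results[[paste0(m, "_random_forest")]]$feasible_k
    }, numeric(1))
    manifest$venn_ks <- as.list(ks)
    intersect_top_features(lists, ks)
  })
  run_stage("report", data.table::fwrite(venn, file.path(out_dir, "venn.csv")))

  manifest$complete <- TRUE
  write_manifest()
  say("[done] artifacts in %s", out_dir)
  invisible(list(dataset = dataset, feature_lists = lists,
                 ifs_results = ifs_results, summary = summary_df,
                 rule_groups = rule_groups, venn = venn))
}
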