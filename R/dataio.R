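#' Read an expression matrix
#'
#' Reads either a MatrixMarket coordinate file with gene/cell sidecar TSVs
#' or a dense TSV (header row = gene ids, first column = cell ids). The
#' in-memory convention is always cells as rows; `transpose = TRUE`
#' handles MatrixMarket files stored genes-as-rows (the CellRanger
#' dialect).
#'
#' @param matrix_path path to a `.mtx` file or a dense `.tsv`.
#' @param genes_path,cells_path one-column (or first-column-used) TSVs of
#'   gene and cell ids; required for MatrixMarket input.
#' @param transpose MatrixMarket file is genes x cells on disk.
#' @return list with `matrix` (dense, cells x genes), `gene_ids`,
#'   `cell_ids` — a labeled dataset minus the labels; combine with
#'   [read_labels()] and [labeled_dataset()].
#' @export
read_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                            transpose = FALSE) {
  if (!file.exists(matrix_path)) stopf("no such file: %s", matrix_path)
  if (grepl("\\.mtx(\\.gz)?$", matrix_path)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      stopf("MatrixMarket input requires 'genes_path' and 'cells_path' sidecars")
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    if (transpose) m <- t(m)
    gene_ids <- read_id_column(genes_path)
    cell_ids <- read_id_column(cells_path)
    if (ncol(m) != length(gene_ids)) {
      stopf("dimension mismatch: %s declares %d gene columns but %s lists %d genes",
            matrix_path, ncol(m), genes_path, length(gene_ids))
    }
    if (nrow(m) != length(cell_ids)) {
      stopf("dimension mismatch: %s declares %d cell rows but %s lists %d cells",
            matrix_path, nrow(m), cells_path, length(cell_ids))
    }
  } else {
    dt <- data.table::fread(matrix_path, sep = "\t", header = TRUE)
    cell_ids <- as.character(dt[[1L]])
    gene_ids <- colnames(dt)[-1L]
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
  }
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids in %s", matrix_path)
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids in %s", matrix_path)
  if (any(!is.finite(m))) stopf("non-finite entries in %s", matrix_path)
  if (any(m < 0)) stopf("negative entries in %s", matrix_path)
  dimnames(m) <- list(cell_ids, gene_ids)
  list(matrix = m, gene_ids = gene_ids, cell_ids = cell_ids)
}

read_id_column <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  as.character(data.table::fread(path, sep = "\t", header = FALSE)[[1L]])
}

#' Write an expression matrix as MatrixMarket + sidecars
#'
#' Writes `matrix.mtx` (cells as rows, full double precision),
#' `genes.tsv` and `cells.tsv` into `dir`; [read_expression()] on the
#' three files restores the matrix exactly.
#'
#' @param x a [labeled_dataset()] or a cells x genes matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_expression <- function(x, dir) {
  if (inherits(x, "labeled_dataset")) x <- x$matrix
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  sm <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
                    "TsparseMatrix")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(x), ncol(x), length(sm@x)),
               sprintf("%d %d %s", sm@i + 1L, sm@j + 1L, format_full(sm@x))),
             paths[1])
  writeLines(colnames(x), paths[2])
  writeLines(rownames(x), paths[3])
  invisible(paths)
}

#' Read per-cell labels
#'
#' Reads a two-column TSV (`cell_id`, `cell_type`, with header) and
#' returns the labels aligned to `cell_ids`. Cell ids in the file that are
#' absent from `cell_ids`, or cells without a label, are errors.
#'
#' @param path label TSV path.
#' @param cell_ids the dataset's cell ids.
#' @return character vector of labels parallel to `cell_ids`.
#' @export
read_labels <- function(path, cell_ids) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(dt) < 2L) stopf("label file %s needs columns cell_id, cell_type", path)
  ids <- dt[[1L]]
  unknown <- setdiff(ids, cell_ids)
  if (length(unknown)) {
    stopf("label file %s contains cell ids absent from the matrix: %s", path,
          paste(utils::head(unknown, 10), collapse = ", "))
  }
  pos <- match(cell_ids, ids)
  if (anyNA(pos)) {
    stopf("label file %s is missing labels for %d cell(s), e.g. %s", path,
          sum(is.na(pos)), cell_ids[which(is.na(pos))[1L]])
  }
  dt[[2L]][pos]
}

#' Write per-cell labels
#' @param dataset a [labeled_dataset()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_labels <- function(dataset, path) {
  data.table::fwrite(data.table::data.table(cell_id = dataset$cell_ids,
                                            cell_type = as.character(dataset$labels)),
                     path, sep = "\t")
  invisible(path)
}

#' Write / read a ranked feature list
#'
#' TSV with a `# method=<name>` header line followed by columns
#' `rank`, `gene_id`, `score` (full precision; `NA` for an unscored
#' tail). The reader restores the list in file order and validates that
#' ranks are contiguous from 1 and scored ranks are non-increasing.
#'
#' @param flist a [feature_list()].
#' @param path TSV path.
#' @return `write_feature_list`: invisibly, `path`;
#'   `read_feature_list`: a [feature_list()].
#' @export
write_feature_list <- function(flist, path) {
  stopifnot(inherits(flist, "feature_list"))
  writeLines(c(sprintf("# method=%s", flist$method),
               "rank\tgene_id\tscore",
               sprintf("%d\t%s\t%s", seq_along(flist$genes), flist$genes,
                       format_full(flist$scores))),
             path)
  invisible(path)
}

format_full <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "NA" else sprintf("%.17g", v),
                character(1))
  out
}

#' @rdname write_feature_list
#' @export
read_feature_list <- function(path) {
  first <- readLines(path, n = 1L)
  method <- sub("^# method=", "", first)
  if (identical(method, first)) stopf("%s: missing '# method=' header line", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = 1L,
                          na.strings = "NA")
  if (!identical(dt$rank, seq_len(nrow(dt)))) {
    stopf("%s: ranks are not contiguous 1..n", path)
  }
  # selection-order lists (mrmr) carry round-criterion scores that need not
  # decrease monotonically; score-ordered lists must.
  if (method != "mrmr") {
    sc <- dt$score[!is.na(dt$score)]
    if (is.unsorted(rev(sc))) stopf("%s: scores increase with rank", path)
  }
  feature_list(method, dt$gene_id, as.numeric(dt$score), reorder = FALSE)
}

#' Write / read an IFS curve table
#'
#' CSV with one row per evaluated subset size: `k`, `acc`, `mcc`,
#' `macro_f1`, `weighted_f1` and the per-fold accuracies.
#'
#' @param ifs an `ifs_result` (or its [as.data.frame.ifs_result()] table).
#' @param path CSV path.
#' @return `write_ifs_table`: invisibly, `path`; `read_ifs_table`: a
#'   data.frame.
#' @export
write_ifs_table <- function(ifs, path) {
  df <- if (inherits(ifs, "ifs_result")) as.data.frame(ifs) else as.data.frame(ifs)
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' @rdname write_ifs_table
#' @export
read_ifs_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = ","))
}

#' Write / read a rule group
#'
#' JSON schema:
#' `{method, class_order, rules: [{id, predicates: [{gene, op, threshold}],
#' class, support, purity}]}` with thresholds at full precision. The
#' optional text rendering prints one `IF ... THEN ...` line per rule with
#' thresholds at 4 significant digits.
#'
#' @param group a rule group ([extract_rules()]).
#' @param path JSON path.
#' @param txt_path optional plain-text path.
#' @return `write_rules`: invisibly, `path`; `read_rules`: a rule group.
#' @export
write_rules <- function(group, path, txt_path = NULL) {
  stopifnot(inherits(group, "rule_group"))
  obj <- list(method = group$method,
              class_order = group$class_order,
              rules = lapply(group$rules, function(r) {
                list(id = r$id,
                     predicates = lapply(seq_len(nrow(r$predicates)), function(j) {
                       list(gene = r$predicates$gene[j], op = r$predicates$op[j],
                            threshold = r$predicates$threshold[j])
                     }),
                     class = r$class, support = r$support, purity = r$purity)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(txt_path)) {
    lines <- vapply(group$rules, function(r) {
      cond <- if (nrow(r$predicates)) {
        paste(sprintf("%s %s %.4g", r$predicates$gene,
                      ifelse(r$predicates$op == "le", "<=", ">"),
                      r$predicates$threshold), collapse = " AND ")
      } else "TRUE"
      sprintf("%s: IF %s THEN %s (support=%d, purity=%.4g)",
              r$id, cond, r$class, r$support, r$purity)
    }, character(1))
    writeLines(lines, txt_path)
  }
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    preds <- r$predicates
    list(id = r$id,
         predicates = data.frame(
           gene = vapply(preds, function(p) p$gene, character(1)),
           op = vapply(preds, function(p) p$op, character(1)),
           threshold = vapply(preds, function(p) as.numeric(p$threshold), numeric(1)),
           stringsAsFactors = FALSE),
         class = r$class, support = as.integer(r$support),
         purity = as.numeric(r$purity))
  })
  structure(list(method = obj$method,
                 class_order = unlist(obj$class_order),
                 rules = rules),
            class = "rule_group")
}
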