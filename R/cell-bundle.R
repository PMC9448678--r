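#' Cell-level data bundle for CROP-seq analysis
#'
#' A cell bundle holds the three aligned pieces of a CROP-seq experiment:
#' `expr` (cells x genes UMI counts), `sgrna_umi` (cells x sgRNAs UMI
#' counts) and `cells` (metadata tibble, one row per cell in the same
#' order). Metadata must contain `cell_id`; the analysis stages add or
#' consume `assigned_sgrna`, `assigned_gene` and `cluster_label` columns.
#' Rows of both matrices are named by `cell_id`.
#'
#' @param expr Cells x genes matrix (coerced to sparse).
#' @param sgrna_umi Cells x sgRNAs matrix (coerced to sparse).
#' @param cells Metadata data frame with a `cell_id` column.
#' @return A list of class `cell_bundle`.
#' @export
as_cell_bundle <- function(expr, sgrna_umi, cells) {
  cells <- as_tibble(cells)
  if (!"cell_id" %in% names(cells)) abort("cell metadata needs a cell_id column")
  expr <- methods::as(Matrix::Matrix(expr, sparse = TRUE), "CsparseMatrix")
  sgrna_umi <- methods::as(Matrix::Matrix(sgrna_umi, sparse = TRUE), "CsparseMatrix")
  if (nrow(expr) != nrow(cells) || nrow(sgrna_umi) != nrow(cells)) {
    abort("expr, sgrna_umi and cells must share one cell ordering (row count)")
  }
  if (any(expr@x < 0) || any(sgrna_umi@x < 0)) abort("counts must be nonnegative")
  rownames(expr) <- cells$cell_id
  rownames(sgrna_umi) <- cells$cell_id
  if (is.null(colnames(expr))) abort("expr needs gene column names")
  if (is.null(colnames(sgrna_umi))) abort("sgrna_umi needs sgRNA column names")
  if ("assigned_sgrna" %in% names(cells)) {
    known <- cells$assigned_sgrna %in% c(colnames(sgrna_umi), NA, "unassigned")
    if (!all(known | is.na(cells$assigned_sgrna))) {
      abort("assigned_sgrna values must exist in sgrna_umi columns")
    }
  }
  structure(list(expr = expr, sgrna_umi = sgrna_umi, cells = cells),
            class = "cell_bundle")
}

#' @export
print.cell_bundle <- function(x, ...) {
  cat(sprintf("<cell_bundle> %d cells x %d genes; %d sgRNAs; metadata: %s\n",
              nrow(x$expr), ncol(x$expr), ncol(x$sgrna_umi),
              paste(names(x$cells), collapse = ", ")))
  invisible(x)
}

#' Read or write a cell bundle (Matrix Market + TSV trio)
#'
#' On disk a bundle is a directory holding `expr.mtx`, `expr_genes.tsv`,
#' `sgrna.mtx`, `sgrna_ids.tsv`, `barcodes.tsv` and `cells.tsv` (tab
#' separated, UTF-8, header rows). Matrices are stored cells x features.
#'
#' @param dir Directory to write into / read from.
#' @param bundle A `cell_bundle`.
#' @return `read_cell_bundle()` returns a `cell_bundle`;
#'   `write_cell_bundle()` returns `dir` invisibly.
#' @export
write_cell_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cell_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(bundle$expr, file.path(dir, "expr.mtx"))
  Matrix::writeMM(bundle$sgrna_umi, file.path(dir, "sgrna.mtx"))
  readr::write_tsv(tibble(gene = colnames(bundle$expr)),
                   file.path(dir, "expr_genes.tsv"), progress = FALSE)
  readr::write_tsv(tibble(sgrna_id = colnames(bundle$sgrna_umi)),
                   file.path(dir, "sgrna_ids.tsv"), progress = FALSE)
  readr::write_tsv(tibble(cell_id = bundle$cells$cell_id),
                   file.path(dir, "barcodes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$cells, file.path(dir, "cells.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_cell_bundle
#' @export
read_cell_bundle <- function(dir) {
  expr <- methods::as(Matrix::readMM(file.path(dir, "expr.mtx")), "CsparseMatrix")
  sgrna <- methods::as(Matrix::readMM(file.path(dir, "sgrna.mtx")), "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "expr_genes.tsv"),
                           col_types = "c", progress = FALSE)$gene
  sgrna_ids <- readr::read_tsv(file.path(dir, "sgrna_ids.tsv"),
                               col_types = "c", progress = FALSE)$sgrna_id
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           col_types = readr::cols(), progress = FALSE,
                           na = "NA")  # keep "" distinct from missing
  colnames(expr) <- genes
  colnames(sgrna) <- sgrna_ids
  as_cell_bundle(expr, sgrna, cells)
}
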