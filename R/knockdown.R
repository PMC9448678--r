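#' Log1p counts-per-million normalization
#'
#' `log1p(count / cell_total * 1e6)` per cell; the working normalization for
#' knockdown-cell selection and differential expression.
#'
#' @param expr Cells x genes count matrix (dense or sparse).
#' @return A dense cells x genes matrix of normalized expression.
#' @export
normalize_log_cpm <- function(expr) {
  m <- as.matrix(expr)
  totals <- rowSums(m)
  totals[totals == 0] <- 1
  log1p(m / totals * 1e6)
}

#' Select the strongest-knockdown cells for a target gene
#'
#' Among cells assigned to sgRNAs targeting `target_gene`, keep those whose
#' normalized (log1p-CPM) expression of the target is strictly below the
#' median of that same population — the half of the perturbed population
#' with the deepest knockdown. With an even population the two middle cells
#' straddle the median, so exactly half are kept; when all cells tie, none
#' are strictly below the median and the selection is empty.
#'
#' @param bundle A `cell_bundle` whose metadata carries `assigned_gene`
#'   (see [add_assignment()]).
#' @param target_gene Target gene symbol; must be a column of `expr`.
#' @param norm_expr Optional precomputed [normalize_log_cpm()] matrix
#'   (recomputed when `NULL`).
#' @return Character vector of selected `cell_id`s (possibly empty; empty
#'   with a warning when no cell is assigned to the target).
#' @export
select_knockdown_cells <- function(bundle, target_gene, norm_expr = NULL) {
  stopifnot(inherits(bundle, "cell_bundle"))
  if (!target_gene %in% colnames(bundle$expr)) {
    abort(paste0("target gene \"", target_gene, "\" not in expression matrix"))
  }
  if (!"assigned_gene" %in% names(bundle$cells)) {
    abort("bundle metadata lacks assigned_gene; run add_assignment() first")
  }
  in_pop <- !is.na(bundle$cells$assigned_gene) &
    bundle$cells$assigned_gene == target_gene
  if (!any(in_pop)) {
    warn(paste0("no cells assigned to ", target_gene, "; empty selection"))
    return(character(0))
  }
  if (is.null(norm_expr)) norm_expr <- normalize_log_cpm(bundle$expr)
  v <- norm_expr[in_pop, target_gene]
  keep <- v < median(v)
  bundle$cells$cell_id[in_pop][keep]
}

#' Differential expression between knockdown and control cells
#'
#' For one target gene: Welch two-sample t-tests per expressed gene on
#' standardized expression (log1p-CPM z-scored per gene across the cells
#' entering the test), knockdown cells versus NTC cells, with Bonferroni
#' (default) or Benjamini-Hochberg adjustment. A gene is significant when
#' its adjusted p is below `alpha` (default 0.1). The effect is the
#' difference of standardized means (knockdown minus control).
#'
#' @param bundle A `cell_bundle` with assignment metadata.
#' @param kd_cells Character vector of knockdown cell ids (e.g. from
#'   [select_knockdown_cells()]).
#' @param ntc_cells Character vector of control cell ids; default: all cells
#'   assigned to NTC sgRNAs.
#' @param target_gene Optional label recorded in the output.
#' @param min_cells Minimum cells per group (default 2); below it the test
#'   is refused with an error.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param alpha Significance level on adjusted p (default 0.1).
#' @return A tibble of class `deg_table`: `target_gene`, `gene`, `effect`,
#'   `p`, `p_adj`, `significant`, with group sizes in attributes.
#' @export
knockdown_deg <- function(bundle, kd_cells, ntc_cells = NULL,
                          target_gene = NA_character_, min_cells = 2,
                          adjust = c("bonferroni", "BH"), alpha = 0.1) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(bundle, "cell_bundle"))
  if (is.null(ntc_cells)) {
    if (!"assigned_gene" %in% names(bundle$cells)) {
      abort("bundle metadata lacks assigned_gene; run add_assignment() first")
    }
    ntc_cells <- bundle$cells$cell_id[
      !is.na(bundle$cells$assigned_gene) & bundle$cells$assigned_gene == "NTC"]
  }
  kd_idx <- match(kd_cells, bundle$cells$cell_id)
  ntc_idx <- match(ntc_cells, bundle$cells$cell_id)
  if (anyNA(kd_idx) || anyNA(ntc_idx)) abort("unknown cell ids")
  if (length(kd_idx) < min_cells || length(ntc_idx) < min_cells) {
    abort(paste0("need >= ", min_cells, " cells per group (",
                 length(kd_idx), " knockdown, ", length(ntc_idx), " control)"))
  }
  idx <- c(kd_idx, ntc_idx)
  grp <- rep(c("kd", "ntc"), c(length(kd_idx), length(ntc_idx)))
  nm <- normalize_log_cpm(bundle$expr[idx, , drop = FALSE])
  res <- purrr::map_dfr(colnames(nm), function(g) {
    v <- nm[, g]
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(tibble(gene = g, effect = 0, p = 1))
    z <- (v - mean(v)) / s  # per-gene standardization across tested cells
    a <- z[grp == "kd"]
    b <- z[grp == "ntc"]
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) return(tibble(gene = g, effect = mean(a) - mean(b), p = 1))
    tibble(gene = g, effect = unname(tt$estimate[1] - tt$estimate[2]),
           p = tt$p.value)
  })
  res$p_adj <- pmin(p.adjust(res$p, method = adjust), 1)
  res$significant <- res$p_adj < alpha
  out <- bind_cols(tibble(target_gene = target_gene), res)
  attr(out, "n_kd") <- length(kd_idx)
  attr(out, "n_ntc") <- length(ntc_idx)
  attr(out, "adjust") <- adjust
  class(out) <- c("deg_table", class(out))
  out
}

#' Per-target DEG summary across a CROP-seq experiment
#'
#' Runs [select_knockdown_cells()] and [knockdown_deg()] for every target
#' gene in the manifest, and summarizes the top `n_top` differentially
#' expressed genes by absolute effect for each target with more than
#' `min_kd_cells` knockdown cells (targets below the floor stay in the full
#' table but are excluded from the summary). Targets whose knockdown
#' selection is too small to test are skipped with a message.
#'
#' @param bundle A `cell_bundle` with assignment metadata.
#' @param manifest The `sgrna_manifest`.
#' @param min_kd_cells Cell floor for the top-DEG summary (default 50,
#'   exclusive).
#' @param n_top Number of summary DEGs per target (default 20).
#' @inheritParams knockdown_deg
#' @return A list with `deg` (all tests, `deg_table`) and `top` (summary
#'   tibble restricted to targets with `> min_kd_cells` knockdown cells).
#' @export
cropseq_deg_screen <- function(bundle, manifest, min_kd_cells = 50,
                               n_top = 20, adjust = c("bonferroni", "BH"),
                               alpha = 0.1) {
  adjust <- match.arg(adjust)
  targets <- unique(manifest$target_gene[!manifest$is_ntc])
  targets <- intersect(targets, colnames(bundle$expr))
  norm <- normalize_log_cpm(bundle$expr)
  kd_counts <- integer(0)
  all_deg <- list()
  for (tg in targets) {
    kd <- suppressWarnings(select_knockdown_cells(bundle, tg, norm_expr = norm))
    kd_counts[tg] <- length(kd)
    res <- tryCatch(
      knockdown_deg(bundle, kd, target_gene = tg, adjust = adjust,
                    alpha = alpha),
      error = function(e) {
        message("skipping ", tg, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) all_deg[[tg]] <- res
  }
  deg <- bind_rows(all_deg)
  if (nrow(deg) == 0) return(list(deg = deg, top = deg, kd_cells = kd_counts))
  top <- deg |>
    filter(kd_counts[.data$target_gene] > min_kd_cells) |>
    group_by(.data$target_gene) |>
    arrange(desc(abs(.data$effect)), .by_group = TRUE) |>
    slice_head(n = n_top) |>
    ungroup()
  list(deg = deg, top = top, kd_cells = kd_counts)
}
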