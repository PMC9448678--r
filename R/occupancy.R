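#' Cluster occupancy relative to non-targeting controls
#'
#' For each perturbed gene g and cluster c, the relative proportion
#' `prop(g, c) = (n_gc / n_g) / (n_NTCc / n_NTC)`: the fraction of g's cells
#' in cluster c divided by the fraction of NTC cells there. The NTC row is
#' identically 1 wherever defined. Clusters with zero NTC cells yield
#' `NA` relative proportions (flagged, never silently 0). Cells without an
#' assignment or without a cluster label are excluded (with a recorded
#' count), as are cells failing the `qc_keep` metadata filter when present.
#'
#' @param bundle A `cell_bundle` whose metadata has `assigned_gene` (or
#'   `assigned_sgrna` for `level = "sgrna"`) and `cluster_label`.
#' @param level `"gene"` (default, pooling each gene's sgRNAs) or `"sgrna"`.
#' @return A tibble of class `occupancy_result` in long form: `group`,
#'   `cluster`, `n_cells`, `prop`, `ntc_prop`, `rel_prop` (`NA` where the
#'   NTC proportion is 0). Attributes: `n_excluded`, `level`.
#' @export
cluster_occupancy <- function(bundle, level = c("gene", "sgrna")) {
  level <- match.arg(level)
  stopifnot(inherits(bundle, "cell_bundle"))
  meta <- bundle$cells
  group_col <- if (level == "gene") "assigned_gene" else "assigned_sgrna"
  if (!group_col %in% names(meta)) {
    abort(paste0("bundle metadata lacks ", group_col, "; run add_assignment() first"))
  }
  if (!"cluster_label" %in% names(meta)) abort("bundle metadata lacks cluster_label")
  keep <- !is.na(meta[[group_col]]) & !is.na(meta$cluster_label)
  if ("qc_keep" %in% names(meta)) keep <- keep & meta$qc_keep
  n_excluded <- sum(!keep)
  meta <- meta[keep, ]
  if (level == "gene") {
    ntc_groups <- "NTC"
  } else {
    ntc_sgrnas <- unique(bundle$cells$assigned_sgrna[
      !is.na(bundle$cells$assigned_gene) & bundle$cells$assigned_gene == "NTC"])
    ntc_groups <- ntc_sgrnas
  }
  is_ntc_cell <- if (level == "gene") {
    meta$assigned_gene == "NTC"
  } else meta$assigned_sgrna %in% ntc_groups
  if (!any(is_ntc_cell)) abort("no NTC cells; cannot normalize occupancy")

  clusters <- sort(unique(meta$cluster_label))
  groups <- sort(unique(meta[[group_col]]))
  tab <- table(factor(meta[[group_col]], levels = groups),
               factor(meta$cluster_label, levels = clusters))
  ntc_counts <- table(factor(meta$cluster_label[is_ntc_cell], levels = clusters))
  n_ntc <- sum(ntc_counts)
  ntc_prop <- as.numeric(ntc_counts) / n_ntc

  out <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("group", "cluster", "n_cells")
  out <- out |>
    group_by(.data$group) |>
    mutate(prop = .data$n_cells / sum(.data$n_cells)) |>
    ungroup() |>
    mutate(ntc_prop = ntc_prop[match(.data$cluster, clusters)],
           rel_prop = ifelse(.data$ntc_prop > 0, .data$prop / .data$ntc_prop,
                             NA_real_))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "level") <- level
  class(out) <- c("occupancy_result", class(out))
  out
}

#' Pivot an occupancy result to a heatmap-ready wide table
#'
#' @param occupancy An `occupancy_result`.
#' @param value `"rel_prop"` (default) or `"n_cells"`.
#' @return A wide tibble, one row per group, one column per cluster.
#' @export
occupancy_matrix <- function(occupancy, value = c("rel_prop", "n_cells")) {
  value <- match.arg(value)
  tidyr::pivot_wider(occupancy[c("group", "cluster", value)],
                     names_from = "cluster",
                     values_from = tidyr::all_of(value))
}

#' Occupancy heatmap
#'
#' log2 relative proportion (perturbation vs NTC) per gene and cluster.
#'
#' @param object An `occupancy_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_result <- function(object, ...) {
  df <- as_tibble(object)
  df$log2_rel <- log2(ifelse(df$rel_prop > 0, df$rel_prop, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$group,
                                   fill = .data$log2_rel)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = expression(log[2] ~ "rel. proportion")) +
    ggplot2::theme_minimal()
}

#' Fisher's exact test on cell-state proportions
#'
#' Two-sided exact test on a 2x2 contingency table of (group) x (in state /
#' not in state): the p-value sums hypergeometric probabilities of tables at
#' most as probable as the observed one, alongside the sample odds ratio
#' `(a * d) / (b * c)`.
#'
#' @param counts_2x2 A 2x2 nonnegative integer matrix (rows: groups;
#'   columns: in-state / not-in-state).
#' @return A one-row tibble: `p_value`, `odds_ratio`.
#' @export
#' @examples
#' state_proportion_test(matrix(c(8, 2, 2, 8), nrow = 2, byrow = TRUE))
state_proportion_test <- function(counts_2x2) {
  m <- as.matrix(counts_2x2)
  if (!all(dim(m) == c(2, 2))) abort("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) abort("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("empty margin in contingency table")
  }
  ft <- fisher.test(m, alternative = "two.sided")
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  tibble(p_value = ft$p.value, odds_ratio = or)
}
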