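#' Call screen hits from a count table
#'
#' End-to-end gene-level analysis of one screen comparison. The stages are:
#'
#' 1. per-sgRNA phenotypes ([compute_sgrna_phenotypes()]), NTC-centered;
#' 2. negative-control quasi-genes ([make_quasi_genes()]);
#' 3. per gene and per quasi-gene, a raw phenotype score (mean of its
#'    sgRNAs' phenotypes by default, or the mean of the top `top_k` by
#'    absolute phenotype) and a two-sided Mann-Whitney p-value of its sgRNA
#'    phenotypes against all NTC phenotypes;
#' 4. standardized phenotype scores against the quasi-gene null
#'    ([standardize_phenotypes()]);
#' 5. Gene Score = standardized phenotype x (-log10 p), and empirical-FDR
#'    hit calls per tail ([empirical_fdr_threshold()]).
#'
#' Quasi-gene rows are returned alongside real genes (flagged `is_quasi`)
#' because they calibrate the cutoff; they are never flagged as hits.
#'
#' @param counts A `screen_counts` tibble.
#' @param manifest The matching `sgrna_manifest`.
#' @param sample_a,sample_b Reference and comparison sample column names.
#' @param fdr_target Empirical FDR target (default 0.1).
#' @param pseudocount Pseudocount for phenotype computation (default 1).
#' @param aggregation `"mean"` (default) or `"top_k"` (mean of the `top_k`
#'   sgRNAs by absolute phenotype).
#' @param top_k Number of sgRNAs used by the `"top_k"` aggregation (default 3).
#' @param n_quasi Number of quasi-genes (default: 2x the number of real
#'   genes).
#' @param quasi_group_size sgRNAs per quasi-gene (default 5).
#' @param seed Seed for quasi-gene sampling (default 1).
#' @return A tibble of class `gene_results` with columns `gene`, `n_sgrnas`,
#'   `raw_phenotype`, `phenotype_score`, `p_value`, `gene_score`, `is_quasi`,
#'   `hit`, `direction`, ordered by descending `|gene_score|` within real
#'   genes first. Cutoffs and parameters are carried in attributes (see
#'   [glance.gene_results()]).
#' @export
#' @examples
#' sim <- simulate_survival_screen(sim_config(
#'   n_genes = 25, n_ntc = 25, fraction_hits = 0.2, effect_sign = -1,
#'   depth = 2e5, seed = 11))
#' res <- call_hits(sim$counts, sim$manifest, "t0", "tF", seed = 11)
#' dplyr::filter(res, hit)
call_hits <- function(counts, manifest, sample_a, sample_b,
                      fdr_target = 0.1, pseudocount = 1,
                      aggregation = c("mean", "top_k"), top_k = 3,
                      n_quasi = NULL, quasi_group_size = 5, seed = 1L) {
  aggregation <- match.arg(aggregation)
  phen <- compute_sgrna_phenotypes(counts, manifest, sample_a, sample_b,
                                   pseudocount = pseudocount)
  ntc_phen <- phen$phenotype[phen$is_ntc]
  if (length(ntc_phen) < 2) abort("need >= 2 NTC sgRNAs for gene statistics")

  quasi <- make_quasi_genes(manifest, n_groups = n_quasi,
                            group_size = quasi_group_size, seed = seed)
  phen_by_id <- setNames(phen$phenotype, phen$sgrna_id)
  real_groups <- split(phen$phenotype[!phen$is_ntc],
                       phen$target_gene[!phen$is_ntc])
  quasi_groups <- split(phen_by_id[quasi$sgrna_id], quasi$quasi_gene)

  agg <- function(v) {
    if (aggregation == "top_k" && length(v) > top_k) {
      v <- v[order(abs(v), decreasing = TRUE)[seq_len(top_k)]]
    }
    mean(v)
  }
  score_groups <- function(groups) {
    tibble(
      gene = names(groups),
      n_sgrnas = lengths(groups),
      raw_phenotype = vapply(groups, agg, numeric(1)),
      p_value = vapply(groups, gene_pvalue_mannwhitney, numeric(1), y = ntc_phen)
    )
  }
  real_tbl <- score_groups(real_groups)
  quasi_tbl <- score_groups(quasi_groups)

  real_tbl$phenotype_score <- standardize_phenotypes(real_tbl$raw_phenotype,
                                                     quasi_tbl$raw_phenotype)
  quasi_tbl$phenotype_score <- standardize_phenotypes(quasi_tbl$raw_phenotype,
                                                      quasi_tbl$raw_phenotype)
  real_tbl$gene_score <- real_tbl$phenotype_score * -log10(real_tbl$p_value)
  quasi_tbl$gene_score <- quasi_tbl$phenotype_score * -log10(quasi_tbl$p_value)

  thr <- empirical_fdr_threshold(real_tbl$gene_score, quasi_tbl$gene_score,
                                 fdr_target = fdr_target)
  real_tbl$is_quasi <- FALSE
  real_tbl$hit <- thr$hit
  real_tbl$direction <- thr$direction
  quasi_tbl$is_quasi <- TRUE
  quasi_tbl$hit <- FALSE
  quasi_tbl$direction <- "none"

  out <- bind_rows(
    arrange(real_tbl, desc(abs(.data$gene_score))),
    arrange(quasi_tbl, desc(abs(.data$gene_score)))
  )
  out <- out[, c("gene", "n_sgrnas", "raw_phenotype", "phenotype_score",
                 "p_value", "gene_score", "is_quasi", "hit", "direction")]
  attr(out, "pos_cutoff") <- thr$pos_cutoff
  attr(out, "neg_cutoff") <- thr$neg_cutoff
  attr(out, "fdr_target") <- fdr_target
  attr(out, "samples") <- c(sample_a, sample_b)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "aggregation") <- aggregation
  class(out) <- c("gene_results", class(out))
  out
}

#' Tidy and summarize gene-level screen results
#'
#' `tidy()` returns the per-gene table as a plain tibble; `glance()` returns
#' a one-row summary with the empirical-FDR cutoffs and hit counts.
#'
#' @param x A `gene_results` object from [call_hits()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gene_results <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "gene_results")
  out
}

#' @rdname tidy.gene_results
#' @export
glance.gene_results <- function(x, ...) {
  real <- x[!x$is_quasi, ]
  tibble(
    n_genes = nrow(real),
    n_quasi = sum(x$is_quasi),
    n_hits = sum(real$hit),
    n_hits_positive = sum(real$direction == "positive"),
    n_hits_negative = sum(real$direction == "negative"),
    pos_cutoff = attr(x, "pos_cutoff"),
    neg_cutoff = attr(x, "neg_cutoff"),
    fdr_target = attr(x, "fdr_target")
  )
}

#' Volcano plot of screen results
#'
#' Standardized phenotype score against -log10 Mann-Whitney p, the usual
#' volcano view of a pooled screen. Quasi-genes are drawn in grey, non-hit
#' genes in orange, and hits in blue (phenotype decreases) or red
#' (increases).
#'
#' @param object A `gene_results` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_results <- function(object, ...) {
  df <- tidy(object)
  df$class <- ifelse(df$is_quasi, "quasi-gene",
                     ifelse(!df$hit, "gene",
                            ifelse(df$direction == "negative",
                                   "hit (negative)", "hit (positive)")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype_score,
                                   y = -log10(.data$p_value),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::scale_colour_manual(values = c(
      "quasi-gene" = "grey60", "gene" = "orange",
      "hit (negative)" = "#2166AC", "hit (positive)" = "#B2182B")) +
    ggplot2::labs(x = "standardized phenotype score",
                  y = expression(-log[10](italic(p))),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.gene_results <- function(x, ...) {
  cat(sprintf("# Screen gene results: %d genes, %d quasi-genes, %d hits (FDR %.0f%%)\n",
              sum(!x$is_quasi), sum(x$is_quasi), sum(x$hit),
              100 * attr(x, "fdr_target")))
  NextMethod()
}
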