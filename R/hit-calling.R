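#' Per-sgRNA phenotype scores
#'
#' The raw phenotype of sgRNA i between two samples a (reference, e.g. t0 or
#' the low sorted bin) and b (e.g. the final time point or the high bin) is
#' its depth-normalized log2 frequency change,
#' `log2(((c_ib + ps) / N_b) * (N_a / (c_ia + ps)))`, where `N` are the
#' sample column sums and `ps` a pseudocount. Phenotypes are then centered so
#' the median over NTC sgRNAs is exactly zero, which anchors the null at the
#' non-targeting controls rather than at the library average.
#'
#' sgRNAs with fewer than `min_reads` reads in the reference sample are
#' flagged (`low_count`), not dropped.
#'
#' @param counts A `screen_counts` tibble.
#' @param manifest The matching `sgrna_manifest` (supplies NTC flags).
#' @param sample_a,sample_b Reference and comparison sample column names.
#' @param pseudocount Added to every count before forming ratios (default 1).
#' @param min_reads Flagging threshold on reference-sample reads (default 10).
#' @return A tibble of class `sgrna_phenotypes` with columns `sgrna_id`,
#'   `target_gene`, `is_ntc`, `raw_lfc`, `phenotype`, `low_count`.
#' @export
compute_sgrna_phenotypes <- function(counts, manifest, sample_a, sample_b,
                                     pseudocount = 1, min_reads = 10) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(counts)) abort(paste0("sample \"", s, "\" not in counts table"))
  }
  m <- match(counts$sgrna_id, manifest$sgrna_id)
  if (anyNA(m)) abort("counts table contains sgRNAs absent from the manifest")
  is_ntc <- manifest$is_ntc[m]
  if (sum(is_ntc) < 1) abort("no NTC sgRNAs; cannot center phenotypes")
  ca <- counts[[sample_a]]
  cb <- counts[[sample_b]]
  raw <- log2(((cb + pseudocount) / sum(cb)) * (sum(ca) / (ca + pseudocount)))
  centered <- raw - median(raw[is_ntc])
  out <- tibble(
    sgrna_id = counts$sgrna_id,
    target_gene = manifest$target_gene[m],
    is_ntc = is_ntc,
    raw_lfc = raw,
    phenotype = centered,
    low_count = ca < min_reads
  )
  class(out) <- c("sgrna_phenotypes", class(out))
  out
}

#' Two-sided Mann-Whitney U test for a gene's sgRNA phenotypes
#'
#' Compares the phenotypes of one gene's sgRNAs against the phenotypes of
#' all NTC sgRNAs. When the smaller group has at most 8 values, the larger
#' at most 1000 and the data are tie-free, the exact null distribution of
#' the rank-sum statistic is used (the usual regime for a gene's handful of
#' sgRNAs against the NTC pool); otherwise the normal approximation with
#' midrank tie correction and continuity correction.
#'
#' @param x Numeric vector: the gene's sgRNA phenotypes.
#' @param y Numeric vector: NTC sgRNA phenotypes (length >= 2).
#' @return Two-sided p-value.
#' @export
gene_pvalue_mannwhitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 2) {
    abort("need >= 1 gene sgRNA phenotype and >= 2 NTC phenotypes")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && min(length(x), length(y)) <= 8 &&
    max(length(x), length(y)) <= 1000
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE)$p.value
  )
  # all-identical degenerate input: no evidence against the null
  if (is.na(p)) p <- 1
  min(p, 1)
}

#' Sample negative-control quasi-genes
#'
#' Quasi-genes are pseudo-genes assembled by sampling NTC sgRNA ids with
#' replacement, in groups of `group_size` (default five, matching the
#' targeting-library design of five sgRNAs per gene). Scoring quasi-genes
#' through the same pipeline as real genes yields the empirical null
#' distribution of gene-level statistics used for standardization and for
#' the empirical-FDR cutoff. The default number of groups is twice the
#' number of real genes, which makes the add-one FDR estimator (see
#' [empirical_fdr_threshold()]) able to declare as few as
#' `1 / (2 * fdr_target)` same-tail hits while retaining its finite-sample
#' guarantee.
#'
#' @param manifest An `sgrna_manifest` with at least one NTC sgRNA.
#' @param n_groups Number of quasi-genes (default `2 *` number of real genes).
#' @param group_size sgRNAs per quasi-gene (default 5).
#' @param seed RNG seed for the resampling.
#' @return A tibble of class `quasi_gene_set` with columns `quasi_gene` and
#'   `sgrna_id` (`n_groups * group_size` rows).
#' @export
make_quasi_genes <- function(manifest, n_groups = NULL, group_size = 5,
                             seed = 1L) {
  ntc_ids <- manifest$sgrna_id[manifest$is_ntc]
  if (length(ntc_ids) < 1) abort("manifest has no NTC sgRNAs")
  n_real <- length(unique(manifest$target_gene[!manifest$is_ntc]))
  n_groups <- n_groups %||% max(2L * n_real, 2L)
  if (n_groups < 1 || group_size < 1) abort("n_groups and group_size must be >= 1")
  picks <- with_preserved_seed({
    set.seed(seed)
    sample(ntc_ids, n_groups * group_size, replace = TRUE)
  })
  out <- tibble(
    quasi_gene = rep(sprintf("quasi%04d", seq_len(n_groups)), each = group_size),
    sgrna_id = picks
  )
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("quasi_gene_set", class(out))
  out
}

#' Standardize raw gene phenotype scores against the quasi-gene null
#'
#' The standardized phenotype score of a gene is its raw phenotype score
#' minus the median raw score of the negative-control quasi-genes, divided
#' by the standard deviation of the quasi-gene raw scores.
#'
#' @param raw_scores Numeric vector of raw gene phenotype scores.
#' @param quasi_scores Numeric vector of raw quasi-gene phenotype scores
#'   (>= 2 distinct values).
#' @return Standardized scores, same length as `raw_scores`.
#' @export
standardize_phenotypes <- function(raw_scores, quasi_scores) {
  if (length(quasi_scores) < 2) abort("need >= 2 quasi-gene scores")
  s <- sd(quasi_scores)
  if (!is.finite(s) || s == 0) abort("quasi-gene scores have zero standard deviation")
  (raw_scores - median(quasi_scores)) / s
}

#' Empirical-FDR Gene Score cutoffs
#'
#' Finds, separately for the positive and negative tail, the smallest
#' absolute Gene Score cutoff whose estimated false-discovery rate is at or
#' below `fdr_target`, using the quasi-gene scores as the empirical null.
#' The estimator at a candidate cutoff c (positive tail) is
#'
#'   `est_FDR(c) = ((1 + #\{quasi >= c\}) / n_quasi * n_genes) / #\{genes >= c\}`
#'
#' The `1 +` in the numerator is a finite-sample (add-one) correction:
#' without it, a single gene exceeding every quasi-gene would always be
#' declared a hit, which under a fully null screen happens with probability
#' about one half; with it, the mean false-discovery proportion stays at or
#' below the target under exchangeability of null gene and quasi-gene
#' scores. Candidate cutoffs are the observed gene scores in the tail. If no
#' candidate satisfies the target the tail has no hits (cutoff `Inf`).
#'
#' @param gene_scores Named or unnamed numeric vector of real-gene scores.
#' @param quasi_scores Numeric vector of quasi-gene scores.
#' @param fdr_target Target empirical FDR in (0, 1) (default 0.1).
#' @return A list with `pos_cutoff`, `neg_cutoff` (score scale; `Inf` /
#'   `-Inf` when a tail is empty), `hit` (logical, per gene) and `direction`
#'   (`"positive"`, `"negative"` or `"none"`).
#' @export
empirical_fdr_threshold <- function(gene_scores, quasi_scores, fdr_target = 0.1) {
  if (length(gene_scores) < 1 || length(quasi_scores) < 1) {
    abort("gene and quasi score sets must be nonempty")
  }
  if (fdr_target <= 0 || fdr_target >= 1) abort("fdr_target must be in (0, 1)")
  n_genes <- length(gene_scores)
  n_quasi <- length(quasi_scores)
  tail_cutoff <- function(g, q) {
    # g, q on the "positive tail" orientation
    cand <- sort(g[g > 0])
    for (c0 in cand) {
      k <- sum(g >= c0)
      Q <- sum(q >= c0)
      est <- ((1 + Q) / n_quasi * n_genes) / k
      if (est <= fdr_target * (1 + 1e-9)) return(c0)
    }
    Inf
  }
  pos_cutoff <- tail_cutoff(gene_scores, quasi_scores)
  neg_cutoff <- -tail_cutoff(-gene_scores, -quasi_scores)
  hit_pos <- gene_scores >= pos_cutoff
  hit_neg <- gene_scores <= neg_cutoff
  list(
    pos_cutoff = pos_cutoff,
    neg_cutoff = neg_cutoff,
    hit = hit_pos | hit_neg,
    direction = ifelse(hit_pos, "positive", ifelse(hit_neg, "negative", "none"))
  )
}
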