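# small builders shared across tests

tiny_manifest <- function(n_genes = 2, sgrnas_per_gene = 2, n_ntc = 3) {
  genes <- sprintf("G%d", seq_len(n_genes))
  gene_col <- rep(genes, each = sgrnas_per_gene)
  ids <- c(paste0(gene_col, "_sg", rep(seq_len(sgrnas_per_gene), n_genes)),
           paste0("ntc", seq_len(n_ntc)))
  target <- c(gene_col, rep("NTC", n_ntc))
  as_sgrna_manifest(tibble::tibble(
    sgrna_id = ids,
    protospacer = vapply(100 + seq_along(ids),
                         screenforge:::synthetic_protospacer, character(1)),
    target_gene = target,
    is_ntc = target == "NTC"
  ))
}

# brute-force two-sided Mann-Whitney p by exhaustive label enumeration;
# U computed from pairwise comparisons, independent of the rank-based path
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(x, y)
  centre <- n1 * (n - n1) / 2
  sel <- utils::combn(n, n1)
  us <- apply(sel, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}

# brute-force two-sided Fisher p over the full hypergeometric support
fisher_enumeration_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# independent add-one empirical-FDR scan over an explicit cutoff grid
fdr_oracle <- function(gene_scores, quasi_scores, q) {
  n_genes <- length(gene_scores)
  n_quasi <- length(quasi_scores)
  scan_tail <- function(g, qs) {
    best <- Inf
    for (c0 in sort(g[g > 0], decreasing = TRUE)) {
      est <- ((1 + sum(qs >= c0)) / n_quasi * n_genes) / sum(g >= c0)
      if (est <= q * (1 + 1e-9)) best <- c0
    }
    best
  }
  list(pos = scan_tail(gene_scores, quasi_scores),
       neg = -scan_tail(-gene_scores, -quasi_scores))
}
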