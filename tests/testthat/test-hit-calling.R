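make_counts <- function(manifest, a, b) {
  as_screen_counts(tibble::tibble(sgrna_id = manifest$sgrna_id,
                                  s_a = as.integer(a), s_b = as.integer(b)),
                   manifest = manifest)
}

test_that("phenotypes are zero for identical samples and NTC-centered", {
  m <- tiny_manifest(n_genes = 2, sgrnas_per_gene = 2, n_ntc = 3)
  cnt <- make_counts(m, c(10, 20, 30, 40, 50, 60, 70), c(10, 20, 30, 40, 50, 60, 70))
  ph <- compute_sgrna_phenotypes(cnt, m, "s_a", "s_b", pseudocount = 1)
  expect_equal(ph$phenotype, rep(0, 7))
  expect_equal(median(ph$phenotype[ph$is_ntc]), 0)
})

test_that("phenotype arithmetic matches direct hand evaluation", {
  # 1 targeting sgRNA 100 -> 400, 3 NTCs flat at 100, pseudocount 1
  m <- tiny_manifest(n_genes = 1, sgrnas_per_gene = 1, n_ntc = 3)
  cnt <- make_counts(m, rep(100, 4), c(400, 100, 100, 100))
  ph <- compute_sgrna_phenotypes(cnt, m, "s_a", "s_b")
  raw_t <- log2((401 / 700) * (400 / 101))
  raw_n <- log2((101 / 700) * (400 / 101))
  expect_equal(ph$phenotype[1], raw_t - raw_n)
  expect_equal(ph$phenotype[1], 1.989, tolerance = 1e-3)
  expect_equal(ph$phenotype[ph$is_ntc], rep(0, 3))
})

test_that("phenotypes are invariant to per-sample depth scaling", {
  m <- tiny_manifest(n_genes = 3, sgrnas_per_gene = 2, n_ntc = 4)
  set.seed(1)
  a <- rpois(10, 200); b <- rpois(10, 200)
  ph1 <- compute_sgrna_phenotypes(make_counts(m, a, b), m, "s_a", "s_b",
                                  pseudocount = 1e-6)
  ph2 <- compute_sgrna_phenotypes(make_counts(m, a, b * 10L), m, "s_a", "s_b",
                                  pseudocount = 1e-6)
  expect_equal(ph1$phenotype, ph2$phenotype, tolerance = 1e-4)
})

test_that("phenotype computation validates its inputs", {
  m <- tiny_manifest()
  cnt <- make_counts(m, rep(10, 7), rep(10, 7))
  expect_error(compute_sgrna_phenotypes(cnt, m, "s_a", "nope"), "not in counts")
  no_ntc <- as_sgrna_manifest(dplyr::mutate(tibble::as_tibble(m),
                                            is_ntc = FALSE,
                                            target_gene = "G1"))
  expect_error(compute_sgrna_phenotypes(cnt, no_ntc, "s_a", "s_b"), "NTC")
  expect_error(compute_sgrna_phenotypes(cnt, m, "s_a", "s_b", pseudocount = 0),
               "pseudocount")
})

test_that("Mann-Whitney p agrees with exhaustive enumeration on small groups", {
  # fully separated 3 vs 3: U = 0, exact two-sided p = 2/20
  expect_equal(gene_pvalue_mannwhitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mw_enumeration_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical multisets carry no evidence
  expect_equal(gene_pvalue_mannwhitney(c(2, 4, 9), c(2, 4, 9)), 1)
  # grid of tie-free cases: implementation equals the permutation oracle
  set.seed(7)
  for (n1 in 1:5) {
    for (n2 in c(5, 10, 20)) {
      x <- rnorm(n1); y <- rnorm(n2)
      expect_equal(gene_pvalue_mannwhitney(x, y), mw_enumeration_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("p-values against a large control group match Monte-Carlo permutation", {
  set.seed(11)
  x <- rnorm(5, mean = 0.3)
  y <- rnorm(500)
  p_impl <- gene_pvalue_mannwhitney(x, y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[1:5]) - 15
  centre <- 5 * 500 / 2
  n_perm <- 1e5
  set.seed(12)
  us <- vapply(seq_len(n_perm), function(i) {
    sum(rk[sample.int(505, 5)]) - 15
  }, numeric(1))
  p_mc <- mean(abs(us - centre) >= abs(u_obs - centre))
  expect_lt(abs(p_impl - p_mc), 0.01)
})

test_that("quasi-gene sampling is with replacement, seeded, NTC-only", {
  m <- tiny_manifest(n_genes = 4, sgrnas_per_gene = 2, n_ntc = 6)
  q <- make_quasi_genes(m, seed = 2)
  expect_equal(nrow(q), 8 * 5)  # default 2x genes, groups of five
  expect_true(all(table(q$quasi_gene) == 5))
  ntc_ids <- m$sgrna_id[m$is_ntc]
  expect_true(all(q$sgrna_id %in% ntc_ids))
  expect_identical(q, make_quasi_genes(m, seed = 2))
  expect_false(identical(q$sgrna_id, make_quasi_genes(m, seed = 3)$sgrna_id))

  one <- tiny_manifest(n_genes = 1, sgrnas_per_gene = 2, n_ntc = 1)
  q1 <- make_quasi_genes(one, n_groups = 3)
  expect_true(all(q1$sgrna_id == one$sgrna_id[one$is_ntc]))

  no_ntc <- as_sgrna_manifest(dplyr::mutate(tibble::as_tibble(m),
                                            is_ntc = FALSE, target_gene = "G"))
  expect_error(make_quasi_genes(no_ntc), "no NTC")
})

test_that("standardization centers at the quasi median and scales by quasi sd", {
  q <- c(0.1, 0.2, 0.3)
  expect_equal(standardize_phenotypes(0.5, q), (0.5 - 0.2) / sd(q))
  expect_equal(standardize_phenotypes(0.5, q), 3, tolerance = 1e-12)
  expect_equal(standardize_phenotypes(0.2, q), 0)
  z <- standardize_phenotypes(q, q)
  expect_equal(median(z), 0)
  expect_equal(sd(z), 1)
  expect_error(standardize_phenotypes(1, c(0.2, 0.2)), "zero standard deviation")
})

test_that("empirical-FDR scan matches an independent cutoff-grid oracle", {
  set.seed(5)
  for (i in 1:20) {
    genes <- rnorm(40, sd = 2)
    quasi <- rnorm(80)
    thr <- empirical_fdr_threshold(genes, quasi, fdr_target = 0.1)
    oracle <- fdr_oracle(genes, quasi, 0.1)
    expect_equal(thr$pos_cutoff, oracle$pos)
    expect_equal(thr$neg_cutoff, oracle$neg)
    expect_equal(thr$hit, genes >= oracle$pos | genes <= oracle$neg)
  }
  # spec toy: 3 genes vs 4 quasi-genes
  thr <- empirical_fdr_threshold(c(3.0, 2.5, 1.0), c(2.6, 0.2, 0.1, 0.0), 0.1)
  oracle <- fdr_oracle(c(3.0, 2.5, 1.0), c(2.6, 0.2, 0.1, 0.0), 0.1)
  expect_equal(thr$pos_cutoff, oracle$pos)
})

test_that("a well-separated null admits every gene as a hit", {
  # with the add-one correction the null mass must be comfortably outnumbered
  thr <- empirical_fdr_threshold(c(5, 4, 3), rep(0, 30), fdr_target = 0.1)
  expect_true(all(thr$hit))
  expect_equal(thr$pos_cutoff, 3)
  # too few quasi-genes: est_FDR = (1/4)*3/3 > 0.1, nothing is called
  thr2 <- empirical_fdr_threshold(c(5, 4, 3), rep(0, 4), fdr_target = 0.1)
  expect_false(any(thr2$hit))
})

test_that("call_hits composes the stages coherently", {
  sim <- simulate_survival_screen(sim_config(
    n_genes = 25, n_ntc = 40, depth = 5e5,
    gamma = c(rep(-1, 6), rep(0, 19)), efficacy = rep(1, 125), seed = 17))
  res <- call_hits(sim$counts, sim$manifest, "t0", "tF", seed = 17)
  real <- dplyr::filter(res, !is_quasi)
  expect_equal(nrow(real), 25)
  expect_equal(sum(res$is_quasi), 50)
  # Gene Score identity and sign coherence
  expect_equal(res$gene_score, res$phenotype_score * -log10(res$p_value))
  nz <- res$p_value < 1 & res$phenotype_score != 0
  expect_equal(sign(res$gene_score[nz]), sign(res$phenotype_score[nz]))
  expect_true(all(res$gene_score[res$p_value == 1] == 0))
  # quasi-genes are never biological hits
  expect_false(any(res$hit[res$is_quasi]))
  # the six engineered dropouts dominate the negative tail
  expect_true(all(sprintf("gene%04d", 1:6) %in%
                    real$gene[real$hit & real$direction == "negative"]))
})

test_that("call_hits is invariant to sgRNA row order", {
  sim <- simulate_survival_screen(sim_config(
    n_genes = 10, n_ntc = 20, depth = 2e5, seed = 23))
  res1 <- call_hits(sim$counts, sim$manifest, "t0", "tF", seed = 23)
  shuffled <- sim$counts[sample(nrow(sim$counts)), ]
  res2 <- call_hits(shuffled, sim$manifest, "t0", "tF", seed = 23)
  expect_equal(tidy(res1), tidy(res2))
})

test_that("tidy/glance/autoplot methods behave", {
  sim <- simulate_survival_screen(sim_config(
    n_genes = 10, n_ntc = 20, depth = 2e5, seed = 29))
  res <- call_hits(sim$counts, sim$manifest, "t0", "tF", seed = 29)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "gene_results"))
  g <- glance(res)
  expect_equal(g$n_genes, 10)
  expect_equal(g$n_quasi, 20)
  expect_equal(g$fdr_target, 0.1)
  expect_s3_class(autoplot(res), "ggplot")
})
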