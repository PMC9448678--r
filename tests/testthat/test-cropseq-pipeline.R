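umi_matrix <- function(rows, ids = paste0("sg", seq_len(ncol(rows)))) {
  colnames(rows) <- ids
  rownames(rows) <- sprintf("cell%03d", seq_len(nrow(rows)))
  rows
}

test_that("singlet assignment separates clean, ambiguous and empty cells", {
  pad <- function(...) c(..., rep(0, 20 - length(c(...))))  # library of 20
  m <- umi_matrix(rbind(
    pad(50),         # pure singlet
    pad(50, 48),     # two dominant guides
    pad(0),          # nothing
    pad(3),          # below min_umi
    pad(40, 1, 0, 1)))  # singlet over ambient
  res <- assign_sgrnas(m, z_cutoff = 3, min_umi = 5)
  expect_equal(res$reason,
               c("assigned", "ambiguous_multiple", "no_signal", "no_signal",
                 "assigned"))
  expect_equal(res$assigned_sgrna, c("sg1", NA, NA, NA, "sg1"))
  expect_error(assign_sgrnas(matrix(1, 2, 1)), ">= 2 sgRNA columns")
})

test_that("assignment is invariant to sgRNA column order", {
  set.seed(4)
  m <- umi_matrix(matrix(rpois(200 * 8, 0.3), nrow = 200) +
                    50 * diag(8)[sample(1:8, 200, replace = TRUE), ])
  r1 <- assign_sgrnas(m)
  perm <- sample(ncol(m))
  r2 <- assign_sgrnas(m[, perm])
  expect_equal(r1$assigned_sgrna, r2$assigned_sgrna)
  expect_equal(r1$reason, r2$reason)
})

test_that("assignment recovers simulated singlets and rejects multiplets", {
  sim <- simulate_cropseq(crop_sim_config(n_cells = 6000, seed = 33))
  res <- assign_sgrnas(sim$bundle)
  cells <- sim$bundle$cells
  singlet <- cells$true_n_integrations == 1
  multi <- cells$true_n_integrations >= 2
  expect_gt(sum(singlet), 100)
  acc <- mean(!is.na(res$assigned_sgrna[singlet]) &
                res$assigned_sgrna[singlet] == cells$true_sgrnas[singlet])
  expect_gte(acc, 0.95)
  expect_lte(mean(!is.na(res$assigned_sgrna[multi])), 0.05)
})

test_that("knockdown-cell selection keeps cells strictly below the median", {
  lib <- tiny_manifest(n_genes = 1, sgrnas_per_gene = 1, n_ntc = 2)
  expr <- matrix(c(0, 1, 2, 3), ncol = 1,
                 dimnames = list(sprintf("cell%03d", 1:4), "G1"))
  # equal totals per cell so log1p-CPM preserves the ordering
  expr <- cbind(expr, HK = 10 - expr[, 1])
  sg <- umi_matrix(cbind(rep(50, 4), 0, 0), ids = lib$sgrna_id)
  cells <- tibble::tibble(cell_id = rownames(expr))
  bundle <- as_cell_bundle(expr, sg, cells)
  bundle <- add_assignment(bundle, assign_sgrnas(sg), lib)
  sel <- select_knockdown_cells(bundle, "G1")
  expect_equal(sort(sel), c("cell001", "cell002"))

  tie_expr <- expr; tie_expr[, "G1"] <- 5; tie_expr[, "HK"] <- 5
  b2 <- as_cell_bundle(tie_expr, sg, cells)
  b2 <- add_assignment(b2, assign_sgrnas(sg), lib)
  expect_length(select_knockdown_cells(b2, "G1"), 0)

  expect_warning(out <- select_knockdown_cells(bundle, "HK"), "no cells assigned")
  expect_length(out, 0)
})

test_that("selected knockdown cells express less target than unselected", {
  lib <- build_cropseq_manifest(genes = "TG1", single_sgrna_gene = NULL)
  sim <- simulate_cropseq(crop_sim_config(n_cells = 5000, moi = 0.14,
                                          knockdown_strength = 0.8,
                                          occupancy_effects = list(),
                                          seed = 41), lib)
  bundle <- add_assignment(sim$bundle, assign_sgrnas(sim$bundle), lib)
  sel <- select_knockdown_cells(bundle, "TG1")
  pop <- bundle$cells$cell_id[!is.na(bundle$cells$assigned_gene) &
                                bundle$cells$assigned_gene == "TG1"]
  expect_gt(length(sel), 10)
  norm <- normalize_log_cpm(bundle$expr)
  expect_lt(mean(norm[sel, "TG1"]), mean(norm[setdiff(pop, sel), "TG1"]))
})

test_that("differential expression finds a spiked gene and is null-quiet", {
  set.seed(55)
  n <- 200
  genes <- c("TGT", paste0("bg", 1:100))
  mu <- rep(20, length(genes))
  expr_kd <- sapply(mu, function(m) rpois(n, m))
  expr_nt <- sapply(mu, function(m) rpois(n, m))
  expr_kd[, 1] <- rpois(n, mu[1] / 5)  # 5-fold suppression in knockdown cells
  expr <- rbind(expr_kd, expr_nt)
  colnames(expr) <- genes
  cells <- tibble::tibble(cell_id = sprintf("c%04d", seq_len(2 * n)))
  rownames(expr) <- cells$cell_id
  sg <- matrix(rep(c(50, 0, 0, 50), each = n), ncol = 2,
               dimnames = list(cells$cell_id, c("sgA", "sgB")))
  bundle <- as_cell_bundle(expr, sg, cells)
  kd <- cells$cell_id[1:n]
  nt <- cells$cell_id[(n + 1):(2 * n)]
  deg <- knockdown_deg(bundle, kd, nt, target_gene = "TGT")
  spiked <- deg[deg$gene == "TGT", ]
  expect_true(spiked$significant)
  expect_lt(spiked$effect, 0)
  expect_true(all(deg$p_adj >= deg$p))
  # everything else is drawn from one distribution: Bonferroni keeps it quiet
  expect_lte(sum(deg$significant[deg$gene != "TGT"]), 1)

  kd_null <- sample(nt, 100)
  null_deg <- knockdown_deg(bundle, kd_null, setdiff(nt, kd_null))
  expect_lte(mean(null_deg$significant), 0.02)
})

test_that("top-DEG summary excludes targets at or below the cell floor", {
  lib <- tiny_manifest(n_genes = 2, sgrnas_per_gene = 1, n_ntc = 2)
  # G1: 120 assigned cells (60 below median); G2: 80 (40 below median <= 50)
  n1 <- 120; n2 <- 80; nn <- 100
  n <- n1 + n2 + nn
  cells <- tibble::tibble(cell_id = sprintf("c%04d", seq_len(n)))
  set.seed(66)
  expr <- cbind(G1 = rpois(n, 30), G2 = rpois(n, 30),
                bg1 = rpois(n, 50), bg2 = rpois(n, 50))
  rownames(expr) <- cells$cell_id
  sg <- matrix(0, n, 4, dimnames = list(cells$cell_id, lib$sgrna_id))
  sg[1:n1, 1] <- 50
  sg[(n1 + 1):(n1 + n2), 2] <- 50
  sg[(n1 + n2 + 1):n, 3] <- 50
  bundle <- as_cell_bundle(expr, sg, cells)
  bundle <- add_assignment(bundle, assign_sgrnas(sg), lib)
  out <- cropseq_deg_screen(bundle, lib, min_kd_cells = 50, n_top = 20)
  expect_setequal(unique(out$deg$target_gene), c("G1", "G2"))
  expect_equal(unique(out$top$target_gene), "G1")
  expect_equal(unname(out$kd_cells["G1"]), 60L)
  expect_equal(unname(out$kd_cells["G2"]), 40L)
  expect_lte(max(table(out$top$target_gene)), 20)
})

test_that("cluster occupancy normalizes proportions to the NTC reference", {
  lib <- tiny_manifest(n_genes = 1, sgrnas_per_gene = 1, n_ntc = 1)
  n_g <- 10; n_n <- 10
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:(n_g + n_n)),
    assigned_gene = rep(c("G1", "NTC"), c(n_g, n_n)),
    assigned_sgrna = rep(c("G1_sg1", "ntc1"), c(n_g, n_n)),
    cluster_label = c(rep("A", 8), rep("B", 2), rep("A", 5), rep("B", 5)))
  expr <- matrix(1, n_g + n_n, 1, dimnames = list(cells$cell_id, "G1"))
  sg <- matrix(1, n_g + n_n, 2,
               dimnames = list(cells$cell_id, c("G1_sg1", "ntc1")))
  bundle <- as_cell_bundle(expr, sg, cells)
  occ <- cluster_occupancy(bundle)
  expect_equal(occ$rel_prop[occ$group == "NTC"], c(1, 1))
  expect_equal(occ$rel_prop[occ$group == "G1" & occ$cluster == "A"],
               (8 / 10) / (5 / 10))
  # cell-count bookkeeping: cluster counts sum to the group total
  sums <- dplyr::count(occ, group, wt = n_cells)
  expect_equal(sums$n, c(10L, 10L))

  # identical composition: row of ones
  cells2 <- dplyr::mutate(cells,
                          cluster_label = rep(c("A", "B"), n_g + n_n)[1:(n_g + n_n)])
  occ2 <- cluster_occupancy(as_cell_bundle(expr, sg, cells2))
  expect_true(all(occ2$rel_prop == 1))

  # a cluster with no NTC cells is NA, not zero
  cells3 <- cells
  cells3$cluster_label[1] <- "C"
  occ3 <- cluster_occupancy(as_cell_bundle(expr, sg, cells3))
  expect_true(is.na(occ3$rel_prop[occ3$group == "G1" & occ3$cluster == "C"]))

  cells4 <- dplyr::mutate(cells, assigned_gene = "G1")
  expect_error(cluster_occupancy(as_cell_bundle(expr, sg, cells4)), "no NTC")
})

test_that("simulated occupancy shifts are recovered end-to-end", {
  sim <- simulate_cropseq(crop_sim_config(n_cells = 10000, seed = 77))
  lib <- sim$manifest
  bundle <- add_assignment(sim$bundle, assign_sgrnas(sim$bundle), lib)
  occ <- cluster_occupancy(bundle)
  up <- sim$truth_occupancy[sim$truth_occupancy$multiplier > 1, ]
  got <- occ$rel_prop[occ$group == up$gene[1] & occ$cluster == up$cluster[1]]
  expect_gt(got, 1)
})

test_that("Fisher state-proportion test matches hypergeometric enumeration", {
  bal <- state_proportion_test(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(bal$p_value, 1)
  expect_equal(bal$odds_ratio, 1)

  m <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  expect_equal(state_proportion_test(m)$p_value, fisher_enumeration_p(m))

  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    while (sum(tab) > 60) tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(state_proportion_test(tab)$p_value,
                 fisher_enumeration_p(tab), tolerance = 1e-9)
    # simultaneous row and column swap leaves the p-value unchanged
    swapped <- tab[2:1, 2:1]
    expect_equal(state_proportion_test(swapped)$p_value,
                 state_proportion_test(tab)$p_value)
  }
  expect_error(state_proportion_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "empty margin")
})
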