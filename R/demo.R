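#' Run an end-to-end simulate-analyze-report demonstration
#'
#' Generates a synthetic dataset in the requested mode, runs the matching
#' analysis, and writes result tables, a JSON run manifest (parameters and
#' seed) and a plain-text report to `out_dir`. For the screen modes the
#' report compares hit calls against the simulation ground truth
#' (sensitivity and realized false-discovery proportion); for CROP-seq it
#' reports assignment rates and the recovered occupancy shifts.
#'
#' @param mode `"survival"`, `"facs"` or `"cropseq"`.
#' @param seed Master seed (default 1).
#' @param out_dir Output directory (created if missing).
#' @param n_genes,n_ntc,depth Screen-mode scaling knobs (defaults 100 genes,
#'   100 NTCs, 1e6 reads: a desk-scale screen).
#' @param n_cells CROP-seq mode size (default 5000).
#' @param fdr_target Hit-calling FDR target (default 0.1).
#' @return Invisibly, a list with the result objects and the report path.
#' @export
run_demo <- function(mode = c("survival", "facs", "cropseq"), seed = 1L,
                     out_dir = ".", n_genes = 100, n_ntc = 100, depth = 1e6,
                     n_cells = 5000, fdr_target = 0.1) {
  mode <- match.arg(mode)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- c(sprintf("screenforge demo: mode=%s seed=%d", mode, seed))
  manifest_json <- list(mode = mode, seed = seed, fdr_target = fdr_target)

  if (mode %in% c("survival", "facs")) {
    cfg <- sim_config(n_genes = n_genes, n_ntc = n_ntc, depth = depth,
                      fraction_hits = 0.1, effect_size = 1, seed = seed)
    sim <- if (mode == "survival") simulate_survival_screen(cfg) else
      simulate_facs_screen(cfg)
    samples <- setdiff(names(sim$counts), "sgrna_id")
    res <- call_hits(sim$counts, sim$manifest, samples[1], samples[2],
                     fdr_target = fdr_target, seed = seed)
    write_counts_table(sim$counts, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(sim$truth_genes, file.path(out_dir, "truth_genes.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(res), file.path(out_dir, "gene_results.tsv"),
                     progress = FALSE)
    truth_col <- names(sim$truth_genes)[2]
    called <- res$gene[!res$is_quasi & res$hit]
    true_hits <- sim$truth_genes$gene[sim$truth_genes$is_hit]
    sens <- if (length(true_hits)) mean(true_hits %in% called) else NA_real_
    fdp <- if (length(called)) mean(!called %in% true_hits) else 0
    g <- glance(res)
    report <- c(report,
      sprintf("library: %d genes x %d sgRNAs + %d NTCs; depth %g reads/sample",
              n_genes, cfg$sgrnas_per_gene, n_ntc, depth),
      sprintf("true hits (%s != 0): %d", truth_col, length(true_hits)),
      sprintf("called hits at FDR %.0f%%: %d (cutoffs %+.3f / %+.3f)",
              100 * fdr_target, g$n_hits, g$pos_cutoff, g$neg_cutoff),
      sprintf("sensitivity: %.3f", sens),
      sprintf("realized false-discovery proportion: %.3f", fdp))
    manifest_json$config <- cfg[c("n_genes", "sgrnas_per_gene", "n_ntc",
                                  "coverage", "doublings", "depth",
                                  "bin_fraction", "fraction_hits",
                                  "effect_size")]
    out <- list(sim = sim, results = res)
  } else {
    ccfg <- crop_sim_config(n_cells = n_cells, seed = seed)
    lib <- build_cropseq_manifest()
    sim <- simulate_cropseq(ccfg, lib)
    assignment <- assign_sgrnas(sim$bundle)
    bundle <- add_assignment(sim$bundle, assignment, lib)
    occ <- cluster_occupancy(bundle)
    write_cell_bundle(bundle, file.path(out_dir, "cropseq_bundle"))
    readr::write_tsv(assignment, file.path(out_dir, "assignment.tsv"),
                     progress = FALSE)
    readr::write_tsv(occupancy_matrix(occ),
                     file.path(out_dir, "occupancy.tsv"), progress = FALSE)
    rate <- mean(assignment$reason == "assigned")
    report <- c(report,
      sprintf("cells: %d; sgRNAs: %d; mean integrations/cell: %.3f",
              n_cells, nrow(lib), mean(bundle$cells$true_n_integrations)),
      sprintf("assigned singlets: %.1f%%", 100 * rate))
    if (nrow(sim$truth_occupancy) > 0) {
      for (r in seq_len(nrow(sim$truth_occupancy))) {
        tr <- sim$truth_occupancy[r, ]
        got <- occ$rel_prop[occ$group == tr$gene & occ$cluster == tr$cluster]
        report <- c(report, sprintf(
          "occupancy truth %s @ %s: %gx -> recovered rel. proportion %.2f",
          tr$gene, tr$cluster, tr$multiplier,
          if (length(got)) got else NA_real_))
      }
    }
    manifest_json$config <- ccfg[c("n_cells", "n_clusters", "moi",
                                   "ambient_rate", "knockdown_strength")]
    out <- list(sim = sim, assignment = assignment, occupancy = occ)
  }
  report_path <- file.path(out_dir, "report.txt")
  writeLines(report, report_path)
  jsonlite::write_json(manifest_json, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(paste(report, collapse = "\n"))
  invisible(c(out, list(report = report_path)))
}
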