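#' Configuration for pooled-screen simulation
#'
#' Bundles and validates every parameter of the survival and FACS
#' bin-sorting screen generators. Defaults mirror a druggable-genome-style
#' screen scaled to the stated experimental design: five sgRNAs per gene,
#' 500 non-targeting controls, 1,000 cells per library element at the start
#' of the screen, and 30% sorted tail bins.
#'
#' Gene effects can be given explicitly (`gamma` / `shift`, one value per
#' gene) or drawn from a sparse mixture: a fraction `fraction_hits` of genes
#' receives effect `effect_size` with a random sign (or a fixed sign via
#' `effect_sign`), the rest are exactly zero. NTC sgRNAs always have zero
#' effect. Per-sgRNA efficacy (the fraction of the gene effect an individual
#' guide realizes, reflecting variable knockdown strength between guides)
#' defaults to Beta(5, 1) draws: most guides strong, occasional weak ones.
#'
#' @param n_genes Number of targeted genes (default 2325).
#' @param sgrnas_per_gene sgRNAs per gene (default 5).
#' @param n_ntc Number of non-targeting control sgRNAs (default 500).
#' @param coverage Cells per library element seeded at t0 (default 1000).
#' @param doublings Population doublings between t0 and the final sample in
#'   survival mode (default 4).
#' @param gamma Optional explicit per-gene growth phenotype (log2 enrichment
#'   per doubling), length `n_genes`.
#' @param shift Optional explicit per-gene reporter displacement (log-scale),
#'   length `n_genes`; FACS mode.
#' @param fraction_hits,effect_size,effect_sign Mixture used when `gamma` /
#'   `shift` is not given: fraction of hit genes (default 0.1), absolute
#'   effect (default 1), and sign (`NULL` = random per hit, or -1 / 1).
#' @param efficacy Optional explicit per-sgRNA efficacy in \[0, 1\] for
#'   targeting sgRNAs (length `n_genes * sgrnas_per_gene`).
#' @param efficacy_shape Beta shape parameters for random efficacies
#'   (default c(5, 1)).
#' @param reporter_mu,reporter_sigma Location and scale of the per-cell
#'   log-reporter signal (defaults 0 and 1).
#' @param bin_fraction Sorted tail fraction per bin (default 0.30).
#' @param depth Sequencing reads per sample; default 500 reads per library
#'   element.
#' @param seed Master seed; stage substreams (ground truth, reporter,
#'   sequencing) are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2325, sgrnas_per_gene = 5, n_ntc = 500,
                       coverage = 1000, doublings = 4,
                       gamma = NULL, shift = NULL,
                       fraction_hits = 0.1, effect_size = 1, effect_sign = NULL,
                       efficacy = NULL, efficacy_shape = c(5, 1),
                       reporter_mu = 0, reporter_sigma = 1,
                       bin_fraction = 0.30,
                       depth = 500 * (n_genes * sgrnas_per_gene + n_ntc),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              sgrnas_per_gene = as.integer(sgrnas_per_gene),
              n_ntc = as.integer(n_ntc),
              coverage = coverage, doublings = doublings,
              gamma = gamma, shift = shift,
              fraction_hits = fraction_hits, effect_size = effect_size,
              effect_sign = effect_sign,
              efficacy = efficacy, efficacy_shape = efficacy_shape,
              reporter_mu = reporter_mu, reporter_sigma = reporter_sigma,
              bin_fraction = bin_fraction, depth = depth,
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$sgrnas_per_gene < 1) abort("need >= 1 gene and >= 1 sgRNA per gene")
  if (cfg$n_ntc < 2) abort("need at least 2 NTC sgRNAs")
  if (cfg$coverage < 1) abort("coverage must be >= 1")
  if (cfg$depth < 1) abort("depth must be >= 1")
  if (cfg$bin_fraction <= 0 || cfg$bin_fraction >= 0.5) abort("bin_fraction must be in (0, 0.5)")
  if (!is.null(gamma) && length(gamma) != cfg$n_genes) abort("gamma must have one value per gene")
  if (!is.null(shift) && length(shift) != cfg$n_genes) abort("shift must have one value per gene")
  if (!is.null(efficacy)) {
    if (length(efficacy) != cfg$n_genes * cfg$sgrnas_per_gene) {
      abort("efficacy must have one value per targeting sgRNA")
    }
    if (any(efficacy < 0 | efficacy > 1)) abort("efficacy must lie in [0, 1]")
  }
  if (cfg$fraction_hits < 0 || cfg$fraction_hits > 1) abort("fraction_hits must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

# library manifest for a simulated screen
build_screen_manifest <- function(n_genes, sgrnas_per_gene, n_ntc) {
  genes <- sprintf("gene%04d", seq_len(n_genes))
  gene_col <- rep(genes, each = sgrnas_per_gene)
  ids <- c(paste0(gene_col, "_sg", rep(seq_len(sgrnas_per_gene), n_genes)),
           sprintf("NTC_sg%03d", seq_len(n_ntc)))
  target <- c(gene_col, rep("NTC", n_ntc))
  as_sgrna_manifest(tibble(
    sgrna_id = ids,
    protospacer = vapply(seq_along(ids), synthetic_protospacer, character(1)),
    target_gene = target,
    is_ntc = target == "NTC"
  ), name = "simulated_screen_library")
}

# draw per-gene effects and per-sgRNA efficacies for one simulated screen
draw_screen_truth <- function(cfg, effect_field) {
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  effect <- cfg[[effect_field]]
  if (is.null(effect)) {
    effect <- numeric(cfg$n_genes)
    n_hits <- round(cfg$fraction_hits * cfg$n_genes)
    if (n_hits > 0) {
      hit_idx <- sample.int(cfg$n_genes, n_hits)
      signs <- if (is.null(cfg$effect_sign)) {
        sample(c(-1, 1), n_hits, replace = TRUE)
      } else rep(cfg$effect_sign, n_hits)
      effect[hit_idx] <- signs * cfg$effect_size
    }
  }
  n_target <- cfg$n_genes * cfg$sgrnas_per_gene
  eff <- cfg$efficacy %||%
    rbeta(n_target, cfg$efficacy_shape[1], cfg$efficacy_shape[2])
  truth_genes <- tibble(gene = genes, effect = effect, is_hit = effect != 0)
  names(truth_genes)[2] <- effect_field
  truth_sgrnas <- tibble(
    sgrna_id = c(paste0(rep(genes, each = cfg$sgrnas_per_gene), "_sg",
                        rep(seq_len(cfg$sgrnas_per_gene), cfg$n_genes)),
                 sprintf("NTC_sg%03d", seq_len(cfg$n_ntc))),
    gene = c(rep(genes, each = cfg$sgrnas_per_gene), rep("NTC", cfg$n_ntc)),
    efficacy = c(eff, rep(0, cfg$n_ntc)),
    effect = c(rep(effect, each = cfg$sgrnas_per_gene), rep(0, cfg$n_ntc))
  )
  names(truth_sgrnas)[4] <- paste0("gene_", effect_field)
  list(genes = truth_genes, sgrnas = truth_sgrnas, efficacy = c(eff, rep(0, cfg$n_ntc)))
}

#' Simulate a survival / proliferation screen
#'
#' Every library element starts at `coverage` cells. Over `doublings`
#' population doublings a cell carrying sgRNA i grows as
#' `2^(doublings * (1 + efficacy_i * gamma_g(i)))`, so a gene with gamma = -1
#' and a fully active guide fails to expand while the background doubles
#' `doublings` times. Sequencing of each sample is multinomial at `depth`
#' reads over abundance-proportional frequencies, so per-sample counts sum to
#' `depth` exactly. NTC sgRNAs have gamma = 0 by construction.
#'
#' @param config A [sim_config()].
#' @return A list of class `screen_sim` with elements `counts`
#'   (`screen_counts` with samples `t0`, `tF`), `manifest`, `truth_genes`,
#'   `truth_sgrnas`, and `config`.
#' @export
#' @examples
#' sim <- simulate_survival_screen(sim_config(n_genes = 20, n_ntc = 20,
#'                                            depth = 1e5, seed = 7))
#' sim$counts
simulate_survival_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ss <- substream_seeds(config$seed, 3)
  manifest <- build_screen_manifest(config$n_genes, config$sgrnas_per_gene,
                                    config$n_ntc)
  truth <- with_preserved_seed({
    set.seed(ss[1])
    draw_screen_truth(config, "gamma")
  })
  gene_gamma <- rep(truth$genes$gamma, each = config$sgrnas_per_gene)
  eff_target <- truth$efficacy[seq_along(gene_gamma)]
  rate <- config$doublings *
    (1 + c(eff_target * gene_gamma, rep(0, config$n_ntc)))
  abundance_t0 <- rep(config$coverage, nrow(manifest))
  abundance_tf <- abundance_t0 * 2^rate
  counts <- with_preserved_seed({
    set.seed(ss[3])
    tibble(
      sgrna_id = manifest$sgrna_id,
      t0 = as.integer(rmultinom(1, config$depth, abundance_t0)[, 1]),
      tF = as.integer(rmultinom(1, config$depth, abundance_tf)[, 1])
    )
  })
  structure(list(counts = as_screen_counts(counts, manifest),
                 manifest = manifest,
                 truth_genes = truth$genes, truth_sgrnas = truth$sgrnas,
                 abundance = tibble(sgrna_id = manifest$sgrna_id,
                                    t0 = abundance_t0, tF = abundance_tf),
                 config = config),
            class = "screen_sim")
}

#' Simulate a FACS bin-sorting screen
#'
#' Each of the `coverage * n_elements` cells carries one sgRNA and draws a
#' log-normal reporter signal whose log-scale location is
#' `reporter_mu + efficacy_i * shift_g(i)`. Cells are ranked by reporter
#' value (ties broken by cell index) and the bottom and top
#' `floor(bin_fraction * n_cells)` cells form the low and high bins — the
#' bottom/top 30% sorting gates at the defaults. Per-bin sgRNA tallies are
#' converted to reads multinomially at `depth` reads per bin.
#'
#' @inheritParams simulate_survival_screen
#' @return A list of class `screen_sim` with `counts` (samples `low_bin`,
#'   `high_bin`), `manifest`, `truth_genes` (column `shift`), `truth_sgrnas`,
#'   `bin_cells` (cells per bin), and `config`.
#' @export
simulate_facs_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ss <- substream_seeds(config$seed, 3)
  manifest <- build_screen_manifest(config$n_genes, config$sgrnas_per_gene,
                                    config$n_ntc)
  truth <- with_preserved_seed({
    set.seed(ss[1])
    draw_screen_truth(config, "shift")
  })
  n_elem <- nrow(manifest)
  gene_shift <- c(rep(truth$genes$shift, each = config$sgrnas_per_gene),
                  rep(0, config$n_ntc))
  mu_elem <- config$reporter_mu + truth$efficacy * gene_shift
  n_per_elem <- as.integer(round(config$coverage))
  cell_elem <- rep(seq_len(n_elem), each = n_per_elem)
  n_cells <- length(cell_elem)
  reporter <- with_preserved_seed({
    set.seed(ss[2])
    rnorm(n_cells, mean = mu_elem[cell_elem], sd = config$reporter_sigma)
  })
  k <- floor(config$bin_fraction * n_cells)
  if (k < 1) abort("bin_fraction * n_cells < 1; no cells to sort")
  ord <- order(reporter)  # stable: ties keep cell-index order
  low_cells <- ord[seq_len(k)]
  high_cells <- ord[seq(n_cells - k + 1L, n_cells)]
  low_tally <- tabulate(cell_elem[low_cells], nbins = n_elem)
  high_tally <- tabulate(cell_elem[high_cells], nbins = n_elem)
  counts <- with_preserved_seed({
    set.seed(ss[3])
    tibble(
      sgrna_id = manifest$sgrna_id,
      low_bin = as.integer(rmultinom(1, config$depth, low_tally)[, 1]),
      high_bin = as.integer(rmultinom(1, config$depth, high_tally)[, 1])
    )
  })
  structure(list(counts = as_screen_counts(counts, manifest),
                 manifest = manifest,
                 truth_genes = truth$genes, truth_sgrnas = truth$sgrnas,
                 bin_cells = k, config = config),
            class = "screen_sim")
}
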