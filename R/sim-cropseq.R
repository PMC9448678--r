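#' Configuration for CROP-seq simulation
#'
#' Parameters of the single-cell perturbation generator. Cells acquire
#' lentiviral sgRNA integrations at low multiplicity of infection
#' (Poisson-distributed, default expected 0.10 integrations per cell, kept
#' below the 0.15 design bound so most infected cells are singlets), adopt a
#' transcriptional cluster whose probability can be reweighted by the
#' perturbation they carry, and emit Poisson UMI counts: a cluster-marker
#' expression program, target-gene suppression in carrier cells, and an
#' sgRNA capture signal on top of a uniform ambient background.
#'
#' @param n_cells Number of cells (default 10000).
#' @param n_clusters Number of transcriptional clusters (default 9).
#' @param cluster_props Base cluster proportions (length `n_clusters`,
#'   summing to 1). Default: a gently decreasing mix.
#' @param markers Tibble with columns `cluster`, `gene`, `fold`: one
#'   distinctive high-expression marker per cluster. Defaults ship a toy
#'   nine-state microglia-flavoured panel (SPP1-like disease-associated,
#'   CCL13-like chemokine, interferon, proliferative, ... states).
#' @param moi Expected integrations per cell (default 0.10; must be < 0.15).
#' @param ambient_rate Expected background UMIs per cell per sgRNA
#'   (default 0.2).
#' @param sgrna_signal Expected captured UMIs per true integration
#'   (default 40).
#' @param knockdown_strength Fractional suppression of a target gene's mean
#'   in cells carrying its sgRNA, in \[0, 1\] (default 0.8).
#' @param occupancy_effects Named list: target gene -> named numeric vector
#'   of multiplicative cluster-probability reweights. `NULL` (default)
#'   assigns a 3x enrichment of the first target gene in cluster `c1` and a
#'   0.3x depletion of the second in cluster `c2` at simulation time, so the
#'   default dataset carries recoverable occupancy shifts.
#' @param target_mean Baseline mean UMIs of each target gene (default 10).
#' @param marker_base_mean Baseline mean of marker genes outside their
#'   cluster (default 5).
#' @param n_housekeeping,housekeeping_mean Background gene panel
#'   (default 20 genes at mean 75), setting overall library size near 2,000
#'   UMIs per cell.
#' @param seed Master seed.
#' @return A validated list of class `crop_sim_config`.
#' @export
crop_sim_config <- function(n_cells = 10000, n_clusters = 9,
                            cluster_props = NULL, markers = NULL,
                            moi = 0.10, ambient_rate = 0.2, sgrna_signal = 40,
                            knockdown_strength = 0.8,
                            occupancy_effects = NULL,
                            target_mean = 10, marker_base_mean = 5,
                            n_housekeeping = 20, housekeeping_mean = 75,
                            seed = 1L) {
  if (is.null(cluster_props)) {
    w <- rev(seq_len(n_clusters)) + n_clusters / 3
    cluster_props <- w / sum(w)
  }
  if (length(cluster_props) != n_clusters) {
    abort("cluster_props must have one entry per cluster")
  }
  if (abs(sum(cluster_props) - 1) > 1e-8) abort("cluster_props must sum to 1")
  if (moi <= 0 || moi >= 0.15) abort("moi must be in (0, 0.15)")
  if (knockdown_strength < 0 || knockdown_strength > 1) {
    abort("knockdown_strength must be in [0, 1]")
  }
  if (ambient_rate < 0 || sgrna_signal <= 0) abort("invalid sgRNA capture rates")
  if (is.null(markers)) {
    panel <- c("SPP1", "CCL13", "ISG15", "MKI67", "CD74", "IL1B",
               "P2RY12", "APOE", "TMEM119", "CX3CR1", "TYROBP", "CTSB")
    markers <- tibble(
      cluster = paste0("c", seq_len(n_clusters)),
      gene = paste0(panel[((seq_len(n_clusters) - 1) %% length(panel)) + 1],
                    "_mk"),
      fold = 8
    )
  }
  structure(list(
    n_cells = as.integer(n_cells), n_clusters = as.integer(n_clusters),
    cluster_props = cluster_props, markers = as_tibble(markers),
    moi = moi, ambient_rate = ambient_rate, sgrna_signal = sgrna_signal,
    knockdown_strength = knockdown_strength,
    occupancy_effects = occupancy_effects,
    target_mean = target_mean, marker_base_mean = marker_base_mean,
    n_housekeeping = as.integer(n_housekeeping),
    housekeeping_mean = housekeeping_mean,
    seed = as.integer(seed)
  ), class = "crop_sim_config")
}

#' Simulate a CROP-seq experiment
#'
#' Generates a [as_cell_bundle()] with ground-truth columns. Per cell:
#' integration count ~ Poisson(moi); integrated sgRNAs uniform over the
#' library; the cluster is drawn from the base proportions, reweighted
#' multiplicatively by the carried gene's `occupancy_effects` (NTC and
#' uninfected cells use base proportions); expression UMIs are Poisson with
#' cluster-dependent marker means and the carried target gene's mean scaled
#' by `(1 - knockdown_strength)`; the sgRNA UMI matrix is a
#' Poisson(`sgrna_signal`) count on each integrated sgRNA plus
#' Poisson(`ambient_rate`) ambient background on every sgRNA.
#'
#' Truth columns in the metadata: `true_n_integrations`, `true_sgrnas`
#' (semicolon-joined), `true_gene` (first integration; `NA` if none) and
#' `cluster_label`. Multiply-infected cells are retained (truth-labelled) so
#' singlet filtering can be tested downstream.
#'
#' @param config A [crop_sim_config()].
#' @param manifest An `sgrna_manifest`, by default [build_cropseq_manifest()].
#' @return A list of class `cropseq_sim` with elements `bundle`
#'   (`cell_bundle`), `truth_occupancy` (tibble gene / cluster / multiplier),
#'   `manifest` and `config`.
#' @export
#' @examples
#' sim <- simulate_cropseq(crop_sim_config(n_cells = 500, seed = 3))
#' mean(sim$bundle$cells$true_n_integrations)
simulate_cropseq <- function(config, manifest = build_cropseq_manifest()) {
  stopifnot(inherits(config, "crop_sim_config"))
  validate_manifest(manifest)
  n_sgrna <- nrow(manifest)
  target_genes <- unique(manifest$target_gene[!manifest$is_ntc])
  clusters <- paste0("c", seq_len(config$n_clusters))
  if (!all(config$markers$cluster %in% clusters)) {
    abort("marker clusters must be among c1..cN")
  }
  effects <- config$occupancy_effects
  if (is.null(effects)) {
    effects <- list()
    if (length(target_genes) >= 1) effects[[target_genes[1]]] <- c(c1 = 3)
    if (length(target_genes) >= 2) effects[[target_genes[2]]] <- c(c2 = 0.3)
  }
  unknown <- setdiff(names(effects), target_genes)
  if (length(unknown) > 0) {
    abort(paste0("occupancy_effects name not a target gene: ",
                 paste(unknown, collapse = ", ")))
  }

  ss <- substream_seeds(config$seed, 4)
  n_cells <- config$n_cells

  # stage 1: integrations
  ints <- with_preserved_seed({
    set.seed(ss[1])
    k <- rpois(n_cells, config$moi)
    draws <- sample.int(n_sgrna, sum(k), replace = TRUE)
    list(k = k, draws = draws)
  })
  cell_of_draw <- rep(seq_len(n_cells), ints$k)
  first_draw <- ints$draws[!duplicated(cell_of_draw)]
  true_gene <- rep(NA_character_, n_cells)
  true_gene[unique(cell_of_draw)] <- manifest$target_gene[first_draw]

  # stage 2: cluster identities (reweighted for carriers of effect genes)
  cluster_idx <- with_preserved_seed({
    set.seed(ss[2])
    idx <- integer(n_cells)
    base_cells <- which(is.na(true_gene) | !(true_gene %in% names(effects)))
    idx[base_cells] <- sample.int(config$n_clusters, length(base_cells),
                                  replace = TRUE, prob = config$cluster_props)
    for (g in names(effects)) {
      gc <- which(!is.na(true_gene) & true_gene == g)
      if (length(gc) == 0) next
      w <- config$cluster_props
      mult <- effects[[g]]
      w[match(names(mult), clusters)] <- w[match(names(mult), clusters)] * mult
      idx[gc] <- sample.int(config$n_clusters, length(gc),
                            replace = TRUE, prob = w / sum(w))
    }
    idx
  })
  cluster_label <- clusters[cluster_idx]

  # stage 3: expression
  genes <- c(target_genes, config$markers$gene,
             sprintf("HK%02d", seq_len(config$n_housekeeping)))
  mu_cluster <- matrix(rep(c(rep(config$target_mean, length(target_genes)),
                             rep(config$marker_base_mean, nrow(config$markers)),
                             rep(config$housekeeping_mean, config$n_housekeeping)),
                           each = config$n_clusters),
                       nrow = config$n_clusters, dimnames = list(clusters, genes))
  for (r in seq_len(nrow(config$markers))) {
    mu_cluster[config$markers$cluster[r], config$markers$gene[r]] <-
      config$marker_base_mean * config$markers$fold[r]
  }
  lambda <- mu_cluster[cluster_idx, , drop = FALSE]
  carrier <- which(!is.na(true_gene) & true_gene %in% target_genes)
  if (length(carrier) > 0) {
    cols <- match(true_gene[carrier], genes)
    lambda[cbind(carrier, cols)] <- lambda[cbind(carrier, cols)] *
      (1 - config$knockdown_strength)
  }
  expr <- with_preserved_seed({
    set.seed(ss[3])
    matrix(rpois(length(lambda), lambda), nrow = n_cells,
           dimnames = list(NULL, genes))
  })

  # stage 4: sgRNA capture = signal on integrations + ambient background
  sgrna_umi <- with_preserved_seed({
    set.seed(ss[4])
    m <- matrix(rpois(n_cells * n_sgrna, config$ambient_rate), nrow = n_cells,
                dimnames = list(NULL, manifest$sgrna_id))
    if (length(ints$draws) > 0) {
      sig <- rpois(length(ints$draws), config$sgrna_signal)
      for (j in seq_along(ints$draws)) {
        m[cell_of_draw[j], ints$draws[j]] <- m[cell_of_draw[j], ints$draws[j]] + sig[j]
      }
    }
    m
  })

  true_sgrnas <- vapply(split(manifest$sgrna_id[ints$draws], factor(cell_of_draw, levels = seq_len(n_cells))),
                        paste, character(1), collapse = ";")
  cells <- tibble(
    cell_id = sprintf("cell%06d", seq_len(n_cells)),
    true_n_integrations = ints$k,
    true_sgrnas = unname(true_sgrnas),
    true_gene = true_gene,
    cluster_label = cluster_label,
    qc_keep = TRUE
  )
  truth_occupancy <- bind_rows(lapply(names(effects), function(g) {
    tibble(gene = g, cluster = names(effects[[g]]),
           multiplier = unname(effects[[g]]))
  }))
  structure(list(bundle = as_cell_bundle(expr, sgrna_umi, cells),
                 truth_occupancy = truth_occupancy,
                 manifest = manifest, config = config),
            class = "cropseq_sim")
}
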