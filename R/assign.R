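#' Assign a single sgRNA identity to each cell
#'
#' Singlet calling on the cell x sgRNA UMI matrix, on the log1p scale. For
#' each cell, the candidate is the sgRNA with the highest count; the
#' background is every other sgRNA of that cell. The candidate's z-statistic
#' is `(log1p(top) - mean(log1p(background))) / sd(log1p(background))` (with
#' a zero-variance background, z is `Inf` when the candidate exceeds the
#' background mean, else 0). The cell is assigned the top sgRNA when the top
#' passes both gates — raw count `>= min_umi` and `z >= z_cutoff` — and the
#' runner-up, tested the same way against the background excluding the two
#' leading sgRNAs, fails at least one of them. Cells whose top fails are
#' `no_signal`; cells where both leaders pass are `ambiguous_multiple`
#' (putative multiplets). The `min_umi` floor carries the ambient-background
#' filtering role: ambient contamination produces low, diffuse counts that
#' never clear it.
#'
#' @param sgrna_umi Cells x sgRNAs matrix (dense or sparse, >= 2 columns),
#'   or a `cell_bundle` (its `sgrna_umi` is used).
#' @param z_cutoff Minimum z-statistic (default 3).
#' @param min_umi Minimum raw UMI count of an assignable sgRNA (default 5).
#' @return A tibble of class `sgrna_assignment` with columns `cell_id`,
#'   `assigned_sgrna` (`NA` when unassigned), `reason` (`assigned`,
#'   `no_signal`, `ambiguous_multiple`) and `z_top`.
#' @export
assign_sgrnas <- function(sgrna_umi, z_cutoff = 3, min_umi = 5) {
  if (inherits(sgrna_umi, "cell_bundle")) sgrna_umi <- sgrna_umi$sgrna_umi
  m <- as.matrix(sgrna_umi)
  if (ncol(m) < 2) abort("need >= 2 sgRNA columns to define a background")
  if (any(m < 0)) abort("sgRNA UMI counts must be nonnegative")
  ids <- colnames(m) %||% paste0("sg", seq_len(ncol(m)))
  cell_ids <- rownames(m) %||% sprintf("cell%06d", seq_len(nrow(m)))
  lm <- log1p(m)

  n <- nrow(m)
  assigned <- rep(NA_character_, n)
  reason <- character(n)
  z_top_out <- numeric(n)
  zstat <- function(value, bg) {
    s <- sd(bg)
    if (!is.finite(s) || s == 0) {
      if (value > mean(bg)) Inf else 0
    } else (value - mean(bg)) / s
  }
  for (i in seq_len(n)) {
    row_raw <- m[i, ]
    row_log <- lm[i, ]
    ord <- order(row_log, decreasing = TRUE)
    top <- ord[1]; runner <- ord[2]
    z_top <- zstat(row_log[top], row_log[-top])
    z_run <- zstat(row_log[runner], row_log[-c(top, runner)])
    z_top_out[i] <- z_top
    top_pass <- row_raw[top] >= min_umi && z_top >= z_cutoff
    run_pass <- row_raw[runner] >= min_umi && z_run >= z_cutoff
    if (top_pass && !run_pass) {
      assigned[i] <- ids[top]
      reason[i] <- "assigned"
    } else if (top_pass && run_pass) {
      reason[i] <- "ambiguous_multiple"
    } else {
      reason[i] <- "no_signal"
    }
  }
  out <- tibble(cell_id = cell_ids, assigned_sgrna = assigned,
                reason = reason, z_top = z_top_out)
  class(out) <- c("sgrna_assignment", class(out))
  out
}

#' Attach assignment results to a cell bundle
#'
#' Joins an [assign_sgrnas()] result into the bundle metadata, adding
#' `assigned_sgrna` and `assigned_gene` (via the manifest; `"NTC"` for
#' control sgRNAs, `NA` when unassigned).
#'
#' @param bundle A `cell_bundle`.
#' @param assignment An `sgrna_assignment` tibble.
#' @param manifest The `sgrna_manifest` mapping sgRNAs to genes.
#' @return The bundle with augmented metadata.
#' @export
add_assignment <- function(bundle, assignment, manifest) {
  stopifnot(inherits(bundle, "cell_bundle"))
  m <- match(bundle$cells$cell_id, assignment$cell_id)
  if (anyNA(m)) abort("assignment is missing cells present in the bundle")
  bundle$cells$assigned_sgrna <- assignment$assigned_sgrna[m]
  bundle$cells$assignment_reason <- assignment$reason[m]
  bundle$cells$assigned_gene <-
    manifest$target_gene[match(bundle$cells$assigned_sgrna, manifest$sgrna_id)]
  bundle
}
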