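#' sgRNA library manifests
#'
#' An sgRNA library manifest is a tibble with one row per library element and
#' columns `sgrna_id` (unique), `protospacer` (DNA over A/C/G/T; may be empty
#' for synthetic libraries that are never matched against reads),
#' `target_gene`, and `is_ntc` (logical). Non-targeting control (NTC) sgRNAs
#' carry the reserved gene label `"NTC"`; they define the empirical null for
#' all downstream screen statistics, so at least two are required by the
#' hit-calling functions.
#'
#' @param x A data frame with columns `sgrna_id`, `protospacer`,
#'   `target_gene`, `is_ntc`.
#' @param name Optional library name, stored as the `"library_name"`
#'   attribute.
#' @return A validated manifest tibble of class `sgrna_manifest`.
#' @export
#' @examples
#' as_sgrna_manifest(tibble::tibble(
#'   sgrna_id = c("g1", "g2", "ntc1", "ntc2"),
#'   protospacer = c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT",
#'                   "GGGGACGTACGTACGTACGT", "CCCCACGTACGTACGTACGT"),
#'   target_gene = c("TREM2", "TREM2", "NTC", "NTC"),
#'   is_ntc = c(FALSE, FALSE, TRUE, TRUE)
#' ))
as_sgrna_manifest <- function(x, name = "library") {
  required <- c("sgrna_id", "protospacer", "target_gene", "is_ntc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(x)[required]
  out$sgrna_id <- as.character(out$sgrna_id)
  out$protospacer <- toupper(as.character(out$protospacer))
  out$target_gene <- as.character(out$target_gene)
  out$is_ntc <- as.logical(out$is_ntc)
  validate_manifest(out)
  attr(out, "library_name") <- name
  class(out) <- c("sgrna_manifest", class(out))
  out
}

validate_manifest <- function(x) {
  if (anyDuplicated(x$sgrna_id)) {
    dup <- unique(x$sgrna_id[duplicated(x$sgrna_id)])
    abort(paste0("duplicated sgrna_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(is.na(x$is_ntc))) abort("is_ntc must be TRUE or FALSE for every row")
  bad_gene <- !x$is_ntc & (is.na(x$target_gene) | x$target_gene == "")
  if (any(bad_gene)) {
    abort(paste0("non-NTC entries need a nonempty target_gene (rows ",
                 paste(head(which(bad_gene), 5), collapse = ", "), ")"))
  }
  if (any(x$is_ntc & x$target_gene != "NTC")) {
    abort("NTC entries must use the reserved gene label \"NTC\"")
  }
  bad_ps <- x$protospacer != "" & !grepl("^[ACGT]+$", x$protospacer)
  if (any(bad_ps)) {
    abort(paste0("protospacer must be over {A,C,G,T} (rows ",
                 paste(head(which(bad_ps), 5), collapse = ", "), ")"))
  }
  invisible(x)
}

#' Read or write an sgRNA library manifest (CSV)
#'
#' The manifest CSV dialect is UTF-8 with a header row and columns
#' `sgrna_id,protospacer,target_gene,is_ntc`; `is_ntc` is serialized as the
#' literals `true`/`false` (case-insensitive on read).
#'
#' @param path Path to a CSV file.
#' @return `read_library_manifest()` returns an `sgrna_manifest` tibble.
#' @export
read_library_manifest <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sgrna_id", "protospacer", "target_gene", "is_ntc")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest CSV ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  flag <- tolower(trimws(raw$is_ntc))
  bad <- !flag %in% c("true", "false")
  if (any(bad)) {
    abort(paste0("malformed is_ntc value on data line ",
                 which(bad)[1], " of ", path,
                 " (expected true/false, got \"", raw$is_ntc[which(bad)[1]], "\")"))
  }
  raw$is_ntc <- flag == "true"
  as_sgrna_manifest(raw, name = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_library_manifest
#' @param manifest An `sgrna_manifest`.
#' @export
write_library_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  out <- as_tibble(manifest)
  out$is_ntc <- ifelse(out$is_ntc, "true", "false")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Build a CROP-seq style sgRNA library manifest
#'
#' Constructs a compact pooled library of the shape used for CROP-seq
#' perturbation screens: two sgRNAs per targeted gene, except one designated
#' gene carried by a single sgRNA, plus a handful of non-targeting controls.
#' With the defaults (39 target genes, one single-sgRNA gene, 4 NTCs) the
#' library has 39 x 2 - 1 + 4 = 81 elements.
#'
#' Protospacers are deterministic 20-mers derived from the element index, so
#' a manifest built twice is identical; they are placeholders for simulation,
#' not real genomic targeting sequences.
#'
#' @param genes Character vector of target gene labels (default 39 synthetic
#'   labels `gene01`..`gene39`).
#' @param single_sgrna_gene A gene from `genes` that receives only one sgRNA,
#'   or `NULL` for none. Default: the last element of `genes`.
#' @param n_ntc Number of non-targeting control sgRNAs (default 4).
#' @return An `sgrna_manifest` tibble.
#' @export
#' @examples
#' nrow(build_cropseq_manifest())  # 81
build_cropseq_manifest <- function(genes = sprintf("gene%02d", 1:39),
                                   single_sgrna_gene = genes[length(genes)],
                                   n_ntc = 4) {
  genes <- as.character(genes)
  if (length(genes) < 1) abort("need at least one target gene")
  if (anyDuplicated(genes)) abort("target gene labels must be unique")
  if (!is.null(single_sgrna_gene) && !single_sgrna_gene %in% genes) {
    abort("single_sgrna_gene must be one of `genes`")
  }
  per_gene <- ifelse(genes %in% single_sgrna_gene, 1L, 2L)
  gene_col <- rep(genes, per_gene)
  idx <- unlist(lapply(per_gene, seq_len))
  ids <- c(paste0(gene_col, "_sg", idx), sprintf("NTC_sg%d", seq_len(n_ntc)))
  target <- c(gene_col, rep("NTC", n_ntc))
  as_sgrna_manifest(tibble(
    sgrna_id = ids,
    protospacer = vapply(seq_along(ids), synthetic_protospacer, character(1)),
    target_gene = target,
    is_ntc = target == "NTC"
  ), name = "cropseq_library")
}

# deterministic 20-mer from an integer index (base-4 expansion)
synthetic_protospacer <- function(i, len = 20L) {
  bases <- c("A", "C", "G", "T")
  # mix the index so neighbouring elements differ across the whole word
  v <- (i * 2654435761) %% (2^31)
  out <- character(len)
  for (k in seq_len(len)) {
    out[k] <- bases[((v %/% 65536) %% 4) + 1]  # bits 16-17: well mixed
    v <- (v * 69069 + 12345) %% (2^31)
  }
  paste(out, collapse = "")
}
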