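#' Screen count tables
#'
#' A screen count table is a tibble with one row per sgRNA: an `sgrna_id`
#' column followed by one nonnegative-integer column per sample. All
#' hit-calling statistics operate on such tables together with the matching
#' library manifest.
#'
#' @param x A data frame with an `sgrna_id` column and numeric sample columns.
#' @param manifest Optional `sgrna_manifest`; when supplied every `sgrna_id`
#'   must be present in it.
#' @return A validated tibble of class `screen_counts`.
#' @export
as_screen_counts <- function(x, manifest = NULL) {
  if (!"sgrna_id" %in% names(x)) abort("counts table needs an sgrna_id column")
  out <- as_tibble(x)
  out$sgrna_id <- as.character(out$sgrna_id)
  samples <- setdiff(names(out), "sgrna_id")
  if (length(samples) == 0) abort("counts table needs at least one sample column")
  for (s in samples) {
    v <- out[[s]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      abort(paste0("sample column \"", s, "\" must hold nonnegative integers"))
    }
    out[[s]] <- as.integer(round(v))
  }
  if (anyDuplicated(out$sgrna_id)) abort("duplicated sgrna_id in counts table")
  if (!is.null(manifest)) {
    unknown <- setdiff(out$sgrna_id, manifest$sgrna_id)
    if (length(unknown) > 0) {
      abort(paste0("sgrna_id not in manifest: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  class(out) <- c("screen_counts", setdiff(class(out), "screen_counts"))
  out
}

#' Read or write a screen count table (TSV)
#'
#' @param path Path to a tab-separated file with header `sgrna_id` plus one
#'   column per sample.
#' @inheritParams as_screen_counts
#' @return `read_counts_table()` returns a `screen_counts` tibble.
#' @export
read_counts_table <- function(path, manifest = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sgrna_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  as_screen_counts(raw, manifest = manifest)
}

#' @rdname read_counts_table
#' @param counts A `screen_counts` tibble.
#' @export
write_counts_table <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path, progress = FALSE)
  invisible(path)
}

#' Count exact protospacer matches in sequencing reads
#'
#' Tallies, for every library element, the number of reads whose trimmed
#' subsequence exactly equals the element's protospacer. This replaces
#' short-read alignment for screen counting: with a correct trim window and
#' error-free or high-quality reads, exact matching is deterministic and
#' recovers the same counts. Reads matching no protospacer are tallied under
#' the `"unmatched"` attribute. An optional mismatch-tolerant mode accepts a
#' single substitution when exactly one library element is within Hamming
#' distance 1 (ties go to unmatched); it is off by default.
#'
#' @param fastq Path to a FASTQ file (may be empty).
#' @param manifest An `sgrna_manifest` whose protospacers all share one length.
#' @param trim Integer vector `c(offset, length)`: 0-based offset into each
#'   read and the window length. Default: offset 0, length = protospacer
#'   length.
#' @param sample Name for the count column (default `"sample"`).
#' @param max_mismatch 0 (exact, default) or 1 (Hamming-1 rescue).
#' @return A `screen_counts` tibble with columns `sgrna_id` and `sample`,
#'   rows in manifest order, and attribute `unmatched` (integer).
#' @export
count_protospacers <- function(fastq, manifest, trim = NULL,
                               sample = "sample", max_mismatch = 0) {
  validate_manifest(manifest)
  ps <- manifest$protospacer
  if (any(ps == "")) abort("manifest has empty protospacers; cannot match reads")
  ps_len <- unique(nchar(ps))
  if (length(ps_len) != 1) abort("all protospacers must share one length")
  if (is.null(trim)) trim <- c(0L, ps_len)
  if (length(trim) != 2 || trim[1] < 0 || trim[2] < 1) {
    abort("trim must be c(offset >= 0, length >= 1)")
  }
  if (trim[2] != ps_len) {
    abort("trim length must equal the protospacer length")
  }
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  n_reads <- length(reads)
  counts <- integer(nrow(manifest))
  unmatched <- 0L
  if (n_reads > 0) {
    if (min(Biostrings::width(reads)) < trim[1] + trim[2]) {
      abort("trim window exceeds read length")
    }
    windows <- as.character(Biostrings::subseq(reads, start = trim[1] + 1L,
                                               width = trim[2]))
    hit <- match(windows, ps)
    if (max_mismatch >= 1 && anyNA(hit)) {
      miss <- which(is.na(hit))
      hit[miss] <- vapply(windows[miss], hamming1_match, integer(1), ps = ps)
    }
    tab <- tabulate(hit[!is.na(hit)], nbins = nrow(manifest))
    counts <- as.integer(tab)
    unmatched <- sum(is.na(hit))
  }
  out <- tibble(sgrna_id = manifest$sgrna_id, !!sample := counts)
  out <- as_screen_counts(out, manifest = manifest)
  attr(out, "unmatched") <- as.integer(unmatched)
  out
}

# index of the unique protospacer within Hamming distance 1, else NA
hamming1_match <- function(window, ps) {
  w <- strsplit(window, "")[[1]]
  d <- vapply(strsplit(ps, ""), function(p) sum(p != w), integer(1))
  ok <- which(d <= 1L)
  if (length(ok) == 1L) ok else NA_integer_
}

#' Write simulated reads for a known count vector
#'
#' Emits a FASTQ in which each library element's protospacer appears exactly
#' `counts` times (fixed quality), so that exact-match counting can be
#' checked against the generating counts.
#'
#' @param counts A `screen_counts` tibble with one sample column.
#' @param manifest The matching `sgrna_manifest`.
#' @param path Output FASTQ path.
#' @param shuffle_seed If non-NULL, shuffle read order reproducibly.
#' @return `path`, invisibly.
#' @export
write_simulated_fastq <- function(counts, manifest, path, shuffle_seed = NULL) {
  stopifnot(ncol(counts) == 2)
  m <- match(counts$sgrna_id, manifest$sgrna_id)
  seqs <- rep(manifest$protospacer[m], counts[[2]])
  if (!is.null(shuffle_seed) && length(seqs) > 1) {
    seqs <- with_preserved_seed({
      set.seed(shuffle_seed)
      sample(seqs)
    })
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read%06d", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}
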