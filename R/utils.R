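# internal helpers

# run code with its own RNG state, restoring the caller's afterwards
with_preserved_seed <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# derive n reproducible substream seeds (< 2^31) from one master seed, so
# simulator stages (abundance, reporter, sequencing) are individually
# reproducible
substream_seeds <- function(seed, n) {
  with_preserved_seed({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
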