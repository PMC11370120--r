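#' @keywords internal
"_PACKAGE"

# Run code under a local RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package route through this so that a
# caller-supplied seed gives bit-identical results without clobbering the
# global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive child seeds from a root seed (kept < 2^31). Used so that pipeline
# stages and CV replicates are independently reproducible.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(2147483646L, n)))
}

# Numeric chromosome key for deterministic (chromosome, position) ordering;
# non-numeric names sort after numeric ones, alphabetically.
chrom_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), 1e9 + as.numeric(factor(chrom)), num)
  key
}

`%||%` <- function(a, b) if (is.null(a)) b else a
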