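#' @importFrom rlang %||% abort warn inform
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All randomized operations in the package go
# through this helper so no function mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic per-task seed derived from a master seed; kept within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + as.double(index)) %% 2147483646) + 1L
}

# sample() without its scalar-x surprise
sample_vec <- function(x, size) {
  x[sample.int(length(x), size)]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
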