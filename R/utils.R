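#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a local RNG state seeded with `seed`; if `seed` is NULL the
# current global stream is used (and advanced). Keeps generators reproducible
# without touching the caller's .Random.seed when a seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed < 2^31 from a base seed and an index, so per-subject
# streams are independent but fully determined by one top-level seed.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

# Moving average by cumulative sums (O(n)); returns a vector the same length
# as x, edge windows truncated.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  if (w == 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
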