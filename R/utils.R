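# Internal helpers shared across modules.

# Deterministic fan-out of a single user seed into per-stage child seeds.
# Child seeds are plain 31-bit integers so they can be passed to set.seed()
# and recorded in output artifacts.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run an expression with a temporary RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(expr)
}

# Identities making up a morph pair name such as "ab" -> c("a", "b").
pair_identities <- function(morph_pair) {
  strsplit(as.character(morph_pair), "", fixed = TRUE)
}

# The identity of the experiment-2 set {a, b, c} not involved in a pair.
third_identity <- function(morph_pair, identities = c("a", "b", "c")) {
  vapply(pair_identities(morph_pair), function(p) setdiff(identities, p)[1L],
         character(1))
}

# Fisher z-transform with clamping so r = +/-1 stays finite.
fisher_z <- function(r, eps = 1e-12) {
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  atanh(r)
}

morph_levels_default <- c(0L, 17L, 33L, 50L, 67L, 83L, 100L)
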