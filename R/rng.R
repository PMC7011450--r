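# Deterministic seed substreams.
#
# All stochastic generators in the package draw from substreams derived from a
# single integer master seed and a string key. Components keyed per site (or
# per location block) therefore do not perturb each other's draws: adding a
# fifth site to a design leaves the values generated for the first four sites
# unchanged.

# 31-bit polynomial string hash (deterministic across platforms).
.hash_key <- function(key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647L
  h
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic substream derivation: the same (seed, key) pair always yields
#' the same child seed (below 2^31), so independent components can each be
#' seeded from one master seed without sharing a stream.
#'
#' @param seed integer master seed.
#' @param key string naming the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + .hash_key(as.character(key))) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded from (seed, key); the
# caller's RNG state is untouched.
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  expr
}

# Standard-normal draws from a keyed substream.
rnorm_stream <- function(seed, key, n) with_substream(seed, key, stats::rnorm(n))
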