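# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds: one independent-looking seed per purpose
# (instance, arrivals, extensions, search), all below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 11 * offset) %% 2147483629)
}

# sample() semantics without the scalar-x surprise
resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

# Per-day occupancy from stay windows [starts, ends], clipped to 1..horizon.
occupancy_from_windows <- function(starts, ends, horizon) {
  if (length(starts) == 0L) return(integer(horizon))
  s <- pmax(as.integer(starts), 1L)
  e <- pmin(as.integer(ends), horizon)
  keep <- s <= e & s <= horizon & e >= 1L
  s <- s[keep]
  e <- e[keep]
  if (length(s) == 0L) return(integer(horizon))
  cumsum(tabulate(s, nbins = horizon) -
           tabulate(e + 1L, nbins = horizon + 1L)[seq_len(horizon)])
}
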