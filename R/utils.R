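# Internal helpers shared across modules.

## Run `code` under a given seed, restoring the caller's RNG state afterwards
## so that package functions never clobber the user's random stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Counter-based derivation of independent sub-seeds from a single base seed.
## Distinct (stream, counter) pairs map to distinct seeds with overwhelming
## probability; the result stays inside the signed 32-bit range set.seed
## accepts.
derive_seed <- function(base_seed, stream, counter = 0L) {
  x <- (as.double(base_seed) %% 2147483647) + 1
  x <- (x * 48271 + as.double(stream) * 1299709) %% 2147483647
  x <- (x * 48271 + as.double(counter) * 15485863) %% 2147483647
  as.integer(x %% 2147483647)
}

check_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop("`", what, "` must be an integer >= ", min, "; got ", format(x),
         call. = FALSE)
  }
  as.integer(x)
}

check_unit_interval <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("`", what, "` must be a single number in [0, 1]; got ", format(x),
         call. = FALSE)
  }
  as.numeric(x)
}
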