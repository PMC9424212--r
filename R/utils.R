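# Internal helpers: seeded evaluation and deterministic child-seed derivation.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed from a root seed plus an index and a name.
# Polynomial string hash mod the Mersenne prime 2^31 - 1; all arithmetic
# stays below 2^52 so doubles carry it exactly.
deriveSeed <- function(root, index, name = "") {
  m <- 2147483647
  h <- (as.numeric(root) %% m)
  h <- (h * 31 + as.numeric(index)) %% m
  for (code in utf8ToInt(as.character(name)))
    h <- (h * 31 + code) %% m
  as.integer(h %% m)
}

.assertCount <- function(x, what, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", what, min),
         call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, what, lo = 0, hi = 1, open_hi = FALSE) {
  ok <- length(x) == 1L && !is.na(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must lie in [%g, %g%s", what, lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  as.numeric(x)
}

# Round half away from zero (R's round() halves to even).
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
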