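# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# Restores the caller's RNG state afterwards so library code never
# perturbs the session stream.  `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character vector, offset by an integer seed.
# Used for per-read tie-breaking so results do not depend on read order.
hash31 <- function(x, seed = 0L) {
  vapply(x, function(s) {
    h <- as.double(seed %% 2147483647L)
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Avalanche mixing of 31-bit hashes (multiply/xor-shift rounds, all exact
# in double precision) so that near-identical ids give unrelated uniforms.
mix31 <- function(h) {
  for (mult in c(69069, 48271, 40692)) {
    h <- (h * mult + 12345) %% 2147483647
    h <- as.double(bitwXor(as.integer(h), bitwShiftR(as.integer(h), 13)))
  }
  h
}

# Uniform variate in [0,1) from a string id + seed.  Cheap, deterministic,
# order-independent.  Repeated ids are hashed once.
hash_runif <- function(ids, seed = 0L) {
  u <- unique(ids)
  v <- mix31(as.double(hash31(u, seed))) / 2147483647
  v[match(ids, u)]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phred_to_char <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 0L), 93L)
  vapply(list(q), function(v) intToUtf8(v + 33L), character(1))
}

char_to_phred <- function(s) utf8ToInt(s) - 33L

`%||%` <- function(a, b) if (is.null(a)) b else a

# Concatenate a list of GRanges (c() does not S4-dispatch on a single
# unnamed argument).
cat_granges <- function(lst) {
  lst <- unname(lst)
  if (!length(lst)) return(GenomicRanges::GRanges())
  if (length(lst) == 1) return(lst[[1]])
  do.call(c, lst)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
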