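# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: fold a string tag into a 31-bit integer.
# Keeps independent stages (per condition, per dataset, per replicate) on
# distinct, reproducible streams derived from one master seed.
deriveSeed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Gene-id namespace of the synthetic universe: g0001, g0002, ...
geneIds <- function(n) sprintf("g%04d", seq_len(n))

# Sorted two-column character matrix -> canonical edge keys "a|b" with a < b.
edgeKeys <- function(from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  paste(a, b, sep = "|")
}

# All unordered pairs between two disjoint id vectors, as a 2-col matrix.
crossPairs <- function(x, y) {
  cbind(rep(x, times = length(y)), rep(y, each = length(x)))
}
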