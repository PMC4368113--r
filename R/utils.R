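## Small internal helpers shared across modules.

MISSING_CODE <- 0L

#' @importFrom withr with_seed
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state; a NULL seed means "use the current stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

## Canonicalise a pair of allele matrices so that alleleA <= alleleB
## elementwise and half-called genotypes become fully MISSING.
.canonicalisePair <- function(a, b) {
  half <- xor(is.na(a), is.na(b))
  n_half <- sum(half)
  if (n_half > 0L) {
    warning(sprintf(
      "%d half-called genotype(s) coerced to missing", n_half),
      call. = FALSE)
    a[half] <- NA_integer_
    b[half] <- NA_integer_
  }
  swap <- !is.na(a) & !is.na(b) & a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  list(a = a, b = b)
}

## Zero-truncated Poisson sampler with a hard cap; parametrised by the
## truncated mean. Rejection sampling keeps the conditional distribution.
.rztpois <- function(n, mean, max) {
  stopifnot(mean > 1, max >= 1)
  f <- function(l) l / (1 - exp(-l)) - mean
  lambda <- stats::uniroot(f, c(1e-8, 1e3))$root
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rpois(length(todo), lambda)
    ok <- draw >= 1L & draw <= max
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

## Union-find with path compression, used for transitive closure of
## pairwise duplicate matches.
.unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1L])
      rj <- find(pairs[k, 2L])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
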