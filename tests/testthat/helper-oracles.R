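## Independent brute-force oracles. These deliberately re-derive every
## quantity by plain enumeration/looping, sharing no code with the
## package internals they check.

## Exhaustive allele tally for one locus of a GenotypeTable.
oracleLocusFreqs <- function(tab, locus) {
  am <- alleleMatrices(tab)
  counts <- list()
  for (i in seq_len(nrow(am$a))) {
    for (al in c(am$a[i, locus], am$b[i, locus])) {
      if (is.na(al)) next
      key <- as.character(al)
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  v <- unlist(counts)
  v[order(as.integer(names(v)))] / sum(v)
}

## Mendelian transition probability for one locus by explicit
## enumeration of parental transmissions. o, d, s are length-2 vectors
## (d and/or s may be NULL = drawn from the population); p is a named
## frequency vector.
oracleTrans <- function(o, d, s, p) {
  alleles <- as.integer(names(p))
  same <- function(x, y) all(sort(x) == sort(y))
  tot <- 0
  if (!is.null(d) && !is.null(s)) {
    for (i in 1:2) for (j in 1:2)
      if (same(c(d[i], s[j]), o)) tot <- tot + 0.25
  } else if (!is.null(d) || !is.null(s)) {
    par <- if (!is.null(d)) d else s
    for (i in 1:2) for (k in seq_along(alleles))
      if (same(c(par[i], alleles[k]), o)) tot <- tot + 0.5 * p[[k]]
  } else {
    for (k1 in seq_along(alleles)) for (k2 in seq_along(alleles))
      if (same(c(alleles[k1], alleles[k2]), o)) tot <- tot + p[[k1]] * p[[k2]]
  }
  tot
}

oracleHW <- function(o, p) oracleTrans(o, NULL, NULL, p)

## Single-parent exclusion count by direct comparison.
oracleMismatch <- function(off, par) {
  n <- 0L
  for (l in seq_len(nrow(off))) {
    if (anyNA(off[l, ]) || anyNA(par[l, ])) next
    if (!any(par[l, ] %in% off[l, ])) n <- n + 1L
  }
  n
}

## Full categorical parentage posterior by direct enumeration.
## offspring: L x 2 matrix; dams/sires: lists of L x 2 matrices (named
## by candidate id); freqList: list of named frequency vectors.
## Returns a data.frame (dam, sire, posterior) over the post-filter
## hypothesis grid including the UNSAMPLED classes.
oraclePosterior <- function(offspring, dams, sires, freqList,
                            e = 0, wUd = NULL, wUs = NULL,
                            maxMismatch = 1L) {
  if (is.null(wUd)) wUd <- 0.5 * length(dams)
  if (is.null(wUs)) wUs <- 0.5 * length(sires)
  keep <- function(cands) {
    ok <- vapply(cands, function(g) {
      oracleMismatch(offspring, g) <= maxMismatch
    }, logical(1))
    cands[ok]
  }
  dams <- keep(dams)
  sires <- keep(sires)
  damIds <- c(names(dams), "UNSAMPLED")
  sireIds <- c(names(sires), "UNSAMPLED")
  lik <- function(d, s) {
    out <- 1
    for (l in seq_along(freqList)) {
      o <- offspring[l, ]
      if (anyNA(o)) next
      dl <- if (is.null(d)) NULL else d[l, ]
      sl <- if (is.null(s)) NULL else s[l, ]
      if ((!is.null(dl) && anyNA(dl)) || (!is.null(sl) && anyNA(sl)))
        next
      p <- freqList[[l]]
      lm <- oracleTrans(o, dl, sl, p)
      out <- out * ((1 - e) * lm + e * oracleHW(o, p))
    }
    out
  }
  rows <- list()
  for (di in damIds) for (si in sireIds) {
    d <- if (di == "UNSAMPLED") NULL else dams[[di]]
    s <- if (si == "UNSAMPLED") NULL else sires[[si]]
    prior <- (if (di == "UNSAMPLED") wUd else 1) *
      (if (si == "UNSAMPLED") wUs else 1)
    rows[[length(rows) + 1L]] <- data.frame(
      dam = di, sire = si, weight = prior * lik(d, s),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$posterior <- out$weight / sum(out$weight)
  out[, c("dam", "sire", "posterior")]
}

## Direct Poisson log-likelihood maximiser: Newton iteration on the
## two-parameter surface with the analytic gradient and Hessian,
## iterated to machine precision.
oraclePoissonFit <- function(y, x) {
  b <- c(log(mean(y) + 0.1), 0)
  X <- cbind(1, x)
  for (it in 1:200) {
    mu <- exp(X %*% b)
    grad <- t(X) %*% (y - mu)
    hess <- -t(X) %*% (X * as.vector(mu))
    step <- solve(hess, grad)
    b <- b - as.vector(step)
    if (max(abs(step)) < 1e-13) break
  }
  b
}
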